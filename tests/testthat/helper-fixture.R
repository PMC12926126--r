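# Shared fixtures, computed lazily and cached for the whole run.

.cache <- new.env(parent = emptyenv())

fixture_study <- function() {
  if (is.null(.cache$fx)) .cache$fx <- make_fixture_study(seed = 20260926)
  .cache$fx
}

# full pipeline on the packaged fixture: reconstruct, fit all families,
# select, run the cohort model under reference-case economics
fixture_cea <- function() {
  if (is.null(.cache$cea)) {
    fx <- fixture_study()
    ipds <- lapply(fx$curves, reconstruct_ipd)
    zoos <- lapply(ipds, fit_survival_zoo, quiet = TRUE)
    tabs <- lapply(zoos, information_table)
    sel <- vapply(tabs, select_best, character(1))
    fits <- Map(function(z, s) z[[s]], zoos, sel)
    .cache$zoo_tabs <- tabs
    .cache$selected <- sel
    .cache$fits <- fits
    .cache$cea <- run_cea(fits$treatment_PFS, fits$treatment_OS,
                          fits$control_PFS, fits$control_OS,
                          inputs = fx$inputs, settings = fx$settings)
  }
  .cache$cea
}

# a small, fast CEA built from closed-form exponential survival functions,
# for tests of the economics/uncertainty machinery that do not need the
# fitted fixture
toy_cea <- function(pap = FALSE) {
  key <- if (pap) "toy_pap" else "toy"
  if (is.null(.cache[[key]])) {
    S_pfs_t <- function(t) exp(-0.07 * t); S_os_t <- function(t) exp(-0.04 * t)
    S_pfs_c <- function(t) exp(-0.11 * t); S_os_c <- function(t) exp(-0.055 * t)
    inp <- economic_inputs(pap = pap)
    .cache[[key]] <- run_cea(S_pfs_t, S_os_t, S_pfs_c, S_os_c, inputs = inp)
  }
  .cache[[key]]
}

# simulated Weibull arm with censoring, for reconstruction round-trips
simulate_censored_weibull <- function(n, shape, median_m, seed,
                                      admin = 36, cens_frac = 0.2) {
  set.seed(seed)
  scale <- median_m / log(2)^(1 / shape)
  tt <- stats::rweibull(n, shape, scale)
  # exponential drop-out tuned to roughly the requested censoring share
  rate <- cens_frac / max(mean(tt), 1e-9)
  cc <- pmin(stats::rexp(n, rate), admin)
  pseudo_ipd(pmax(pmin(tt, cc), 1e-6), as.integer(tt <= cc))
}
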