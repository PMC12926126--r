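# Synthetic two-arm trial generator: arm- and endpoint-specific event-time
# distributions with within-subject PFS <= OS coupling, drop-out and
# administrative censoring, and emulation of figure digitization (click
# grid + at-risk table) so the whole pipeline is testable end to end.

#' Generating truth for the synthetic trial
#'
#' Distributions are parameterized by their median: control PFS Weibull
#' (median 6 months, shape 1.3), treatment PFS log-logistic (median 9,
#' shape 1.8), control OS Weibull (median 12, shape 1.3), treatment OS
#' log-normal (median 16, sdlog 0.8). 140/136 subjects per arm, uniform
#' recruitment over 18 months, administrative censoring at 36 months of
#' follow-up, exponential drop-out at 0.01/month. PFS and OS share a
#' comonotone uniform draw, so a subject's PFS never exceeds their OS.
#'
#' @param n_treatment,n_control Subjects per arm.
#' @param admin_censor_months Administrative censoring time.
#' @param recruit_months Uniform recruitment window (affects nothing under
#'   follow-up-time censoring but is kept for realism of at-risk decay).
#' @param dropout_rate Exponential drop-out rate per month.
#' @return List of class `truth_spec` with a `dist` entry per
#'   arm/endpoint: `list(family, median, shape)`.
#' @export
truth_spec <- function(n_treatment = 140, n_control = 136,
                       admin_censor_months = 36, recruit_months = 18,
                       dropout_rate = 0.01) {
  structure(list(
    n = c(treatment = n_treatment, control = n_control),
    admin_censor_months = admin_censor_months,
    recruit_months = recruit_months,
    dropout_rate = dropout_rate,
    dist = list(
      control_PFS = list(family = "weibull", median = 6, shape = 1.3),
      treatment_PFS = list(family = "llogis", median = 9, shape = 1.8),
      control_OS = list(family = "weibull", median = 12, shape = 1.3),
      treatment_OS = list(family = "lnorm", median = 16, shape = 0.8))),
    class = "truth_spec")
}

# quantile function of a median-parameterized family
truth_quantile <- function(d, u) {
  switch(d$family,
         weibull = stats::qweibull(u, d$shape, d$median / log(2)^(1 / d$shape)),
         llogis = d$median * (u / (1 - u))^(1 / d$shape),
         lnorm = stats::qlnorm(u, log(d$median), d$shape),
         exp = stats::qexp(u, log(2) / d$median),
         stop("unknown family ", d$family))
}

#' Simulate one arm/endpoint of pseudo-IPD
#'
#' Event times are drawn from the arm's generating distribution;
#' within-arm PFS and OS use a shared uniform draw (comonotone coupling),
#' and any residual PFS > OS (possible across different families) is
#' resolved as PFS = OS x Beta(4, 2) fraction. Censoring is the minimum
#' of administrative follow-up and exponential drop-out.
#'
#' @param spec A [truth_spec()].
#' @param arm `"treatment"` or `"control"`.
#' @param endpoint `"PFS"` or `"OS"`.
#' @param seed Integer seed; identical seeds give identical records (the
#'   per-subject uniform draws are shared across endpoints).
#' @return A [pseudo_ipd()].
#' @export
simulate_arm <- function(spec, arm = c("treatment", "control"),
                         endpoint = c("PFS", "OS"), seed = 1) {
  arm <- match.arg(arm); endpoint <- match.arg(endpoint)
  n <- spec$n[[arm]]
  stop_if(n <= 0, "empty arm")
  set.seed(seed)
  u <- stats::runif(n)                  # shared event-time draw (comonotone)
  u_drop <- stats::runif(n)
  u_beta <- stats::rbeta(n, 4, 2)
  t_os <- truth_quantile(spec$dist[[paste0(arm, "_OS")]], u)
  t_pfs <- truth_quantile(spec$dist[[paste0(arm, "_PFS")]], u)
  bad <- t_pfs > t_os
  t_pfs[bad] <- t_os[bad] * u_beta[bad]
  t_ev <- if (endpoint == "PFS") t_pfs else t_os
  t_drop <- -log(u_drop) / max(spec$dropout_rate, 1e-12)
  t_cens <- pmin(spec$admin_censor_months, t_drop)
  time <- pmin(t_ev, t_cens)
  event <- as.integer(t_ev <= t_cens)
  time <- pmax(time, 1e-6)
  pseudo_ipd(time, event, arm = arm, endpoint = endpoint)
}

#' Emulate figure digitization of a KM curve
#'
#' Evaluates the Kaplan-Meier estimator at the click grid (optionally
#' jittered by a seeded uniform error to emulate digitization noise,
#' then re-monotonized) and computes the at-risk table exactly.
#'
#' @param ipd A [pseudo_ipd()].
#' @param grid Click times (months, within the observed range).
#' @param risk_times At-risk table times (default every 3 months).
#' @param jitter Half-width of the uniform digitization error on the
#'   survival scale (0 = exact).
#' @param seed Seed for the jitter.
#' @return A [digitized_curve()].
#' @export
digitize_km <- function(ipd, grid = NULL, risk_times = NULL, jitter = 0,
                        seed = 1) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  tmax <- max(ipd$time)
  grid <- grid %||% seq(tmax / 60, tmax, length.out = 60)
  stop_if(length(grid) == 0, "empty click grid")
  risk_times <- risk_times %||% seq(0, tmax, by = 3)
  km <- km_estimate(ipd)
  s <- km_at(km, grid)
  if (jitter > 0) {
    set.seed(seed)
    s <- s + stats::runif(length(s), -jitter, jitter)
    s <- pmin(pmax(s, 0), 1)
    s <- cummin(s)                      # re-monotonize
  }
  n_risk <- vapply(risk_times, function(x) sum(ipd$time >= x), numeric(1))
  digitized_curve(c(0, grid), c(1, s), risk_times, n_risk,
                  arm = attr(ipd, "arm"), endpoint = attr(ipd, "endpoint"))
}

#' Build the packaged synthetic fixture study
#'
#' Simulates both arms and endpoints under the default [truth_spec()],
#' digitizes each curve (0.002 jitter), and bundles the reference-case
#' economics and model settings. Deterministic given the seed; optionally
#' written out as curve/risk CSVs plus `econ.yaml` and `truth.json`.
#'
#' @param seed Master seed.
#' @param dir Optional output directory for the fixture files.
#' @param spec A [truth_spec()].
#' @return List of class `fixture_bundle`: `curves` (4
#'   [digitized_curve()]), `ipd_truth` (4 [pseudo_ipd()]), `inputs`
#'   ([economic_inputs()]), `settings` ([model_settings()]), `seed`.
#' @export
make_fixture_study <- function(seed = 20260926, dir = NULL,
                               spec = truth_spec()) {
  combos <- expand.grid(arm = c("treatment", "control"),
                        endpoint = c("PFS", "OS"),
                        stringsAsFactors = FALSE)
  curves <- list(); ipds <- list()
  for (i in seq_len(nrow(combos))) {
    arm <- combos$arm[i]; ep <- combos$endpoint[i]
    # endpoints share the arm's subject-level draws via a common seed
    ipd <- simulate_arm(spec, arm, ep,
                        seed = seed + match(arm, c("treatment", "control")))
    key <- paste(arm, ep, sep = "_")
    ipds[[key]] <- ipd
    curves[[key]] <- digitize_km(ipd, jitter = 0.002, seed = seed + 10 + i)
  }
  bundle <- structure(
    list(curves = curves, ipd_truth = ipds,
         inputs = economic_inputs(), settings = model_settings(),
         seed = seed),
    class = "fixture_bundle")
  if (!is.null(dir)) write_fixture(bundle, dir)
  bundle
}

write_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(bundle$curves)) {
    write_digitized_curve(bundle$curves[[key]],
                          file.path(dir, paste0(key, "_curve.csv")),
                          file.path(dir, paste0(key, "_risk.csv")))
  }
  write_econ_yaml(bundle$inputs, file.path(dir, "econ.yaml"))
  jsonlite::write_json(list(seed = bundle$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(bundle)
}

#' Write economic inputs to YAML
#'
#' @param inputs An [economic_inputs()].
#' @param file Output path.
#' @export
write_econ_yaml <- function(inputs, file) {
  spec <- inputs$spec
  rows <- lapply(seq_len(nrow(spec)), function(i)
    list(mean = spec$base[i], lower = spec$lower[i], upper = spec$upper[i],
         distribution = spec$dist[i], role = spec$role[i]))
  names(rows) <- spec$name
  yaml::write_yaml(list(
    parameters = rows,
    profile = list(ref_weight_kg = inputs$profile$ref_weight_kg,
                   height_cm = inputs$profile$height_cm,
                   weight_loss = inputs$profile$weight_loss),
    scenario = list(pap = inputs$pap, price_fraction = inputs$price_fraction,
                    monitoring_every_n_cycles = inputs$monitoring_every_n_cycles,
                    wtp = inputs$wtp)), file)
  invisible(inputs)
}

#' Read economic inputs from YAML
#'
#' @param file Path written by [write_econ_yaml()].
#' @return An [economic_inputs()].
#' @export
read_econ_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  prof <- patient_profile(y$profile$ref_weight_kg %||% 66.9,
                          y$profile$height_cm %||% 163.5,
                          y$profile$weight_loss %||% 0.10)
  inp <- economic_inputs(
    profile = prof,
    pap = isTRUE(y$scenario$pap),
    price_fraction = y$scenario$price_fraction %||% 1,
    monitoring_every_n_cycles = y$scenario$monitoring_every_n_cycles %||% 1,
    wtp = y$scenario$wtp %||% 40457.32)
  if (!is.null(y$parameters)) {
    for (nm in names(y$parameters)) {
      if (nm %in% names(inp$params) && nm != "cost_combo_cycle") {
        inp$params[[nm]] <- y$parameters[[nm]]$mean
        i <- match(nm, inp$spec$name)
        inp$spec$base[i] <- y$parameters[[nm]]$mean
        inp$spec$lower[i] <- y$parameters[[nm]]$lower %||% inp$spec$lower[i]
        inp$spec$upper[i] <- y$parameters[[nm]]$upper %||% inp$spec$upper[i]
      }
    }
  }
  inp
}
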