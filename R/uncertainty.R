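# Uncertainty analysis: one-way sensitivity (tornado), moment-matched
# probabilistic sensitivity analysis, acceptability curve, and threshold
# price search for the high-cost biologic.

#' Moment-match a parameter to its sampling distribution
#'
#' The 95% bounds give `SE = (upper - lower) / 3.92`. Gamma:
#' `shape = mean^2/SE^2`, `scale = SE^2/mean`. Beta:
#' `alpha = mean * (mean(1-mean)/SE^2 - 1)`, `beta = (1-mean) * (same)`.
#' A zero SE degenerates to a fixed parameter.
#'
#' @param base,lower,upper Mean and 95% bounds.
#' @param dist `"Gamma"`, `"Beta"` or `"Fixed"`.
#' @return List with `dist` and its parameters (`shape`/`scale` or
#'   `alpha`/`beta`, or `value` for Fixed).
#' @export
moment_match <- function(base, lower, upper, dist = c("Gamma", "Beta", "Fixed")) {
  dist <- match.arg(dist)
  se <- (upper - lower) / 3.92
  if (dist == "Fixed" || se <= 0 || base == 0) {
    return(list(dist = "Fixed", value = base))
  }
  if (dist == "Gamma") {
    stop_if(base < 0, "Gamma-distributed parameter must be non-negative")
    return(list(dist = "Gamma", shape = base^2 / se^2, scale = se^2 / base))
  }
  stop_if(base < 0 || base > 1, "Beta-distributed parameter outside [0, 1]")
  v <- se^2
  stop_if(v >= base * (1 - base), "Beta moment matching infeasible: SE too large")
  f <- base * (1 - base) / v - 1
  list(dist = "Beta", alpha = base * f, beta = (1 - base) * f)
}

sample_param <- function(mm, n) {
  switch(mm$dist,
         Fixed = rep(mm$value, n),
         Gamma = stats::rgamma(n, shape = mm$shape, scale = mm$scale),
         Beta = stats::rbeta(n, mm$alpha, mm$beta))
}

MIX_GROUPS <- list(
  treatment = c("mix_t_folfiri", "mix_t_tas", "mix_t_bsc", "mix_t_folfox"),
  control = c("mix_c_combo", "mix_c_folfiri", "mix_c_bsc"))

#' One-way sensitivity analysis (tornado)
#'
#' Each parameter is set to its lower then upper bound with all others at
#' base, and the ICER recomputed on the fixed cohort traces. Mix
#' proportions are renormalized within their arm after the perturbation;
#' utilities are capped at 1. Entries are sorted by descending ICER range.
#'
#' @param cea A fitted [run_cea()] model.
#' @param spec Parameter specification table (default: the model's own);
#'   must have columns `name`, `base`, `lower`, `upper`.
#' @return Class `tornado`: data.frame `parameter`, `icer_low`,
#'   `icer_high`, `width`, plus `base_icer` attribute.
#' @export
owsa <- function(cea, spec = NULL) {
  stopifnot(inherits(cea, "cea"))
  spec <- spec %||% cea$inputs$spec
  base_p <- cea$inputs$params
  stop_if(!all(spec$name %in% names(base_p)),
          paste("unknown parameter(s):",
                paste(setdiff(spec$name, names(base_p)), collapse = ", ")))
  base_icer <- cea$result$icer
  eval_at <- function(nm, value) {
    p <- base_p
    p[[nm]] <- value
    if (grepl("^u_", nm)) p[[nm]] <- min(p[[nm]], 1)
    for (g in MIX_GROUPS) if (nm %in% g) p[g] <- p[g] / sum(p[g])
    reaccumulate(cea, p)$icer
  }
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    nm <- spec$name[i]
    lo <- eval_at(nm, spec$lower[i])
    hi <- eval_at(nm, spec$upper[i])
    data.frame(parameter = nm, icer_low = lo, icer_high = hi,
               width = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  class(out) <- c("tornado", "data.frame")
  out
}

#' @export
plot.tornado <- function(x, top = 12, ...) {
  x <- utils::head(x, top)
  x <- x[rev(seq_len(nrow(x))), ]
  base <- attr(x, "base_icer")
  graphics::par(mar = c(4, 12, 2, 1))
  graphics::plot(NULL, xlim = range(c(x$icer_low, x$icer_high, base)),
                 ylim = c(0.5, nrow(x) + 0.5), yaxt = "n",
                 xlab = "ICER (USD/QALY)", ylab = "", main = "One-way sensitivity")
  graphics::segments(x$icer_low, seq_len(nrow(x)), x$icer_high, lwd = 8,
                     col = "steelblue")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(x)), labels = x$parameter, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo sampling of the economic parameters (Gamma for costs, Beta
#' for probabilities/utilities via [moment_match()]); the cohort traces
#' (and by default the discount rate) stay at base. Mix proportions are
#' renormalized per draw. Draws yielding non-finite outcomes are rejected
#' and resampled.
#'
#' @param cea A fitted [run_cea()] model.
#' @param n_draws Number of draws (reference case 1000).
#' @param seed Master seed; the draw sequence is reproducible given it.
#' @param include_discount Also sample the discount rate (default FALSE:
#'   reference-case discounting convention).
#' @return Class `psa_result`: data.frame `draw`, `dcost`, `dqaly` with
#'   attributes `seed`, `n_rejected`, `wtp`.
#' @export
psa <- function(cea, n_draws = 1000, seed = 1, include_discount = FALSE) {
  stopifnot(inherits(cea, "cea"))
  spec <- cea$inputs$spec
  base_p <- cea$inputs$params
  set.seed(seed)
  mms <- lapply(seq_len(nrow(spec)), function(i)
    moment_match(base_p[[spec$name[i]]], spec$lower[i], spec$upper[i], spec$dist[i]))
  names(mms) <- spec$name
  if (!include_discount) mms[["discount_rate"]] <- list(dist = "Fixed",
                                                        value = base_p[["discount_rate"]])
  # combo cycle cost is sampled around its (possibly scenario-adjusted) base
  draw_matrix <- function(n) {
    m <- vapply(mms, sample_param, numeric(n), n = n)
    if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(mms)))
    m
  }
  res <- matrix(NA_real_, n_draws, 2)
  n_rej <- 0L
  filled <- 0L
  while (filled < n_draws) {
    m <- draw_matrix(n_draws - filled)
    for (j in seq_len(nrow(m))) {
      p <- base_p
      p[colnames(m)] <- m[j, ]
      for (g in MIX_GROUPS) if (sum(p[g]) > 0) p[g] <- p[g] / sum(p[g])
      r <- reaccumulate(cea, p)
      if (is.finite(r$delta_cost) && is.finite(r$delta_qalys)) {
        filled <- filled + 1L
        res[filled, ] <- c(r$delta_cost, r$delta_qalys)
      } else {
        n_rej <- n_rej + 1L
        stop_if(n_rej > 10 * n_draws, "PSA rejection rate too high")
      }
    }
  }
  out <- data.frame(draw = seq_len(n_draws), dcost = res[, 1], dqaly = res[, 2])
  attr(out, "seed") <- seed
  attr(out, "n_rejected") <- n_rej
  attr(out, "wtp") <- cea$inputs$wtp
  class(out) <- c("psa_result", "data.frame")
  out
}

#' @export
plot.psa_result <- function(x, wtp = attr(x, "wtp"), ...) {
  graphics::plot(x$dqaly, x$dcost, pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = "Incremental QALYs", ylab = "Incremental cost (USD)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(0, wtp, lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention is cost-effective,
#' `P(lambda * dE - dC > 0)`, over a willingness-to-pay grid.
#'
#' @param psa_result A [psa()] result.
#' @param wtp_grid Vector of thresholds (USD/QALY).
#' @return Class `ceac`: data.frame `wtp`, `p_ce`.
#' @export
ceac <- function(psa_result, wtp_grid = seq(0, 200000, by = 5000)) {
  stopifnot(inherits(psa_result, "psa_result"))
  stop_if(length(wtp_grid) == 0, "empty WTP grid")
  stop_if(nrow(psa_result) == 0, "no PSA draws")
  p <- vapply(wtp_grid, function(l)
    mean(l * psa_result$dqaly - psa_result$dcost > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, p_ce = p),
            class = c("ceac", "data.frame"))
}

#' @export
plot.ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$p_ce, type = "l", ylim = c(0, 1),
                 xlab = "Willingness to pay (USD/QALY)",
                 ylab = "P(cost-effective)",
                 main = "Cost-effectiveness acceptability curve", ...)
  invisible(x)
}

#' Threshold price search for ramucirumab
#'
#' Bisection on the nominal-price fraction `f` in `[0, 1]` until the ICER
#' meets the willingness-to-pay target within 0.5 USD/QALY, exploiting
#' monotonicity of the ICER in the price. The fraction rescales the
#' nominal unit price wherever ramucirumab is bought; under the
#' assistance-program scenario the intervention arm additionally keeps
#' its 2/3 effective-price factor.
#'
#' @param cea A fitted [run_cea()] model (at `price_fraction = 1`).
#' @param target Willingness-to-pay target (default: the model's WTP).
#' @param tol Convergence tolerance on `|ICER - target|`, USD/QALY.
#' @return List `fraction`, `price_per_100mg`, `icer`, `iterations`; or,
#'   when no fraction in `[0, 1]` meets the target, `fraction = NA` with a
#'   `boundary` message.
#' @export
threshold_price <- function(cea, target = NULL, tol = 0.5) {
  stopifnot(inherits(cea, "cea"))
  target <- target %||% cea$inputs$wtp
  icer_at <- function(f) {
    inp <- cea$inputs
    inp$price_fraction <- f
    cea2 <- cea
    cea2$inputs <- inp
    reaccumulate(cea2, inp$params)$icer
  }
  i0 <- icer_at(0); i1 <- icer_at(1)
  if (is.na(i0) || is.na(i1)) return(list(fraction = NA_real_, boundary = "undefined ICER"))
  if (i1 <= target) {
    return(list(fraction = 1, price_per_100mg = RAM_PRICE_PER_100MG,
                icer = i1, iterations = 0L,
                boundary = "already cost-effective at nominal price"))
  }
  if (i0 > target) {
    return(list(fraction = NA_real_, icer_at_zero = i0,
                boundary = "no price in [0, 1] meets the target"))
  }
  lo <- 0; hi <- 1; it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    im <- icer_at(mid)
    if (abs(im - target) < tol || it >= 100L) break
    if (im > target) hi <- mid else lo <- mid
  }
  list(fraction = mid, price_per_100mg = mid * RAM_PRICE_PER_100MG,
       icer = im, iterations = it)
}
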