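# Three-state Markov cohort model (progression-free, progressed, dead):
# time-dependent transition probabilities from the two survival functions,
# discounted cost and QALY accumulation, and the incremental comparison.

#' Markov model settings
#'
#' 28-day cycles over a 10-year horizon (130 cycles), annual discounting
#' at 5%, willingness-to-pay threshold of 40,457.32 USD/QALY (three times
#' 2024 per-capita GDP), no half-cycle correction in the reference case.
#'
#' @param horizon_years Model horizon.
#' @param cycle_days Cycle length in days.
#' @param discount_rate Annual discount rate in `[0, 1]`.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @param half_cycle Apply half-cycle correction to state membership.
#' @return List of class `model_settings`, with `n_cycles` derived as
#'   `floor(horizon_days / cycle_days)`.
#' @export
model_settings <- function(horizon_years = 10, cycle_days = 28,
                           discount_rate = 0.05, wtp = 40457.32,
                           half_cycle = FALSE) {
  stop_if(discount_rate < 0 || discount_rate > 1, "discount rate outside [0, 1]")
  stop_if(wtp <= 0, "WTP must be positive")
  n_cycles <- floor(horizon_years * DAYS_PER_YEAR / cycle_days + 1e-9)
  structure(list(horizon_years = horizon_years, cycle_days = cycle_days,
                 n_cycles = n_cycles, discount_rate = discount_rate,
                 wtp = wtp, half_cycle = half_cycle),
            class = "model_settings")
}

#' Per-cycle discount factor
#'
#' `(1 + r)^(-cycle * cycle_days / 365.25)`.
#'
#' @param cycle Cycle index `>= 0`.
#' @param r Annual discount rate.
#' @param cycle_days Cycle length in days.
#' @return Factor in `(0, 1]`.
#' @export
discount_factor <- function(cycle, r, cycle_days = CYCLE_DAYS) {
  stop_if(any(cycle < 0), "negative cycle index")
  stop_if(r < 0, "negative discount rate")
  (1 + r)^(-cycle * cycle_days / DAYS_PER_YEAR)
}

#' Transition probabilities for one cycle
#'
#' Death claims occupants of both alive states at the overall-survival
#' hazard, `q_death = 1 - S_os(t+1)/S_os(t)`; progression is the residual
#' of leaving the progression-free state,
#' `p(PFS->PD) = max(0, q_exit - q_death)` with
#' `q_exit = 1 - S_pfs(t+1)/S_pfs(t)`. Probabilities are clamped to
#' `[0, 1]` and rows always sum to one; a PFS curve sitting above the OS
#' curve triggers clamping (logged via attribute) rather than an error.
#'
#' @param cycle Cycle index `t >= 0` (transition from `t` to `t+1`).
#' @param S_pfs,S_os Survival functions of time in months.
#' @param cycle_days Cycle length in days.
#' @return 3x3 transition matrix, states `c("PFS", "PD", "Death")`, with
#'   attribute `clamped` (logical).
#' @export
transition_probs_at <- function(cycle, S_pfs, S_os, cycle_days = CYCLE_DAYS) {
  stop_if(cycle < 0, "negative cycle")
  m <- cycle_days / DAYS_PER_MONTH
  t0 <- cycle * m; t1 <- (cycle + 1) * m
  sp0 <- S_pfs(t0); sp1 <- S_pfs(t1)
  so0 <- S_os(t0); so1 <- S_os(t1)
  stop_if(any(!is.finite(c(sp0, sp1, so0, so1))),
          sprintf("non-finite survival at cycle %d", cycle))
  stop_if(so0 <= 0 && so1 > 0, "OS survival rises from zero")
  stop_if(sp0 <= 0 && sp1 > 0, "PFS survival rises from zero")
  q_death <- if (so0 > 0) 1 - so1 / so0 else 1
  q_exit <- if (sp0 > 0) 1 - sp1 / sp0 else 1
  q_death <- min(max(q_death, 0), 1)
  q_exit <- min(max(q_exit, 0), 1)
  clamped <- q_exit < q_death
  p_pd <- max(0, q_exit - q_death)
  p_stay <- min(max(1 - p_pd - q_death, 0), 1)
  P <- matrix(c(p_stay, p_pd, q_death,
                0, 1 - q_death, q_death,
                0, 0, 1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("PFS", "PD", "Death"), c("PFS", "PD", "Death")))
  attr(P, "clamped") <- clamped
  P
}

#' Run the Markov cohort
#'
#' Everyone starts progression-free; occupancy is propagated through the
#' per-cycle transition matrices. Absent clamping, death occupancy at
#' cycle t equals `1 - S_os(t)` exactly.
#'
#' @param S_pfs,S_os Survival functions of time in months.
#' @param settings A [model_settings()].
#' @return Class `cohort_trace`: data.frame with columns `cycle`, `pfs`,
#'   `pd`, `death`, `incident_deaths`, `incident_progressions` for cycles
#'   `0..n_cycles`; attribute `clamped_cycles` lists cycles where the
#'   progression residual was clamped.
#' @export
run_cohort <- function(S_pfs, S_os, settings = model_settings()) {
  n <- settings$n_cycles
  occ <- matrix(0, n + 1, 3, dimnames = list(NULL, c("PFS", "PD", "Death")))
  occ[1, ] <- c(1, 0, 0)
  inc_d <- inc_p <- numeric(n + 1)
  clamped <- integer(0)
  for (t in seq_len(n)) {
    P <- transition_probs_at(t - 1, S_pfs, S_os, settings$cycle_days)
    if (attr(P, "clamped")) clamped <- c(clamped, t - 1L)
    occ[t + 1, ] <- occ[t, ] %*% P
    inc_d[t + 1] <- occ[t + 1, "Death"] - occ[t, "Death"]
    inc_p[t + 1] <- occ[t, "PFS"] * P["PFS", "PD"]
  }
  out <- data.frame(cycle = 0:n, pfs = occ[, 1], pd = occ[, 2],
                    death = occ[, 3], incident_deaths = inc_d,
                    incident_progressions = inc_p)
  attr(out, "clamped_cycles") <- clamped
  class(out) <- c("cohort_trace", "data.frame")
  out
}

#' Accumulate discounted costs and QALYs along a trace
#'
#' Per cycle: on-treatment drug cost while progression-free (intervention:
#' the combination every cycle; control: oxaliplatin doublet for cycles
#' 1-3, fluoropyrimidine maintenance thereafter), post-progression mix
#' cost per progressed cycle (optionally duration-capped), monitoring
#' cost for both alive states, end-of-life cost on incident deaths, and
#' utility-weighted time in state. One-off adverse-event cost and
#' disutility are charged at model entry.
#'
#' @param trace A [run_cohort()] trace.
#' @param inputs An [economic_inputs()].
#' @param arm `"treatment"` or `"control"`.
#' @param settings A [model_settings()].
#' @param params Optional parameter vector overriding `inputs$params`
#'   (used by the sensitivity analyses).
#' @return List with discounted `cost` (USD) and `qalys`.
#' @export
accumulate <- function(trace, inputs, arm = c("treatment", "control"),
                       settings = model_settings(), params = NULL) {
  arm <- match.arg(arm)
  stopifnot(inherits(trace, "cohort_trace"), inherits(inputs, "econ_inputs"))
  p <- params %||% inputs$params
  r <- if (!is.null(params)) params[["discount_rate"]] else settings$discount_rate
  n <- settings$n_cycles
  tcyc <- seq_len(n)
  df <- discount_factor(tcyc, r, settings$cycle_days)
  pfs <- trace$pfs[tcyc + 1]; pd <- trace$pd[tcyc + 1]
  if (isTRUE(settings$half_cycle)) {
    pfs <- (trace$pfs[tcyc] + trace$pfs[tcyc + 1]) / 2
    pd <- (trace$pd[tcyc] + trace$pd[tcyc + 1]) / 2
  }
  inc_d <- trace$incident_deaths[tcyc + 1]

  cc <- combo_costs(inputs, p)
  if (arm == "treatment") {
    drug <- rep(cc$on_treatment, n)
    mix_p <- p[c("mix_t_folfiri", "mix_t_tas", "mix_t_bsc", "mix_t_folfox")]
    mix_c <- c(p[["cost_folfiri_cycle"]], p[["cost_tas_cycle"]],
               p[["cost_bsc_cycle"]], p[["cost_folfox_cycle"]])
  } else {
    drug <- c(rep(p[["cost_folfox_cycle"]], min(3, n)),
              rep(p[["cost_5fu_cycle"]], max(0, n - 3)))
    mix_p <- p[c("mix_c_combo", "mix_c_folfiri", "mix_c_bsc")]
    mix_c <- c(cc$pd_mix, p[["cost_folfiri_cycle"]], p[["cost_bsc_cycle"]])
  }
  mix_p <- mix_p / sum(mix_p)
  pd_cost <- pd_mix_cost(mix_p, mix_c)

  # progressed occupancy still on subsequent-line treatment: capped by
  # time since progression when requested (death-only exit after entry)
  pd_on_tx <- pd
  cap <- inputs$pd_cost_cap
  if (is.finite(cap) && cap < n) {
    surv_ratio <- (1 - trace$death)
    pd_on_tx <- vapply(tcyc, function(t) {
      ages <- 0:min(cap - 1, t - 1)
      entr <- trace$incident_progressions[t - ages + 1]
      alive_frac <- ifelse(surv_ratio[t - ages + 1] > 0,
                           surv_ratio[t + 1] / surv_ratio[t - ages + 1], 0)
      sum(entr * pmin(alive_frac, 1))
    }, numeric(1))
    pd_on_tx <- pmin(pd_on_tx, pd)
  }

  every <- inputs$monitoring_every_n_cycles
  monitor <- ifelse(tcyc %% every == 0, p[["cost_lab"]] + p[["cost_imaging"]], 0)

  costs <- drug * pfs + pd_cost * pd_on_tx + monitor * (pfs + pd) +
    p[["cost_eol"]] * inc_d
  stop_if(any(costs < -1e-9), "negative per-cycle cost component")
  ae <- ae_burden(p, arm)
  total_cost <- sum(df * costs) + ae$cost
  qalys <- sum(df * (pfs * p[["u_pfs"]] + pd * p[["u_pd"]])) * CYCLE_YEARS -
    ae$qaly_loss
  list(cost = total_cost, qalys = qalys)
}

#' Incremental cost-effectiveness comparison
#'
#' @param treated,control Lists with `cost` and `qalys`.
#' @param wtp Willingness-to-pay threshold for the verdict.
#' @return Class `cea_result`: per-arm totals, `delta_cost`,
#'   `delta_qalys`, `icer` (`NA` when the effect difference is zero),
#'   `dominance` in `{"dominant", "dominated", "tradeoff"}`, and the WTP
#'   verdict.
#' @export
icer <- function(treated, control, wtp = 40457.32) {
  dc <- treated$cost - control$cost
  de <- treated$qalys - control$qalys
  stop_if(any(!is.finite(c(dc, de))), "non-finite totals")
  dominance <- if (dc <= 0 && de >= 0 && (dc < 0 || de > 0)) "dominant"
  else if (dc >= 0 && de <= 0 && (dc > 0 || de < 0)) "dominated"
  else "tradeoff"
  ic <- if (de != 0) dc / de else NA_real_
  verdict <- if (dominance == "dominant") "cost-effective"
  else if (dominance == "dominated") "not cost-effective"
  else if (!is.na(ic) && ic <= wtp) "cost-effective" else "not cost-effective"
  structure(list(treated = treated, control = control,
                 delta_cost = dc, delta_qalys = de, icer = ic,
                 dominance = dominance, wtp = wtp, verdict = verdict),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness comparison\n")
  cat(sprintf("  %-10s cost %12.2f USD   effect %6.2f QALYs\n", "treatment",
              x$treated$cost, x$treated$qalys))
  cat(sprintf("  %-10s cost %12.2f USD   effect %6.2f QALYs\n", "control",
              x$control$cost, x$control$qalys))
  cat(sprintf("  delta cost %.2f USD, delta effect %.2f QALYs\n",
              x$delta_cost, x$delta_qalys))
  if (x$dominance == "tradeoff" && !is.na(x$icer)) {
    cat(sprintf("  ICER %.2f USD/QALY (WTP %.2f): %s\n", x$icer, x$wtp, x$verdict))
  } else {
    cat(sprintf("  %s (WTP %.2f): %s\n", x$dominance, x$wtp, x$verdict))
  }
  invisible(x)
}

#' Fit the full cost-effectiveness model
#'
#' The central model constructor: takes the four selected survival
#' functions (or `surv_fit` objects), runs the cohort per arm, and
#' accumulates discounted totals under the given economics and scenario.
#'
#' @param S_pfs_t,S_os_t,S_pfs_c,S_os_c Survival functions of months (or
#'   `surv_fit` objects) for treatment/control PFS/OS.
#' @param inputs An [economic_inputs()].
#' @param settings A [model_settings()].
#' @return Class `cea`: contains `result` (a [icer()] `cea_result`),
#'   per-arm traces, inputs and settings. Methods: `print`, `summary`.
#' @export
run_cea <- function(S_pfs_t, S_os_t, S_pfs_c, S_os_c,
                    inputs = economic_inputs(), settings = model_settings()) {
  inputs$params[["discount_rate"]] <- settings$discount_rate
  as_fn <- function(s) if (inherits(s, "surv_fit")) function(t) survival_at(s, t) else s
  S_pfs_t <- as_fn(S_pfs_t); S_os_t <- as_fn(S_os_t)
  S_pfs_c <- as_fn(S_pfs_c); S_os_c <- as_fn(S_os_c)
  tr_t <- run_cohort(S_pfs_t, S_os_t, settings)
  tr_c <- run_cohort(S_pfs_c, S_os_c, settings)
  out_t <- accumulate(tr_t, inputs, "treatment", settings)
  out_c <- accumulate(tr_c, inputs, "control", settings)
  structure(
    list(result = icer(out_t, out_c, wtp = inputs$wtp),
         trace_treatment = tr_t, trace_control = tr_c,
         inputs = inputs, settings = settings,
         survival = list(pfs_t = S_pfs_t, os_t = S_os_t,
                         pfs_c = S_pfs_c, os_c = S_os_c)),
    class = "cea")
}

#' @export
print.cea <- function(x, ...) {
  cat(sprintf("Markov cohort CEA: %d cycles of %g days, discount %.1f%%\n",
              x$settings$n_cycles, x$settings$cycle_days,
              100 * x$settings$discount_rate))
  if (isTRUE(x$inputs$pap)) cat("  scenario: patient assistance program\n")
  if (x$inputs$price_fraction != 1) {
    cat(sprintf("  scenario: ramucirumab at %.0f%% of nominal price\n",
                100 * x$inputs$price_fraction))
  }
  print(x$result)
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  res <- object$result
  tab <- data.frame(
    group = c("Treatment", "Control"),
    total_cost = c(res$treated$cost, res$control$cost),
    qalys = c(res$treated$qalys, res$control$qalys),
    delta_cost = c(res$delta_cost, NA),
    delta_qalys = c(res$delta_qalys, NA),
    icer = c(res$icer, NA))
  print(x_fmt <- within(tab, {
    total_cost <- round(total_cost, 2); qalys <- round(qalys, 2)
    delta_cost <- round(delta_cost, 2); delta_qalys <- round(delta_qalys, 2)
    icer <- round(icer, 2)
  }), row.names = FALSE)
  invisible(tab)
}

# re-evaluate totals for new parameter values on the fixed traces
reaccumulate <- function(cea, params) {
  out_t <- accumulate(cea$trace_treatment, cea$inputs, "treatment",
                      cea$settings, params = params)
  out_c <- accumulate(cea$trace_control, cea$inputs, "control",
                      cea$settings, params = params)
  icer(out_t, out_c, wtp = cea$inputs$wtp)
}
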