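# Shared constants and small helpers.

DAYS_PER_MONTH <- 365.25 / 12
DAYS_PER_YEAR <- 365.25
CYCLE_DAYS <- 28
CYCLE_MONTHS <- CYCLE_DAYS / DAYS_PER_MONTH
CYCLE_YEARS <- CYCLE_DAYS / DAYS_PER_YEAR

#' Canonical survival family names
#'
#' The fifteen families fitted by [fit_survival()], in the fixed order used
#' for reporting and for tie-breaking in [select_best()].
#'
#' @return Character vector of length 15.
#' @export
surv_families <- function() {
  c("Exponential", "Weibull", "Gamma", "Log-normal", "Gompertz",
    "Log-logistic", "GeneralizedGamma", "FP1", "FP2", "RCS",
    "RP-hazard", "RP-odds", "RP-normal", "GAM", "MCM")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
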