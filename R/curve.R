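# Digitized Kaplan-Meier curves: container, validation, CSV input.

#' Construct a digitized Kaplan-Meier curve
#'
#' Bundles digitized survival-curve coordinates with the matching
#' numbers-at-risk table for one arm and endpoint. Times are in months.
#' Validation enforces the structure a published KM figure must have:
#' the curve starts at (0, 1), survival is non-increasing, at-risk counts
#' are non-increasing, and times are strictly increasing. Tiny upticks in
#' survival (at most `1e-6`, digitization jitter) are clamped to the
#' previous value; larger increases are errors.
#'
#' @param time Numeric vector of click times (months, >= 0).
#' @param survival Numeric vector of survival probabilities in `[0, 1]`.
#' @param risk_time Numeric vector of at-risk table times (months).
#' @param n_risk Integer vector of numbers at risk at `risk_time`.
#' @param arm Arm label.
#' @param endpoint Endpoint label, `"PFS"` or `"OS"`.
#' @param total_events Optional total event count used to rescale events in
#'   the final reconstruction interval; default `NULL` (unknown).
#' @return An object of class `digitized_curve` with elements `points`
#'   (data.frame `time`, `survival`), `risk` (data.frame `time`, `n_risk`),
#'   `arm`, `endpoint`, `total_events`.
#' @seealso [read_digitized_curve()], [reconstruct_ipd()]
#' @export
digitized_curve <- function(time, survival, risk_time, n_risk,
                            arm = "arm", endpoint = "OS",
                            total_events = NULL) {
  stop_if(length(time) != length(survival), "time and survival lengths differ")
  stop_if(length(risk_time) != length(n_risk), "risk_time and n_risk lengths differ")
  stop_if(length(risk_time) < 1L, "risk table needs at least one row")
  ord <- order(time)
  time <- time[ord]; survival <- survival[ord]
  # collapse duplicate times, keeping the last digitized value
  keep <- !duplicated(time, fromLast = TRUE)
  time <- time[keep]; survival <- survival[keep]

  stop_if(any(time < 0), "negative click time")
  stop_if(any(survival < -1e-9 | survival > 1 + 1e-9), "survival outside [0, 1]")
  survival <- pmin(pmax(survival, 0), 1)

  if (time[1] != 0 || abs(survival[1] - 1) > 1e-9) {
    warning("curve does not start at (0, 1); anchor inserted", call. = FALSE)
    if (time[1] == 0) {
      survival[1] <- 1
    } else {
      time <- c(0, time); survival <- c(1, survival)
    }
  }
  # monotonicity with jitter clamp
  for (k in seq_along(survival)[-1]) {
    if (survival[k] > survival[k - 1]) {
      stop_if(survival[k] - survival[k - 1] > 1e-6,
              sprintf("survival increases at row %d (t = %g): %.6f -> %.6f",
                      k, time[k], survival[k - 1], survival[k]))
      survival[k] <- survival[k - 1]
    }
  }

  ordr <- order(risk_time)
  risk_time <- risk_time[ordr]; n_risk <- n_risk[ordr]
  stop_if(anyDuplicated(risk_time) > 0, "duplicate risk-table times")
  stop_if(any(n_risk < 0) || any(n_risk != round(n_risk)),
          "at-risk counts must be non-negative integers")
  stop_if(any(diff(n_risk) > 0), "at-risk counts must be non-increasing")
  if (!is.null(total_events)) {
    stop_if(total_events < 0 || total_events != round(total_events),
            "total_events must be a non-negative integer")
  }

  structure(
    list(points = data.frame(time = time, survival = survival),
         risk = data.frame(time = risk_time, n_risk = as.integer(n_risk)),
         arm = arm, endpoint = endpoint, total_events = total_events),
    class = "digitized_curve")
}

#' Read a digitized curve from CSV files
#'
#' `curve_file` must have columns `time_months,survival`; `risk_file` must
#' have columns `time_months,n_risk`. Rows are sorted, duplicate times are
#' collapsed (last value kept), and a missing (0, 1) anchor is inserted with
#' a warning.
#'
#' @inheritParams digitized_curve
#' @param curve_file,risk_file Paths to the two CSV files.
#' @return A [digitized_curve()] object.
#' @export
read_digitized_curve <- function(curve_file, risk_file, arm = "arm",
                                 endpoint = "OS", total_events = NULL) {
  stop_if(!file.exists(curve_file), "curve file not found: ", curve_file)
  stop_if(!file.exists(risk_file), "risk file not found: ", risk_file)
  cv <- utils::read.csv(curve_file)
  rk <- utils::read.csv(risk_file)
  stop_if(!all(c("time_months", "survival") %in% names(cv)),
          "curve CSV must have columns time_months,survival")
  stop_if(!all(c("time_months", "n_risk") %in% names(rk)),
          "risk CSV must have columns time_months,n_risk")
  digitized_curve(cv$time_months, cv$survival, rk$time_months, rk$n_risk,
                  arm = arm, endpoint = endpoint, total_events = total_events)
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("Digitized KM curve: %s / %s\n", x$arm, x$endpoint))
  cat(sprintf("  %d click points over [0, %g] months; %d at-risk times (n0 = %d)\n",
              nrow(x$points), max(x$points$time), nrow(x$risk), x$risk$n_risk[1]))
  if (!is.null(x$total_events)) cat(sprintf("  reported events: %d\n", x$total_events))
  invisible(x)
}

#' Write a digitized curve to CSV files
#'
#' Inverse of [read_digitized_curve()]; used by the synthetic fixture writer.
#'
#' @param curve A `digitized_curve`.
#' @param curve_file,risk_file Output paths.
#' @return Invisibly, the curve.
#' @export
write_digitized_curve <- function(curve, curve_file, risk_file) {
  utils::write.csv(
    data.frame(time_months = curve$points$time, survival = curve$points$survival),
    curve_file, row.names = FALSE)
  utils::write.csv(
    data.frame(time_months = curve$risk$time, n_risk = curve$risk$n_risk),
    risk_file, row.names = FALSE)
  invisible(curve)
}
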