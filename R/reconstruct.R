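# Pseudo individual-patient data from digitized KM curves:
# interval-wise inversion of the product-limit estimator against the
# published numbers at risk (the standard click-point/at-risk algorithm).

#' Construct a pseudo-IPD object
#'
#' @param time Positive event/censoring times in months.
#' @param event Event indicator, 1 = event, 0 = censored.
#' @param arm,endpoint Labels carried through the pipeline.
#' @return Object of class `pseudo_ipd`: a data.frame with columns `time`,
#'   `event` and attributes `arm`, `endpoint`.
#' @export
pseudo_ipd <- function(time, event, arm = "arm", endpoint = "OS") {
  stop_if(length(time) == 0L, "pseudo-IPD needs at least one record")
  stop_if(length(time) != length(event), "time and event lengths differ")
  stop_if(any(!is.finite(time)) || any(time <= 0), "times must be positive and finite")
  stop_if(!all(event %in% c(0, 1)), "event indicator must be 0 or 1")
  out <- data.frame(time = as.numeric(time), event = as.integer(event))
  attr(out, "arm") <- arm
  attr(out, "endpoint") <- endpoint
  class(out) <- c("pseudo_ipd", "data.frame")
  out
}

#' @export
print.pseudo_ipd <- function(x, ...) {
  cat(sprintf("Pseudo-IPD: %s / %s - %d subjects, %d events, %d censored\n",
              attr(x, "arm"), attr(x, "endpoint"), nrow(x),
              sum(x$event), sum(1 - x$event)))
  invisible(x)
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Inverts the product-limit estimator interval by interval between
#' consecutive at-risk times: within each interval the number of censorings
#' is adjusted iteratively (censoring times spread uniformly) until the
#' implied number at risk at the next at-risk time matches the published
#' count, while event counts at each click point are chosen so the KM
#' estimator of the reconstructed data reproduces the digitized survival
#' probabilities. The final interval assumes no censoring unless
#' `total_events` was supplied on the curve, in which case events in that
#' interval are rescaled to match and the remainder censored. Subjects
#' still at risk after the last click point are censored there. The
#' reconstruction is fully deterministic.
#'
#' @param curve A [digitized_curve()].
#' @return A [pseudo_ipd()] with one record per subject entering the first
#'   interval.
#' @references Guyot et al. (2012) BMC Medical Research Methodology 12:9.
#' @export
reconstruct_ipd <- function(curve) {
  stopifnot(inherits(curve, "digitized_curve"))
  t_s <- curve$points$time
  S <- curve$points$survival
  trisk <- curve$risk$time
  nrisk <- curve$risk$n_risk
  K <- length(t_s)
  stop_if(nrisk[1] <= 0, "zero subjects at risk at start")
  stop_if(trisk[1] > t_s[1] + 1e-9, "risk table must start at or before the first click time")

  # drop risk times beyond the last click, and zero counts after the first
  # row: neither constrains the interval-wise inversion (the no-censoring
  # rule of the final interval takes over from the last positive count)
  keep <- trisk <= t_s[K] + 1e-9 & (nrisk > 0 | seq_along(nrisk) == 1L)
  trisk <- trisk[keep]; nrisk <- nrisk[keep]
  I <- length(trisk)
  # first click index at or after each risk time
  lower <- vapply(trisk, function(tt) which(t_s >= tt - 1e-9)[1], integer(1))
  lower[1] <- 1L
  upper <- c(lower[-1] - 1L, K)

  d <- integer(K)          # events at click k
  cen <- integer(K)        # censorings in [t_s[k], t_s[k+1])
  nhat <- integer(K + 1L)  # at risk just before click k
  nhat[1] <- nrisk[1]
  KM <- rep(1, K)
  klast <- 1L

  run_interval <- function(i, ncen_i, d, cen, nhat, KM, klast) {
    lo <- lower[i]; hi <- upper[i]
    t_end <- if (i < I) t_s[lower[i + 1]] else t_s[K]
    # spread censor times uniformly, bin them to click sub-intervals
    cen[lo:hi] <- 0L
    if (ncen_i > 0 && t_end > t_s[lo]) {
      ct <- t_s[lo] + seq_len(ncen_i) * (t_end - t_s[lo]) / (ncen_i + 1)
      for (k in lo:hi) {
        k_end <- if (k < K) t_s[k + 1] else Inf
        cen[k] <- sum(ct >= t_s[k] & ct < k_end)
      }
    }
    for (k in lo:hi) {
      if (k == 1L) {
        d[k] <- 0L
        KM[k] <- 1
        klast <- 1L
      } else {
        if (nhat[k] > 0 && KM[klast] > 0) {
          d[k] <- round(nhat[k] * (1 - S[k] / KM[klast]))
          d[k] <- max(0L, min(d[k], nhat[k]))
          KM[k] <- KM[klast] * (1 - d[k] / nhat[k])
        } else {
          d[k] <- 0L
          KM[k] <- KM[klast]
        }
        if (d[k] > 0) klast <- k
      }
      nhat[k + 1L] <- nhat[k] - d[k] - cen[k]
      if (nhat[k + 1L] < 0) {
        cen[k] <- cen[k] + nhat[k + 1L]
        nhat[k + 1L] <- 0L
      }
    }
    list(d = d, cen = cen, nhat = nhat, KM = KM, klast = klast)
  }

  for (i in seq_len(max(I - 1L, 0L))) {
    lo <- lower[i]
    # initial censoring guess from the survival drop across the interval
    ncen_i <- if (S[lo] > 0) {
      max(0L, round(nhat[lo] * S[lower[i + 1]] / S[lo] - nrisk[i + 1]))
    } else 0L
    for (iter in 1:60) {
      st <- run_interval(i, ncen_i, d, cen, nhat, KM, klast)
      diff <- st$nhat[lower[i + 1]] - nrisk[i + 1]
      if (diff == 0 || (diff < 0 && ncen_i <= 0)) break
      ncen_i <- ncen_i + diff
      if (ncen_i < 0) ncen_i <- 0L
      stop_if(iter == 60,
              sprintf("reconstruction failed to match at-risk count in interval %d", i))
    }
    d <- st$d; cen <- st$cen; nhat <- st$nhat; KM <- st$KM; klast <- st$klast
  }
  # final interval: no censoring before the last click unless rescaling
  st <- run_interval(I, 0L, d, cen, nhat, KM, klast)
  d <- st$d; cen <- st$cen; nhat <- st$nhat; KM <- st$KM

  if (!is.null(curve$total_events)) {
    lo <- lower[I]
    excess <- sum(d) - curve$total_events
    if (excess != 0) {
      idx <- which(d > 0 & seq_len(K) >= lo)
      tot <- sum(d[idx])
      target <- max(0L, tot - excess)
      if (length(idx) > 0 && tot > 0) {
        scaled <- floor(d[idx] * target / tot)
        rem <- target - sum(scaled)
        if (rem > 0) {
          extra <- order(d[idx] * target / tot - scaled, decreasing = TRUE)[seq_len(rem)]
          scaled[extra] <- scaled[extra] + 1L
        }
        # removed events become censorings at the same click
        cen[idx] <- cen[idx] + (d[idx] - scaled)
        d[idx] <- scaled
      }
    }
  }

  # assemble records: events at click times, censorings spread within
  # sub-intervals, survivors past the last click censored there
  times <- numeric(0); events <- integer(0)
  for (k in seq_len(K)) {
    if (d[k] > 0) {
      times <- c(times, rep(t_s[k], d[k]))
      events <- c(events, rep(1L, d[k]))
    }
    if (cen[k] > 0) {
      k_end <- if (k < K) t_s[k + 1] else t_s[K]
      ct <- if (k_end > t_s[k]) {
        t_s[k] + seq_len(cen[k]) * (k_end - t_s[k]) / (cen[k] + 1)
      } else rep(t_s[k], cen[k])
      times <- c(times, ct)
      events <- c(events, rep(0L, cen[k]))
    }
  }
  n_left <- nhat[K + 1L]
  if (n_left > 0) {
    times <- c(times, rep(t_s[K], n_left))
    events <- c(events, rep(0L, n_left))
  }
  # guard against zero times (clicks exactly at 0 carry no subjects)
  times[times <= 0] <- min(t_s[t_s > 0], 1e-6) / 2
  pseudo_ipd(times, events, arm = curve$arm, endpoint = curve$endpoint)
}

#' Kaplan-Meier estimate of a pseudo-IPD dataset
#'
#' Product-limit estimator, returned as a step function anchored at (0, 1).
#'
#' @param ipd A [pseudo_ipd()].
#' @return Data.frame with columns `time`, `survival` (step-function values
#'   just after each distinct time, starting with the (0, 1) anchor).
#' @export
km_estimate <- function(ipd) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  stop_if(nrow(ipd) == 0L, "empty pseudo-IPD")
  sf <- survival::survfit(survival::Surv(ipd$time, ipd$event) ~ 1, conf.type = "none")
  data.frame(time = c(0, sf$time), survival = c(1, sf$surv))
}

# evaluate a KM step function at arbitrary times (right-continuous)
km_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  idx[idx < 1L] <- 1L
  km$survival[idx]
}

#' Write pseudo-IPD to CSV
#'
#' Columns `time_months,event,arm,endpoint`.
#'
#' @param ipd A [pseudo_ipd()].
#' @param file Output path.
#' @export
write_ipd <- function(ipd, file) {
  utils::write.csv(
    data.frame(time_months = ipd$time, event = ipd$event,
               arm = attr(ipd, "arm"), endpoint = attr(ipd, "endpoint")),
    file, row.names = FALSE)
  invisible(ipd)
}

#' Read pseudo-IPD from CSV
#'
#' @param file CSV with columns `time_months,event` and optionally
#'   `arm`, `endpoint`.
#' @return A [pseudo_ipd()].
#' @export
read_ipd <- function(file) {
  x <- utils::read.csv(file)
  stop_if(!all(c("time_months", "event") %in% names(x)),
          "IPD CSV must have columns time_months,event")
  pseudo_ipd(x$time_months, x$event,
             arm = if ("arm" %in% names(x)) x$arm[1] else "arm",
             endpoint = if ("endpoint" %in% names(x)) x$endpoint[1] else "OS")
}
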