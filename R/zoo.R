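# Fit the whole family zoo, tabulate information criteria, pick the best.

#' Fit all survival families to one dataset
#'
#' Fits every family in `families` (default: the full fifteen), collecting
#' failures as non-converged entries rather than erroring.
#'
#' @inheritParams fit_survival
#' @param families Subset of [surv_families()].
#' @param quiet Suppress per-family failure warnings.
#' @return Object of class `surv_zoo`: a named list of `surv_fit` objects
#'   (failed families are absent), with attribute `failed` naming them.
#' @export
fit_survival_zoo <- function(ipd, families = surv_families(), knots = NULL,
                             count_fp_powers = FALSE, quiet = FALSE) {
  fits <- list()
  failed <- character(0)
  for (fam in families) {
    f <- tryCatch(
      fit_survival(ipd, fam, knots = knots, count_fp_powers = count_fp_powers),
      error = function(e) {
        if (!quiet) warning(sprintf("%s fit failed: %s", fam, conditionMessage(e)),
                            call. = FALSE)
        NULL
      })
    if (!is.null(f)) fits[[fam]] <- f else failed <- c(failed, fam)
  }
  stop_if(length(fits) == 0, "no family converged")
  attr(fits, "failed") <- failed
  class(fits) <- "surv_zoo"
  fits
}

#' @export
print.surv_zoo <- function(x, ...) {
  print(information_table(x))
  invisible(x)
}

#' Information-criterion table for a set of fitted models
#'
#' @param fits A `surv_zoo` or list of `surv_fit` objects.
#' @return Data.frame with columns `family`, `loglik`, `k`, `n`, `AIC`,
#'   `BIC`, `converged`, sorted in canonical family order. Non-converged or
#'   absent families are omitted.
#' @export
information_table <- function(fits) {
  fits <- Filter(Negate(is.null), unclass(fits))
  stop_if(length(fits) == 0, "no fits supplied")
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "surv_fit"))
    stop_if(f$k <= 0, "fit with non-positive parameter count")
    data.frame(family = f$family, loglik = f$loglik, k = f$k, n = f$n,
               AIC = f$AIC, BIC = f$BIC, converged = f$converged)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$converged, , drop = FALSE]
  stop_if(nrow(tab) == 0, "no converged fits")
  ord <- match(tab$family, surv_families())
  tab <- tab[order(ord), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Select the best-fitting family from an information table
#'
#' Returns the family minimizing the primary criterion (AIC by default).
#' Exact ties on AIC are broken by lower BIC; a remaining tie is resolved
#' in favour of the *later* family in canonical order, i.e. the more
#' flexible listing (identical criteria mean the flexible model collapsed
#' onto its nested special case, so the survival functions coincide and
#' the flexible label mirrors reported selection practice). An explicit
#' `override` (visual-inspection choice) takes precedence.
#'
#' @param table Data.frame with columns `family`, `AIC`, and optionally
#'   `BIC`; typically from [information_table()], but printed AIC/BIC
#'   values can be fed directly.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @param override Optional family name to force (must be in the table).
#' @param tol Absolute tolerance for declaring ties.
#' @return The selected family name.
#' @export
select_best <- function(table, criterion = c("AIC", "BIC"), override = NULL,
                        tol = 1e-6) {
  criterion <- match.arg(criterion)
  stop_if(is.null(table) || nrow(table) == 0, "empty information table")
  if (!is.null(override)) {
    stop_if(!override %in% table$family, "override family not in table")
    return(override)
  }
  crit <- table[[criterion]]
  cand <- which(crit <= min(crit) + tol)
  if (length(cand) > 1 && "BIC" %in% names(table) && criterion != "BIC") {
    b <- table$BIC[cand]
    cand <- cand[b <= min(b) + tol]
  }
  if (length(cand) > 1) {
    ord <- match(table$family[cand], surv_families())
    ord[is.na(ord)] <- seq_along(ord)[is.na(ord)]
    cand <- cand[which.max(ord)]
  }
  table$family[cand[1]]
}
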