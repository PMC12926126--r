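# Fractional-polynomial log-hazard families (FP1/FP2).
#
# ln h(t) = b0 + b1 g_p1(t) [+ b2 g_p2(t)], with g_p(t) = t^p and
# g_0(t) = ln t; repeated powers use the usual convention
# b1 t^p + b2 t^p ln t. Powers are profile-selected over the standard set.

FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

fp_term <- function(t, p) if (p == 0) log(t) else t^p

# log-hazard for power vector `powers` (length 1 or 2) and coefficients beta
fp_loghaz <- function(t, powers, beta) {
  if (length(powers) == 1L) {
    beta[1] + beta[2] * fp_term(t, powers)
  } else if (powers[1] != powers[2]) {
    beta[1] + beta[2] * fp_term(t, powers[1]) + beta[3] * fp_term(t, powers[2])
  } else {
    beta[1] + beta[2] * fp_term(t, powers[1]) +
      beta[3] * fp_term(t, powers[1]) * log(t)
  }
}

# Is the hazard integrable at 0? Check the dominant small-t behaviour.
fp_integrable <- function(powers, beta) {
  co <- beta[-1]
  if (length(powers) == 2L && powers[1] == powers[2]) {
    # b1 t^p + b2 t^p ln t: for p<0 the ln-t product term dominates
    p <- powers[1]
    if (p < 0) {
      # exponent ~ t^p (b1 + b2 ln t): b2 < 0 drives it to +Inf
      if (co[2] < 0 || (co[2] == 0 && co[1] > 0)) return(FALSE)
      return(TRUE)
    }
    if (p == 0) {
      # ln h = b0 + b1 ln t + b2 (ln t)^2
      if (co[2] > 0) return(FALSE)
      if (co[2] < 0) return(TRUE)
      return(co[1] > -1)
    }
    return(TRUE)
  }
  neg <- which(powers < 0)
  if (length(neg)) {
    pmin_idx <- neg[which.min(powers[neg])]
    if (co[pmin_idx] > 0) return(FALSE)
    if (co[pmin_idx] < 0) return(TRUE) # exponent -> -Inf, h -> 0
    # zero coefficient on the singular term: fall through to remaining terms
    powers <- powers[-pmin_idx]; co <- co[-pmin_idx]
    if (!length(powers)) return(TRUE)
    return(fp_integrable(powers, c(0, co)))
  }
  z <- which(powers == 0)
  if (length(z)) return(co[z[1]] > -1) # h ~ t^{b}
  TRUE
}

# 64-node Gauss-Legendre rule on [0,1], with u = t v^2 substitution to
# cluster nodes near zero where FP hazards can be steep.
.gl64 <- local({
  n <- 64L
  # Golub-Welsch via symmetric tridiagonal eigen-decomposition
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- b; A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  # map from [-1,1] to [0,1]
  list(v = (x + 1) / 2, w = w / 2)
})

# cumulative hazard at each t (vectorised) by quadrature
fp_cumhaz <- function(t, powers, beta) {
  if (!fp_integrable(powers, beta)) return(rep(Inf, length(t)))
  # closed forms for the single-term cases
  if (length(powers) == 1L) {
    b0 <- beta[1]; b1 <- beta[2]
    if (powers == 0) {
      return(if (b1 > -1) exp(b0) * t^(b1 + 1) / (b1 + 1) else rep(Inf, length(t)))
    }
    if (powers == 1) {
      return(if (abs(b1) < 1e-12) exp(b0) * t else exp(b0) * (exp(b1 * t) - 1) / b1)
    }
  }
  v <- .gl64$v; w <- .gl64$w
  # substitution u = t v^2, du = 2 t v dv, vectorised over all t at once
  u <- outer(v^2, t)                    # 64 x n
  h <- exp(fp_loghaz(u, powers, beta))
  out <- as.numeric(crossprod(w * 2 * v, h)) * t
  out[t <= 0] <- 0
  out
}

fp_loglik <- function(beta, powers, time, event) {
  H <- fp_cumhaz(time, powers, beta)
  if (any(!is.finite(H))) return(-Inf)
  ll <- sum(event * fp_loghaz(time, powers, beta)) - sum(H)
  if (!is.finite(ll)) -Inf else ll
}

# design row g_j(u) for each coefficient (intercept included)
fp_basis_mat <- function(u, powers) {
  if (length(powers) == 1L) {
    cbind(1, fp_term(u, powers))
  } else if (powers[1] != powers[2]) {
    cbind(1, fp_term(u, powers[1]), fp_term(u, powers[2]))
  } else {
    g <- fp_term(u, powers[1])
    cbind(1, g, g * log(u))
  }
}

# analytic score: d ell / d beta_j = sum_i d_i g_j(t_i) - sum_i dH_i/dbeta_j
fp_score <- function(beta, powers, time, event) {
  if (!fp_integrable(powers, beta)) return(rep(0, length(beta)))
  v <- .gl64$v; w <- .gl64$w
  u <- outer(v^2, time)                 # 64 x n
  h <- exp(fp_loghaz(u, powers, beta))
  wt <- (w * 2 * v)
  npar <- length(beta)
  dH <- matrix(0, length(time), npar)
  X_t <- fp_basis_mat(time, powers)
  Xu <- fp_basis_mat(as.vector(u), powers)
  for (j in seq_len(npar)) {
    gj <- matrix(Xu[, j], nrow(u), ncol(u))
    dH[, j] <- as.numeric(crossprod(wt, gj * h)) * time
  }
  colSums(event * X_t) - colSums(dH)
}

fit_fp <- function(time, event, degree = 1, count_powers = FALSE) {
  n_ev <- sum(event)
  b0_init <- log(max(n_ev, 0.5) / sum(time))
  best <- NULL
  power_sets <- if (degree == 1) {
    lapply(FP_POWERS, function(p) p)
  } else {
    out <- list()
    for (i in seq_along(FP_POWERS)) for (j in i:length(FP_POWERS)) {
      out[[length(out) + 1L]] <- c(FP_POWERS[i], FP_POWERS[j])
    }
    out
  }
  # warm starts for FP2: coefficients of the matching single-power fit
  fp1_beta <- NULL
  if (degree == 2) {
    fp1_beta <- lapply(FP_POWERS, function(p) {
      f <- tryCatch(
        stats::optim(c(b0_init, 0), function(b) -fp_loglik(b, p, time, event),
                     method = "BFGS", control = list(maxit = 200, reltol = 1e-9)),
        error = function(e) NULL)
      if (is.null(f)) c(b0_init, 0) else f$par
    })
    names(fp1_beta) <- as.character(FP_POWERS)
  }
  for (pw in power_sets) {
    npar <- 1L + if (degree == 1) 1L else 2L
    init <- if (degree == 2) {
      c(fp1_beta[[as.character(pw[1])]], 0)
    } else c(b0_init, rep(0, npar - 1L))
    fit <- tryCatch(
      stats::optim(init, function(b) -fp_loglik(b, pw, time, event),
                   gr = function(b) -fp_score(b, pw, time, event),
                   method = "BFGS",
                   control = list(maxit = 400, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || -fit$value > best$loglik + 1e-9) {
      best <- list(powers = pw, beta = fit$par, loglik = -fit$value,
                   converged = fit$convergence == 0)
    }
  }
  stop_if(is.null(best), "no FP power (pair) produced a finite likelihood")
  k <- (if (degree == 1) 2L else 3L) + if (count_powers) degree else 0L
  pars <- c(stats::setNames(best$beta, paste0("b", seq_along(best$beta) - 1)),
            stats::setNames(best$powers, paste0("p", seq_along(best$powers))))
  powers <- best$powers; beta <- best$beta
  sfun <- function(t) {
    H <- vapply(t, function(ti) {
      if (ti <= 0) return(0)
      # adaptive integration of the hazard; quadrature fallback
      r <- tryCatch(
        stats::integrate(function(u) exp(fp_loghaz(u, powers, beta)),
                         0, ti, rel.tol = 1e-8, stop.on.error = FALSE)$value,
        error = function(e) NA_real_)
      if (!is.finite(r) || is.na(r)) r <- fp_cumhaz(ti, powers, beta)
      r
    }, numeric(1))
    exp(-H)
  }
  list(pars = pars, loglik = best$loglik, k = k,
       converged = best$converged, sfun = sfun)
}
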