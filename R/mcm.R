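# Weibull mixture-cure model: S(t) = pi + (1 - pi) * S_w(t | shape, scale),
# with the cure fraction pi on the logit scale. Fitted by quasi-Newton
# maximisation with seeded random restarts.

mcm_loglik <- function(par, time, event) {
  pi_ <- stats::plogis(par[1])
  a <- exp(par[2]); b <- exp(par[3])
  if (!is.finite(a) || !is.finite(b) || a > 1e6 || b > 1e12) return(-Inf)
  Sw <- suppressWarnings(stats::pweibull(time, a, b, lower.tail = FALSE))
  fw <- suppressWarnings(stats::dweibull(time, a, b))
  if (any(!is.finite(Sw)) || any(!is.finite(fw))) return(-Inf)
  S <- pi_ + (1 - pi_) * Sw
  f <- (1 - pi_) * fw
  ll <- sum(event * log(pmax(f, 1e-300))) + sum((1 - event) * log(pmax(S, 1e-300)))
  if (!is.finite(ll)) -Inf else ll
}

fit_mcm <- function(time, event, n_restarts = 5, seed = 20260926) {
  stop_if(sum(event) == 0, "all records censored: cure model degenerate")
  km <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  s_last <- min(km$surv)
  pi0 <- min(max(s_last, 0.01), 0.95)
  # crude Weibull inits from uncensored times
  tv <- time[event == 1]
  m <- mean(log(tv)); s <- stats::sd(log(tv))
  if (!is.finite(s) || s <= 0) s <- 1
  init <- c(stats::qlogis(pi0), log(1.2 / s), m)
  init[3] <- log(stats::median(tv))
  obj <- function(p) -mcm_loglik(p, time, event)
  best <- NULL
  starts <- list(init)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    starts[[r + 1L]] <- init + stats::rnorm(3, 0, c(1.5, 0.4, 0.4))
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || -fit$value > best$loglik + 1e-8) {
      best <- list(par = fit$par, loglik = -fit$value,
                   converged = fit$convergence == 0)
    }
  }
  stop_if(is.null(best), "mixture-cure fit failed from all starts")
  pi_ <- stats::plogis(best$par[1])
  a <- exp(best$par[2]); b <- exp(best$par[3])
  sfun <- function(t) pi_ + (1 - pi_) * stats::pweibull(t, a, b, lower.tail = FALSE)
  list(pars = c(cure_fraction = pi_, shape = a, scale = b),
       loglik = best$loglik, k = 3L, converged = best$converged, sfun = sfun)
}
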