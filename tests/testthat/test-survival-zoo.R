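# Survival family fitting, information criteria, and model selection.

test_that("exponential fit matches the closed-form MLE oracle", {
  ipd <- pseudo_ipd(c(1, 2, 3), c(1, 1, 1))
  fit <- fit_survival(ipd, "Exponential")
  # closed form: lambda = d / sum(t), l = d log(lambda) - lambda sum(t)
  lam <- 3 / 6
  ll <- 3 * log(lam) - lam * 6
  expect_equal(unname(fit$pars[1]), lam, tolerance = 1e-6)
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  expect_equal(fit$AIC, 2 * 1 - 2 * ll, tolerance = 1e-6)
  expect_equal(fit$BIC, log(3) - 2 * ll, tolerance = 1e-6)
  expect_equal(survival_at(fit, 2), exp(-1), tolerance = 1e-6)
  expect_equal(survival_at(fit, 0), 1)
})

test_that("weibull optimizer solution matches an independent Newton oracle", {
  ipd <- simulate_censored_weibull(120, 1.5, 10, seed = 2)
  fit <- fit_survival(ipd, "Weibull")
  # independent oracle: direct maximization of the Weibull likelihood on a
  # fine profile of the shape parameter (scale concentrated out)
  prof <- function(a) {
    d <- sum(ipd$event)
    b <- (sum(ipd$time^a) / d)^(1 / a)
    sum(ipd$event * (log(a) + (a - 1) * log(ipd$time) - a * log(b))) -
      sum((ipd$time / b)^a)
  }
  a_hat <- stats::optimize(prof, c(0.2, 6), maximum = TRUE)
  expect_equal(fit$loglik, a_hat$objective, tolerance = 1e-6)
  expect_equal(unname(fit$pars["shape"]), a_hat$maximum, tolerance = 1e-4)
})

test_that("parameter recovery: fitted median within 10% of truth", {
  ipd <- simulate_censored_weibull(500, 1.4, 8, seed = 9)
  fit <- fit_survival(ipd, "Weibull")
  expect_lt(abs(median_survival(fit) - 8) / 8, 0.1)
})

test_that("nested models collapse onto their special cases", {
  ipd <- simulate_censored_weibull(150, 1.3, 9, seed = 4)
  pairs <- list(
    c("RP-hazard", "Weibull"),
    c("RP-normal", "Log-normal"),
    c("RP-odds", "Log-logistic"))
  for (p in pairs) {
    flex <- fit_survival(ipd, p[1], knots = 0)
    base <- fit_survival(ipd, p[2])
    expect_lt(abs(flex$loglik - base$loglik), 1e-4)
    expect_lt(abs(flex$AIC - base$AIC), 1e-4)
  }
  # FP1 with zero slope is exponential
  b <- c(log(0.3), 0)
  S_fp <- exp(-maintCEA:::fp_cumhaz(5, 0.5, b))
  expect_equal(S_fp, exp(-0.3 * 5), tolerance = 1e-6)
  # mixture cure with vanishing cure fraction is its base Weibull
  ipd2 <- simulate_censored_weibull(150, 1.3, 9, seed = 12)
  wb <- fit_survival(ipd2, "Weibull")
  mcm_ll <- maintCEA:::mcm_loglik(
    c(stats::qlogis(1e-12), log(wb$pars[["shape"]]), log(wb$pars[["scale"]])),
    ipd2$time, ipd2$event)
  expect_lt(abs(mcm_ll - wb$loglik), 1e-4)
})

test_that("fitted survival functions are proper over the model horizon", {
  ipd <- simulate_censored_weibull(150, 1.3, 9, seed = 4)
  grid <- (0:130) * 28 / (365.25 / 12)
  for (fam in c("Exponential", "Gompertz", "GeneralizedGamma", "FP1", "FP2",
                "RCS", "GAM", "MCM")) {
    fit <- fit_survival(ipd, fam)
    s <- survival_at(fit, grid)
    expect_true(all(s >= 0 & s <= 1), info = fam)
    expect_true(all(diff(s) <= 1e-8), info = fam)
    expect_equal(s[1], 1, info = fam)
  }
  # mixture cure levels off at its cure fraction
  mcm <- fit_survival(ipd, "MCM")
  expect_equal(survival_at(mcm, 1e5), unname(mcm$pars["cure_fraction"]),
               tolerance = 1e-6)
  expect_error(survival_at(mcm, -1), "negative")
})

test_that("fitting guards reject degenerate inputs", {
  expect_error(fit_survival(pseudo_ipd(1:5, rep(0, 5)), "Weibull"),
               "all records censored")
  expect_error(fit_survival(pseudo_ipd(1:4, c(1, 1, 1, 0)), "MCM"),
               "at least 5 events")
})

test_that("information table applies the AIC/BIC formulas", {
  f1 <- structure(list(family = "Exponential", pars = 1, loglik = -10, k = 1,
                       n = 50, AIC = 22, BIC = 2 * 10 + log(50),
                       converged = TRUE, sfun = identity),
                  class = "surv_fit")
  f2 <- structure(list(family = "Weibull", pars = 1:3, loglik = -9, k = 3,
                       n = 50, AIC = 24, BIC = 3 * log(50) + 18,
                       converged = TRUE, sfun = identity),
                  class = "surv_fit")
  tab <- information_table(list(f1, f2))
  expect_equal(tab$AIC, c(22, 24))
  f3 <- f1; f3$k <- 0
  expect_error(information_table(list(f3)), "parameter count")
  expect_error(information_table(list()), "no fits")
})

test_that("the full zoo produces one row per converged family", {
  ipd <- simulate_censored_weibull(200, 1.4, 8, seed = 21)
  zoo <- fit_survival_zoo(ipd, quiet = TRUE)
  tab <- information_table(zoo)
  expect_equal(nrow(tab), 15)
  expect_setequal(tab$family, surv_families())
  expect_true(all(abs(tab$AIC - (2 * tab$k - 2 * tab$loglik)) < 1e-9))
  expect_true(all(abs(tab$BIC - (tab$k * log(tab$n) - 2 * tab$loglik)) < 1e-9))
})

test_that("select_best applies the minimum-AIC rule with tie-breaks", {
  tab <- data.frame(family = c("Weibull", "Log-normal"),
                    AIC = c(100, 100), BIC = c(96.00, 95.77))
  expect_equal(select_best(tab), "Log-normal")  # lower BIC wins the tie
  tab2 <- data.frame(family = c("Log-normal", "RP-normal"),
                     AIC = c(89.83, 89.83), BIC = c(95.77, 95.77))
  expect_equal(select_best(tab2), "RP-normal")  # flexible listing wins
  tab3 <- data.frame(family = c("Weibull", "Gamma"), AIC = c(90, 91),
                     BIC = c(95, 94))
  expect_equal(select_best(tab3), "Weibull")
  expect_equal(select_best(tab3, criterion = "BIC"), "Gamma")
  expect_equal(select_best(tab3, override = "Gamma"), "Gamma")
  expect_error(select_best(tab3[0, ]), "empty")
})
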