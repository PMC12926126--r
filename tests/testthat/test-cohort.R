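# Markov cohort engine: discounting, transitions, trace, accumulation, ICER.

CYC_M <- 28 / (365.25 / 12)

test_that("discount factor follows the closed form", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(13, 0), 1)
  expect_equal(discount_factor(13, 0.05), 1.05^(-364 / 365.25))
  expect_equal(round(discount_factor(13, 0.05), 5), 0.95254)
  expect_error(discount_factor(-1, 0.05), "negative")
})

test_that("transition probabilities match the exponential closed form", {
  # survival in months scaled so one cycle carries hazard 0.2 / 0.1
  S_pfs <- function(t) exp(-0.2 * t / CYC_M)
  S_os <- function(t) exp(-0.1 * t / CYC_M)
  P <- transition_probs_at(0, S_pfs, S_os)
  expect_equal(P["PFS", "Death"], 1 - exp(-0.1), tolerance = 1e-12)
  expect_equal(P["PFS", "PD"], (1 - exp(-0.2)) - (1 - exp(-0.1)),
               tolerance = 1e-12)
  expect_equal(rowSums(P), c(PFS = 1, PD = 1, Death = 1))

  # no events: identity
  P1 <- transition_probs_at(5, function(t) 1, function(t) 1)
  expect_equal(unname(P1), diag(3), ignore_attr = TRUE)

  # PFS decaying slower than OS: progression clamped to zero
  P2 <- transition_probs_at(0, function(t) exp(-0.05 * t),
                            function(t) exp(-0.2 * t))
  expect_equal(P2["PFS", "PD"], 0)
  expect_equal(rowSums(P2), c(PFS = 1, PD = 1, Death = 1))
  expect_true(attr(P2, "clamped"))
})

test_that("cohort trace conserves occupancy and reproduces OS", {
  S_pfs <- function(t) exp(-0.2 * t)
  S_os <- function(t) exp(-0.1 * t)
  tr <- run_cohort(S_pfs, S_os)
  expect_equal(nrow(tr), 131)
  expect_lt(max(abs(rowSums(tr[, c("pfs", "pd", "death")]) - 1)), 1e-10)
  expect_true(all(diff(tr$death) >= -1e-12))
  tm <- tr$cycle * CYC_M
  expect_lt(max(abs(tr$death - (1 - S_os(tm)))), 1e-9)
  expect_lt(max(abs(tr$pfs + tr$pd - S_os(tm))), 1e-9)

  # degenerate: PFS = OS means nobody ever progresses
  tr2 <- run_cohort(S_os, S_os)
  expect_true(all(tr2$pd == 0))
})

test_that("constant-probability trace equals the matrix-power oracle", {
  # q_death = 0.1 and q_exit = 0.3 per cycle, exactly
  S_os <- function(t) 0.9^(t / CYC_M)
  S_pfs <- function(t) 0.7^(t / CYC_M)
  tr <- run_cohort(S_pfs, S_os)
  P <- matrix(c(0.7, 0.2, 0.1,
                0, 0.9, 0.1,
                0, 0, 1), 3, 3, byrow = TRUE)
  v <- c(1, 0, 0)
  for (t in 1:130) {
    v <- as.numeric(v %*% P)
    expect_lt(max(abs(unlist(tr[t + 1, c("pfs", "pd", "death")]) - v)), 1e-12)
  }
  # the two-cycle occupancy, by hand: P^2 applied to (1,0,0)
  expect_equal(unname(unlist(tr[3, c("pfs", "pd", "death")])),
               c(0.49, 0.32, 0.19), tolerance = 1e-12)
})

test_that("accumulation reproduces closed-form cost/QALY identities", {
  inp <- economic_inputs()
  p0 <- inp$params
  p0[grep("^risk_", names(p0))] <- 0  # switch off adverse events
  p0[["discount_rate"]] <- 0

  # one undiscounted cycle fully progression-free
  s1 <- model_settings(horizon_years = 28 / 365.25, discount_rate = 0)
  tr1 <- run_cohort(function(t) 1, function(t) 1, s1)
  out1 <- accumulate(tr1, inp, "treatment", s1, params = p0)
  expect_equal(out1$qalys, 0.68 * 28 / 365.25, tolerance = 1e-9)

  # flat occupancy, no discounting: cost is cycles x per-cycle cost
  s <- model_settings(discount_rate = 0)
  tr <- run_cohort(function(t) 1, function(t) 1, s)
  out <- accumulate(tr, inp, "treatment", s, params = p0)
  expect_equal(out$cost, 130 * (6011.10 + 44.7 + 95.45), tolerance = 1e-6)

  # dead cohort: end-of-life cost only, no QALYs
  trd <- tr1
  trd$pfs <- c(1, 0); trd$pd <- 0; trd$death <- c(0, 1)
  trd$incident_deaths <- c(0, 1)
  outd <- accumulate(trd, inp, "treatment", s1, params = p0)
  expect_equal(outd$cost, p0[["cost_eol"]], tolerance = 1e-9)
  expect_equal(outd$qalys, 0, tolerance = 1e-12)
})

test_that("control arm switches from doublet to maintenance after cycle 3", {
  inp <- economic_inputs()
  p0 <- inp$params
  p0[grep("^risk_", names(p0))] <- 0
  p0[["discount_rate"]] <- 0
  p0[["cost_lab"]] <- 0; p0[["cost_imaging"]] <- 0
  s <- model_settings(discount_rate = 0)
  tr <- run_cohort(function(t) 1, function(t) 1, s)
  out <- accumulate(tr, inp, "control", s, params = p0)
  expect_equal(out$cost, 3 * 86.40 + 127 * 8.80, tolerance = 1e-9)
})

test_that("discounting strictly reduces totals", {
  cea0 <- toy_cea()
  prev_c <- Inf; prev_q <- Inf
  for (r in c(0, 0.03, 0.05, 0.08)) {
    s <- model_settings(discount_rate = r)
    cea <- run_cea(cea0$survival$pfs_t, cea0$survival$os_t,
                   cea0$survival$pfs_c, cea0$survival$os_c,
                   settings = s)
    expect_lt(cea$result$treated$cost, prev_c)
    expect_lt(cea$result$treated$qalys, prev_q)
    prev_c <- cea$result$treated$cost
    prev_q <- cea$result$treated$qalys
  }
})

test_that("icer computes increments, dominance and the WTP verdict", {
  r <- icer(list(cost = 58186.72, qalys = 1.14),
            list(cost = 4844.27, qalys = 0.75))
  expect_equal(r$delta_cost, 53342.45)
  expect_equal(r$delta_qalys, 0.39)
  expect_equal(r$icer, 53342.45 / 0.39)
  expect_equal(r$verdict, "not cost-effective")

  expect_equal(icer(list(cost = 10, qalys = 1), list(cost = 5, qalys = 0.5))$icer, 10)
  expect_equal(icer(list(cost = 5, qalys = 1), list(cost = 10, qalys = 0.5))$dominance,
               "dominant")
  expect_equal(icer(list(cost = 10, qalys = 0.4), list(cost = 5, qalys = 0.5))$dominance,
               "dominated")
  tie <- icer(list(cost = 10, qalys = 0.5), list(cost = 5, qalys = 0.5))
  expect_true(is.na(tie$icer))
})

test_that("model settings derive the cycle count and validate inputs", {
  s <- model_settings()
  expect_equal(s$n_cycles, 130)
  expect_equal(s$cycle_days, 28)
  expect_error(model_settings(discount_rate = -0.1), "discount")
  expect_error(model_settings(wtp = 0), "WTP")
})
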