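# Body-surface-area dosing, regimen costs, adverse events, PAP.

test_that("Mosteller BSA matches the anthropometric reference points", {
  expect_equal(round(bsa_mosteller(163.5, 66.9), 2), 1.74)
  expect_equal(round(bsa_mosteller(163.5, 0.90 * 66.9), 2), 1.65)
  expect_equal(round(bsa_mosteller(163.5, 0.85 * 66.9), 2), 1.61)
  expect_equal(bsa_mosteller(60, 60), 1)
  expect_error(bsa_mosteller(-1, 60), "positive")
  # strictly increasing in each argument; invariant under product-preserving swaps
  expect_gt(bsa_mosteller(163.5, 70), bsa_mosteller(163.5, 66.9))
  expect_gt(bsa_mosteller(170, 66.9), bsa_mosteller(163.5, 66.9))
  expect_equal(bsa_mosteller(163.5, 66.9), bsa_mosteller(66.9, 163.5))
})

test_that("patient profile derives effective weight and BSA", {
  pr <- patient_profile()
  expect_equal(pr$weight_kg, 60.21)
  expect_equal(pr$bsa, sqrt(163.5 * 60.21 / 3600))
  pr15 <- patient_profile(weight_loss = 0.15)
  expect_equal(pr15$weight_kg, 56.865)
  expect_error(patient_profile(weight_loss = 0.6), "weight_loss")
})

test_that("cycle drug cost follows dose x body-size x price arithmetic", {
  pr <- patient_profile()  # 60.21 kg
  ram_only <- regimen_def("ram", data.frame(
    drug = "ramucirumab", basis = "per_kg", dose = 8, admins = 2,
    price_per_mg = 6.1605))
  expect_equal(cycle_drug_cost(ram_only, pr), 963.36 * 6.1605, tolerance = 1e-9)
  expect_equal(cycle_drug_cost(ram_only, pr), 5934.78, tolerance = 1e-4)

  free <- regimen_def("free", data.frame(
    drug = "x", basis = "flat", dose = 100, admins = 1, price_per_mg = 0))
  expect_equal(cycle_drug_cost(free, pr), 0)
  expect_error(regimen_def("bad", data.frame(
    drug = "x", basis = "per_pound", dose = 1, admins = 1, price_per_mg = 1)),
    "basis")

  # calibration identity: combo cost at the reference profile is 6011.10
  expect_equal(cycle_drug_cost(maintCEA:::combo_regimen(), pr), 6011.10,
               tolerance = 1e-9)

  # linearity in unit price and in BSA for per-m2 components
  pac <- function(price, wl = 0.1) cycle_drug_cost(
    regimen_def("pac", data.frame(drug = "p", basis = "per_m2", dose = 80,
                                  admins = 3, price_per_mg = price)),
    patient_profile(weight_loss = wl))
  expect_equal(pac(2), 2 * pac(1), tolerance = 1e-12)
  expect_equal(pac(1, 0.15) / pac(1, 0.1),
               patient_profile(weight_loss = 0.15)$bsa / patient_profile()$bsa,
               tolerance = 1e-12)
})

test_that("post-progression mix costs are weighted means", {
  expect_equal(pd_mix_cost(c(0.36, 0.17, 0.29, 0.18),
                           c(149.83, 552.68, 211.27, 86.40)),
               224.7147, tolerance = 1e-4)
  expect_equal(pd_mix_cost(c(0.258, 0.112, 0.63),
                           c(6011.10, 149.83, 211.27)),
               1700.745, tolerance = 1e-3)
  expect_equal(pd_mix_cost(1, 42), 42)
  expect_error(pd_mix_cost(c(0.5, 0.4), c(1, 1)), "sum to 1")
})

test_that("adverse-event burden aggregates risk-weighted costs and disutilities", {
  p <- economic_inputs()$params
  b <- ae_burden(p, "treatment")
  expect_equal(b$cost, 0.26 * 321.67 + 0.02 * 472.73 + 0.06 * 3000 + 0.03 * 9247,
               tolerance = 1e-9)
  expect_equal(round(b$cost, 2), 550.50)
  expect_equal(b$qaly_loss,
               (0.26 * 0.09 + 0.02 * 0.125 + 0.06 * 0.03 + 0.03 * 0.08) *
                 28 / 365.25, tolerance = 1e-12)
  # the control arm has no VTE risk, so VTE contributes nothing
  bc <- ae_burden(p, "control")
  p2 <- p; p2[["cost_vte"]] <- 1e9
  expect_equal(ae_burden(p2, "control")$cost, bc$cost)
  p3 <- p; p3[grep("^risk_", names(p3))] <- 0
  expect_equal(ae_burden(p3, "treatment"), list(cost = 0, qaly_loss = 0))
})

test_that("PAP cuts the effective on-treatment ramucirumab price by one third", {
  inp <- economic_inputs()
  pap <- apply_pap(inp)
  cc0 <- maintCEA:::combo_costs(inp)
  cc1 <- maintCEA:::combo_costs(pap)
  ram_part <- inp$params[["cost_combo_cycle"]] * inp$ram_frac_of_combo
  expect_equal(cc1$on_treatment, cc0$on_treatment - ram_part / 3, tolerance = 1e-9)
  # the post-progression combination stays at nominal price
  expect_equal(cc1$pd_mix, cc0$pd_mix)
  expect_equal(2 / 3 * 616.05, 410.70)
})

test_that("intervention on-treatment cost dominates control cost at any wasting level", {
  for (wl in seq(0, 0.3, by = 0.05)) {
    inp <- economic_inputs(profile = patient_profile(weight_loss = wl))
    cc <- maintCEA:::combo_costs(inp)
    expect_gt(cc$on_treatment, inp$params[["cost_folfox_cycle"]])
    expect_gt(cc$on_treatment, inp$params[["cost_5fu_cycle"]])
  }
})

test_that("economic inputs validate mixes and respond to the profile", {
  inp <- economic_inputs()
  expect_equal(inp$params[["cost_combo_cycle"]], 6011.10, tolerance = 1e-9)
  mix_t <- inp$params[c("mix_t_folfiri", "mix_t_tas", "mix_t_bsc", "mix_t_folfox")]
  expect_equal(sum(mix_t), 1, tolerance = 1e-9)
  inp15 <- economic_inputs(profile = patient_profile(weight_loss = 0.15))
  expect_lt(inp15$params[["cost_combo_cycle"]], 6011.10)
  expect_lt(inp15$params[["cost_folfox_cycle"]], 86.40)
})

test_that("economic inputs survive a YAML round-trip", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  inp <- economic_inputs(pap = TRUE)
  inp$params[["cost_lab"]] <- 50
  i <- match("cost_lab", inp$spec$name); inp$spec$base[i] <- 50
  write_econ_yaml(inp, tmp)
  inp2 <- read_econ_yaml(tmp)
  expect_true(inp2$pap)
  expect_equal(inp2$params[["cost_lab"]], 50)
  expect_equal(inp2$params[["cost_combo_cycle"]], 6011.10, tolerance = 1e-9)
})
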