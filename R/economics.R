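# Economic inputs: reference-case parameter table, anthropometrics and
# body-surface-area dosing, per-cycle regimen costs, adverse-event burden,
# post-progression treatment mixes, and the patient-assistance-program
# price adjustment.

RAM_PRICE_PER_100MG <- 616.05  # USD per 100 mg vial, nominal
RAM_PRICE_PER_MG <- RAM_PRICE_PER_100MG / 100

#' Body surface area by the Mosteller formula
#'
#' \eqn{BSA = \sqrt{height_{cm} \cdot weight_{kg} / 3600}} square metres,
#' returned at full precision (round only for display).
#'
#' @param height_cm Height in centimetres, positive.
#' @param weight_kg Weight in kilograms, positive.
#' @return BSA in m^2.
#' @examples
#' round(bsa_mosteller(163.5, 66.9), 2)  # 1.74
#' @export
bsa_mosteller <- function(height_cm, weight_kg) {
  stop_if(any(height_cm <= 0) || any(weight_kg <= 0),
          "height and weight must be positive")
  sqrt(height_cm * weight_kg / 3600)
}

#' Patient anthropometric profile
#'
#' The reference pre-illness anthropometrics (66.9 kg, 163.5 cm) with a
#' configurable cachexia-related weight-loss fraction (0.10 in the
#' reference case, 0.15 in the severe-wasting scenario). Effective weight
#' and Mosteller BSA are derived fields.
#'
#' @param ref_weight_kg Pre-illness reference weight.
#' @param height_cm Height.
#' @param weight_loss Fraction of reference weight lost, in `[0, 0.5]`.
#' @return List with `ref_weight_kg`, `height_cm`, `weight_loss`,
#'   `weight_kg` (effective) and `bsa` (m^2), class `patient_profile`.
#' @export
patient_profile <- function(ref_weight_kg = 66.9, height_cm = 163.5,
                            weight_loss = 0.10) {
  stop_if(weight_loss < 0 || weight_loss > 0.5, "weight_loss outside [0, 0.5]")
  w <- ref_weight_kg * (1 - weight_loss)
  structure(list(ref_weight_kg = ref_weight_kg, height_cm = height_cm,
                 weight_loss = weight_loss, weight_kg = w,
                 bsa = bsa_mosteller(height_cm, w)),
            class = "patient_profile")
}

#' Define a drug regimen
#'
#' @param name Regimen label.
#' @param components Data.frame with columns `drug`, `basis`
#'   (`"per_m2"`, `"per_kg"` or `"flat"`), `dose` (mg per administration,
#'   or mg total for flat), `admins` (administrations per 28-day cycle)
#'   and `price_per_mg` (USD).
#' @return Class `regimen_def`.
#' @export
regimen_def <- function(name, components) {
  need <- c("drug", "basis", "dose", "admins", "price_per_mg")
  stop_if(!all(need %in% names(components)), "missing regimen columns")
  stop_if(any(components$dose < 0) || any(components$price_per_mg < 0) ||
            any(components$admins < 0), "doses, prices and admins must be >= 0")
  stop_if(!all(components$basis %in% c("per_m2", "per_kg", "flat")),
          "unknown dose basis")
  structure(list(name = name, components = components), class = "regimen_def")
}

#' Drug cost of one 28-day cycle for a regimen
#'
#' Sum over components of dose x (BSA | weight | 1) x administrations x
#' unit price; linear per-mg pricing without vial rounding in the
#' reference case (`vial_rounding` rounds each administration's dose up to
#' whole 100-mg vials, for exploration).
#'
#' @param regimen A [regimen_def()].
#' @param profile A [patient_profile()].
#' @param vial_rounding Round each administered dose up to 100-mg vials.
#' @return USD per 28-day cycle.
#' @export
cycle_drug_cost <- function(regimen, profile, vial_rounding = FALSE) {
  stopifnot(inherits(regimen, "regimen_def"), inherits(profile, "patient_profile"))
  comp <- regimen$components
  mult <- vapply(comp$basis, function(b) {
    switch(b, per_m2 = profile$bsa, per_kg = profile$weight_kg, flat = 1)
  }, numeric(1))
  mg <- comp$dose * mult
  if (vial_rounding) mg <- ceiling(mg / 100) * 100
  sum(mg * comp$admins * comp$price_per_mg)
}

# Intervention regimen: paclitaxel 80 mg/m2 on days 1, 8, 15 and
# ramucirumab 8 mg/kg on days 1 and 15 of each 28-day cycle. The
# paclitaxel per-mg price is calibrated once so the combination cycle cost
# equals the reference-case table value (6,011.10 USD at the 10%
# weight-loss profile); ramucirumab is priced at 6.1605 USD/mg.
combo_regimen <- function(ram_price_per_mg = RAM_PRICE_PER_MG,
                          pac_price_per_mg = NULL) {
  if (is.null(pac_price_per_mg)) pac_price_per_mg <- calibrated_pac_price()
  regimen_def("Paclitaxel+Ramucirumab", data.frame(
    drug = c("paclitaxel", "ramucirumab"),
    basis = c("per_m2", "per_kg"),
    dose = c(80, 8),
    admins = c(3, 2),
    price_per_mg = c(pac_price_per_mg, ram_price_per_mg)))
}

calibrated_pac_price <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    prof <- patient_profile(weight_loss = 0.10)
    ram_cost <- 8 * prof$weight_kg * 2 * RAM_PRICE_PER_MG
    pac_mg <- 80 * prof$bsa * 3
    cached <<- (6011.10 - ram_cost) / pac_mg
    cached
  }
})

#' Reference-case economic parameter table
#'
#' All model parameters with their base values, plausible bounds and
#' sampling distributions: per-cycle regimen costs, monitoring costs,
#' grade >= 3 adverse-event risks/costs/disutilities, end-of-life cost,
#' health-state utilities, the annual discount rate, and the
#' post-progression regimen-mix proportions of both arms. Bounds are 95%
#' intervals (most rows: +/-25% of the mean).
#'
#' @return Data.frame with columns `name`, `base`, `lower`, `upper`,
#'   `dist` (`Gamma`, `Beta` or `Fixed`) and `role`.
#' @export
parameter_table <- function() {
  p <- function(name, base, lower, upper, dist, role)
    data.frame(name = name, base = base, lower = lower, upper = upper,
               dist = dist, role = role)
  rbind(
    p("cost_folfox_cycle",   86.40,   64.80,   108.00,  "Gamma", "cost"),
    p("cost_combo_cycle",    6011.10, 4508.33, 7513.88, "Gamma", "cost"),
    p("cost_folfiri_cycle",  149.83,  112.37,  187.29,  "Gamma", "cost"),
    p("cost_5fu_cycle",      8.80,    6.60,    11.00,   "Gamma", "cost"),
    p("cost_tas_cycle",      552.68,  414.51,  690.85,  "Gamma", "cost"),
    p("cost_bsc_cycle",      211.27,  158.45,  264.08,  "Gamma", "cost"),
    p("cost_lab",            44.70,   33.52,   55.87,   "Gamma", "cost"),
    p("cost_imaging",        95.45,   71.59,   119.31,  "Gamma", "cost"),
    p("cost_neutropenia",    321.67,  241.25,  402.08,  "Gamma", "cost"),
    p("cost_anemia",         472.73,  354.55,  590.91,  "Gamma", "cost"),
    p("cost_neuropathy",     3000,    2250,    3750,    "Gamma", "cost"),
    p("cost_vte",            9247,    6935.25, 11558.75,"Gamma", "cost"),
    p("cost_eol",            1419.15, 1064.37, 1773.94, "Gamma", "cost"),
    p("risk_neutropenia_t",  0.26,    0.20,    0.32,    "Beta",  "probability"),
    p("risk_neutropenia_c",  0.09,    0.068,   0.11,    "Beta",  "probability"),
    p("risk_anemia_t",       0.02,    0.015,   0.025,   "Beta",  "probability"),
    p("risk_anemia_c",       0.03,    0.02,    0.04,    "Beta",  "probability"),
    p("risk_neuropathy_t",   0.06,    0.045,   0.075,   "Beta",  "probability"),
    p("risk_neuropathy_c",   0.07,    0.0525,  0.0875,  "Beta",  "probability"),
    p("risk_vte_t",          0.03,    0.0225,  0.0375,  "Beta",  "probability"),
    p("risk_vte_c",          0,       0,       0,       "Beta",  "probability"),
    p("u_pfs",               0.68,    0.51,    0.85,    "Beta",  "utility"),
    p("u_pd",                0.42,    0.315,   0.525,   "Beta",  "utility"),
    p("du_neutropenia",      0.09,    0.0675,  0.1125,  "Beta",  "utility"),
    p("du_anemia",           0.125,   0.09375, 0.15625, "Beta",  "utility"),
    p("du_neuropathy",       0.03,    0.02,    0.04,    "Beta",  "utility"),
    p("du_vte",              0.08,    0.06,    0.09,    "Beta",  "utility"),
    p("discount_rate",       0.05,    0,       0.08,    "Beta",  "rate"),
    p("mix_t_folfiri",       0.36,    0.27,    0.45,    "Beta",  "proportion"),
    p("mix_t_tas",           0.17,    0.1275,  0.2125,  "Beta",  "proportion"),
    p("mix_t_bsc",           0.29,    0.2175,  0.3625,  "Beta",  "proportion"),
    p("mix_t_folfox",        0.18,    0.135,   0.225,   "Beta",  "proportion"),
    p("mix_c_combo",         0.258,   0.1935,  0.3225,  "Beta",  "proportion"),
    p("mix_c_folfiri",       0.112,   0.084,   0.14,    "Beta",  "proportion"),
    p("mix_c_bsc",           0.63,    0.4725,  0.7875,  "Beta",  "proportion"))
}

#' Assemble the full economic input set
#'
#' Bundles the reference parameter table, the patient profile, drug prices
#' (with the paclitaxel per-mg price calibrated to the combination cycle
#' cost at the reference profile) and scenario switches.
#'
#' @param profile A [patient_profile()].
#' @param pap Apply the patient-assistance "buy two, get one free" scheme
#'   (intervention-arm on-treatment ramucirumab at 2/3 effective price).
#' @param price_fraction Ramucirumab nominal price multiplier in `[0, 1]`
#'   (threshold analysis), applied wherever ramucirumab is bought.
#' @param monitoring_every_n_cycles Apply laboratory + imaging cost every
#'   n-th cycle (default 1 = every cycle).
#' @param pd_cost_cap Maximum number of cycles post-progression treatment
#'   cost is applied per progressing patient (`Inf` = until death).
#' @param wtp Willingness-to-pay threshold, USD per QALY.
#' @return List of class `econ_inputs`; `$params` is a named base-value
#'   vector, `$spec` the full [parameter_table()].
#' @export
economic_inputs <- function(profile = patient_profile(), pap = FALSE,
                            price_fraction = 1,
                            monitoring_every_n_cycles = 1,
                            pd_cost_cap = Inf, wtp = 40457.32) {
  stop_if(price_fraction < 0, "price_fraction must be >= 0")
  spec <- parameter_table()
  params <- stats::setNames(spec$base, spec$name)
  # combination cycle cost re-derived from component dosing at this profile
  reg <- combo_regimen()
  params[["cost_combo_cycle"]] <- cycle_drug_cost(reg, profile)
  ram_cost <- 8 * profile$weight_kg * 2 * RAM_PRICE_PER_MG
  # BSA-dosed chemotherapy costs scale with BSA relative to the reference
  # profile the table was costed at (10% weight loss)
  ref_bsa <- patient_profile(weight_loss = 0.10)$bsa
  for (nm in c("cost_folfox_cycle", "cost_folfiri_cycle", "cost_5fu_cycle",
               "cost_tas_cycle")) {
    params[[nm]] <- params[[nm]] * profile$bsa / ref_bsa
  }
  mix_t <- params[c("mix_t_folfiri", "mix_t_tas", "mix_t_bsc", "mix_t_folfox")]
  mix_c <- params[c("mix_c_combo", "mix_c_folfiri", "mix_c_bsc")]
  stop_if(abs(sum(mix_t) - 1) > 1e-9 || abs(sum(mix_c) - 1) > 1e-9,
          "post-progression mix proportions must sum to 1")
  structure(
    list(params = params, spec = spec, profile = profile,
         ram_frac_of_combo = ram_cost / params[["cost_combo_cycle"]],
         pap = pap, price_fraction = price_fraction,
         monitoring_every_n_cycles = monitoring_every_n_cycles,
         pd_cost_cap = pd_cost_cap, wtp = wtp),
    class = "econ_inputs")
}

#' Apply the patient-assistance program price adjustment
#'
#' "Buy two, get one free": the effective ramucirumab price for the
#' intervention arm's maintenance treatment is multiplied by 2/3. All
#' other prices - including the control arm's post-progression use of the
#' combination at nominal price - are unchanged, so QALYs are unaffected.
#'
#' @param inputs An `econ_inputs`.
#' @return The inputs with `pap = TRUE`.
#' @export
apply_pap <- function(inputs) {
  stopifnot(inherits(inputs, "econ_inputs"))
  inputs$pap <- TRUE
  inputs
}

# effective per-cycle on-treatment drug cost of the intervention arm and
# the combination cost used in the control arm's post-progression mix
combo_costs <- function(inputs, params = inputs$params) {
  combo <- params[["cost_combo_cycle"]]
  rf <- inputs$ram_frac_of_combo
  f <- inputs$price_fraction
  papf <- if (isTRUE(inputs$pap)) 2 / 3 else 1
  list(on_treatment = combo * ((1 - rf) + rf * f * papf),
       pd_mix = combo * ((1 - rf) + rf * f))
}

#' Post-progression mix cost per cycle
#'
#' Weighted mean of component per-cycle costs; proportions must sum to 1.
#'
#' @param proportions Named or unnamed numeric vector of mix proportions.
#' @param costs Per-cycle USD costs, same order.
#' @return USD per cycle.
#' @examples
#' pd_mix_cost(c(0.36, 0.17, 0.29, 0.18), c(149.83, 552.68, 211.27, 86.40))
#' @export
pd_mix_cost <- function(proportions, costs) {
  stop_if(length(proportions) != length(costs), "length mismatch")
  stop_if(abs(sum(proportions) - 1) > 1e-6, "proportions must sum to 1")
  sum(proportions * costs)
}

#' One-off adverse-event burden for an arm
#'
#' Expected management cost and QALY loss over the grade >= 3 events
#' (neutropenia, anemia, peripheral neuropathy, VTE), applied once at
#' treatment initiation; each disutility is carried for one cycle.
#'
#' @param params Named parameter vector (see [parameter_table()]).
#' @param arm `"treatment"` or `"control"`.
#' @return List with `cost` (USD) and `qaly_loss`.
#' @export
ae_burden <- function(params, arm = c("treatment", "control")) {
  arm <- match.arg(arm)
  sfx <- if (arm == "treatment") "_t" else "_c"
  ev <- c("neutropenia", "anemia", "neuropathy", "vte")
  risks <- params[paste0("risk_", ev, sfx)]
  costs <- params[paste0("cost_", ev)]
  dus <- params[paste0("du_", ev)]
  list(cost = sum(risks * costs),
       qaly_loss = sum(risks * dus) * CYCLE_YEARS)
}
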