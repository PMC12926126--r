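---
title: "Methods: from published survival curves to a cost-effectiveness verdict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from published survival curves to a cost-effectiveness verdict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

maintCEA implements a complete trial-based cost-effectiveness analysis of
switch maintenance with ramucirumab + paclitaxel versus continued
oxaliplatin-based chemotherapy in advanced HER2-negative gastric and
gastroesophageal junction cancer. This vignette is the package's own
account of the science: the model, its assumptions, the defaults and why
they are set where they are, the numerical choices, and what the test
suite does and does not establish.

## Pseudo individual-patient data

Published survival evidence arrives as a figure: digitized click
coordinates $(t_k, S_k)$ and a numbers-at-risk table $(T_i, n_i)$. The
reconstruction inverts the Kaplan–Meier estimator interval by interval:
within each inter-risk interval the number of censorings is adjusted
iteratively (censoring times spread uniformly — the algorithm's standard
assumption, since publications report no censoring detail) until the
implied count at the next at-risk time matches the published one, while
event counts at each click are the rounded solution of the product-limit
recursion. The final interval assumes no censoring before the last click
unless a reported total event count is supplied, in which case events in
that interval are rescaled to match. The procedure is deterministic.

Three validation properties guard it: a round-trip (the KM curve of the
reconstruction stays within $|\Delta S| \le 0.02$ of the digitized points
for $n = 200$ arms), count conservation (subjects entering the first
interval equal the first at-risk count; boundary counts match the
published table up to the one-subject slack that integer rounding can
leave when the censoring budget is exhausted), and determinism.

Curve validation clamps survival upticks of at most $10^{-6}$
(digitization jitter) to the previous value; larger increases are
errors. A missing $(0, 1)$ anchor is inserted with a warning. At-risk
rows with a zero count after the first row are dropped before inversion:
they constrain nothing beyond the curve itself, and keeping them would
force the inversion to censor subjects whose deaths the curve still
records. Time is in months throughout, with 1 month = 365.25/12 days.

## The fifteen-family survival zoo

Each arm/endpoint is fitted by maximizing the censored-data
log-likelihood $\ell = \sum_i d_i \log h(t_i) + \log S(t_i)$ over:

* the classical parametric families (exponential, Weibull, gamma,
  log-normal, Gompertz, log-logistic, generalized gamma), via
  `flexsurv`;
* Royston–Parmar restricted cubic splines in $\ln t$ on three scales —
  log cumulative hazard ("RP-hazard"), log failure odds ("RP-odds"),
  probit ("RP-normal") — each with 1 internal knot at the median
  uncensored log time by default (0–3 configurable), plus a 2-knot
  log-cumulative-hazard spline kept as a distinct "RCS" row. The two
  spline rows are listed separately because published model zoos list
  them separately; with no published specification of the distinction,
  the knot counts are the design choice here.
* fractional polynomials on the log-hazard scale,
  $\ln h(t) = \beta_0 + \beta_1 t^{p_1} (+\, \beta_2 t^{p_2})$ with
  powers from $\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$, $t^0 \equiv \ln t$,
  and the usual $t^p \ln t$ convention for repeated powers. Powers are
  profile-selected (every power/pair refitted, best likelihood kept) and
  not counted in $k$, matching common practice; `count_fp_powers = TRUE`
  switches that. The cumulative hazard uses closed forms where they
  exist ($p \in \{0, 1\}$ single-term) and otherwise 64-node
  Gauss–Legendre quadrature under the substitution $u = t v^2$, which
  clusters nodes near zero where negative powers make the hazard steep;
  non-integrable corners of the parameter space (e.g. a positive
  coefficient on $t^{-2}$) are detected analytically and assigned
  $\ell = -\infty$. The exported survival evaluator integrates the
  hazard adaptively at relative tolerance $10^{-8}$.
* a penalized piecewise-exponential smoother ("GAM"): follow-up split
  into 28-day cells, cell event counts modelled as Poisson with a
  log-exposure offset and a penalized thin-plate smooth of time (REML),
  the survival likelihood recovered from the fitted cell hazards, and
  the smoother's total effective degrees of freedom entering $k$. Beyond
  the data the last cell hazard is carried forward.
* a Weibull mixture-cure model $S(t) = \pi + (1 - \pi) S_w(t)$, cure
  fraction on the logit scale initialized at the last observed KM value,
  fitted by BFGS with five seeded random restarts.

$AIC = 2k - 2\ell$ and $BIC = k \ln n - 2\ell$ with $n$ the number of
subjects (not events) — the convention in survival-extrapolation
practice; the source is silent on this. Selection takes the minimum AIC;
exact ties break by lower BIC, then in favour of the *later* family in
canonical order. That last tie-break deserves a word: an exact AIC+BIC
tie between a flexible family and its nested special case (probit-scale
spline with zero effective knots versus log-normal, say) means the two
fitted survival functions coincide, so the choice cannot affect the
model; resolving toward the flexible listing mirrors how such ties are
reported in practice. A `criterion = "BIC"` switch and a
visual-inspection `override` argument are provided.

Nesting identities are verified numerically in the tests: the 0-knot
spline variants reproduce Weibull / log-normal / log-logistic
likelihoods to $10^{-4}$; FP1 with zero slope is exponential; the
mixture-cure likelihood at $\pi \to 0$ is its base Weibull.

## The Markov cohort model

Three mutually exclusive states — progression-free (PFS), progressed
(PD), dead — over 130 cycles of 28 days (10 years); everyone starts in
PFS. The published analysis names the transitions but not their
derivation from the two marginal curves, so the package uses the
construction that reproduces both marginals exactly when the curves do
not cross: the overall-survival hazard claims occupants of both alive
states, $q_{death}(t) = 1 - S_{os}(t+1)/S_{os}(t)$, and progression is
the residual of PFS exit, $p_{PFS \to PD}(t) = \max(0,\, q_{exit} -
q_{death})$. If a fitted PFS curve sits above the OS curve the residual
clamps to zero (logged, not an error). Absent clamping, death occupancy
equals $1 - S_{os}(t)$ exactly and the trace rows sum to one to
$10^{-10}$; both are tested, as is agreement with a $3 \times 3$
matrix-power oracle under constant probabilities ($10^{-12}$).

Costs per cycle: on-treatment drug cost while progression-free
(intervention: the combination until progression; control: oxaliplatin
doublet for cycles 1–3 — oxaliplatin stops at week 24 having started
12 weeks before model entry — then fluoropyrimidine maintenance),
post-progression mix cost per PD cycle, monitoring (laboratory 44.70 +
imaging 95.45 USD) for both alive states every cycle
(`monitoring_every_n_cycles` available; trial follow-up was 12-weekly),
end-of-life cost (1,419.15 USD) on incident deaths in their cycle, and a
one-off adverse-event cost at entry. QALYs weight time in state by
utilities 0.68 (PFS) and 0.42 (PD) times 28/365.25 years per cycle, less
a one-off entry decrement of one cycle's duration for adverse events —
treatment-initiation events in the source trial. Discounting is
$(1+r)^{-t \cdot 28/365.25}$ at $r = 5\%$/year (0–8% explored). No
half-cycle correction by default (none is mentioned in the source); a
flag exists. Post-progression cost runs until death by default with a
duration-cap option implemented by tracking progression cohorts by time
since entry; the published per-arm totals are hard to reconcile with any
single convention, and no intent is guessed.

The willingness-to-pay threshold is stored as the printed constant
40,457.32 USD/QALY (three times 2024 per-capita GDP; recomputing
3 × 13,485.77 gives 40,457.31 — the printed value wins, both noted).
Display rounding never feeds back into computation: incremental cost and
effect are carried at full precision, which is why a table showing
53,342.45 / 0.39 can legitimately print an ICER that is not their
two-decimal quotient.

## Economics

Dosing uses the Mosteller formula $BSA = \sqrt{h_{cm} w_{kg}/3600}$ at a
pre-illness reference of 66.9 kg / 163.5 cm. Advanced-GEJ patients are
mostly cachectic, so the base case assumes 10% weight loss (effective
60.21 kg, BSA 1.6536 m²) and the severe-wasting scenario 15%
(56.865 kg, 1.6071 m²); BSA is kept at full precision and rounded only
for display. Pricing is linear per mg without vial rounding — the
published combination cycle cost (6,011.10 USD) is consistent with
per-mg billing of ramucirumab at 6.1605 USD/mg but not with 100-mg vial
round-up; a `vial_rounding` flag exists for exploration. No paclitaxel
unit price is published, so it is calibrated once so that the
combination cycle cost equals 6,011.10 USD at the base profile
(residual 76.32 USD over 396.9 mg, i.e. 0.1923 USD/mg). Under the
weight-loss scenario all BSA-dosed chemotherapy costs scale with the BSA
ratio and the combination is recomputed from component dosing.

The patient-assistance program ("buy two, get one free", all patients
assumed eligible) multiplies the *effective* on-treatment ramucirumab
price by 2/3 for the intervention arm only; the control arm's
post-progression use of the combination stays at nominal price, which is
what keeps the control arm's totals fixed across the PAP scenario. The
threshold-analysis price fraction, by contrast, models a *nominal* price
cut and therefore rescales ramucirumab wherever it is bought. QALYs are
invariant under both, a tested property.

## Uncertainty analysis

One-way analysis sets each parameter to its lower/upper bound (95%
bounds from the parameter table, mostly ±25% of the mean; discount rate
0–8%) with everything else at base, on the fixed cohort traces; mix
proportions are renormalized within their arm, utilities capped at 1.
Probabilistic analysis moment-matches each row — $SE = (upper -
lower)/3.92$; Gamma with $shape = \mu^2/SE^2$, $scale = SE^2/\mu$ for
costs; Beta with $\alpha = \mu(\mu(1-\mu)/SE^2 - 1)$ for probabilities
and utilities — and draws 1,000 parameter vectors under a single master
seed. The discount rate is held at base in the PSA by reference-case
convention despite having a listed distribution
(`include_discount = TRUE` to sample it); mix proportions are sampled
independently per row and renormalized, as no joint (Dirichlet) scheme
is published. Survival parameters are not resampled: transition
probabilities enter the PSA at their point estimates, so the CEAC
reflects economic-parameter uncertainty only — a deliberate narrowing,
flagged as a limitation. Non-finite draws are rejected and resampled
with a logged count. The acceptability curve is
$P(\lambda \Delta E - \Delta C > 0)$ over a threshold grid.

Threshold search bisects the price fraction on $[0, 1]$ until
$|ICER(f) - \lambda| < 0.5$ USD/QALY; since $\Delta C$ is affine in the
fraction and $\Delta E$ constant, the ICER is monotone and the tests
compare the result against the closed-form crossing of the affine
bracket as an independent oracle, besides re-running the model at the
returned fraction.

## The synthetic study

The source trial's curves are not printed and cannot be redistributed,
so the generator emulates their structure rather than their values: two
arms (140/136 subjects — the enrolment split rounded), PFS and OS per
arm with control PFS Weibull (median 6 months, shape 1.3), treatment PFS
log-logistic (median 9, shape 1.8), control OS Weibull (median 12, shape
1.3 — sharing the PFS shape keeps the comonotone coupling from ever
crossing), treatment OS log-normal (median 16, sdlog 0.8); exponential
drop-out at 0.01/month plus administrative censoring at 36 months;
KM click grids of 60 points with ±0.002 uniform digitization jitter and
exact 12-weekly at-risk tables. PFS and OS share a subject-level uniform
draw (comonotone coupling) so progression never outlives the subject;
residual violations across different families fall back to
PFS = OS × Beta(4, 2). Effect sizes were chosen once so the treatment
arm gains QALYs at a high incremental cost — the qualitative regime of
the published analysis (ICER far above threshold, zero acceptability at
the threshold, PAP lowering but not rescuing the ICER, a threshold
fraction well below 1) — and are not adjusted thereafter.

What passing tests show: the machinery is internally consistent, the
reconstruction inverts what the generator digitizes, fitted families
recover generating medians within 10% at $n = 500$, and the pipeline's
qualitative conclusions are stable. What they do not show: agreement
with the published absolute totals, which require the original curves;
and model-selection sharpness — across 20 replicates the generating
family lands in the AIC top three about three-quarters of the time,
because flexible superset families (generalized gamma, FP2) can edge out
the truth by small margins. That is a property of AIC among overlapping
families, not a defect the tests hide.

## Numerical choices, in one place

* Optimizers: BFGS with analytic gradients for the fractional
  polynomials, relative tolerance $10^{-10}$ on the objective; five
  seeded restarts for the 3-parameter mixture-cure model; `flexsurv`
  defaults elsewhere; REML for the hazard smoother.
* Convergence failures are flagged and excluded from selection with a
  warning, never silently dropped.
* Degenerate inputs error early: all-censored data, fewer than 3 events
  for ≤2-parameter families or 5 for larger ones, zero at-risk at start,
  survival rising from zero.
* Year = 365.25 days; month = 365.25/12 days; cycle = 28 days
  (0.9199 months); all conversions flow from these.
* Problem sizes in the test suite — $n = 200$ round-trips, $n = 500$
  recovery, 1,000 PSA draws, 130-cycle traces — are the analysis's own
  reference conditions.

## Known limitations

* The transition construction assumes the OS hazard applies equally to
  both alive states; with strong state-dependent mortality this
  under-specifies PD mortality.
* PSA omits survival-parameter uncertainty (see above).
* The cohort-level duration cap on post-progression cost assumes
  death-only exit from PD when apportioning time since progression.
* AIC/BIC values, and therefore selected families, on synthetic data
  will not match the published goodness-of-fit table, which depends on
  the unavailable source curves.
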