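---
title: "Methods: trial-based cost-effectiveness analysis of closed-loop initiation from CGM outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis of closed-loop initiation from CGM outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmcea)
```

# The problem

Closed-loop (automated insulin delivery) systems are the standard of care in
type 1 diabetes, but access depends on how initiation is organized. `cgmcea`
implements a trial-based (non-modeled) cost-effectiveness analysis comparing
two care models over a one-year horizon from the payer perspective: an
out-of-hospital initiation pathway (arm label `CIRDIA`, an office-visit-based
multisite model) against conventional hospital-based initiation (`HC`, a
day-hospitalization-based model). Effectiveness is the CGM time in range
(TIR, 70–180 mg/dL); safety is the Glycemia Risk Index (GRI). Costs are
built bottom-up from care-pathway events priced against a tariff catalog.

# Glycemic metrics

A CGM trace is summarized into the occupancy of five consensus glucose
bands: `<54`, `54–69`, `70–180`, `181–250` and `>250` mg/dL. On a continuous
glucose value `g` the edge convention is: very low `g < 54`; low
`54 <= g < 70`; in range `70 <= g <= 180`; high `180 < g <= 250`; very high
`g > 250` — integer band labels are honored with no gaps. Readings are
weighted by their sampling-interval duration, capped at twice the median
interval; under uniform sampling (the typical 5-minute CGM grid) this is
equal weighting, and the package assumes reading-weighted and time-weighted
percentages coincide.

The GRI compresses the out-of-range occupancies into one risk score:

$$\mathrm{hypo} = \%{<}54 + 0.8\cdot\%{54\text{–}69},\qquad
  \mathrm{hyper} = \%{>}250 + 0.5\cdot\%{181\text{–}250}$$
$$\mathrm{GRI} = \min\!\big(100,\; 3.0\,\mathrm{hypo} + 1.6\,\mathrm{hyper}\big)$$

The coefficient set (3.0, 1.6, 0.8, 0.5) and the clip at 100 come from the
metric's source publication; they are fixed constants, not tunables. Risk
zones are the equal 20-point quintiles of the score, upper-closed:
A `[0,20]`, B `(20,40]`, C `(40,60]`, D `(60,80]`, E `(80,100]`, so the zone
map is total and gap-free on `[0,100]`. Zone grids report the count and
fraction of a cohort in zones C–E ("intermediate or higher risk").

# Micro-costing

Costs follow a bottom-up micro-costing design: each patient's care pathway
is a list of `(nomenclature source, code, quantity)` items priced as
`quantity × unit tariff` against a `tariff_catalog` keyed by the French
payer nomenclatures (NGAP professional acts, CCAM procedures, NABM
laboratory acts, LPP devices, GHS hospital-stay tariffs). With a one-year
horizon no discount rate is applied, and the payer perspective for a fully
covered condition means no out-of-pocket share. Per-arm summaries report the
sample mean, the sample SD (n−1 denominator; a singleton arm reports SD 0
with a warning) and the total, and the package enforces
`total = n × mean` in its own outputs. The shipped catalog
(`inst/extdata/tariff_catalog_synthetic.csv`) contains *synthetic
placeholder tariffs* of realistic magnitude; real published tariff values
must be supplied by the user for any real costing exercise.

# Incremental analysis

For intervention vs comparator arm summaries, increments are componentwise
differences: ΔC (EUR), ΔE (TIR points) and ΔS (GRI points; negative is an
improvement). The ICER is ΔC/ΔE, EUR per TIR point gained; the ICSR is
expressed as a positive magnitude |ΔC|/|ΔS|, EUR per GRI point reduced.
Negative ratios are never reported bare: every ratio carries the dominance
label of its quadrant (ISPOR convention), and when the outcome increment is
within an equality tolerance of zero a flag replaces the ratio
(cheaper-and-equal = dominant; costlier-and-equal = dominated; an outcome
gain at zero incremental cost is dominant). The dominance classifier is a
total function of (ΔC, Δoutcome): dominant, dominated, tradeoff_NE
(costlier and better), tradeoff_SW (cheaper and worse), indifferent (equal
cost). The equality tolerance defaults to 1e-9 — effectively exact
arithmetic for published summary inputs — and is configurable for real
patient-level data, where "equally effective" is a substantive choice.
Effectiveness (cost–TIR) and safety (cost–GRI) are two separate planes.

Two ratio conventions coexist for the worked base case: from the *printed*
increments (−441.20/0.70 and −441.20/−0.22) the ratios are −630.29 and
2005.45; published analyses that keep unrounded intermediate values print
−625.83 and 2011.02, a ≤1% difference attributable purely to input
rounding. The package computes from its inputs and documents both.

# Probabilistic sensitivity analysis

Uncertainty is propagated by joint Monte Carlo sampling of all six
arm-level parameters — per-arm cost, TIR and GRI — each draw giving a point
on the two cost-effectiveness planes:

* costs: gamma distributions, moment-matched (`shape = (mean/SD)^2`,
  `scale = SD^2/mean`), so draws are strictly positive;
* TIR and GRI: normal distributions truncated to `[0,100]`, parameterized by
  the parent normal's mean/SD with no truncation-moment correction (the
  common applied convention);
* all six parameters independent — no correlation structure is imposed.

Quadrants use strict signs (SE = less costly & more effective, SW, NE, NW);
exact zeros, a probability-zero event under continuous sampling, are
assigned by the sign of the base-case increment. Design choices worth
stating:

* **SD vs SE uncertainty scale.** The package defaults to sampling with the
  printed arm-level SDs (`psa_config(scale = "sd")`). Scaling to standard
  errors (`scale = "se"`) shrinks uncertainty by √n and drives the
  proportion-less-costly to ≈100%; the SD convention reproduces published
  PSA proportions in this application far better and is exposed as a switch
  rather than hard-coded. Under it the analytic proportion-less-costly for
  the default inputs is Φ(441.20/√(427.3² + 192²)) ≈ 0.83.
* **Degenerate limit.** All SDs = 0 collapses every draw onto the base case
  (with a warning), so the PSA is continuous with the deterministic CEA.
* **Determinism.** Every stochastic routine takes a seed and restores the
  caller's RNG state (`withr::local_seed`), so identical inputs are
  bit-identical and independent runs do not interact.

# Group statistics

Between-arm comparisons pass each sample through a Shapiro–Wilk gate at
α = 0.05 (the level is a package choice): if both samples look normal, a
two-tailed Student t test; otherwise the Wilcoxon rank-sum (Mann–Whitney)
test — the rank-sum test, not the signed-rank test, because the arms are
independent groups. Subgroup tables stratify by the age classes `[16,25)`,
`[25,45)`, `[45,65)`, `[65,∞)` (half-open, so the classes partition the
cohort) plus a total row. Because arm membership is not randomized, the
package provides inverse probability of treatment weighting: a logistic
propensity model of arm on chosen covariates, stabilized weights
(prevalence/propensity), truncation at the weights' 1st/99th percentiles,
and weighted arm summaries plus weighted standardized mean differences for
balance checking. Covariate list and weight specification are user
parameters; the defaults (age, BMI, baseline TIR and GRI) target the
baseline imbalance this design exhibits.

# The synthetic cohort generator

No patient-level data are distributed, so the generator is the package's
substrate for testing and demonstration. It emulates:

* arm sizes 128/73; ages 16–80 drawn within published age-class
  proportions; 52% women; BMI truncated-normal per arm;
* TIR and GRI at M0 and M12 as truncated normals on `[0,100]` matching the
  published per-arm means/SDs — consistent with the PSA's distributional
  assumption;
* dependence via a Gaussian copula whose 4×4 latent correlation is the
  Kronecker product of a timepoint block and a metric block: within-patient
  M0→M12 correlation 0.4 (not published; exposed as `rho_time`) and TIR–GRI
  rank correlation −0.85 (both metrics summarize one profile; exposed as
  `rho_tir_gri`). The Kronecker construction keeps the matrix positive
  semi-definite for any admissible pair.
* care-pathway events: one initiation (day hospitalization for every
  hospital patient; with probability 0.13 for out-of-hospital patients,
  matching the published 13%), 3 teleconsultations, 3 consultations, a
  telemonitoring package with uptake 0.5 (uptake depended on initiation
  date and is not published; exposed as a parameter), and 12 months of
  device/consumable rental;
* per-patient costs calibrated so each arm hits its published mean/SD
  (8373.12/427.30 and 8814.32/192 EUR): the fixed events' mean and variance
  are known in closed form (Bernoulli initiation mode and telemonitoring
  uptake), and the device/consumable charge — the dominant, least
  publicly-decomposed component — absorbs the residual as a moment-matched
  gamma. Costs are therefore strictly positive by construction.

CGM traces are generated non-physiologically: reading counts per band by
largest-remainder rounding, uniform glucose within bands, deterministic
seed-keyed shuffle. They have exactly the requested band occupancy (within
the rounding granularity `100/n` readings) but no meal/insulin dynamics, no
autocorrelation and no diurnal structure — adequate for validating
occupancy arithmetic, not for testing dynamics-sensitive methods.

What passing tests on this generator do **not** show: real CGM data have
serial correlation and non-Gaussian tails; real cost data are mixtures with
point masses at tariff multiples, not smooth gammas; and the real arms
differ in unmeasured ways no generator parameter represents. The generator
validates the pipeline's arithmetic and statistical behavior, not clinical
conclusions.

# Numerical choices and problem sizes

* Truncated-normal sampling is inverse-CDF (`qnorm` on a uniform restricted
  to the truncation mass), exact up to floating point; draws are clamped to
  the bounds to guard extreme-quantile rounding.
* Moment-recovery tests compare sample moments against the *truncated*
  distribution's closed-form moments (`tnorm_moments`), not the parent
  parameters, so truncation bias is handled analytically rather than by
  widened tolerances.
* Largest-remainder rounding ties break by band order (deterministic).
* The test suite uses 5000 patients/arm for moment recovery, 10,000–200,000
  Monte Carlo draws for PSA checks, 200 random targets for trace
  round-trips, 1e5 points for the quadrant oracle and 2000 null replicates
  for the type-I-error check of the gated comparison — sizes chosen so
  binomial/standard-error tolerances (3–4 SE) are tight while the whole
  suite runs in well under a minute.

# Known limitations

* The tariff catalog is synthetic; headline cost levels are only as real as
  the catalog supplied.
* The PSA ignores parameter correlation (none is published); correlated
  cost-effect draws would widen or narrow quadrant proportions.
* No willingness-to-pay thresholds, acceptability curves or net monetary
  benefit: no WTP value exists for a TIR point, so dominance classification
  is the decision output.
* One-year horizon only; no discounting machinery beyond the explicit
  no-discount rule.
* HbA1c is deliberately absent as an outcome (no longer systematically
  measured in this care setting).
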