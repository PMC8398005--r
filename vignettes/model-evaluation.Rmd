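---
title: "External evaluation of infliximab population PK models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{External evaluation of infliximab population PK models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ifxeval` implements the machinery of an external evaluation of published
population pharmacokinetic (popPK) models of infliximab: the models
themselves, population and MAP empirical-Bayes prediction, residual
diagnostics (PWRES/IWRES/NPDE), prediction-corrected visual predictive
checks, and Bayesian trough forecasting. Because individual patient TDM data
of this kind cannot generally be shared, the package also ships a synthetic
cohort generator that emulates the marginal structure of a real-world
evaluation population, so that the whole pipeline is testable against known
truth. This vignette records the models, procedures, numerical choices and
their rationale.

## The model registry

Eight published models (`A`–`H`) are encoded from their sources: one- or
two-compartment linear disposition with zero-order IV infusion input, typical
parameters (`CL`, `V1`, and `V2`, `Q` for two-compartment models),
multiplicative covariate equations, diagonal log-normal inter-individual
variability (IIV), inter-occasion variability (IOV) on clearance for model
`G` (18.3%), and a residual-error specification per model.

Covariate terms take four functional forms, all multiplicative on a
structural parameter:

* `power`: `(x / center)^theta` — allometric weight and albumin terms,
  e.g. `CL = 0.23 · (WT/67)^0.603 · …` (model A);
* `exp_linear`: `exp(theta · x)` — 0/1 flags (sex, disease, methotrexate);
* `ratio_power`: `theta^(x − center)` — printed ratio effects such as
  `1.722^ADA` (model E) or `0.964^(HBI−6)`;
* `factor`: `1 + theta · x` — model F's ADA effect `(1 + 1.59 · ADA)`.

Evaluating a model at its reference covariates reproduces its published
typical values exactly; this is enforced by the constructor and asserted in
the test suite. `strip_covariates()` returns the covariate-free variant used
for the re-evaluation without covariates (all factors pinned at 1, typical
values unchanged; idempotent).

Design choices where the sources are ambiguous:

* **Model E central volume.** The printed linear form
  `4.94 · 0.964 · (HBI − 6)` yields non-positive volumes for HBI ≤ 6 and is
  treated as a typographical artifact of the power form
  `V1 = 4.94 · 0.964^(HBI−6)`, which is what the registry implements.
* **Model E sex coding.** The other models code `SEX` as 0 = female,
  1 = male; model E's coding is reversed (female = 1 carries the 1.345
  factor). The coding is a per-model field (`sex_coding`), overridable.
* **Model E treatment period.** `1.40^PERIOD` is coded with induction = 1,
  maintenance = 0 (reference), the induction phase carrying the higher
  clearance.
* **Model G weight exponents** are implemented with the negative signs as
  printed in the source table, although volumes decreasing with weight are
  physiologically unusual; the registry is a transcription, not a
  re-estimation.
* **Residual-error conventions.** Models published from Monolix (`A`–`D`)
  compose combined errors as `sd = σ_add + σ_prop·f`; NONMEM-derived models
  (`E`–`H`) as `sd = sqrt(σ_add² + (σ_prop·f)²)`. The convention is a
  per-model field. Model `F`'s source does not report a residual model; the
  registry carries the imputed combined error `σ_add = 0.80` mg/L,
  `σ_prop = 22%` (median of the published models).
* **IIV magnitudes** are not reprinted in the source table; the registry
  ships a default of 30% (log-scale SD) on `CL` and `V1`, clearly an
  assumption. All self-consistency tests simulate and evaluate under the
  same Ω, so their conclusions do not hinge on this default.
* **Eligibility windows.** Model D's "first six months of treatment" is
  implemented as time since first dose ≤ 183 days; "adults" uses the age
  dichotomy the models themselves use (pediatric < 15 years).

## The prediction engine

Internal units are days, mg, L (clearances in L/day). Concentrations under
constant parameters use closed-form superposition of per-infusion analytic
solutions; the two-compartment eigenvalues are computed in the stable
sum/product form (`β = k10·k21/α`) to avoid cancellation when `Q ≪ CL`.
When parameters change over time — covariate records are piecewise-constant
(last observation carried forward), and IOV gives each inter-infusion
interval its own clearance — amounts are propagated exactly across segments
with the 2×2 matrix exponential (Lagrange form; Jordan-form limit at a
repeated eigenvalue). A numeric `deSolve::lsoda` oracle integrates the same
mass-balance equations segment by segment at tolerances of 1e-11 and is used
only as an independent cross-check; the test suite requires closed form and
oracle to agree within 1e-6 relative error (relative to concentrations
floored at 1e-3 mg/L, far below the assay LLOQ, since below that level the
oracle's own absolute tolerance dominates).

Residual draws that would produce negative concentrations are truncated at
zero. The truncation puts a probability atom at zero for very low troughs;
the NPDE machinery accounts for it (below). The default infusion duration is
2 h (0.0833 days), configurable — true durations are not reported, and no
result here is asserted to be sensitive to it.

## Synthetic cohorts

`cohort_config()` encodes the evaluation-population summaries: 157 subjects,
52.2% female, weight median 68 kg (range 24–150), median 23 infusions per
subject at median 44-day intervals (14–79), median dose 400 mg (180–1000,
constant per subject), trough-only sampling with median 2 samples per
subject (1–6), 7.6% ADA-positive, and a Crohn-dominated disease mix. Only
medians and ranges are published, so the parametric forms are package
choices: truncated log-normals for weight, age, intervals and dose with
`sdlog` 0.2–0.35 and medians fixed at the published medians (verified
analytically against the truncated quantile function before any test was
written), a shifted negative binomial (2 + NB(μ=22, size=8)) whose truncated
median is 23 for infusion counts, and a uniform 0–24 h pre-infusion offset
for trough times. Disease percentages are normalised to sum to 1 (the real
population contains multi-pathology patients, so the published percentages
sum to 103.2%). Albumin (`N(40, 4)` g/L truncated to 25–55) and the
Harvey–Bradshaw index (Poisson(4)) are needed by models `E`–`H` but not
published for this population; they are field-realistic assumptions. ADA
status is assigned at baseline and held constant (seroconversion times are
not available). Joint covariate correlations (e.g. dose–weight) are
deliberately not modelled: passing tests show the pipeline's statistical
machinery is sound under a realistic marginal structure, not that the
generator reproduces any real cohort's joint distribution.

Quantification limits follow the assay: observations below 0.3 mg/L are
excluded, values above 40 mg/L (the dilution ceiling) are excluded, and
exclusions are logged. Null-calibration checks of the diagnostics run on
unfiltered simulated data, because applying an inclusion rule to the
observations but not to the simulated reference distribution would distort
the null itself.

## MAP estimation and forecasting

`map_estimate()` maximises
`log N(y | f(θ_typ·e^η), sd_res(f)) + log N(η | 0, Ω)` over η (and, for
models with IOV, per-occasion κ on clearance for the occasions that contain
observations), with population parameters fixed. Optimisation runs in
unconstrained η-space via `nlminb` from η = 0 plus four deterministically
jittered starts (objective tolerance 1e-8); residual SDs are floored at
1e-8 mg/L to keep the objective finite at zero predictions. Zero
observations return the prior mode. As Ω → 0 the estimate collapses to the
typical values; with rich noiseless data it recovers the simulated
parameters (both are asserted in tests).

Forecasting estimates individual parameters from the data available up to
the anchor infusion *n* and predicts the troughs of infusions *n*, *n*+1,
*n*+2 noiselessly at the MAP parameters, using the actually administered
doses. The estimation window is "observations at or before the *n*-th
infusion time": the trough drawn just before infusion *n* is the last datum
included, and the trough of infusion *n*+1 — a forecast target — is
excluded. Future covariate values are unknown at forecast time, so
predictions carry the last covariate record inside the window forward;
future occasions keep κ = 0 (the prior mode). Per-horizon ME/MPE/RMSE
delegate to the same metric implementation used everywhere else.

## Metrics and residual diagnostics

For observations `y` and predictions `ŷ`:
`ME = mean(ŷ − y)` (mg/L, with 95% t-interval and Student test),
`MPE% = 100·mean((y − ŷ)/y)`, `RMSE% = 100·sqrt(mean(((y − ŷ)/y)²))`,
`R² = 100·cor(y, ŷ)²`, plus a Spearman rank correlation test. Note the sign
conventions: ME is prediction minus observation while MPE/RMSE are relative
to the observation — both exactly as used in the external-evaluation
literature. Relative metrics require LLOQ-filtered (positive) observations
and refuse to divide by zero.

**PWRES** are simulation-based: K replicate observation vectors per subject
give an empirical mean and covariance; PWRES is the lower-Cholesky
decorrelated difference between the observed vector and the simulation mean
(an eigenvalue floor handles near-singular empirical covariances, and the
fallback is flagged). **IWRES** are `(y − IPRED)/sd_res(IPRED)`.

**NPDE** simulate 2K replicates per subject: the first K estimate the
decorrelation mean and Cholesky factor, and the observation is ranked among
the remaining K reference replicates after both are decorrelated with the
same transform. The split matters: ranking the observation inside the same
batch that estimates the decorrelation induces within-subject dependence
and a ≈1% variance inflation at K = 200, which is enough to distort the
size of the variance test. With the split, observation and reference
replicates are exactly exchangeable under the true model. The prediction
discrepancy uses the deterministic mid-rank position
`pde = (r + ½)/(K + 1)` with ties counted half
(`r = #below + #equal/2`) — never exactly 0 or 1, unbiased finite-K
variance (a clamped strict-rank `r/K` convention inflates it to ≈1.024 at
K = 200), and the half-weighting of ties is what keeps the zero-truncation
atom from being pushed to the extreme bottom rank. `NPDE = Φ⁻¹(pde)`.

The four tests on an NPDE sample are: Wilcoxon signed-rank against mean 0;
a two-sided χ² variance test against 1 (the usual implementation of the
"Fisher" variance comparison, which the literature names but does not
define); Shapiro–Wilk normality; and a Miao–Gel–Gastwirth-type symmetry test — the
scaled mean–median difference referred to a sign-flip (symmetrization)
resampling distribution rather than its asymptotic normal approximation,
whose size is conservative at a few hundred observations. The exact
symmetry test used by the reference software is unspecified, so this choice
is documented rather than asserted as equivalent. No
multiple-testing correction is applied (raw p-values are reported per
model). Default K is 1000; the test suite uses K = 200 for speed, where the
suite's own calibration check (200 replicate evaluations of a 100-subject
cohort) verifies all four tests hold their nominal 5% size.

`eta_shrinkage()` reports `1 − sd(η̂)/ω` per parameter; it approaches 1 as
per-subject data vanish and 0 for rich designs, and the suite checks the
direction.

## Prediction-corrected VPC

`run_pcvpc()` bins observations by time since first dose into equal-count
quantile bins (default 8; bins with fewer than 2 observations are merged
with a neighbour and the merges logged), corrects each observation and each
simulated value by `median(PPRED in bin)/PPRED_point`, and summarises
observed 10th/50th/90th percentiles per bin against the 2.5–97.5%
envelope of the same percentiles across simulated replicate datasets
(default 1000). Time since first dose is the axis because the data are
dominated by troughs — time since last dose would collapse all points. The
binning, percentiles and envelope level are configurable; the sources do
not state theirs, so none of these defaults is asserted against published
figures. `vpc_coverage_miss()` summarises the fraction of (bin, percentile)
cells outside the envelope; stripping covariates from a covariate-driven
cohort increases it, which the suite checks directionally.

## Problem sizes and numerical defaults

Reported-scale defaults are K = 1000 NPDE replicates and 1000 VPC
replicates. The test suite scales down by design: K = 200 with 100-subject
cohorts for the calibration study, 150-subject cohorts for misspecification
detection (sized so each replicate has >99% power for the observed NPDE
shift of ≈ +0.4), and 50–150 subjects elsewhere. Convergence tolerance for
MAP is 1e-8 on the objective; ODE cross-checks run at 1e-11 tolerances;
registry serialisation writes doubles at 17 significant digits so the YAML
round-trip is bit-exact.

## Known limitations

* The synthetic cohort reproduces marginal summaries only; conclusions
  about any real population require real data.
* NPDE normality is asymptotic in K and exact only for models that are
  multivariate normal after decorrelation; with strongly log-normal IIV the
  residual non-normality is visible at very large sample sizes.
* BLQ observations are excluded, not likelihood-censored; models whose
  subpopulation has substantial BLQ mass are evaluated on the observable
  range only.
* Nonlinear (target-mediated) elimination, absorption models and
  dose-adaptation logic are out of scope.
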