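---
title: "Scoring and prognostic validation of diabetic foot ulcer classification systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and prognostic validation of diabetic foot ulcer classification systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfuscore)
```

## The problem

Diabetic foot ulcers are a leading cause of non-traumatic lower-limb
amputation. Several bedside classification systems grade ulcer severity
from clinical findings, and a recurring clinical question is how well
each system *prognosticates*: given a wound assessment at the index
encounter, how well does the score separate patients who will undergo a
major amputation (above the ankle) within six months from those who will
not? `dfuscore` implements four widely used systems and the complete
statistical toolkit of such an external validation, so the analysis can
be run end-to-end on any cohort that provides the required wound fields
and a binary six-month outcome — or on synthetic cohorts with known,
tunable structure.

Minor (toe or transmetatarsal) amputations are deliberately counted in
the "no major amputation" group throughout: the outcome partition is
{major} / {minor, no major} / {none}, and no patient is ever counted in
two groups.

## The four systems and their exact point mappings

All four classifiers are deterministic, total functions of a single
per-patient `WoundRecord` row (see `?dfu_cohort` for the column
dictionary). Where a published system leaves a detail open, the choice
made here is stated explicitly.

**Meggitt–Wagner (MW, grades 0–5).** A most-severe-wins ladder:
extensive gangrene → 5, localized gangrene → 4, osteomyelitis or deep
abscess → 3, depth to tendon/capsule or bone → 2, superficial ulcer → 1,
intact skin → 0. The ladder order follows the scale's definition as an
ordered severity hierarchy: a superficial ulcer with extensive gangrene
is grade 5, not 1.

**University of Texas (UT, 4 × 4 grid).** Depth grade 0–3 (intact,
superficial, tendon/capsule, bone/joint) crossed with stage A–D (A
neither, B infection, C ischemia, D both). Infection is any IDSA grade
above none; ischemia is any Doppler-waveform grade above none. The
discrimination analysis never treats the grid as a single 16-level
ordinal: following standard practice it analyses the depth grade as an
ordinal score, infection and ischemia as binary scores, and the "grade 3
stage D versus everything else" indicator as a binary score.

**SINBAD (0–6).** One point per adverse item: site beyond the forefoot,
ischemia, neuropathy, bacterial infection, area ≥ 1 cm² (closed lower
bound, so exactly 1 cm² scores the point), and depth beyond superficial.

**Saint Elian (6–30).** Ten items in three domains. Anatomical
(location, topography, number of zones) and contributing items (depth,
area, healing phase) score 1/2/3 in their listed order; aggravating
items (ischemia, infection, edema, neuropathy) score 0–3. The published
severity bands pin the scale's top at 30 and its bottom at 6, which
fixes this per-item scheme. Two boundary decisions are ours:

* a total of exactly 10 is graded **mild** (the published bands "mild
  < 10, moderate 11–20" leave 10 unassigned; ≤ 10 keeps the bands
  contiguous);
* the middle area band is the closed interval **[10, 40] cm²** (the
  system's definition states 10–40 cm²; an alternative source table
  prints 10–39.9, which for areas recorded to 0.1 cm² is the same set
  minus the single value 40.0).

Band collapses for the incidence/relative-risk analysis merge
sparse-event categories with their neighbours: MW {1–3, 4–5}, UT
{other, 3D}, SINBAD {1–4, 5, 6}, Saint Elian {<16, 16–20, >20}, always
with the lowest theoretical-risk band as reference.

## The validation statistics

`dfu_validation()` is the single entry point; it returns a classed
object with `print`, `summary`, `plot` and `predict` methods, and every
number in the printed tables has an unrounded twin in
`as_report_json()` — formatting is the only lossy step.

**Relative risks.** For a band $b$ against reference $r$ the estimator
is the closed-form incidence ratio $RR = (e_b/n_b)/(e_r/n_r)$ with
robust (sandwich) standard error of $\log RR$ equal to
$\sqrt{1/e_b - 1/n_b + 1/e_r - 1/n_r}$. For a saturated Poisson model
on a categorical exposure this *is* the robust-variance Poisson
regression estimator (the test suite verifies equality against
`glm` + `sandwich::vcovHC(type = "HC0")`), so no iterative fit is run.
A band with zero events on either side is flagged `calculable = FALSE`
("NC"), never an error. CIs use $z = 1.959964$; p-values below 0.001
print as "<0.001".

**ROC and AUROC.** The AUC is the tie-corrected pair statistic
$[\#(x_{pos} > x_{neg}) + \tfrac12\#(x_{pos} = x_{neg})]/(n_{pos}n_{neg})$,
computed via mid-ranks and identical to the trapezoidal area under the
empirical ROC. Variance comes from the DeLong placement values
($s_{10}/n_{pos} + s_{01}/n_{neg}$), the CI is the normal interval
truncated to [0, 1], and the paired test uses the full placement-value
covariance with a two-sided normal reference; identical curves return
p = 1 by convention. Qualitative labels follow prespecified bands
(0.70–0.79 moderate, 0.80–0.89 good, ≥ 0.90 excellent, with 0.50 chance
and below-chance flagged).

**Operating characteristics.** Sensitivity, specificity, PPV and NPV
carry exact Clopper–Pearson intervals from Beta quantiles; likelihood
ratios use the log method. Zero PPV/NPV denominators are reported as
undefined-with-flag. `threshold_sweep()` evaluates the rule
score ≥ t at every distinct observed score, and `youden_best()`
maximizes $J = se + sp - 1$, breaking ties toward the lowest threshold
(maximizing sensitivity among the maximizers). Report rounding is half
away from zero at the printed precision.

**Stratification and degeneracy.** Care-setting strata (or any
partition) are analysed independently; a stratum with zero events or
zero non-events yields an explicit incalculable marker rather than a
number. A cohort whose outcome vector is entirely one-sided produces a
degenerate report (warning plus markers), not a crash.

**Power.** `power_paired_auc()` estimates the power of the paired
DeLong test by Monte Carlo under an equal-variance binormal model: the
event-group mean for target AUC $\theta$ is $\sqrt2\,\Phi^{-1}(\theta)$
and the two scores share a within-patient correlation. This is a
simulation stand-in for an a-priori power computation whose exact
method is rarely reported; it is deterministic under a fixed seed and
its null rejection rate is checked to sit near $\alpha$.

**No multiplicity adjustment** is applied across the 21 pairwise
comparisons, matching how such validations are conventionally reported;
calibration statistics and time-to-event modelling are out of scope
(discrimination only, binary six-month outcome).

## The synthetic cohort generator

Real wound-level data are rarely redistributable, so the package ships
a generator whose *structure* mirrors what the analysis assumes. One
standard-normal latent severity $L$ per patient drives everything:

* the outcome through a logistic link $p = \mathrm{logit}^{-1}(a + bL)$,
  with the intercept $a$ root-found so the expected incidence matches
  the target (default 11.4%) and slope $b = 3$ fixing the
  discrimination ceiling;
* every wound item through an ordered-threshold model on
  $L + \sigma_i\varepsilon$, with cutpoints placed at the normal
  quantiles of the item's target marginal frequencies — so noise moves
  an item's correlation with severity without disturbing its marginal;
  area uses a Gaussian copula into a log-normal (≈45% under 10 cm²,
  ≈26% over 40 cm²);
* a minor amputation among the non-major patients (same latent, own
  intercept, default 25%);
* care setting: with `events_inpatient_only` (the default) every event
  patient plus the most severe non-event patients fill the inpatient
  quota (default 31.9%), reproducing both an event-free outpatient
  stratum and, by restriction of the severity range, spectrum bias —
  every score discriminates strictly worse among inpatients than
  overall.

The default marginals emulate a referral-hospital cohort with advanced
disease (about 46% bone-deep wounds, 60% ischemia, 43% gangrene of any
extent). A shared latent plus independent item noise induces the
positive inter-score correlation that makes paired DeLong tests
meaningful, which is exactly the regime the validation operates in.

**Calibration.** Five noise knobs are tuned by bisection against a
large fixed-seed pilot, in an order chosen so each knob only depends on
items already fixed: ischemia (targets the binary ischemia score's
AUROC, default 0.65), infection (0.65), the depth/osteomyelitis/gangrene
group (Meggitt–Wagner, 0.81), the site/neuropathy/area group (SINBAD,
0.75), and the Saint Elian-specific items (0.90). The shipped defaults
(`dfu_default_noise()`) are the output of
`calibrate_sim_noise(dfu_sim_config(seed = 1), n_pilot = 20000)`;
regenerating at n = 5000 recovers each configured AUC within ±0.02. The
infection knob calibrates to zero noise: a binary item at ~73%
prevalence has an AUROC ceiling of about 0.651 under these conditions,
which happens to sit on its target. Targets outside a knob's attainable
range raise an error rather than silently clamping.

**What the generator does not emulate.** The real joint distribution of
the ten Saint Elian items is unpublished; a single-factor latent model
cannot reproduce an arbitrary covariance structure, multi-ulcer
patients, laboratory covariates, recurrence, or time-to-event dynamics.
Passing parameter-recovery tests therefore demonstrates that the
*statistical machinery* is correct under a plausible data-generating
process, not that any particular real cohort looks like this model.

## Numerical choices and test scale

* All CIs default to 95%; the AUROC interval is the DeLong normal
  interval. Its known small-sample behaviour is worth stating: at
  n = 342 with ~39 events, 500-replicate simulations in the test suite
  put per-score coverage between 91% and 95% — slight undercoverage
  concentrated in the high-AUC (≈0.90) score, a documented property of
  the normal-scale interval near the boundary; pooled across the four
  calibrated scores coverage is ≈92.6%.
* Bisection tolerance for calibration is ±0.005 on the pilot AUC;
  pilot sizes of 8000–20000 keep pilot noise well under that.
* The test suite's simulation sizes (pilots up to 20000, one
  400000-patient cohort to fix "true" AUCs, 500 replicates at the study
  scale of n = 342) were chosen to keep Monte-Carlo error a fraction of
  each tolerance while the full suite runs in well under a minute.
* Ties in `youden_best()` go to the lowest threshold; `roc_auc()`
  thresholds are the observed score values for the rule score ≥ t.
* Enum vocabularies are closed: unknown CSV tokens are hard errors
  naming row and field; a complete-case filter at read time drops and
  logs incomplete rows (mirroring a complete-case analysis), and
  cohorts round-trip through CSV exactly.

## A worked example

The 12-patient `example_cohort()` spans every MW grade, all four UT
stages, every SINBAD total and all three Saint Elian bands, with three
major amputations (all inpatients) and an event-free outpatient
stratum:

```{r example}
coh <- example_cohort()
cbind(id = coh$patient_id, dfu_scores(coh))
fit <- dfu_validation(coh)
fit
```

The event-free outpatient stratum is marked, never imputed:

```{r strata}
fit$stratified$saint_elian
```

A calibrated synthetic run at the study's scale:

```{r synthetic}
sim <- simulate_cohort(dfu_sim_config(seed = 11))
sfit <- dfu_validation(sim)
sfit$roc$saint_elian
sfit$stratified$saint_elian
```

## Known limitations

* Printed summary tables of a published validation do not identify
  patient-level score–outcome pairings, so patient-level AUROCs of a
  real study cannot be reconstructed from its tables; only statistics
  that are functions of printed counts are exactly reproducible, and
  the discrimination machinery is instead validated against brute-force
  oracles and calibrated synthetic cohorts.
* The robust-variance closed form assumes the saturated categorical
  exposure model; it is not a general GLM replacement.
* One wound record per patient (the index ulcer, one index limb);
  contralateral events and bilateral ulcers are out of scope.
* WIfI and PEDIS-as-a-score are not implemented (the former requires
  pressure measurements outside the data model).
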