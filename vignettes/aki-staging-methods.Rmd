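---
title: "Staging acute kidney injury from laboratory creatinine: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging acute kidney injury from laboratory creatinine: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akiaudit)
```

## The problem

Acute kidney injury (AKI) is an abrupt decline in renal function, detected
in routine hospital data as a rise in serum creatinine, a fall in estimated
glomerular filtration rate (eGFR), or failing urine output. `akiaudit`
implements a complete audit pipeline for hospital admission cohorts: it
grades every admission under three criterion sets in contemporaneous use —
RIFLE (Risk/Injury/Failure), AKIN (stages 1–3) and AKIB (stages 1–3,
absolute creatinine rises only, no urine-output rule) — and aggregates the
verdicts into incidence, risk-factor and outcome analyses.

The methodological difficulty is not the thresholds themselves but their
application to *irregularly sampled* laboratory series with *incomplete
baseline information*. This vignette records how the package resolves each
of those points, what the synthetic-cohort generator does and does not
emulate, and the numerical conventions used throughout.

## Reference renal function

Every relative criterion ("> 1.5× baseline") needs a reference. The
package's baseline rules, in order:

1. **Measured prior.** The lowest creatinine in the 183 days (six calendar
   months) before admission, inclusive. `determine_baseline()` records the
   value, its time, and `source = "measured-prior"`.
2. **Better on admission.** If the admission sample is lower than every
   prior value, the admission value becomes the reference
   (`source = "admission"`): an acutely unwell patient's best observed
   function is the closest available estimate of their true baseline.
3. **Assumed normal.** With no history and no documented renal impairment,
   the baseline is eGFR 75 mL/min/1.73 m² with creatinine 60 µmol/L
   (female) or 80 µmol/L (male) — the midpoint of a typical laboratory
   normal range. These are point values; treating a normal-range *bound*
   as the baseline would bias every ratio upward.
4. **Impaired, no history.** With documented chronic kidney disease but no
   prior result, the admission value is the reference: an assumed-normal
   baseline would misgrade stable CKD as severe AKI.

When creatinine and eGFR nominate different baselines, the lower
creatinine wins and eGFR is recomputed from it, keeping the two references
consistent; the two scales are monotonically linked, so a genuine conflict
can only arise from demographic adjustment, and the creatinine scale is
the primary measurement.

eGFR uses the four-variable IDMS-traceable MDRD equation (coefficient
175), with the 0.742 female and 1.212 Black-ethnicity factors, creatinine
converted from µmol/L by division by 88.4. The 175 coefficient matches UK
laboratory reporting practice of the audit era; the older 186 coefficient
is deliberately not offered, since mixing the two silently shifts every
eGFR-based stage boundary.

## Windows on irregular series: the rolling nadir

Criteria phrased "over 48 hours" or "over 7 days" are operationalised as a
half-open look-back: for a measurement at time $t$ with window $w$, the
reference is the minimum eligible value in $(t - w,\, t]$. Eligible values
are earlier in-window measurements, plus the baseline when

* its reference time falls inside the window,
* its time is unknown (assumed-normal baselines), or
* the measurement is the admission sample (the *pre-admission
  assumption*: an unexplained elevation already present on admission is
  taken to have developed within the criterion's window — 7 days for
  RIFLE, 48 h for AKIN).

This rolling-nadir convention is the standard operationalisation used by
electronic AKI alerting systems. It is also the package's main behavioural
assumption: an audit that compared in-hospital values only to the fixed
admission baseline would grade slow in-hospital deteriorations
differently. The brute-force oracle used in the tests evaluates *all
ordered in-window pairs* instead, which is mathematically equivalent
(maximising a rise over pairs selects the in-window minimum as reference)
but independently coded.

Two consequences worth noting:

* A measured baseline from months ago is *not* an eligible 48-hour AKIN
  reference for a value recorded on day 5; only in-hospital dynamics can
  stage such an admission post-admission under AKIN.
* AKIB carries no baseline assumption at all — a baseline participates
  only as an ordinary measurement when its collection time is known. An
  elevation present on admission with an old or unknown baseline is
  therefore invisible to AKIB, which is why AKIB systematically reports
  the lowest incidence of the three systems.

All inequalities are strict, exactly as the criteria are written: a ratio
of exactly 1.5 or a rise of exactly 26 µmol/L does not trigger. Units are
µmol/L throughout (the 26/44/88/132 increments are the standard AKIN/AKIB
steps on that scale).

Within RIFLE, the creatinine-ratio and eGFR-decline columns are evaluated
independently and the *maximum* stage wins. Because eGFR scales as
creatinine$^{-1.154}$, a 25 % eGFR fall corresponds to a ratio of about
1.28 — the eGFR rule is the more sensitive of the two whenever baseline
eGFR is consistent with baseline creatinine, and dominates Risk-level
detection. RRT maps to AKIN stage 3 only (RIFLE's Failure column has no
RRT rule; its Loss/ESRD categories are out of scope). Recorded anuria
longer than 12 h is Failure/stage 3 under RIFLE and AKIN; oliguria
(< 400 mL/day) is recorded but grades nothing in any system, and
volumetric urine-output rates (mL/kg/h) are not modelled.

## Timing

Each admission receives exactly one episode per system — the most severe
stage at any time during the admission — labelled `pre-admission` when the
criterion is already met by the admission sample against the baseline, and
`post-admission` when first met later. Stage 0 has timing `none`.

## Cohort statistics

* **Exclusions:** maternity admissions, stays under 24 h, and
  maintenance-dialysis patients (no native renal function to injure).
  Non-dialysis CKD stage 4/5 patients remain in the cohort.
* **Sepsis** is the audit's pragmatic two-of-three flag: WCC < 4 or
  > 12 × 10⁹/L, CRP > 50 mg/L, temperature > 38.0 °C; a missing component
  counts as not met.
* **Stage tables** report counts, percentages (rounded half-up to one
  decimal) and exact Clopper–Pearson binomial intervals — stage-3 cells
  are small, so asymptotic intervals would be misleading.
* **Odds ratios** are cross-product estimates with Woolf (log) confidence
  intervals and two-sided mid-p exact tests from the hypergeometric
  distribution. No continuity correction is applied to zero cells; the OR
  is reported as undefined instead.
* **Risk factors:** univariate and full multivariate maximum-likelihood
  logistic models plus backward elimination (AIC by default, BIC
  selectable). "Stepwise" is underdetermined as a description, so the
  direction and criterion are explicit, configurable arguments. Predictors
  with runaway standard errors (> 10 on the logit scale, the glm signature
  of separation) are flagged non-estimable rather than reported.
* **Length of stay** is whole days by floor; comparisons use Mann–Whitney
  tests, the stage trend uses Kruskal–Wallis and Spearman correlation.
* **Repeat testing:** an admission eGFR < 60 mL/min with only a single
  creatinine flags a missed repeat test, unless a documented six-month
  baseline shows no change (within 10 % by default — "no change" needs a
  tolerance to be computable).

## The synthetic cohort generator

No patient-level data ship with the package; `generate_cohort()` exists so
that every stage of the pipeline is exercisable and *checkable*. Its
defaults (`reference_config()`) encode the study conditions of an
unselected emergency-admission cohort:

| quantity | default | units |
|---|---|---|
| any-criterion AKI incidence | 25.4 | % of analysed admissions |
| stage mix given AKI | 68 / 20 / 12 | % stages 1/2/3 |
| known prior baseline | 45.7 | % of admissions |
| AKI odds ratios: CKD, sepsis, diuretic, age | 4.02, 7.24, 1.87, 1.02/yr | — |
| median LOS none / stages 1–3 | 4 / 8 / 12 / 16 | days (log-normal, σ = 0.6) |
| mortality none / stages 1–3 | 3.3 / 10.3 / 14.7 / 15 | % |
| critical care none / stages 1–3 | 1.7 / 4.3 / 11.8 / 23.8 | % |
| acute RRT given stage 3 | 33 | % |
| maternity / short-stay / dialysis | 1.2 / 0.8 / 2.3 | % of raw admissions |
| sampling rate; noise | 1/day; σ = 0.04 | log-scale multiplicative |

The logistic intercept is solved numerically so the mean risk over the
analysed admissions equals the target incidence; the realised incidence is
then binomial around it. Each AKI admission is assigned a stage, a target
criterion set, and a timing; `generate_trajectory()` back-solves a
piecewise-linear rise–peak–recovery curve whose peak lands strictly inside
the assigned stage band. For RIFLE the band accounts for the
patient-specific eGFR thresholds (assumed-normal baselines make the eGFR
and creatinine scales inconsistent, so the band is computed per patient
rather than from fixed ratios). Every candidate series is replayed through
`classify_admission()` — with the baseline re-derived from the emitted
prior measurements exactly as the audit will derive it — and regenerated
with shrinking noise on mismatch; the final fallback is noiseless, for
which the band construction guarantees the verdict. This makes the
round-trip property (assigned stage ≡ engine verdict) exact by
construction, which is what the generator is for: it validates the
*plumbing*, not the biology.

Patients with a measured prior baseline start their in-hospital series at
1.05× that baseline — acutely admitted patients typically run slightly
above their healthy nadir, and a symmetric start would reclassify half of
them as `admission`-source baselines.

What the generator does **not** emulate: creatinine pharmacokinetics
(rise and recovery are piecewise-linear with log-normal noise);
multi-admission patient histories; correlated comorbidities; seasonal or
weekday structure (the `week` covariate is included with a true
coefficient of zero precisely so the analysis can demonstrate its
unimportance); and AKIB's full real-world overlap with the other systems —
pre-admission episodes with unknown baseline times cannot trigger AKIB, so
synthetic AKIB incidence sits below an audited cohort's unless AKIB-
targeted episodes are oversampled. Passing tests therefore demonstrate
correctness of the staging and analysis machinery under known conditions,
not fidelity of any particular clinical trajectory.

## Numerical conventions and problem sizes

* Percentages are rounded half away from zero to one decimal at table
  emission only; all internal arithmetic is unrounded.
* Dates are parsed strictly as ISO-8601 and handled as UTC `POSIXct`.
* Window membership is $(t-w, t]$: a pair exactly $w$ apart is outside.
* The RNG is R's default Mersenne–Twister, seeded once per cohort from the
  config; no global state survives a call.
* Test problem sizes were chosen to bound each property's Monte-Carlo
  error well below its assertion margin: 10,000 random ≤ 8-point series
  for engine/oracle equivalence, 1,000 admissions for the generator
  round trip, 5,000 for coefficient recovery (±2 SE), 10,000 for marginal
  calibration (±3 binomial SE).

## Known limitations

* The rolling-nadir reference is an operationalisation choice; audits
  using a fixed admission baseline will grade slow in-hospital
  deteriorations differently.
* Stage monotonicity in the input holds at the series peak but not
  pointwise: raising an interior nadir can lower a rolling-nadir stage.
  This is a property of the convention, not a bug.
* The mid-p exact test uses the doubled smaller tail; other mid-p
  variants differ in the third decimal for small tables.
* `mdrd_egfr()` is undefined below age 18 and increasingly biased near
  normal renal function; the package refuses paediatric input rather than
  extrapolating.
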