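---
title: "Methods: EDI screening accuracy and calibrated simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EDI screening accuracy and calibrated simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ediscreen)
```

This vignette is the package's own account of its statistical methods:
the screening statistic, the diagnostic-accuracy machinery, the synthetic
data generator and the design choices behind each, including the
numerical corner cases and the limits of what the synthetic evaluation
can show.

## The screening statistic

The Expiratory Disproportion Index is

$$\mathrm{EDI} = 100 \times \frac{\mathrm{FEV}_1\ [\mathrm{L}]}{\mathrm{PEFR}\ [\mathrm{L/s}]}.$$

Its discriminating power rests on an asymmetry between two kinds of
airflow obstruction. A *fixed upper-airway* obstruction (e.g. benign
subglottic stenosis) acts as an orifice: it caps the instantaneous flow
achievable at any lung volume. The flow-volume curve is truncated to a
plateau, the peak flow collapses to the cap, but the volume expired over
the whole first second — which integrates flow over a wide range of lung
volumes — falls much less. FEV1/PEFR therefore rises. *Diffuse
lower-airway* obstruction (asthma) scales flows down across the maneuver
roughly proportionally; a common positive factor cancels in the ratio and
the EDI is unchanged. `edi_value()` implements the ratio with no internal
rounding: values are carried at full floating precision into
classification and rounded (2 decimals) only for display, because the
order of rounding versus thresholding changes boundary cases and the
published analysis does not specify it.

Classification against the referral cutoff (48 EDI units by default) uses
a **strict** inequality: an EDI exactly equal to the cutoff is
screen-negative, matching the published "EDI > 48 means referral"
phrasing. Because the complementary "< 48" phrasing leaves equality
formally unassigned, the rule is exposed as the `strict` flag on
`screen_positive()`, `classify_edi()` and everything downstream.

## Index extraction from sampled curves

`extract_indices()` reconstructs the three indices from a sampled
maneuver (`time`, cumulative expired `volume`, instantaneous `flow`):

* **FEV1**: expired volume at t = 1 s by *linear interpolation* of the
  volume samples. Linear interpolation is the standard reconstruction and
  is exact whenever volume is piecewise linear between samples; for
  smooth curves its error is bounded by the usual
  $h^2 \max|\dot{Q}|/8$ single-interval quadrature bound, which the test
  suite asserts under grid refinement.
* **PEFR**: the maximum of the flow samples.
* **FVC**: the final volume sample.

Curves are validated before extraction: strictly increasing time from 0,
non-decreasing volume from 0, non-negative flow, at least 3 samples, at
least 1 s of maneuver for FEV1. The flow channel must also agree with the
numerical derivative of volume: on every sampling interval the secant
slope of volume is compared with the trapezoidal mean of the two flow
endpoints, and the largest deviation must stay within a tolerance
(default 5% of peak flow, configurable). The interval form was chosen
over a central-difference form because it is exact for piecewise
quadratic volume — which includes every curve the package's own simulator
produces and the constant/linear-flow textbook cases — whereas central
differences on a non-uniform grid are biased near the sharp rise to peak
flow and would reject correct curves.

No back-extrapolated time-zero correction (the ATS/ERS start-of-test
procedure) is applied: t = 0 is taken as given. Vendor software applies
that correction before exporting indices, and simulated curves start
cleanly at zero; implementing it would add a degree of freedom the
downstream analysis never exercises. Likewise, repeated-test selection
("the first sufficiently interpretable maneuver") is deliberately left to
the caller: the cohort schema requires one row per patient and the
package does not guess at an interpretability criterion that is nowhere
operationalized.

## Diagnostic accuracy

With SGS as the diseased class and screen-positivity as above,
`build_contingency()` produces the 2x2 table (tp, fn, fp, tn) and
`sensitivity_specificity()` the plain ratios tp/(tp+fn) and tn/(fp+tn).

**Binomial intervals.** Two methods are implemented and always labeled in
the output: Clopper–Pearson (default) — the exact central interval from
beta quantiles, lower bound 0 at 0 successes and upper bound 1 at n
successes, with actual coverage at or above the nominal level — and the
Wilson score interval. The source study's software (SPSS) does not report
its interval method, and neither textbook method reproduces its printed
CI bounds exactly; the package therefore documents its own methods rather
than reverse-engineering unprinted procedures, and no test asserts the
published CI digits.

**ROC and AUC.** `roc_points()` places one candidate threshold at every
distinct observed value (positivity strictly greater), plus a −∞
threshold, so both degenerate endpoints — (sensitivity 1, specificity 0)
and (0, 1) — are always present and the curve is monotone by
construction. `edi_auc()` computes the area two ways: trapezoidal
integration of the ROC polygon, and the Mann–Whitney form (the fraction
of SGS–asthma pairs ordered correctly, ties credited 1/2, computed from
midranks in O(n log n)). The two are algebraically identical; the package
treats agreement within 1e-12 as an internal correctness guard and aborts
if it fails. Ties therefore get the standard half-credit treatment, and
the AUC is invariant under any strictly increasing transformation of the
EDI scale.

**AUC intervals.** Hanley–McNeil's closed-form standard error with a
normal interval (clamped to [0, 1]; the interval collapses to [1, 1]
under perfect separation) is the default, approximating the normal-theory
interval the source analysis most likely used. A stratified percentile
bootstrap (resampling within each condition group, deterministic given a
seed) is the alternative; stratification keeps both groups present in
every resample. If a group carries a single distinct value the bootstrap
warns and proceeds — the resampled AUCs are then degenerate and the
interval is not informative.

**Cutoff selection.** `best_cutoff()` maximizes Youden's
J = sensitivity + specificity − 1. Ties are broken toward the *lower*
threshold: for a screening test whose cost of a missed stenosis dominates
the cost of one unnecessary laryngoscopy, favoring sensitivity is the
clinically appropriate direction. The `integer_grid` option evaluates
only integer cutoffs (published cutoffs in this literature are integers:
48, 50); integer cutoffs are mapped onto the ROC step function, an
integer c acting like the largest observed value not exceeding c. The
published study describes its cutoff choice in two inconsistent ways
(per-cutoff sensitivity/specificity inspection in the methods, a
bootstrap analysis in the discussion); Youden over the integer grid is
this package's documented default, and bootstrap cutoff selection is out
of scope. Note also that an optimized cutoff evaluated on the data that
chose it is optimistically biased — `evaluate_accuracy()` records whether
the cutoff was fixed or optimized for exactly this reason.

**Group comparisons.** `compare_groups()` delegates to the standard
tests: two-sided Mann–Whitney (exact enumeration when the combined n ≤ 12
and there are no ties, otherwise the tie-corrected normal approximation
without continuity correction) for continuous variables, and Fisher's
exact test (two-sided by summing tables no more probable than the
observed) for binary ones. No multiplicity adjustment is applied to a
table of such comparisons, matching standard practice for cohort
characteristics tables.

## The synthetic cohort generator

The generator stands in for the study's raw data, which are not publicly
deposited. It works at two levels.

**Index level.** Published group summaries give only a median and IQR per
group. For a positive, right-skewed index the log-normal is the minimal
two-parameter family consistent with those quantiles:
`fit_lognormal_from_quantiles()` sets μ = ln(median) and
σ = ln(q3/q1) / (2 z₀.₇₅) with z₀.₇₅ = 0.6744898. This reproduces the
median and the quartile *ratio* exactly; the individual quartiles are
exact only when the printed quartiles are symmetric about the median on
the log scale. The published EDI quantiles are mildly asymmetric
(ln(67.10/54.33) = 0.211 versus ln(79.18/67.10) = 0.166 for the SGS
group), so the calibration splits that asymmetry evenly — an exact
three-quantile match is impossible for any two-parameter log-normal, and
the residual is the price of the parsimony. The calibrated defaults,
50 SGS patients from LogNormal(4.2062, 0.2792) and 32 asthma patients
from LogNormal(3.6361, 0.2372), *are* the study conditions; they imply a
closed-form AUC of Φ((μ₁−μ₀)/√(σ₁²+σ₀²)) = Φ(1.557) ≈ 0.940 (inside the
published interval 0.86–0.98), sensitivity ≈ 88.5% and specificity ≈
83.9% at cutoff 48, and ≈ 85.4% / 87.8% at cutoff 50 — all within a few
points of the published operating points, which is the package's evidence
that a log-normal calibration is jointly consistent with the published
quantiles and accuracy figures. Within-patient FEV1–PEFR correlation is
*not* modeled at this level (the published summaries cannot identify it);
the curve simulator supplies mechanistically coupled indices instead.

**Curve level.** `simulate_flow_volume_curve()` generates one maneuver
from a deliberately simple template — flow rising linearly to the peak
over `rise_time` (default 0.1 s, a realistic time-to-peak for a forced
expiration), then a triangular (linear-in-time) descending limb expiring
exactly `fvc` liters. It is not a physiological pressure-flow model; it
exists to exhibit the mechanism, and three phenotypes are derived from it
in closed form:

* *normal* — the template itself;
* *fixed_uao* — the template's flow-volume relationship clipped at
  `flow_cap`, with expiration prolonged exactly (the time coordinate is
  the closed-form integral of dV/Q along the clipped curve) so the full
  FVC is still expired. PEFR falls to the cap while FEV1 falls much less,
  so the EDI rises monotonically as the cap tightens — asserted as a
  sweep property in the tests.
* *asthma* — every flow multiplied by `global_scale` on the template's
  own time support, so the expired volume scales proportionally as well
  (total `global_scale × fvc`), and FEV1, PEFR and the EDI scale
  coherently: the EDI is exactly invariant. A design note: one could
  instead preserve FVC under the flow reduction by prolonging expiration,
  but that variant provably *raises* FEV1 relative to PEFR and therefore
  raises the EDI — a proportionally-reduced-but-FVC-preserving "asthma"
  curve would mimic stenosis and invert the very contrast the phenotype
  exists to demonstrate. Since the mechanistic point (proportional flow
  reduction leaves the EDI unchanged) is the load-bearing property, the
  package scales volume with flow and documents the deviation.
  `scoop_factor` additionally bends the descending limb into the concave
  ("scooped") shape of real obstructive curves, flow decaying as the
  1/(1−scoop) power of remaining time at fixed scaled volume; scooping
  lowers FEV1 but not PEFR, so severe diffuse obstruction pushes the EDI
  *down* — consistent with the low EDIs reported for COPD and fibrosis.

Sampling uses a uniform time grid with the template's segment boundaries
(end of rise, plateau edges) inserted as explicit samples, so every
sampling interval lies in one smooth piece: the flow/volume consistency
check is then exact for the piecewise-quadratic phenotypes at any
permitted sample count (n ≥ 50), the sampled PEFR equals the true peak
exactly, and a 200-sample curve reproduces dense-grid (20,000-sample)
indices within 0.5%. Optional multiplicative log-normal noise perturbs
the flow channel only and defaults to 0.

**The deterministic fixture.** `make_table2_fixture()` reconstructs an
82-patient cohort consistent with the published screening table: the six
screen-negative SGS patients carry exactly the six published EDI values
(realized as FEV1 = EDI/100 L against PEFR = 1 L/s, a pairing chosen
because it is exactly representable in floating point), and the remaining
44 + 5 + 27 records are drawn once, under a fixed documented construction
seed, from the calibrated group log-normals truncated to the correct side
of 48 by rejection sampling, with PEFR values drawn from log-normals
quantile-matched to the published group PEFR summaries and FEV1 back-
computed. The construction seed was chosen so the fixture also reproduces
the published cutoff analysis — its integer-grid Youden optimum is 48,
where its contingency table is exactly the published (44, 6, 5, 27) — and
so the synthetic values stay near the published observed EDI ranges. Only
the marginal counts, the six printed values, and the cutoff-48 operating
point are faithful to the source; every other value is synthetic, and the
published cutoff-50 operating point is *not* reproduced by the fixture
(it is jointly incompatible with Youden-optimality at 48) — the
large-sample tests check that operating point on the calibrated
distributions instead.

## Numerical choices and degenerate inputs

* Cutoff ties in `best_cutoff()` are resolved with a 1e-12 slack on J
  before taking the lowest threshold, so floating-point noise cannot
  flip a genuine tie.
* `proportion_ci()` pins the boundary cases exactly (lower = 0 at x = 0,
  upper = 1 at x = n) rather than relying on qbeta limits.
* σ = 0 group specs are honored exactly: every draw equals exp(μ).
* Cohort CSVs are written at shortest round-trip precision and re-parsed
  with correctly rounded conversion, so `read_cohort(write_cohort(x))` is
  bit-identical; the JSON report is written at 17 significant digits for
  the same reason.
* Single-condition inputs, empty margins, non-positive indices, unknown
  group labels and short maneuvers all fail with named validation errors
  rather than propagating NaNs.

## What the synthetic evaluation does and does not show

Passing tests on simulated cohorts demonstrate that the *pipeline* is
correct (oracle-checked statistics, exact table reconstruction, seeded
reproducibility) and that the log-normal calibration is *consistent* with
the published quantiles and operating points at large n and at the study
sizes. They do not validate the EDI on real patients: the generator draws
EDI values directly (no FEV1–PEFR correlation structure, no measurement
error model, no comorbidity structure such as the coexisting obstructive
lung disease that produced the published false negatives, no obesity
effects), the curve simulator is a geometric template rather than
respiratory mechanics, and the printed group summaries cannot identify
anything beyond the marginal EDI distributions. Conclusions about
clinical screening performance belong to studies with endoscopically
verified cohorts; this package's claim is narrower — given per-patient
indices, it computes the screening analysis correctly and reproducibly.

## Problem sizes used in the checks

The packaged checks use 200,000 draws per group for median recovery, a
million draws for calibration recovery, 20,000 per group for the
closed-form AUC comparison, 100,000 per group for large-sample operating
points, 200 replicate cohorts at the study's 50/32 for the replicate AUC,
and 500 replicates for optimal-cutoff recovery — sizes at which the
Monte-Carlo error is comfortably below each asserted tolerance.
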