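---
title: "FTV-based response modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FTV-based response modeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ftvresponse)
```

This vignette documents the models and procedures implemented in
`ftvresponse`, the assumptions behind them, the parameters that matter,
and the design choices made where the design was genuinely open.

## 1. Functional tumor volume

### Model

Each DCE-MRI exam supplies three co-registered volumes: pre-contrast
$S_0$, early post-contrast $S_1$ (~2 min 30 s after injection) and late
post-contrast $S_2$ (~7 min 30 s). Two voxelwise kinetic maps are
derived:

$$\mathrm{PE} = \frac{S_1 - S_0}{S_0} \times 100\%, \qquad
  \mathrm{SER} = \frac{S_1 - S_0}{S_2 - S_0}.$$

PE measures how strongly a voxel enhances; SER contrasts early against
late enhancement, so SER > 1 indicates washout kinetics typical of tumor
and SER near 0 persistent (often benign) enhancement. A voxel counts
toward FTV when it lies inside the patient's rectangular VOI and
strictly exceeds both thresholds (default $\mathrm{PE} > 70\%$,
$\mathrm{SER} > 0$). FTV in cc is the voxel count times the voxel volume
in mm³ divided by 1000 — exactly, with no partial-volume weighting.

### Numerical choices and degenerate inputs

- **Strict inequalities.** "Above 70%" and "above 0" are taken
  literally: a voxel exactly at a threshold is excluded. This only
  matters for synthetic data, where exact threshold values can occur.
- **Invalid voxels.** $S_0 \le 0$ makes PE undefined; $S_2 = S_0$ makes
  SER undefined. Both are excluded from segmentation rather than
  clamped, because any numeric substitute would silently invent
  kinetics. A voxel with $S_2 < S_0 < S_1$ gets a negative SER and
  legitimately fails SER > 0 (washout below baseline).
- **VOI convention.** Boxes are 0-based, half-open `[lo, hi)`, axis
  order (x, y, z) matching the voxel-size triple. The VOI and the
  thresholds are fixed at baseline and keyed to the patient, never
  re-optimized at later timepoints — re-segmenting at T1/T2 with
  different settings would confound measured change with analyst drift.
- **Percent change.** $\Delta\mathrm{FTV} = (\mathrm{FTV}_t -
  \mathrm{FTV}_{ref})/\mathrm{FTV}_{ref} \times 100$. A zero baseline
  FTV makes the change undefined; the function returns `NA` (never a
  silent 0) and such records are dropped before modeling, mirroring the
  exclusion of patients with incomplete FTV measurements.

## 2. Synthetic data

### Phantoms

`generate_phantom()` places an ellipsoidal lesion (PE and SER above the
default thresholds) on a non-enhancing background (PE below threshold)
over a constant pre-contrast baseline, with optional i.i.d. Gaussian
noise per volume. Before noise, the set of enhancing voxels is exactly
the lattice points of the ellipsoid, so the segmentation chain can be
validated against a known count. The constructor enforces the level
separation (lesion PE > 70 > background PE, lesion SER > 0) so the
ground-truth mask and the default thresholds cannot drift apart.

### Cohorts

`generate_cohort()` draws, per patient: subtype from the four-class
HR/HER2 mix (default 40/16/9/35% — the composition of a large
neoadjuvant analysis cohort); pCR from the subtype's prevalence (default
20/39/66/45%; the two HER2+ class values are back-computed from the
minimum attainable PPV of published threshold curves, since PPV at the
all-positive threshold equals prevalence, and are approximations);
baseline FTV log-normally (meanlog $\log 20$, sdlog 0.8 — right-skewed
volumes spanning roughly 5–100 cc, typical of trial-eligible tumors of
at least 2 cm); and percent FTV changes at T1 and T2 from group-specific
Gaussians truncated at −100% (FTV cannot shrink by more than all of
itself). Truncation is by resampling, so the distribution keeps its
shape on the support.

### The effect-size default

The late-timepoint change defaults are **pCR ~ N(−78, 6²)** and
**non-pCR ~ N(−50, 35²)** (T1: N(−53, 16²) vs N(−30, 35²)), i.e.
responders shrink deeply and consistently while non-responders are
heterogeneous. This choice is deliberate and worth explaining, because
it controls which clinical phenomena the synthetic cohort can
reproduce:

- The tight responder distribution and diffuse non-responder
  distribution mean the *most extreme* shrinkage values are usually
  non-pCR patients. Consequently the positive predictive value
  attainable by any probability threshold in a low-prevalence stratum
  (pCR rate 20%) is structurally capped near 60%, and PPV levels of 70%
  and 90% are unattainable — exactly the `+Inf` behavior that published
  threshold tables show for HR+/HER2− cohorts. A design grid over 25
  seeds confirmed this pattern holds with frequency 1.0, while the
  high-prevalence stratum (66%) always meets the 50% level at
  threshold 0.
- The price is discrimination: the resulting cross-validated AUC on
  synthetic cohorts is ≈0.89, higher than the 0.68–0.74 reported for
  real subtype cohorts. Within a two-Gaussian family truncated at
  −100%, a ~0.7 AUC and a structurally bounded maximum PPV are mutually
  exclusive: lowering AUC requires group overlap that places responder
  mass at the −100% boundary, which makes the single top-scored patient
  a true pCR with high probability and hands every PPV level a finite
  (if useless) threshold. We prioritized the threshold-tradeoff
  pattern, which is the behavior the decision rule depends on; the AUC
  discrepancy is a known, documented gap.
- Both means and sds are configuration, not hard-coded truth
  (`cohort_spec()`), so studies of other effect sizes are one argument
  away.

What the synthetic cohort does **not** emulate: registration error
between serial exams, acquisition artifacts and fat-suppression
failures, non-Gaussian response kinetics, correlation between baseline
FTV and response, lymph-node status, and treatment-arm effects. Passing
tests on synthetic data therefore establish the *software* implements
the stated procedures exactly, and that the procedures behave as
designed under known conditions — not that the fitted coefficients or
thresholds transfer to any real cohort.

## 3. Logistic models and predictor selection

Candidate predictors are baseline FTV (cc) and the percent changes at
T1 and T2 (percent units), entered untransformed so that predicted
probabilities — and hence the selected thresholds — live on the same
scale a clinic would use. All 7 non-empty subsets are candidates.

Selection maximizes mean held-out AUC over **5 stratified folds**
(positives and negatives split separately, so each training fold keeps
both classes; a fold that still degenerates triggers a bounded number of
reseeded refolds). Cross-validation is the default because in-sample AUC
always favors the largest predictor set; `k = 5` balances fold-size
stability against small strata. The AUC itself is the Mann–Whitney rank
statistic (ties counted half), exact for any score vector.

**Near-tie parsimony.** Candidates within `tie_tol = 0.01` of the best
mean AUC count as tied, and ties resolve toward fewer predictors, then
lexicographic order. An exact-equality tie rule would let a pure-noise
predictor win roughly half of near-ties on sampling error, producing
unstable, over-large models; 0.01 is roughly the fold-to-fold noise of
AUC at the stratum sizes used here and keeps selection reproducible
under record permutation. The winner is refit on all records.

**Separation.** `glm` can converge on completely separated data without
any warning, so `fit_logistic()` additionally flags fits whose fitted
scores split the classes perfectly; the coefficients are reported with a
warning and probabilities remain defined, letting small strata degrade
visibly instead of invisibly. The full-cohort model uses FTV variables
only (no subtype indicators): the subtype-specific models are the
decision-relevant ones, and the full model serves as a pooled baseline.

## 4. Threshold selection and the decision rule

For scores $p_i$ and the rule "predicted pCR iff $p_i \ge t$",
`ppv_sensitivity_curve()` evaluates every distinct predicted probability
plus $t = 0$. At $t = 0$ all patients are predicted positive, forcing
sensitivity 100% and PPV equal to prevalence — the anchor that makes a
high-prevalence stratum meet a 50% PPV level at threshold 0.

`select_threshold()` returns the *smallest* candidate $t$ with
$\mathrm{PPV}(t) \ge$ the level. Because sensitivity is non-increasing
in $t$, this maximizes sensitivity subject to the constraint. PPV is not
monotone in $t$, so the rule is defined as "smallest qualifying
threshold", not "all larger thresholds also qualify". If no candidate
qualifies, the selection is the `+Inf` sentinel (sensitivity 0, no
patient predicted pCR) — serialized as the literal string `"+Inf"` in
reports. The `≥` classification rule (rather than `>`) guarantees the
threshold-0 row behaves as documented regardless of score values.

Sensitivity confidence intervals are Wald, $\hat p \pm 1.96\sqrt{\hat
p(1-\hat p)/n}$, clipped to [0, 100] — degenerate (zero-width) at the
boundaries, which is acceptable here because the reported operating
points are descriptive, not inferential. The denominator is the true pCR
count of the evaluated stratum.

`recommend()` encodes the clinical rule: below the subtype threshold (or
any probability against `+Inf`) → continue NAC; at or above →
early-surgery *candidate*, upgraded to *recommended* only when core
biopsy confirms no invasive disease. The biopsy enters as a boolean
confirmation flag only; its acquisition and histopathology are out of
scope.

## 5. Cohort statistics

Fisher's exact tests (2×2 and r×c, exact or Monte Carlo under fixed
margins) use the probability-mass two-sided rule — the sum of all
outcomes no more probable than the observed table — which is the
convention of standard exact-test implementations and reproduces the
published comparison p-values (0.17, 0.26) from their printed counts.
The age comparison is a Welch t-test computed from summary statistics
(means, sds, ns), since raw ages are not part of the printed record. The
exclusion audit applies filters in a fixed order — missing
outcome/receptor first, then missing FTV at any timepoint — so its
per-reason counts reconcile exactly with enrollment flowcharts
(990 − 99 − 77 = 814).

## 6. Problem sizes and determinism

The default synthetic cohort is 5000 patients, large enough that every
subtype stratum supports stratified 5-fold selection and the
threshold-pattern behavior is stable across seeds, while the full
pipeline completes in seconds. Test-suite simulations use 100 random
phantoms for the segmentation oracle, 200 random cohorts for the
threshold-scan oracle, n = 20,000 for coefficient recovery and
n = 50,000 for the closed-form binormal AUC check. All randomness flows
from explicit integer seeds; identical seeds reproduce byte-identical
CSV artifacts.

## 7. Known limitations

- FTV segmentation is thresholding inside a box: no morphology, no
  connectivity filtering, no partial-volume handling.
- The Wald interval is anti-conservative for sensitivities near 0 or
  100% at small n; a score interval would behave better but would not
  match the reporting convention the package mirrors.
- Threshold selection operates on full-cohort predictions from the
  CV-selected, refit model; the thresholds themselves are not
  cross-validated, so their operating characteristics are optimistic on
  the training cohort.
- The synthetic AUC sits above the published real-data range (see §2);
  conclusions about discrimination on real cohorts cannot be drawn from
  the synthetic default.
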