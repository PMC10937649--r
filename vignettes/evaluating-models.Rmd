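---
title: "Evaluating and comparing supervised ML models with metricomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and comparing supervised ML models with metricomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metricomp)
```

## The problem

Comparing machine learning models sounds simple — compute a metric for
each, pick the larger — but two things routinely go wrong. First, the
metric itself can mislead: on a tumour-segmentation slice where 1–2% of
pixels are foreground, a model that finds no tumour at all still scores a
pixel accuracy above 0.97, while its Dice score is 0. Second, the
comparison is a statistical question: metric values from the same test
instances are *paired*, values from cross-validation rounds are *not
independent*, and the popular paired t-test is sensitive to outliers and
invalid on resampled test sets. `metricomp` implements the metrics from
their defining formulas and wires them to the paired tests that suit each
evidence regime.

## Metrics and their conventions

### Count-based classification metrics

All ratio metrics derive from the four counts TP, TN, FP, FN held in a
`binary_confusion`. The internal orientation is fixed — rows are the true
class, columns the predicted class — and constructors accept an
`orientation` flag that transposes on ingest, because reported matrices
use both conventions and silent transposition is the classic bug. A
zero-denominator metric (e.g. sensitivity with no positive instances)
raises a typed `metricomp_undefined_metric` condition instead of returning
a conventional 0 or 1: silent conventions differ across ecosystems, and an
aggregate that quietly absorbs an undefined per-class value is worse than
an error that names the class.

Cohen's κ = (p₀ − p_e)/(1 − p_e) corrects accuracy by the agreement
p_e expected from the marginals; MCC is the correlation of true and
predicted labels. Both have k-class forms that reduce exactly to the 2×2
formulas at k = 2 (property-tested on 1000 random matrices). Macro
averaging computes a metric per one-vs-rest class matrix and averages
(equal class weight); micro averaging pools the counts first (equal
instance weight). For any square confusion matrix the pooled FP and FN
totals coincide, so micro precision = micro recall = micro F1; with
balanced classes micro and macro also agree for accuracy, sensitivity,
specificity and Youden's index. One documented discrepancy: on the
embedded 4-class worked matrix the multi-class κ formula gives
(389/560 − 1/4)/(3/4) ≈ 0.593, while the reported caption rounds κ to
0.598; the formula value is what the package (and its tests) assert.

### Scores, ROC and thresholds

The decision rule is `score >= threshold → positive`; the boundary case is
positive by definition. ROC curves enumerate one point per distinct score
plus an infinite sentinel, so they always run from (0, 0) to (1, 1) with
both coordinates non-decreasing; ties are merged into single curve points,
and the trapezoidal area then equals the Mann–Whitney estimator (kernel
value ½ on ties) exactly — the suite verifies the identity on 500 random
score sets. Threshold selection (`select_threshold`) evaluates Youden's
index or accuracy at midpoints between consecutive distinct scores plus
sentinels, breaking ties toward the smallest threshold, and refuses
test-role predictions: a threshold tuned on the test set produces
optimistically biased metrics. `cross_entropy` is deliberately the literal
single-sum −Σ pᵢ log qᵢ (natural log, only positive labels contribute);
the conventional two-term loss is available as `binary_cross_entropy`,
clearly separated.

### Regression

Pearson's r follows its defining formula; Spearman's r_s is Pearson on
mid-ranks (average ranks on ties — the standard convention, chosen here
because rank handling is otherwise unspecified). MAE and MSE are true
means: the sums of absolute/squared residuals are divided by n so values
are comparable across test sets of different sizes, with `sum = TRUE`
exposing the raw sums for readers following the bare-sum formulas.

### Segmentation

Dice and IoU are computed from voxel counts and satisfy IoU = D/(2 − D);
SVD = 1 − D and VOE = 1 − IoU are their error complements. Surfaces are
the mask voxels with at least one out-of-mask neighbour (grid boundary
counts as outside); default connectivity is 8 in 2D and 26 in 3D, with 4,
6 and 18 available. Two numerical choices deserve note:

* **ASD denominator.** The average symmetric surface distance sums
  distances over surface voxels; the denominator here is |∂X| + |∂Y|, the
  count matching the summands, which makes ASD a genuine average distance.
  The variant that divides the same sums by the full volumes |X| + |Y| is
  available behind `literal_denominator = TRUE`, since that reading also
  circulates.
* **Hausdorff over surfaces.** Directed `hd` is computed over surface
  voxels (point-to-set distances are defined via the opposing surface);
  for solid masks a voxel-wise directed maximum can differ, and
  surface-to-surface is the default because it is the symmetric-surface
  convention the other distances use.

Anisotropic voxel spacing is accepted as a per-axis scale vector applied
inside the Euclidean distance. SSIM uses the standard two-term form
(2ūv̄ + c₁)/(ū² + v̄² + c₁) · (2s_uv + c₂)/(s_u² + s_v² + c₂) with
population moments (so one-pixel windows are defined), a single
whole-image window by default, tiled windows on request, and default
constants c₁ = (0.01L)², c₂ = (0.03L)² proportional to the squared dynamic
range L. The surface Dice coefficient is the literal voxel-set Dice of the
two surfaces; the distance-tolerance variant found elsewhere in the
literature is intentionally out of scope.

### Detection and retrieval

Boxes are closed real-coordinate rectangles, area (x_max − x_min)(y_max −
y_min), no pixel +1 convention. Matching processes predictions in
decreasing confidence; a prediction may claim one unmatched ground-truth
box of its own class with IoU at or above the threshold, the highest IoU
winning and exact ties breaking toward the earlier-listed ground truth.
Matching is class-partitioned: a prediction never matches a ground truth
of another class and counts as a false positive for its own. Average
precision integrates the precision envelope (every-point interpolation),
which removes the sawtooth ambiguity of the raw curve; the raw trapezoid
is available via `method = "trapezoid"`. mAP averages per-class APs over
classes that have ground truth, and mAP@[0.5:0.95] averages thresholds
0.5, 0.55, …, 0.95. Retrieval metrics are the printed formulas: P@k, AP
normalised by the collection's total relevant count, and DCG with gains
discounted by log₂(rank + 1) and the conventional grade gains 10 / 7 / 3 /
0.5 / 0.

## Statistical tests

All tests return a `metric_test` (printable as a standard `htest`) with
the statistic, reference distribution, degrees of freedom, a p-value and
the branch used. The two-sided convention is p = 2·min(lower tail, upper
tail), capped at 1; the Friedman and McNemar χ² branches use the upper
tail, as is conventional for those statistics.

* **Sign test**: ties dropped (N reduced), exact Binomial(N, ½) p always
  computed, the normal approximation (mean N/2, sd √N/2) reported
  alongside for N ≥ 20. Weak power; listed for completeness.
* **Wilcoxon signed-rank**: zeros discarded, average ranks on tied
  absolute differences, T = min(R⁺, R⁻). Exact branch for n ≤ 25 without
  ties (the printed z formula has no tie correction, and the exact
  distribution is cheap there); normal approximation above or with ties.
  The cutoff is a documented package choice — the statistic is defined
  both ways and the switching rule is otherwise open.
* **Friedman**: within-round ranks with rank 1 for the *highest* metric
  value (direction does not affect the statistics but is fixed so rank
  outputs are reproducible); χ²_F on K − 1 df, and the recommended
  Iman–Davenport F_ID on (K − 1, (K − 1)(J − 1)) df, the default because
  χ²_F is overly conservative. When one model wins every round χ²_F
  attains J(K − 1) and F_ID's denominator vanishes: that is reported as an
  undefined-statistic condition, not infinity.
* **McNemar**: continuity-corrected (|b − c| − 1)²/(b + c) against χ²₁
  when b + c ≥ 20, exact two-sided binomial p = min(1, 2P(X ≤ min(b, c)))
  below; both branches can be forced, since reported p-values do not
  always name the branch used.
* **DeLong**: AUCs via the Ψ kernel; variances and covariance from the
  standard structural components (per-positive means V10, per-negative
  means V01, sample covariances scaled by 1/m and 1/n). Validated two
  ways: against an independent reference implementation on random data,
  and by Monte-Carlo calibration showing Z_D approximately standard normal
  under the null. If the estimated variance of the difference is zero, the
  test errors — except in the knife-edge case where the two AUC estimates
  coincide exactly, where Z_D = 0 and p = 1 are returned with a note.
* **Variance chain**: the F-test S₁²/S₂² (two-sided, twice the smaller
  tail) for normal data; Bartlett's, Levene's (group-mean centering by
  default) and the Shapiro–Wilk normality gate are delegated to vetted
  routines (`stats`, `car`) and wrapped in the uniform result form —
  re-deriving Shapiro–Wilk's coefficients would add risk and no value.

## The advisor

`advise()` encodes the test-selection logic as a *data* rule table
(`advisor_rules()`), matched top to bottom, so the whole decision space
can be printed, audited and tested exhaustively. Each rule carries a
rationale and caveats; rules restating explicit written guidance are
tagged `"text"`, placements completing the grid (e.g. Friedman for > 2
models compared on per-instance metric values) are tagged `"inferred"`.
Hard refusals are classed errors: pooled-error accuracy comparison on a
single test set, AUC without scores, variance questions for more than two
models. The advisor never returns the paired t-test: the function exists
(`paired_t_test`) for pedagogy and sensitivity analyses, but resampled
evidence invalidates it, and recommendations on multiple-test-set evidence
carry the non-independence caveat.

## Synthetic data: what it emulates and what it does not

The generators exist so every test (and the calibration evidence below)
runs without real images or trained networks.

* `synth_scores` draws a balanced test set (default n = 600, matching a
  300 + 300 worked-example design) from a latent-signal model with
  per-model noise and configurable inter-model correlation (default 0.5)
  and class separation (default 1.45, putting AUC near 0.85, the scale of
  the worked examples). Correlation 1 with equal separation yields the
  exact DeLong null.
* `synth_masks` places a disk of the requested foreground fraction
  (default 1.3%, a small tumour-like target on a 128×128 grid) and jitters
  its centre and radius for the prediction; `placement = "disjoint"`
  realises the accuracy-vs-Dice imbalance demonstration.
* `synth_paired_metrics` generates the J×K metric matrix (default J = 25,
  a repeated five-fold design's rounds; K = 2) as baseline + shared
  per-round effect + model effect + noise.

These generators emulate the *statistical structure* the tests consume —
pairing, correlation, effect sizes — not real data: scores are
logistic-Gaussian rather than network outputs, masks are geometric disks
without anatomical texture, and metric matrices are additive Gaussian.
Passing tests therefore demonstrate that the formulas, branch rules and
calibration are correct, not that any particular model generalises.

## Calibration evidence

The test suite verifies, each run: exact-branch p-values of the sign,
Wilcoxon and McNemar tests against brute-force enumeration of their null
distributions (n ≤ 10); type-I error of the Wilcoxon (n = 20), sign
(N = 25), Friedman/F_ID (J = 15, K = 3) and McNemar (5000-instance paired
errors) tests within three Monte-Carlo standard errors of α = 0.05 over
2000 null replicates; and the DeLong Z_D statistic's approximate standard
normality under a simulated null. Problem sizes were chosen so the
discrete tests' attainable significance levels sit near 0.05 (very small
N makes any exact test conservative by construction, which is a property
of discreteness, not an implementation artefact) and so the full suite
runs in about a minute.

## Worked-example fixtures

`load_fixture()` exposes the embedded worked examples: the 600-image
binary confusion matrix, the 560-image 4-class matrix, the two
discordant-count pairs, and a 128×128 mask pair realising the reported
pixel tallies (TP 181, TN 16156, FP 17, FN 30 → Dice 0.885, IoU 0.794).
The mask geometry is synthetic — pixels ordered by distance from the grid
centre, so the truth is a disk-like blob — because only the counts are
reported and every derived metric depends on the counts alone.

## Known limitations

* No probability-calibration metrics (Brier, ECE), no class-weighted
  averaging, no partial AUC or ROC confidence bands, no 95th-percentile
  Hausdorff, no post-hoc Nemenyi/Holm procedures after Friedman, no
  corrected resampled t-test variants.
* Surface distances build full pairwise distance matrices between surface
  voxel sets; fine for slices and moderate 3D masks, memory-heavy for very
  large surfaces.
* `detection_pr_curve` re-runs matching at every confidence cut-off
  (faithful to the definition, quadratic in the number of detections);
  `map_at` uses the standard pooled cumulative formulation.
* The exact Wilcoxon branch requires tie-free absolute differences; with
  ties it falls back to the normal approximation even at small n.
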