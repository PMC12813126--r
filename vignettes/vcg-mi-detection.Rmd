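---
title: "Loop morphology and stacked classification for MI detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop morphology and stacked classification for MI detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcgmi)
```

This vignette documents the scientific and numerical choices behind
`vcgmi`: the signal model, the twelve loop features, the statistical
screen, the classifier grid and stacking protocol, and what the synthetic
cohort generator does and does not emulate.

## Signal model and baseline removal

A vectorcardiogram is the 3-D trajectory of the cardiac electrical vector,
sampled on three orthogonal (Frank) leads X, Y, Z in millivolts. Slow
baseline wander from respiration and electrode drift (typically below
0.5 Hz) corrupts loop geometry, so each lead is decomposed into

> signal = detrended + baseline,

where the baseline is a second-order Savitzky–Golay (local least-squares
polynomial) smooth. For the order-2 smoother the approximate −3 dB point is

> `f_cutoff = f_s / (2 · window)`,

about **0.416 Hz** at the default window of 1201 samples and 1 kHz. The
polynomial order affects the transition shape but not this first-order
cutoff estimate, which is why `sg_cutoff()` depends only on the window and
the sampling rate. The window must be odd; records shorter than the window
shrink it to the largest odd length with a warning.

Implementation rests on `signal::sgolayfilt()`. Interior samples are the
classical centered-window least-squares fit; at the edges the polynomial
fitted on the first/last *full* window is evaluated at the off-center
positions. No zero padding is involved, so the first and last half-window
are transient-free, the decomposition is exactly additive, the operator is
linear, and any input that is globally a polynomial of degree ≤ 2 is
absorbed entirely into the baseline (all three properties are asserted in
the test suite).

## Delineation

The pipeline needs per-beat QRS and T windows; these are placed with fixed
physiological constants around a magnitude-based R detector:

| constant | default | meaning |
|---|---|---|
| `threshold_frac` | 0.5 | fraction of the rolling 2-s maximum of ‖v(t)‖ |
| `refractory_ms` | 200 | minimum R-to-R lockout |
| `qrs_half_ms` | 60 | QRS window half-width |
| `t_on_ms` | 120 | T window onset after R |
| `t_off_ms_cap`, `t_off_rr_frac` | 450, 0.7 | T offset: min(450 ms, 0.7·RR) |

Beats with preceding RR < 300 ms or windows crossing the record boundary
are dropped and counted. These constants are conventional QRS/T durations,
deliberately simple and fully exposed in `delineation_config()`; the
package makes no attempt at arrhythmia-aware delineation or separate
T-peak detection (the T maxima are taken over the whole T window).

## The twelve loop features

For an ordered loop of 3-D points the *optimal plane* is obtained from the
singular value decomposition of the centered point matrix; the first two
right singular vectors span the least-squares plane, and projecting onto
them yields the loop's principal components. Feature definitions:

* `arcQRS` — discrete arc length of the projected QRS loop (open curve: no
  closing segment, since it is a sampled curve integral).
* `areaQRS`, `areaT` — shoelace area of the projected loop *with* closure
  (a polygon area). Each loop is projected onto its own optimal plane. For
  self-intersecting loops this is the absolute signed area, documented
  behavior rather than the geometric union.
* `maxVecQRS`, `maxVecT` — √(max X² + max Y² + max Z²) with per-lead maxima
  taken independently over the raw window. The maxima need not be
  simultaneous, so this is *not* the maximum instantaneous magnitude and is
  *not* rotation invariant; it is kept in this literal form because that is
  how the feature is defined in the field, with `strict_max_norm = TRUE`
  available as an escape hatch.
* `maxGravQRS` — largest Euclidean distance from the QRS centroid.
* `maxVel/meanVel/stdVel` for QRS and T — forward-difference speeds
  ‖p_{i+1} − p_i‖·f_s on the raw 3-D points (mV/s), with the *population*
  standard deviation so the statistic is a plain moment of the speed
  series. Velocities are computed on raw 3-D loops, not projections: speed
  is a property of the spatial trajectory, and for exactly planar loops the
  two agree anyway.
* Units: mV for lengths/vectors, mV² for areas, mV·s⁻¹ for velocities —
  made sampling-rate independent by the f_s scaling.

Beat-level vectors are aggregated to one record-level vector by the
per-feature **median** (configurable to mean): outlying beats are
deliberately retained in the data, and the median keeps single distorted
beats from dominating a record.

## Feature screening

Each feature is tested between the MI and HC groups with the two-sided
Mann–Whitney U test, preceded by Shapiro–Wilk normality checks (reported
pooled and per class) that motivate the nonparametric choice. The exact
null distribution is enumerated when `n_a · n_b ≤ 400` and the pooled
sample is tie-free; otherwise the normal approximation with tie and
continuity corrections is used (fully tied samples report p = 1). Features
are ranked by ascending p with name-alphabetical tie-breaks; α = 0.05, no
multiple-testing correction across the twelve features, and *no feature is
ever dropped* — screening is descriptive, as all features are carried into
classification regardless. Boxplot summaries use type-7 (linear
interpolation) quartiles — the Tukey fences depend on the quartile rule, so
it is fixed and documented — and outliers are listed, never removed.

## The classifier grid

`enumerate_grid()` yields exactly 210 configurations in stable order.
Established packages back the families they cover: `rpart` for decision
trees (split criterion Gini or cross-entropy; the max-splits cap is
enforced by pruning on the complexity table, since rpart has no direct
split-count control), `e1071::svm` (kernel scale *s* enters as
γ = 1/s²; polynomial kernels use offset 1; the scaled linear kernel is
degree-1 polynomial; scores are Platt probabilities), `randomForest`, and
`glmnet` for penalized logistic regression. The remaining families are
implemented in the package because no installed equivalent offers their
required options: KNN with city-block/Chebyshev distances and
inverse/squared-inverse vote weights; Gaussian discriminant analysis in
six variants (pooled or per-class covariance, optionally diagonalized,
optionally Moore–Penrose pseudo-inverted with pseudo-log-determinants);
kernel-density naive Bayes with Gaussian/box/Epanechnikov/triangular
kernels (normal-reference bandwidth, densities floored at 1e-12 before
logs); a 1–2 hidden-layer tanh MLP trained by L-BFGS on the cross-entropy
loss with a small L2 term (1e-4) for conditioning; and a boosting engine
(below).

Logistic-regression rows pair a class prior (uniform priors are realized
as class-balancing observation weights), an L1 or L2 penalty at a fixed
small λ = 0.01, and one of six named solvers. All supported solvers reach
the same penalized optimum, so the solver acts as a row label; the
solver/penalty combinations that are not supported are enumerated but
flagged, and running them yields an explicit unsupported-configuration
result instead of an exception, keeping the grid count at 210.

The boosting family uses exhaustive-search decision stumps and weighted
pooled-covariance LDA as weak learners (closed-form and fast, so hundreds
of cycles stay cheap): discrete AdaBoost; random-undersampling boosting
(each cycle keeps the minority class and weight-samples the majority down
to parity); LogitBoost (Newton steps with regression stumps on the working
response, clipped to ±4); GentleBoost (regression stumps on the ±1 labels
under exponential weights); and a robust variant — AdaBoost whose example
weights follow the bounded logistic loss gradient, capping the influence
of outliers that the exponential loss would amplify. Scores are
`plogis(2F)` of the accumulated margin.

## Cross-validation and stacking

One stratified fold plan (per-fold class counts within one of perfect
stratification) is shared by every configuration. Features are
standardized *inside* each fold using training-fold statistics only. Every
sample is scored exactly once, by the model that excluded its fold; the
training index sets are recorded so the no-leakage property is a
structural assertion, not a convention. All randomness (folds, learner
initializations, resampling, permutation shuffles) derives from one master
seed via fixed tags, so each stage is independently reproducible.

The stack takes the nine per-family best configurations (highest CV
accuracy, ties broken toward higher sensitivity, which is the clinically
favored metric for MI detection) and trains a logistic-regression
meta-classifier on their out-of-fold scores — continuous scores, not hard
labels, since they strictly generalize them. Because the protocol behind
published stacked CV metrics is rarely spelled out, the package adopts the
leakage-safe reading: an outer pass over the same folds refits the
meta-classifier on the OOF rows of the other nine folds and scores the
held-out fold, so the reported stacked metrics are themselves out-of-fold.

Metrics follow the standard confusion-matrix suite (MI positive):
sensitivity, specificity, PPV, NPV, accuracy, f1; any metric with a zero
denominator is reported as `NA`, never silently 0 (small HC groups can
produce empty cells). ROC curves sweep the distinct scores; AUC uses the
trapezoid rule, which handles ties as midpoints and therefore equals the
Mann–Whitney rank statistic U/(n₁n₂) — a dual-route identity the tests
exploit. The operating cut-point maximizes the Youden index J = TPR − FPR
with ties resolved toward higher sensitivity; the closest-to-(0,1)
criterion is available as an alternative because the convention behind
published cut-points is often unstated.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the features of real Frank-lead data
that the pipeline measures:

* beat trains at 1 kHz, heart rate drawn uniformly per record from 60–90
  bpm, with ≤5% beat-to-beat jitter on loop radii and RR;
* QRS and T loops as planar ellipses (half-axis ratio 2:1) in random
  planes fixed per record, traced from and back to the origin so the apex
  (2× the major half-axis) falls exactly on the R sample; defaults: QRS
  1.2 mV over 90 ms, T 0.35 mV over 160 ms;
* analytic ground truth per beat: R position, enclosed area πab, mean
  tracing speed = perimeter/duration (perimeter by numerical quadrature);
* between-record amplitude heterogeneity: one global log-normal factor
  (σ = 0.15) plus independent QRS/T factors (σ = 0.08), emulating
  inter-patient variability so the classes overlap rather than separate
  trivially;
* sinusoidal baseline wander (0.1 mV at 0.15 Hz — below the 0.416 Hz
  cutoff, so detrending should remove it) and white noise (3 µV, a
  plausible residual for high-quality 16-bit recordings);
* class effects: MI multiplies the QRS loop *area* by
  `mi_qrs_area_scale = 0.5`, realized on the minor half-axis so the area
  feature (not every QRS feature) carries the signature, and multiplies
  the T *tracing speed* by `mi_t_velocity_scale = 0.6`, split between a
  modest size reduction (scale^0.3) and slowed tracing (scale^−0.7) —
  mirroring reduced amplitude plus delayed repolarization. With these
  defaults the screen ranks the T-velocity and QRS-area features on top,
  the same qualitative ordering reported for real MI cohorts.

What the generator does **not** emulate: P waves, ST-segment shifts,
conduction abnormalities, non-planar or figure-eight loops, ectopy and
arrhythmia, electrode artifacts, or the severe 347-vs-80 class imbalance
of the real database (defaults are 40/40). Passing tests on synthetic
cohorts therefore validate the *machinery* — geometry, statistics,
leakage-freedom, reproducibility — not clinical performance; numbers
obtained on this cohort say nothing about sensitivity or specificity on
real patients.

## Numerical choices and degenerate inputs

* SVD-based plane fits reject loops with all points identical; singular
  values are returned descending and the axes are orthonormal to 1e-9.
* Sign ambiguity of singular vectors is irrelevant to every feature (areas
  and arc lengths are absolute; projections change sign only).
* Covariance inversions add a relative ridge of 1e-10 (plain variants) or
  use an eigenvalue cutoff at 1e-10 of the largest (pseudo variants).
* Constant features standardize to zero (unit divisor guard at 1e-12) and
  fully tied Mann–Whitney samples report p = 1 rather than NaN.
* Boosting weak-learner errors are clipped to [1e-10, 1−1e-10]; a cycle
  with error ≥ 0.5 terminates the ensemble.
* Problem sizes in the shipped tests and acceptance run: 40+40 records of
  10 s at 1 kHz for the cohort-level checks, 1000-draw simulations for the
  statistical size checks, and the full 210-configuration grid under
  10-fold CV — sizes chosen so a complete run stays in the minutes range
  on one CPU while every stage is exercised end to end.

## Known limitations

* Beat delineation uses fixed windows; records with extreme heart rates or
  wide QRS complexes would need retuned constants.
* The `maxVec` features are frame-dependent by definition; comparing them
  across recordings assumes a consistent lead system.
* The logistic meta-classifier is fitted unregularized; with many highly
  correlated base models and few samples its coefficients are unstable
  (its out-of-fold *predictions*, which all reported metrics use, are the
  meaningful output).
* WFDB support covers format 16 header/data pairs (the PTB layout) only;
  no annotations, no multi-segment records, no WFDB writing.
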