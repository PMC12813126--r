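# vcgmi — myocardial infarction detection from vectorcardiographic loop morphology

`vcgmi` is an R implementation of a vectorcardiography (VCG) processing
pipeline for the automated detection of myocardial infarction (MI). It is
aimed at biomedical-signal researchers who work with three-lead orthogonal
(Frank) recordings — for example the VCG channels of the public PTB
diagnostic ECG database — and want a reproducible path from raw leads to a
cross-validated classifier with leakage-free decision-level fusion.

Infarcted myocardium conducts depolarization and repolarization abnormally,
which deforms the spatial QRS and T loops traced by the cardiac vector
**v**(t) = (X(t), Y(t), Z(t)). The package quantifies those deformations
with twelve morphological features and feeds them into a stacking ensemble.

## Pipeline

1. **Baseline removal.** Each lead is detrended by subtracting a
   second-order Savitzky–Golay smooth with a long window (default 1201
   samples). Its approximate cutoff is
   `f_cutoff = f_s / (2 · window)` ≈ 0.416 Hz at 1 kHz, below respiratory
   wander but far below QRS content. The decomposition is exactly additive:
   detrended + baseline reconstructs the input.
2. **Delineation.** R peaks are local maxima of the spatial magnitude
   ‖**v**(t)‖ over an adaptive threshold (half the rolling 2-s maximum, 200
   ms refractory). Each beat is cut into a QRS loop (R ± 60 ms) and a T loop
   (R + 120 ms to R + min(450 ms, 0.7·RR)).
3. **Loop features.** For each loop the *optimal plane* is fitted by SVD of
   the centered point matrix X_c = U Λ Wᵀ; the first two right singular
   vectors span the least-squares plane and the projected coordinates are
   the principal components. From these come: `arcQRS` (discrete arc length
   Σ‖p_{i+1} − p_i‖ of the projected QRS loop), `areaQRS`/`areaT` (shoelace
   area of the closed projected loop), `maxVecQRS`/`maxVecT`
   (√(max X² + max Y² + max Z²), independent per-lead maxima),
   `maxGravQRS` (largest distance from the loop centroid), and velocity
   statistics max/mean/SD of ‖p_{i+1} − p_i‖·f_s for both loops. Per-record
   values are beat-wise medians.
4. **Screening.** Shapiro–Wilk normality and two-sided Mann–Whitney U tests
   per feature (exact enumeration for small tie-free samples), ranked by
   ascending p. Screening is diagnostic: all twelve features continue
   downstream, and Tukey-fence outliers are flagged but never removed.
5. **Classifier grid.** 210 hyperparameter configurations across nine
   families — SVM (25), discriminant analysis (6), KNN (36), decision tree
   (32), neural network (20), naive Bayes (10), random forest (25),
   logistic regression (24, with the unsupported solver/penalty rows
   enumerated and flagged), and boosting ensembles (32) — each evaluated by
   stratified 10-fold cross-validation with per-fold standardization.
6. **Stacking.** The per-family best configurations feed a logistic
   regression meta-classifier trained exclusively on out-of-fold (OOF)
   scores; the stacked model is itself evaluated out-of-fold, and the
   recorded training index sets make the no-leakage guarantee checkable.
   Performance is reported as sensitivity, specificity, accuracy, PPV, NPV,
   f1, confusion matrices, and ROC/AUC with a Youden-index cut-point.

A synthetic cohort generator (`generate_cohort()`) produces labeled beat
trains whose QRS/T loops are planar ellipses with analytic ground truth
(area, perimeter, tracing speed, R-peak positions), between-record
amplitude heterogeneity, baseline wander and noise; MI records get a
reduced QRS-loop area and a reduced T-loop velocity. Every stage of the
package is testable against this ground truth without external data.

## Worked example

```r
library(vcgmi)

cfg     <- synthetic_config(n_mi = 20, n_hc = 20, duration_s = 8, seed = 42)
cohort  <- generate_cohort(cfg)
features <- cohort_features(cohort$records)

screen_features(features)
#> Feature screen (sorted by Mann-Whitney p, all features retained):
#>  rank    feature     sw_p     mw_p
#>     1    stdVelT 0.002780 3.95e-09
#>     2    maxVelT 0.048200 7.37e-09
#>     3    areaQRS 0.315000 5.02e-07
#>     4   meanVelT 0.033600 6.18e-07
#>     5      areaT 0.954000 7.47e-04
#>     6     arcQRS 0.080000 1.14e-01
#>  ...

grid  <- train_grid(features, features$label, seed = 42,
                    families = c("KNN", "SVM", "DA", "NB"), k = 10)
stack <- vcg_stack(features, features$label, grid = grid, seed = 42, k = 10)
summary(stack)
#> Base models (per-family best by CV accuracy):
#>  family                              params  acc sens spec    auc
#>     SVM                kernel=poly3 scale=3 1.00    1  1.0 1.0000
#>      DA                         type=linear 1.00    1  1.0 1.0000
#>     KNN k=5 distance=euclidean weight=equal 0.95    1  0.9 0.9900
#>      NB   prior=uniform distribution=normal 0.95    1  0.9 0.9725
#> ...
#> Stacked out-of-fold performance: sens 100.00%  spec 100.00%  acc 100.00%  ...
```

The screen ranks the T-velocity and QRS-area features first — exactly the
constructed infarction effects — with Mann–Whitney p far below 0.05, while
amplitude-dominated features (`maxVecQRS`, `maxVecT`) stay uninformative.
The Shapiro–Wilk column justifies the nonparametric test (most features are
non-normal at the 5% level). On this deliberately clean 20+20 cohort the
stacked out-of-fold accuracy is 100%; real recordings, with their much
larger biological variability, sit well below that.

Reading measured data instead of synthetic cohorts:

```r
rec <- read_wfdb_record("path/to/s0010_re", lead_names = c("vx", "vy", "vz"))
fv  <- extract_features(rec)   # detrend -> delineate -> 12 features
```

A command-line front end over the same functions is installed as
`exec/vcgmi` (`vcgmi all --dir run --seed 1`), staging
simulate → extract → screen → train-grid → stack with artifact manifests.

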