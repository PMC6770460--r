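---
title: "Methods: cross-over miRNA training analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-over miRNA training analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

crossmir implements the complete analysis of a two-period randomized
cross-over endurance-training study of blood-borne miRNA expression. This
vignette documents the statistical procedures, the choices made where the
design was genuinely open, the synthetic-data generator that stands in for
raw study data, and the limits of what the test suite demonstrates.

## Study design and data model

Each of the participants trains through two multi-week endurance periods
separated by a wash-out, with blood drawn before and after each period
(timepoints E1, A1, E2, A2, one sample per participant × timepoint). One of
the two order groups drinks a glucose solution before every session of
period 1, the other before every session of period 2, so each participant
serves as their own control for the carbohydrate question. Per sample the
design records participant, timepoint, order group, microarray chip, gender
and red-cell count; per participant × timepoint a phenotype table records
VO2 max (mL·min⁻¹·kg⁻¹) and clinical covariates. Two flags are derived
mechanically: `training_state` (pre for E1/E2, post for A1/A2) and
`treated_period` (whether the sample's period was that participant's glucose
period).

All statistics operate on log2-scale expression after preprocessing.

## Preprocessing

The chain is quantile normalization → log2 (skipped when the input is
already log2) → detection filter → expression filter → outlier removal, each
with one tunable threshold:

* **Quantile normalization**: every column is mapped onto the across-sample
  mean of order statistics; ties receive the mean of their rank range. The
  operation is idempotent and makes all column value distributions
  identical.
* **Detection filter** (`detection_fraction = 0.5`): a feature must be
  called present in at least half the samples. When no present/absent calls
  accompany the data, a value above the sample's 5th percentile counts as
  detected.
* **Expression filter** (`q3_min = 3.5` log2 units): the type-7 third
  quartile of a feature's log2 values must not fall below the threshold. The
  boundary is kept — only values strictly below are discarded — because the
  rule is phrased as discarding low expression, and the filters run in the
  documented order (detection first), which makes the two removal lists
  disjoint. Missing values in surviving features are imputed by the feature
  median, with a message.
* **Outlier removal** (`min_mean_rho = 0.85`): a sample whose mean pairwise
  Spearman correlation with all other samples falls below the threshold is
  removed. The rule runs once, not iteratively, matching a design in which a
  single discordant hybridization is the expected failure mode.

## Variance decomposition

`run_pca()` is a thin wrapper over `prcomp` (samples as observations,
features centered, unscaled) with one convention added: each component's
sign is chosen so its largest-magnitude loading is positive, removing the
arbitrary sign of the decomposition. `select_high_loading_features()`
returns the features whose loading magnitude on the first components exceeds
a threshold (default 0.1) plus mean-|loading| summaries for comparing
feature subsets.

`run_pvca()` attributes expression variance to design factors:

1. eigendecompose the sample × sample covariance of the feature-centered
   matrix;
2. retain the smallest leading set of components reaching
   `var_threshold = 0.9` cumulative variance;
3. decompose each retained component's score vector into variance components
   for every factor and every identifiable pairwise interaction;
4. average the per-component attributions weighted by each component's share
   of **total** variance, assigning the unretained tail to the residual;
5. clamp the aggregate at zero and normalize.

Two estimator details deviate from the conventions popularized by earlier
PVCA implementations, both for measurable reasons:

* **Moment solver instead of REML as default.** The default engine solves
  the Henderson-style method-of-moments system built from the projection
  quadratic forms of all terms. Because this estimator is linear in the
  data, per-component estimates may be negative, but their
  eigenvalue-weighted aggregate is nearly unbiased. Calibration on planted
  three-component simulations (200 features, 60 samples, 20 replicates;
  participant 0.5, chip 0.3, residual 0.2) recovers all fractions within a
  few hundredths. A restricted-maximum-likelihood engine
  (`estimator = "reml"`, via lme4) is also provided; its non-negativity
  constraint, applied per component and then aggregated over many weak
  components, systematically inflates factor totals and starves the
  residual, which is why it is not the default.
* **Total-share weighting with the tail assigned to the residual.**
  Renormalizing eigenvalue weights among only the retained components erases
  the unstructured variance living in the discarded tail; since that tail is
  noise-dominated by construction, it is counted as residual.

Interactions that replicate a parent partition, or whose levels mostly hold
a single sample, are dropped with a warning. The latter rule matters in this
design: participant × timepoint has exactly one sample per cell, so a random
effect on it is indistinguishable from the residual — any variance such a
term appears to explain in a saturated fit is an artifact of
unidentifiability. Consequently the package reports the identifiable
participant × training-state interaction (two samples per cell) instead, and
the robust statement on simulated data is that person-dependent variance
(participant main effect plus this interaction) and the training-state
effect each dominate the technical factors (chip, gender, order group); how
the person-dependent share splits between main effect and interaction varies
between realizations, because the within-period wave shape (wash-out level,
dampened second peak) belongs to no identifiable factor and is counted as
residual.

Low-dimensional embeddings (t-SNE, UMAP) are treated as external: the
package consumes sample cluster labels from any embedding and tests their
enrichment in an annotation flag with the hypergeometric upper tail
P(X ≥ k).

## Differential expression

Six comparison setups cross the two periods with three participant subsets
(pooled, glucose-period participants, no-glucose participants); each
compares post vs pre within the period. The default test is the paired
Student t across participants with both samples — these are repeated
measures — with a Welch unpaired alternative (`paired = FALSE`) provided as
a sensitivity switch, since either reading of "t-test" is defensible for
this design. Fold change is the post-mean minus pre-mean of log2 values;
a feature is called up (down) when log2FC ≥ 1 (≤ −1) and unadjusted
p < 0.05. Benjamini–Hochberg adjustment is reported alongside; the volcano
categorization deliberately uses unadjusted p-values. Degenerate features
with a constant nonzero paired difference are reported at the smallest
representable double with a message rather than failing.

`fisher_set_difference()` builds the 2×2 table
`[[|A∩B|, |A\B|], [|B\A|, U−|A∪B|]]` over the tested universe and returns
the two-sided Fisher exact p. Because the table construction behind such an
overlap test is not canonical, a `"union"` alternative (universe restricted
to A∪B) is available and both are documented; no printed literature value is
hard-coded as truth.

## Temporal wave clustering

Features are z-scored (mean 0, sample SD 1 across samples; zero-variance
features are dropped with a warning), reduced to their mean z per timepoint,
and partitioned with Lloyd k-means (k = 6, 50 restarts under a fixed seed,
Euclidean distance). One choice deserves emphasis: the 4-point profiles are
**shape-standardized** (centered and scaled per feature) before clustering.
With realistic response-amplitude spread, Euclidean k-means on raw profiles
partitions features radially by amplitude rather than by temporal shape;
standardization makes the clusters shape families, which is what the
wave-pattern analysis is after. Raw-profile clustering remains available
(`scale_profiles = FALSE`), as does hierarchical clustering with complete
linkage (`method = "hclust"`).

Labels are assigned deterministically — descending magnitude of the
centroid's first peak (A1 − E1), positive direction first — so runs are
comparable. Because no specific clustering algorithm is canonical for this
analysis, exact cluster sizes are not treated as a reproduction target.
Cluster curves are least-squares cubic B-splines (no interior knots) through
the four timepoint means; with four support points and four coefficients the
curve interpolates the means exactly.

## VO2 max association

`participant_correlations()` computes, per participant, the Spearman
correlation of each feature with absolute VO2 max over the participant's
available timepoints (at most 4 pairs; fewer than 3 gives NA).

`fit_vo2_model()` regresses VO2 max on expression with an elastic net
(glmnet) over a near-square grid of `n_hyper = 50` (mixing, penalty)
candidates, selected by repeated cross-validated R² (per-fold 1 − SSE/SST,
averaged over 6 folds × 10 repeats), then refit on all data. Two
conventions:

* **Folds are stratified by participant** by default, so a participant's
  four samples never straddle train and test; with repeated measures,
  unstratified folds leak identity and inflate R². Unstratified folds are
  available (`group_folds = FALSE`) as the sensitivity switch for comparing
  against analyses that did not stratify.
* **Importance is the absolute coefficient on the standardized predictor
  scale** (|coefficient| × feature SD). Coefficients themselves are reported
  on the original scale; the standardized magnitude makes the importance
  ranking invariant to feature units.

R² is the selection metric by default with RMSE as an option; for a fixed
response the two rank hyperparameters identically up to fold-level
weighting. Setting `alpha = 0, lambda = 0` bypasses the grid and reproduces
ordinary least squares on full-rank instances to ~1e-6.

`clinical_tests()` applies, per clinical column and period: paired t-tests
of the pre/post change within the treated and untreated participant sets and
pooled, an unpaired Welch test of post vs pre values, and a Welch test of
the per-participant changes between treated and untreated sets, with a BH
column over everything reported.

## Carbohydrate recommendation and marker screen

`assign_recommendation_groups()` computes Δ1 = VO2(A1) − VO2(E1) and
Δ2 = VO2(A2) − VO2(E2) and recommends supplementation (r = 1) exactly when
the change in the participant's glucose period strictly exceeds the change
in the other period — greater improvement or smaller worsening under
treatment. A tie gives r = 0 with a flag: absent evidence of benefit, no
supplementation is recommended. Participants missing any of the four VO2
values are excluded with a per-participant reason.

`evaluate_marker()` summarizes one feature over the 2 × 2 cells
(pre/post training × glucose/no-glucose period, each sample in exactly one
cell) per recommendation group, tests the group contrast per cell with
Welch's t, and correlates the participant's marker log2 fold change
(post − pre within a period) with the same period's ΔVO2, per condition and
group.

`screen_markers()` systematizes the candidate search: a feature is a
candidate when the post-training no-glucose cell separates the groups
(p < α = 0.05) while the other three cells do not (p ≥ α), ranked by the
discriminating p-value. One structural property should be understood when
interpreting screen output: for a genuinely planted marker the three null
cells each stay non-significant with probability 1 − α, so even a perfect
marker passes the full pattern with probability at most (1 − α)³ ≈ 0.857.
The screen's recovery guarantee is therefore conditional — when the planted
marker passes the pattern it ranks first essentially always — and a null
dataset yields about α(1 − α)³ · n spurious candidates, which the
calibration checks verify against binomial bounds.

## The synthetic-data generator

`simulate_study()` emulates the study conditions so every stage is testable
offline. Defaults: 23 participants in order groups of 13 and 10 (6 f/7 m
and 4 f/6 m), 4 timepoints, 17 chips, 400 features of which 307 form six
wave clusters of sizes 51/35/67/64/70/20 and 93 are low-expressed probes
that the filters should remove. Expression is generated directly on the
log2 scale as

```
baseline + participant intercept + response · gain · wave(timepoint)
         + chip + gender + marker + noise
```

with the following default conditions, each tied to a feature of the
emulated study and frozen before being used in any test:

* baselines spread widely across features (SD ≈ 4.5 log2 units, the dynamic
  range of real arrays), which is what keeps inter-sample Spearman
  correlations above the 0.85 outlier threshold everywhere;
* three up-first and three mirrored down-first wave shapes over
  (E1, A1, E2, A2) — sustained rise, overshoot-below-baseline, and full
  wash-out reset — every one with a dampened second peak, distinct after
  shape standardization;
* gamma-distributed per-feature response amplitudes, so only a tail of
  roughly 20–30 of the 307 responsive features crosses |log2FC| ≥ 1, as in
  the emulated contrasts;
* bounded uniform participant response multipliers with a fixed quantile
  spread around a sub-unit mean (0.55 ± √3·0.6), permuted across
  participants: heterogeneous training response (including adverse
  responders) without resampling the dataset-level signal strength;
* technical terms: chip offsets (SD 0.15), a +0.5 male shift on a fixed 15%
  feature subset (gonosomal-like probes), residual noise SD 0.2;
* a marker feature with low between-person variance, mildly
  training-responsive, carrying a +1 log2 post-training shift in CHO
  responders during their no-treatment period. This planted contrast is
  deliberately stronger than the printed contrast of the real candidate
  (≈ 0.4 log2) so the planted truth is unambiguous; the weaker regime can be
  emulated by lowering `marker_effect`;
* VO2 trajectories: baseline ~ N(35, 5), untreated period gain ~ N(2, 1),
  and a responder bonus ± max(N(1.5, 0.5), 0.1) whose sign is the latent
  responder class; with the default noiseless measurements the ordering of
  the two period gains encodes the class exactly, so the recommendation rule
  can be validated against planted truth.

What the generator does **not** emulate: probe-level scanner signal and raw
intensity distributions (everything is generated post-log2), annotation
errors, carry-over of expression between periods, correlated feature blocks
beyond the six wave clusters, and any expression–VO2 coupling other than the
planted marker. Passing tests therefore demonstrate the pipeline's
correctness and recovery behavior under the stated design, not the
biological conclusions that real data would support.

## Numerical choices and problem sizes

Quantile normalization resolves ties by average rank; Spearman correlations
use average ranks; the Q3 quantile is type 7; constant-difference t-tests
report the smallest representable double rather than failing; k-means uses
200 Lloyd iterations and 50 restarts; glmnet refits use a short descending
lambda path ending at the selected penalty with threshold 1e-12; every
stochastic routine takes an explicit seed and derives per-component
sub-seeds deterministically, so identical seeds give bit-identical results.

The simulation sizes used by the test suite and the acceptance script —
20 replicates for PVCA recovery (200 features × 60 samples), 20 seeds for
wave-cluster recovery and the marker screen (the full 400 × 92 default
study), 20 replicates of the 200-feature/96-sample sparse regression with
6 folds × 2 repeats, and brute-force oracle checks on instances of a few
dozen observations — were chosen to characterize each property stably in a
few seconds apiece; all thresholds asserted in the tests are the documented
pipeline tolerances, not quantities fitted to runs.

## Known limitations

* PVCA attribution for variance generated by participant-specific response
  scaling splits between the participant main effect and the
  participant × training-state interaction in a realization-dependent way;
  only their sum is stable.
* The marker screen's four-cell pattern has the (1 − α)³ pass-rate ceiling
  described above; a screening application that cannot afford to miss
  candidates should rank all features by the discriminating cell's p-value
  and treat the pattern flag as secondary.
* The elastic-net R² under participant-stratified folds is systematically
  lower (and more honest) than under sample-level folds; comparisons with
  analyses that did not stratify must switch `group_folds` accordingly.
* With four timepoints, the cluster curves are exact interpolants; they
  smooth nothing and exist for display.
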