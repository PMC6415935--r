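---
title: "Methods: dynamical neural-pattern analysis of prior-guided visual disambiguation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamical neural-pattern analysis of prior-guided visual disambiguation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mooneyrsa)
```

## The scientific problem

A Mooney image is a two-tone degraded photograph that is typically
unrecognizable until the viewer has seen the matching grayscale original
once; from then on the same degraded input is recognized effortlessly
("disambiguation"). Because the physical stimulus is identical before and
after disambiguation, the paradigm isolates the contribution of a perceptual
prior to recognition. `mooneyrsa` implements the multivariate analysis chain
used to characterize the neural dynamics of this process in sensor-level
magnetoencephalography together with region-of-interest fMRI patterns:

1. time-resolved linear decoding of perceptual state (pre- vs.
   post-disambiguation) with temporal generalization;
2. time-resolved representational dissimilarity matrices (RDMs) over all
   (condition, image) pairs under three metrics — 1 − Pearson r,
   (cross-validated) squared Euclidean distance, and a single-trial
   separability statistic;
3. theoretical model RDMs for stimulus-feature, recognition-content, and
   attentional-state coding, with model-based RSA;
4. model-driven sensor–fMRI fusion via commonality analysis; and
5. nonparametric group inference by cluster-based permutation tests.

Because no public recordings accompany the design, the package ships a
fully synthetic experiment generator whose defaults reproduce the study
conditions (33 real + 6 catch image sets, 14 runs, 18 subjects, 6 pre- and 6
post-disambiguation Mooney presentations and 3 grayscale presentations per
image). Every analysis stage is exercised end to end against this generator.

## The experiment generator

### Design schedule

`build_design()` schedules trials so that a set's Mooney image appears
pre-disambiguation in its introduction run, its grayscale image and
post-disambiguation Mooney presentations in the following run. A full-run
block holds 3 grayscale trials, then 6 Mooney trials in random order, then
the same 6 re-randomized (15 trials); each block is presented three times per
run, and the first and last of the 14 runs are half runs. The schedule
guarantees 6 + 6 Mooney and 3 grayscale presentations per image and that a
Mooney trial is labelled "post" exactly when its grayscale image occurred
earlier. How sets are distributed over introduction runs is not uniquely
determined by the published constants (12 full runs introduce more slots than
33 real sets fill at 3 per run, hence the 39 = 33 + 6 total with catch sets);
the scheduler exposes `set_assignment` and defaults to a seeded random
assignment. Catch sets receive a non-matching grayscale image and control
for repetition effects.

### Behavior

`simulate_behavior()` draws, per image and stage, a latent recognized/
not-recognized class (rates default to the observed 34% spontaneous and 87%
post-disambiguation recognition), then six Bernoulli recognition reports per
stage at `p_hit = 0.9` within the recognized class and `p_miss = 0.1`
otherwise. This produces the bimodal per-image count distribution on which
the behavioral classification rests: at most 2 of 6 reports is
"not-recognized", at least 4 of 6 "recognized";
`select_disambiguated_sets()` applies the conjunction (not-recognized pre,
recognized post). Verbal identification is one correlated Bernoulli draw per
stage.

### Sensor epochs

Each simulated trial is a sum of planted components, each a fixed sensor
pattern scaled by a time envelope, plus i.i.d. Gaussian sensor noise:

* **evoked** (every trial): Gaussian bump at 150 ms plus a sustained plateau
  while the image is on screen;
* **stimulus** (image-specific; shared by a Mooney image across stages, with
  separate patterns for grayscale images): Gaussian bump at 200 ms (sd
  80 ms) plus an optional second bump at 1.35 s (sd 100 ms, relative
  amplitude 0.5) mirroring the reported late re-emergence of
  stimulus-feature coding;
* **class** (Mooney vs. grayscale gross statistics): stimulus envelope;
* **recognition** (image-specific; shared between a post-disambiguation
  Mooney image and its matching grayscale image; absent pre-disambiguation
  and for catch Mooney images): logistic ramp with midpoint 600 ms;
* **attention** (condition-level; present in recognized conditions):
  Gaussian bump at 500 ms (sd 100 ms).

Image-specific patterns are generated from latent feature vectors
(`latent_dim = 8` per component type) pushed through a random orthonormal
map into sensor space. The point of the latent layer is cross-modal realism:
`simulate_roi_patterns()` pushes the *same* latent vectors through
ROI-specific orthonormal maps into voxel space, so sensor and ROI data share
image-level representational geometry — the property that makes RDM-based
fusion meaningful — while having unrelated measurement bases. With 8 latent
dimensions for 33 images, pairwise image similarities have substantial
spread (s.d. ≈ 1/√8), giving each component a non-trivial geometry.

Amplitudes default to evoked 1, stimulus 1, class 0.6, recognition 1,
attention 0.8, with per-sensor noise s.d. 0.25 and 40 sensors (tests and
examples often use 24–32). The noise level was chosen so the group-average
dissimilarity curves have the dynamic range reported for real data — an
evoked-driven trough around 0.4–0.6 after stimulus onset and a visible late
separation between conditions; component amplitudes are order-one by
construction and were not tuned per analysis.

Component patterns are shared across subjects (only noise differs), which
makes the group-average RDM geometry cleaner than real between-subject
variability would; consequences for inference are noted under Limitations.

What the generator does **not** emulate: MEG forward fields and sensor
covariance, 1/f spectra, eye movements, hemodynamics, inter-subject
topography differences, or behavior-coupled trial-by-trial component
fluctuations (component membership follows condition, not the simulated
button presses). Passing recovery tests on this generator therefore
demonstrates the correctness and calibration of the analysis chain, not that
real recordings would yield the same latencies.

## Preprocessing

`filter_band()` demeans and linearly detrends each channel, applies a
3rd-order Butterworth filter forward and backward (zero phase), then
anti-alias filters and decimates to the band's target rate: slow cortical
potentials (0.05–5 Hz, 10 Hz) and the event-related field range (low-pass
35 Hz, 100 Hz). Zero-phase filtering is used because the downstream
statistics make no causal claims beyond latency ordering — a shift-free
response is preferable to a causal filter's group delay; the tests verify
the double-pass Butterworth magnitude response analytically (including
bilinear-transform frequency warping). The slow band's 5 Hz edge sits
exactly at the 10 Hz target's Nyquist frequency; the anti-alias filter (0.8
× target Nyquist) provides the guard band. `epoch_and_baseline()` cuts
−0.5 s to +3.0 s epochs and subtracts the per-sensor mean of the
pre-stimulus window; `normalize_across_sensors()` z-scores the sensor vector
at every time sample, so pattern analyses compare topography shapes, not
amplitudes.

## Decoding

`decode_timecourse()` classifies presentation stage at every time point with
a linear SVM at fixed cost 1 (no per-time hyperparameter search). Samples
are per-image patterns averaged across all six per-stage presentations;
folds are a deterministic odd–even split over image sets (parity of the
sorted image index), which keeps both stage averages of an image in the same
fold and thereby rules out image-identity leakage between folds. Accuracy is
balanced accuracy averaged over the two folds; decision ties go to the
negative class. `activation_patterns()` converts backward-model weights to
forward-model topographies by multiplying with the training-data covariance.
`temporal_generalization()` evaluates every training-time rule at every test
time under the same folds, so the matrix diagonal equals the within-time
curve exactly.

Note what the generator implies here: only condition-level components
generalize across image sets, so decodability concentrates where the
attention component is active; image-specific recognition components do not
transfer from training to test images. A null generator (recognition and
attention amplitudes 0) is decoded at chance — the calibration the
acceptance script recomputes.

## RDM analyses

`rdm_series()` builds a symmetric 99 × 99 matrix per time point over the
entries Pre 1..33, Post 1..33, Gray 1..33 (catch sets excluded; main
diagonal stored missing). For the correlation and plain-Euclidean metrics,
entries are per-image averages of the first three presentations (matching
the three grayscale presentations); the single-trial metrics use all 6
Mooney trials per stage and all 3 grayscale trials:

* `one_minus_r`: 1 − Pearson r across sensors.
* `euclidean`: squared Euclidean distance, stored as a raw sum over sensors
  (not normalized by sensor count).
* `cv_euclidean`: trials are split into 3 folds in presentation order
  (6 trials → 3 folds of 2; 3 trials → folds of 1); for fold j the pattern
  difference from fold j is multiplied with the difference from the held-out
  trials and products averaged over folds. Independent noise in the two
  partitions is uncorrelated, so the noise contribution cancels in
  expectation: identical true patterns give distance 0 on average, unlike
  the plain distance, whose noise bias tracks condition-specific noise
  levels.
* `separability`: for images A (m trials) and B (n trials),
  `r_within − r_between`, where `r_within` is the average of the two
  within-image mean Fisher-z trial correlations and `r_between` the mean
  Fisher-z correlation over all m × n cross pairs. The score stays in z
  space (no back-transform) and is zero in expectation for exchangeable
  trial sets. Averaging the two within-image means (rather than summing
  them) is required for that calibration at chance level 0 and is the
  reading the package adopts.

Correlations at ±1 (noise-free fixtures, identical trials) are clipped to
±(1 − 10⁻¹⁰) before the Fisher transform.

Summary operations follow the study's analyses: mean upper-triangle
dissimilarity per within-condition square
(`within_condition_dissimilarity_timecourse()`); geometry correlations
between two within-condition squares of the similarity matrix 1 − RDM after
Fisher-z of the entries (`intra_rdm_correlation()`; Pre–Pre vs. Post–Post
indexes stimulus-feature geometry, Post–Post vs. Gray–Gray recognition
geometry); and, on the separability RDMs, the mean between-condition
diagonal and the off-diagonal-minus-diagonal contrast
(`cross_condition_diagonal_timecourse()`,
`offdiagonal_minus_diagonal_timecourse()`).

## Model RDMs and fusion

`build_model_rdm()` encodes the three a-priori models with levels 0, 0.5, 1
and explicit missing cells (the main diagonal always; additionally the
Mooney–grayscale matching diagonals in the stimulus model, for which no
a-priori ordering exists). The recognition model's two low levels (unrecognized
pairs; matching post/gray pairs) are a modelling convention and separately
settable. Any analysis combining matrices excludes the union of missing
cells (listwise).

`model_rsa_timecourse()` computes the Spearman correlation between the
upper triangles of the group-averaged sensor RDM and a model per time point.
`commonality_shared()` and `commonality_unique()` implement variance
partitioning over rank-transformed RDM vectors: all vectors are converted to
average ranks and R² values come from ordinary least squares, so a
single-predictor R² equals squared Spearman rho, consistent with the
correlation choice elsewhere (`rank_transform = FALSE` switches to raw
values). Shared commonality between the sensor RDM, an ROI RDM and model M1
is `R²(f) + R²(m1) − R²(f, m1)`; the commonality unique to M1 relative to a
competitor M2 is `R²(f, m2) + R²(m1, m2) − R²(m2) − R²(f, m1, m2)`.
Negative commonalities (suppression) are reported, not clipped.
Rank-deficient predictor sets are handled by QR pivoting with a warning.

`fusion_map()` assembles the full analysis: unique commonality for the
stimulus and recognition models (each partialling the other, since their
neural correlates overlap in time), shared commonality for the attention
model, per ROI and time point. Significance uses the entry-order permutation
scheme (below), and cells are additionally masked by the dual-significance
rule: the sensor–model correlation must fall in a significant cluster at
that time and the ROI–model correlation must be permutation-significant.
`fusion_upper_bound()` reports the squared Spearman correlation between
sensor and ROI RDMs — the ceiling on what any model can explain; the shared
(attention) commonality respects the bound analytically, while unique
commonalities can exceed it under suppression.

## Group inference

`cluster_permutation_timecourse()` tests a group time course against chance
with a one-tailed one-sample Wilcoxon signed-rank test per sample. The exact
null distribution of the W statistic is computed by dynamic programming on
the realized (possibly tied) ranks, which also makes the sign-flip
permutation scheme cheap: ranks of |deviation| are invariant under sign
flips, so each of the (default 500) permutations is a masked column sum.
Clusters are contiguous runs of pointwise p < 0.05, summarized by their
summed W; observed summaries are compared with the 95th percentile of the
per-permutation maxima. Sign-flipping each subject's deviation from chance
is the exchangeability-preserving one-sample analogue of shuffling class
labels. `cluster_permutation_tgm()` is the two-dimensional version with
4-neighbour connectivity; paired condition contrasts reuse the one-sample
machinery on per-subject differences (with 5000 shuffles by convention for
RDM condition contrasts).

`rdm_order_permutation_null()` builds the null for any RDM-series statistic
by shuffling the order of all 99 (condition, image) entries, identically for
rows, columns, and every time point of a series. Shuffling entries, rather
than the 33 images within condition blocks, is deliberate: a within-block
shuffle leaves every purely block-structured statistic — the entire
attention model, for instance — numerically invariant, so its null would be
degenerate. Clusters are contiguous samples where the observed statistic
exceeds the per-time 95th percentile of the null, significant when larger
than the 95th percentile of the per-permutation maximum cluster sizes.
`fdr_mask()` applies Benjamini–Hochberg (the classic step-up rule; no
dependency correction) where FDR control is wanted instead.

## Numerical and design choices

* Folds, ties, and orderings are deterministic (parity folds,
  presentation-order fold assignment, negative-class ties) so repeated runs
  are bit-identical under a fixed seed; every stochastic stage derives its
  seed from one master seed.
* Fisher-z clipping at ±(1 − 10⁻¹⁰) keeps degenerate noise-free fixtures
  finite.
* The cross-validated distance pairs fold j with the mean of the held-out
  folds; distances are averaged over the three folds.
* Epoch grids anchor t = 0 on a sample; decimation keeps sample times on
  the original grid.
* Problem sizes in the test-suite recovery runs: 18 subjects, 32 sensors,
  33 + 6 image sets, RDM analyses on the 10 ms grid and single-trial
  separability on a 20 ms grid, 500 permutations per permutation test.
  These are the package's chosen desk-scale study conditions; the summary
  windows (early 0.05–0.4 s, late 0.7–1.1 s) bracket the planted envelopes.

## Known limitations

* Identical component patterns across subjects overstate group-level
  geometry consistency; permutation nulls for group-averaged RDM statistics
  inherit smooth temporal structure, and short-lived effects are then
  conservative under the max-cluster-size criterion.
* ROI RDMs are static, so cross-ROI onset differences in the fusion maps
  reflect signal-to-noise, not conduction delays; onset *orderings* between
  model types are meaningful, latency magnitudes are not.
* The behavioral simulation and the sensor components are decoupled
  (components follow condition, not simulated reports), so
  behaviorally-constrained decoding subsets change statistical power only.
* The separability statistic is reported unweighted when m ≠ n (simple
  average of the two within-image means); a pair-count-weighted variant
  would differ for unbalanced designs.
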