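# mooneyrsa

Dynamical neural-pattern analysis of prior-guided visual disambiguation.

A Mooney image — a two-tone, degraded photograph — is usually unrecognizable
until the matching grayscale original has been seen once; afterwards the
identical degraded input is recognized instantly and lastingly. Because the
stimulus is constant while perception flips, the paradigm isolates how a
perceptual prior reshapes neural processing. `mooneyrsa` implements the full
multivariate analysis chain for this paradigm on sensor-level
neurophysiological recordings (MEG-style epochs) and ROI-level fMRI
activation patterns, together with a synthetic experiment generator so that
every stage runs and is tested end to end without any data download.

It is aimed at cognitive-neuroimaging researchers who want a tested,
scriptable reference implementation of these analyses:

* **Design & behavior** — the interleaved pre/post-disambiguation trial
  scheduler (33 real + 6 catch image sets, 14 runs, 15-trial blocks), a
  behavioral simulator with the bimodal recognition-count structure, and the
  "recognized ≥ 4 / not-recognized ≤ 2 of 6" selection rule
  (`build_design()`, `simulate_behavior()`, `select_disambiguated_sets()`).
* **Simulation** — sensor epochs with planted evoked, stimulus, class,
  recognition, and attention components riding on white noise, and ROI
  activation patterns sharing the same latent image-level geometry
  (`make_ground_truth()`, `simulate_sensor_epochs()`,
  `simulate_roi_patterns()`).
* **Preprocessing** — zero-phase Butterworth band filtering with decimation
  (slow cortical potentials 0.05–5 Hz @ 10 Hz; event-related field band
  DC–35 Hz @ 100 Hz), epoching with baseline correction, and per-sample
  z-scoring across sensors.
* **Decoding** — time-resolved linear SVM decoding of perceptual state with
  balanced accuracy under deterministic odd–even image folds, activation
  pattern transforms, and temporal generalization matrices.
* **RSA** — time-resolved 99 × 99 representational dissimilarity matrices
  under `1 - r`, squared Euclidean, cross-validated Euclidean (the noise
  contribution cancels across folds), and a single-trial separability
  statistic `r_within - r_between` computed in Fisher-z space; condition
  block algebra, across-image dissimilarity curves, and intra-RDM geometry
  correlations.
* **Models & fusion** — the stimulus / recognition / attention model RDMs
  with entries {0, 0.5, 1, NA}, model-based RSA, and model-driven
  sensor–fMRI fusion by commonality analysis over rank-transformed RDM
  vectors: shared variance `R²(f) + R²(m) − R²(f,m)` and model-unique
  variance `R²(f,m2) + R²(m1,m2) − R²(m2) − R²(f,m1,m2)`.
* **Inference** — cluster-based permutation tests (exact one-sample Wilcoxon
  signed-rank W summed over clusters against a sign-flip max-cluster null;
  1-D time courses and 2-D generalization matrices), entry-order permutation
  nulls for RDM statistics, and Benjamini–Hochberg FDR masks.

## Worked example

Simulate a six-subject study at the default study conditions, select the
behaviorally disambiguated image sets, decode perceptual state, and compare
the three theoretical models against the time-resolved RDMs:

```r
library(mooneyrsa)
library(dplyr)

design <- build_design(n_real_sets = 33, n_catch_sets = 6, n_runs = 14, seed = 1)
behavior <- simulate_behavior(design, seed = 1)
sel <- select_disambiguated_sets(behavior, "subjective")
length(sel)
#> [1] 16

gt <- make_ground_truth(design, n_sensors = 32, seed = 1)
epochs <- simulate_sensor_epochs(design, gt, n_subjects = 6,
                                 sampling_rate = 50, seed = 1) |>
  normalize_across_sensors()
epochs
#> <sensor_epochs> 6 subject(s), 585 trials, 32 sensors, 176 samples
#>   (-0.50..3.00 s @ 50 Hz, band raw, normalized)

dec <- decode_timecourse(epochs, image_subset = sel)
glance(dec)
#> # A tibble: 1 × 5
#>   mean_accuracy peak_accuracy peak_time n_subjects n_times
#>           <dbl>         <dbl>     <dbl>      <int>   <int>
#> 1         0.585             1      0.46          6     176

rdms <- rdm_series(epochs, metric = "one_minus_r")
grp <- rdm_group_average(rdms)
for (kind in c("stimulus", "attention", "recognition")) {
  tc <- model_rsa_timecourse(grp,
    build_model_rdm(kind, 33, image_ids = rdms$image_ids)) |> filter(time > 0)
  cat(sprintf("%-12s peak rho %.2f at %.2f s\n",
              kind, max(tc$rho), tc$time[which.max(tc$rho)]))
}
#> stimulus     peak rho 0.44 at 0.20 s
#> attention    peak rho 0.74 at 0.52 s
#> recognition  peak rho 0.20 at 0.98 s
```

The numbers show the signature dynamics the package is built around: 16 of
33 image sets meet the behavioral disambiguation criterion; decoding of
perceptual state peaks where the condition-level attention component is
active (0.46 s; image-specific components do not generalize across the
image folds, so the long ramp of recognition activity does not itself drive
state decoding); and the model correlations peak in the order stimulus
(0.20 s) → attention (0.52 s) → recognition (late), the early-to-late
progression from stimulus-feature coding to recognition-content coding.
`separability_rdm_series()`, `fusion_map()` and the `cluster_*` functions
continue the chain; `run_pipeline(run_config(...))` executes all stages and
writes tidy result tables plus a JSON summary. `autoplot()` methods exist
for decoding results, RDM slices, model RDMs, generalization matrices, and
fusion maps.

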