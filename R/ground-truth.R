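#' Planted component structure for the synthetic generator
#'
#' Defines the latent structure the sensor simulator plants into epochs:
#'
#' * an image-specific **stimulus** component, shared by a Mooney image across
#'   the pre- and post-disambiguation stages and active early (Gaussian bump
#'   at 200 ms, sd 80 ms, plus an optional smaller second bump at 1.35 s);
#'   grayscale images carry their own stimulus components;
#' * a **class** component separating gross Mooney vs. grayscale image
#'   statistics, sharing the stimulus envelope;
#' * an image-specific **recognition** component, shared between a
#'   post-disambiguation Mooney image and its matching grayscale image and
#'   active late (logistic ramp, midpoint 600 ms); catch-set Mooney images get
#'   no recognition component and their non-matching grayscale images carry
#'   their own;
#' * a condition-level **attention** component present in recognized
#'   conditions (post-disambiguation Mooney and grayscale), peaking at an
#'   intermediate latency (Gaussian bump at 500 ms, sd 100 ms);
#' * a shared **evoked** response common to every trial.
#'
#' Image-specific components are generated from latent feature vectors:
#' each image draws a unit-norm vector in a `latent_dim`-dimensional feature
#' space per component type, and the sensor pattern is that vector pushed
#' through a random orthonormal map into sensor space. The image-by-image
#' similarity structure (the representational geometry) therefore lives in
#' the latent space, and [simulate_roi_patterns()] pushes the *same* latent
#' vectors through ROI-specific maps — so sensor and ROI data share
#' image-level geometry, as neural data from one brain does across
#' modalities. Condition-level component patterns (evoked, attention, class)
#' are independent draws on the unit sphere, mutually near-orthogonal in
#' expectation.
#'
#' @param design a [build_design()] schedule (supplies set ids and types).
#' @param n_sensors number of sensors; must exceed the component count.
#' @param amplitudes named list of component amplitudes: `evoked`, `stimulus`,
#'   `class`, `recognition`, `attention`.
#' @param noise_sd standard deviation of i.i.d. Gaussian sensor noise added
#'   per trial, sensor, and sample.
#' @param stim_second_bump relative amplitude of the late second stimulus
#'   bump at 1.35 s (0 disables it).
#' @param latent_dim dimension of the latent feature space generating
#'   image-specific geometry (must be <= `n_sensors`).
#' @param seed integer seed for the component pattern draws.
#' @return An object of class `mooney_ground_truth`: component patterns,
#'   envelope functions of peristimulus time, amplitudes, and noise scale.
#' @export
make_ground_truth <- function(design, n_sensors = 40,
                              amplitudes = list(
                                evoked = 1, stimulus = 1, class = 0.6,
                                recognition = 1, attention = 0.8
                              ),
                              noise_sd = 0.25,
                              stim_second_bump = 0.5,
                              latent_dim = 8,
                              seed = 1) {
  sets <- attr(design, "sets")
  stopifnot(n_sensors >= 6, latent_dim <= n_sensors)

  with_seed(seed, {
    # latent image geometries: unit columns in feature space, one per set
    latent <- lapply(
      c(stim_mooney = 1, stim_gray = 2, recognition = 3,
        recognition_catch_gray = 4),
      function(...) unit_cols(latent_dim, nrow(sets), sets$set_id)
    )
    qmap <- orthonormal_map(n_sensors, latent_dim)
    patterns <- c(
      list(
        evoked = unit_cols(n_sensors, 1)[, 1],
        attention = unit_cols(n_sensors, 1)[, 1],
        class_mooney = unit_cols(n_sensors, 1)[, 1],
        class_gray = unit_cols(n_sensors, 1)[, 1]
      ),
      lapply(latent, function(z) qmap %*% z)
    )
  })

  envelopes <- list(
    evoked = function(t) {
      exp(-(t - 0.15)^2 / (2 * 0.08^2)) +
        0.4 * stats::plogis(t / 0.05) * stats::plogis((2 - t) / 0.05)
    },
    stimulus = function(t) {
      (t > 0) * (exp(-(t - 0.2)^2 / (2 * 0.08^2)) +
        stim_second_bump * exp(-(t - 1.35)^2 / (2 * 0.1^2)))
    },
    recognition = function(t) (t > 0) * stats::plogis((t - 0.6) / 0.1),
    attention = function(t) (t > 0) * exp(-(t - 0.5)^2 / (2 * 0.1^2))
  )

  structure(
    list(
      sets = sets, n_sensors = n_sensors, patterns = patterns,
      latent = latent, latent_dim = latent_dim, envelopes = envelopes,
      amplitudes = amplitudes, noise_sd = noise_sd, seed = seed
    ),
    class = "mooney_ground_truth"
  )
}

# columns of unit norm, optionally named
unit_cols <- function(nr, nc, names = NULL) {
  m <- matrix(rnorm(nr * nc), nr, nc)
  m <- sweep(m, 2, sqrt(colSums(m^2)), "/")
  colnames(m) <- names
  m
}

# random map with orthonormal columns (norm- and geometry-preserving)
orthonormal_map <- function(nr, nc) {
  qr.Q(qr(matrix(rnorm(nr * nc), nr, nc)))[, seq_len(nc), drop = FALSE]
}

# Noise-free sensors x time signal for one trial type, on time grid `times`.
# Component membership depends only on (set, image_type, stage, set_type).
trial_signal <- function(gt, set_id, image_type, stage, set_type, times) {
  a <- gt$amplitudes
  env <- lapply(gt$envelopes, function(f) f(times))
  p <- gt$patterns
  m <- a$evoked * outer(p$evoked, env$evoked)
  if (image_type == "grayscale") {
    m <- m + a$stimulus * outer(p$stim_gray[, set_id], env$stimulus) +
      a$class * outer(p$class_gray, env$stimulus)
    recog <- if (set_type == "real") p$recognition[, set_id] else
      p$recognition_catch_gray[, set_id]
    m <- m + a$recognition * outer(recog, env$recognition) +
      a$attention * outer(p$attention, env$attention)
  } else {
    m <- m + a$stimulus * outer(p$stim_mooney[, set_id], env$stimulus) +
      a$class * outer(p$class_mooney, env$stimulus)
    if (identical(stage, "post") && set_type == "real") {
      m <- m + a$recognition * outer(p$recognition[, set_id], env$recognition) +
        a$attention * outer(p$attention, env$attention)
    }
  }
  m
}

#' Simulate epoched sensor data with planted components
#'
#' Generates sensor epochs for one or more subjects from a trial schedule and
#' a ground-truth component specification. Every trial is the sum of the
#' shared evoked response, its condition-appropriate image-specific and
#' condition-level components weighted by their time envelopes, and white
#' Gaussian sensor noise. Component patterns are shared across subjects (a
#' common representational geometry); noise is drawn independently per subject
#' from seeds split off the master seed.
#'
#' @param design a [build_design()] schedule.
#' @param ground_truth a [make_ground_truth()] object.
#' @param n_subjects number of simulated subjects.
#' @param sampling_rate sampling rate of the epoch grid in Hz.
#' @param tmin,tmax epoch limits in seconds relative to stimulus onset.
#' @param seed master integer seed; per-subject noise seeds derive from it.
#' @return A [sensor_epochs()] object.
#' @export
simulate_sensor_epochs <- function(design, ground_truth, n_subjects = 1,
                                   sampling_rate = 100, tmin = -0.5,
                                   tmax = 3.0, seed = 1) {
  gt <- ground_truth
  times <- seq(tmin, tmax, by = 1 / sampling_rate)
  n_time <- length(times)
  n_trials <- nrow(design)

  # one signal matrix per distinct trial type
  types <- design |>
    dplyr::distinct(.data$set_id, .data$image_type, .data$stage, .data$set_type)
  type_key <- function(set_id, image_type, stage) {
    paste(set_id, image_type, ifelse(is.na(stage), "na", stage))
  }
  signals <- purrr::pmap(types, function(set_id, image_type, stage, set_type) {
    trial_signal(gt, set_id, image_type, stage, set_type, times)
  })
  names(signals) <- type_key(types$set_id, types$image_type, types$stage)
  trial_type <- type_key(design$set_id, design$image_type, design$stage)

  base <- array(0, dim = c(n_trials, gt$n_sensors, n_time))
  for (i in seq_len(n_trials)) {
    base[i, , ] <- signals[[trial_type[i]]]
  }

  values <- lapply(seq_len(n_subjects), function(s) {
    if (gt$noise_sd == 0) return(base)
    with_seed(derive_seed(seed, s), {
      base + array(
        rnorm(n_trials * gt$n_sensors * n_time, sd = gt$noise_sd),
        dim = dim(base)
      )
    })
  })

  sensor_epochs(
    values = values, times = times, sampling_rate = sampling_rate,
    events = design, band = "raw"
  )
}

#' Simulate a continuous multichannel recording
#'
#' Concatenates the schedule's trials into one continuous sensors-by-samples
#' recording, with each trial's planted signal placed at its onset and
#' pre/post padding so that all epochs fit inside the recording. Used to
#' exercise the filtering and epoching stages end to end.
#'
#' @inheritParams simulate_sensor_epochs
#' @param iti inter-onset interval in seconds (must exceed the epoch length).
#' @param pad leading/trailing padding in seconds.
#' @return A list of class `continuous_recording`: `values` (sensors x
#'   samples matrix), `sampling_rate`, `times`, `onsets` (onset times in
#'   seconds, one per trial), and `events` (the design tibble).
#' @export
simulate_continuous_recording <- function(design, ground_truth,
                                          sampling_rate = 100, iti = 4,
                                          pad = 1, seed = 1) {
  gt <- ground_truth
  n_trials <- nrow(design)
  onsets <- pad + 0.5 + iti * (seq_len(n_trials) - 1)
  total <- pad + 0.5 + iti * n_trials + 3.0 + pad
  n_samp <- ceiling(total * sampling_rate)
  times <- (seq_len(n_samp) - 1) / sampling_rate

  values <- matrix(0, nrow = gt$n_sensors, ncol = n_samp)
  grid <- seq(-0.5, 3.0, by = 1 / sampling_rate)
  for (i in seq_len(n_trials)) {
    sig <- trial_signal(
      gt, design$set_id[i], design$image_type[i], design$stage[i],
      design$set_type[i], grid
    )
    j0 <- round((onsets[i] - 0.5) * sampling_rate) + 1L
    idx <- j0:(j0 + length(grid) - 1L)
    values[, idx] <- values[, idx] + sig
  }
  if (gt$noise_sd > 0) {
    with_seed(derive_seed(seed, 0L), {
      values <- values + matrix(rnorm(length(values), sd = gt$noise_sd),
        nrow = nrow(values)
      )
    })
  }
  structure(
    list(
      values = values, sampling_rate = sampling_rate, times = times,
      onsets = onsets, events = design
    ),
    class = "continuous_recording"
  )
}

#' Default ROI mixing profiles
#'
#' Four synthetic regions spanning the cortical hierarchy: a stimulus-
#' dominated early visual region, a mixed object-selective region, a
#' recognition-dominated frontal region, and an attention-dominated parietal
#' region. Weights are the non-negative mixing coefficients of the stimulus,
#' recognition, and attention components in that region's activation
#' patterns.
#'
#' @return A tibble with columns `roi`, `w_stimulus`, `w_recognition`,
#'   `w_attention`.
#' @export
make_roi_profiles <- function() {
  tibble::tibble(
    roi = c("V1", "LOC", "Frontal", "Parietal"),
    w_stimulus = c(1, 0.7, 0.05, 0.05),
    w_recognition = c(0.1, 0.45, 1, 0.3),
    w_attention = c(0.05, 0.2, 0.4, 1)
  )
}

#' Simulate ROI activation patterns
#'
#' Builds, for each region profile, one activation pattern per (condition,
#' image) cell of the 33-real-set design — 99 feature vectors per ROI —
#' mixing the same image-specific stimulus/recognition and condition-level
#' attention structure planted in the sensor simulator, plus i.i.d. Gaussian
#' noise. Image-specific components are the ground truth's *latent* feature
#' vectors pushed through an ROI-specific orthonormal map into voxel space,
#' so each ROI shares the planted image-level representational geometry with
#' the sensor data (weighted by its profile) while having its own basis.
#' Stands in for GLM activation patterns of an fMRI session; it is
#' synthetic, with no hemodynamics.
#'
#' @param ground_truth a [make_ground_truth()] object (supplies set ids).
#' @param roi_profiles tibble as from [make_roi_profiles()].
#' @param n_voxels feature dimension per ROI (>= 2).
#' @param noise_sd feature noise standard deviation.
#' @param class_weight relative weight of the Mooney/grayscale class component
#'   inside the stimulus term.
#' @param common_weight weight of the region-level mean activation pattern
#'   shared by every entry (the fMRI analog of the shared evoked response;
#'   it makes unrecognized-image patterns mutually similar rather than pure
#'   noise).
#' @param seed integer seed.
#' @return Object of class `roi_patterns`: a named list of 99 x `n_voxels`
#'   matrices (rows labelled in the fixed Pre/Post/Gray block order) plus the
#'   profile table.
#' @export
simulate_roi_patterns <- function(ground_truth, roi_profiles = make_roi_profiles(),
                                  n_voxels = 60, noise_sd = 0.1,
                                  class_weight = 0.6, common_weight = 1,
                                  seed = 1) {
  stopifnot(n_voxels >= 2, all(
    roi_profiles$w_stimulus >= 0, roi_profiles$w_recognition >= 0,
    roi_profiles$w_attention >= 0
  ))
  sets <- ground_truth$sets
  real <- sets$set_id[sets$set_type == "real"]
  n <- length(real)
  labels <- rdm_labels(real)
  stopifnot(n_voxels >= ground_truth$latent_dim)

  rois <- purrr::pmap(roi_profiles, function(roi, w_stimulus, w_recognition,
                                             w_attention) {
    with_seed(derive_seed(seed, match(roi, roi_profiles$roi)), {
      bmap <- orthonormal_map(n_voxels, ground_truth$latent_dim)
      vstim <- bmap %*% ground_truth$latent$stim_mooney[, real, drop = FALSE]
      vgstim <- bmap %*% ground_truth$latent$stim_gray[, real, drop = FALSE]
      vrecog <- bmap %*% ground_truth$latent$recognition[, real, drop = FALSE]
      vatt <- unit_cols(n_voxels, 1)[, 1]
      vclass_m <- unit_cols(n_voxels, 1)[, 1]
      vclass_g <- unit_cols(n_voxels, 1)[, 1]
      vcommon <- common_weight * unit_cols(n_voxels, 1)[, 1]
      pat <- matrix(0, nrow = 3 * n, ncol = n_voxels,
        dimnames = list(labels, NULL)
      )
      for (i in seq_len(n)) {
        pre <- vcommon + w_stimulus * (vstim[, i] + class_weight * vclass_m)
        post <- pre + w_recognition * vrecog[, i] + w_attention * vatt
        gray <- vcommon + w_stimulus * (vgstim[, i] + class_weight * vclass_g) +
          w_recognition * vrecog[, i] + w_attention * vatt
        pat[i, ] <- pre
        pat[n + i, ] <- post
        pat[2 * n + i, ] <- gray
      }
      pat + matrix(rnorm(length(pat), sd = noise_sd), nrow = nrow(pat))
    })
  })
  names(rois) <- roi_profiles$roi
  structure(
    list(patterns = rois, profiles = roi_profiles, image_ids = real),
    class = "roi_patterns"
  )
}
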