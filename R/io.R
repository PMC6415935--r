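#' Save sensor epochs to a directory
#'
#' Writes a plain-text container: `meta.json` (named axes, sampling rate,
#' band, normalization flag), `events.tsv` (tab-separated events table), and
#' one `values_s<k>.txt` file per subject holding the flattened array at full
#' precision (`%.17g`, lossless for doubles).
#'
#' @param epochs a [sensor_epochs()] object.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_epochs <- function(epochs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    dims = dim(epochs$values[[1]]),
    n_subjects = length(epochs$values),
    times = sprintf("%.17g", epochs$times),
    sampling_rate = epochs$sampling_rate,
    band = epochs$band,
    normalized = epochs$normalized
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  utils::write.table(epochs$events, file.path(path, "events.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  for (s in seq_along(epochs$values)) {
    writeLines(
      sprintf("%.17g", as.vector(epochs$values[[s]])),
      file.path(path, sprintf("values_s%02d.txt", s))
    )
  }
  invisible(path)
}

#' Load sensor epochs saved by [save_epochs()]
#'
#' @param path directory written by [save_epochs()].
#' @return A [sensor_epochs()] object, bit-identical to the one saved.
#' @export
load_epochs <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) abort("missing container metadata ('meta.json')")
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  ev_file <- file.path(path, "events.tsv")
  if (!file.exists(ev_file)) {
    abort("missing events table ('events.tsv') in epochs container")
  }
  events <- tibble::as_tibble(utils::read.table(ev_file,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE
  ))
  values <- lapply(seq_len(meta$n_subjects), function(s) {
    v <- as.numeric(readLines(file.path(path, sprintf("values_s%02d.txt", s))))
    array(v, dim = meta$dims)
  })
  sensor_epochs(
    values = values, times = as.numeric(meta$times),
    sampling_rate = meta$sampling_rate, events = events, band = meta$band,
    normalized = meta$normalized
  )
}

#' Pipeline run configuration
#'
#' Bundles every parameter of a full synthetic analysis run. All stochastic
#' stages derive their seeds from the single `seed`. Defaults reproduce the
#' reference study conditions (33 real + 6 catch sets, 14 runs, 18 subjects);
#' scale `n_subjects`, `n_sensors`, `sampling_rate` and the permutation
#' counts down for quick runs.
#'
#' @param n_real_sets,n_catch_sets,n_runs design parameters.
#' @param n_subjects,n_sensors,sampling_rate generator parameters.
#' @param noise_sd sensor noise level.
#' @param p_spontaneous,p_post_recognize behavioral rates.
#' @param cost decoder cost.
#' @param n_perm_decoding,n_perm_contrast,n_perm_model permutation counts for
#'   decoding cluster tests, RDM condition contrasts, and model RSA/fusion.
#' @param run_fusion logical; include ROI simulation and fusion.
#' @param seed master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_real_sets = 33, n_catch_sets = 6, n_runs = 14,
                       n_subjects = 18, n_sensors = 40, sampling_rate = 100,
                       noise_sd = 0.25, p_spontaneous = 0.34,
                       p_post_recognize = 0.87, cost = 1,
                       n_perm_decoding = 500, n_perm_contrast = 5000,
                       n_perm_model = 1000, run_fusion = TRUE, seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full synthetic analysis pipeline
#'
#' Chains every stage — design scheduling, behavioral simulation and
#' selection, sensor simulation, normalization, perceptual-state decoding
#' with cluster inference, dissimilarity and separability RDM analyses,
#' model RDMs and model RSA, and (optionally) ROI simulation with
#' commonality-analysis fusion — and writes tidy result tables plus a
#' machine-readable `summary.json` (including the configuration and seeds)
#' to `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with all intermediate results.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("mooney_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed (seed %d): %s",
        name, config$seed, conditionMessage(e)
      ))
    })
  }

  design <- stage("design", build_design(
    config$n_real_sets, config$n_catch_sets, config$n_runs,
    seed = derive_seed(config$seed, 1)
  ))
  behavior <- stage("behavior", simulate_behavior(design,
    p_spontaneous = config$p_spontaneous,
    p_post_recognize = config$p_post_recognize,
    seed = derive_seed(config$seed, 2)
  ))
  subset <- stage("selection", suppressWarnings(
    select_disambiguated_sets(behavior, "subjective")
  ))
  gt <- stage("ground_truth", make_ground_truth(design,
    n_sensors = config$n_sensors, noise_sd = config$noise_sd,
    seed = derive_seed(config$seed, 3)
  ))
  epochs <- stage("simulate", simulate_sensor_epochs(design, gt,
    n_subjects = config$n_subjects, sampling_rate = config$sampling_rate,
    seed = derive_seed(config$seed, 4)
  ))
  epochs <- stage("normalize", normalize_across_sensors(epochs))

  decoding <- stage("decode", decode_timecourse(epochs,
    config = decoder_config(config$cost)
  ))
  decode_cluster <- if (config$n_subjects >= 2) {
    stage("decode_stats", cluster_permutation_timecourse(
      decoding$accuracy, chance = 0.5, n_perm = config$n_perm_decoding,
      seed = derive_seed(config$seed, 5)
    ))
  } else NULL

  rdms <- stage("rsa", rdm_series(epochs, metric = "one_minus_r"))
  dissim <- stage("rsa", within_condition_dissimilarity_timecourse(rdms))
  intra <- stage("rsa", dplyr::bind_rows(
    dplyr::mutate(intra_rdm_correlation(rdms, "pre", "post"), contrast = "stimulus"),
    dplyr::mutate(intra_rdm_correlation(rdms, "post", "gray"), contrast = "recognition")
  ))

  sep <- stage("separability", separability_rdm_series(epochs))
  sep_diag <- stage("separability", cross_condition_diagonal_timecourse(sep))
  sep_offdiag <- stage("separability", offdiagonal_minus_diagonal_timecourse(sep))

  n_img <- length(rdms$image_ids)
  models <- stage("models", list(
    stimulus = build_model_rdm("stimulus", n_img, image_ids = rdms$image_ids),
    recognition = build_model_rdm("recognition", n_img, image_ids = rdms$image_ids),
    attention = build_model_rdm("attention", n_img, image_ids = rdms$image_ids)
  ))
  grp <- rdm_group_average(rdms)
  model_rsa <- stage("models", purrr::imap_dfr(models, function(m, nm) {
    dplyr::mutate(model_rsa_timecourse(grp, m), model = nm, .before = 1)
  }))

  fusion <- NULL
  if (isTRUE(config$run_fusion)) {
    roi <- stage("fusion", simulate_roi_patterns(gt,
      seed = derive_seed(config$seed, 6)
    ))
    fusion <- stage("fusion", fusion_map(grp, roi_rdm(roi),
      models = models, n_perm = min(config$n_perm_model, 200),
      seed = derive_seed(config$seed, 7)
    ))
  }

  # outputs
  utils::write.table(design, file.path(out_dir, "events.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(behavior$recognition, file.path(out_dir, "behavior.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(decoding$accuracy, file.path(out_dir, "decoding_accuracy.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(dissim, file.path(out_dir, "dissimilarity_curves.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(model_rsa, file.path(out_dir, "model_rsa.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  summary <- list(
    config = unclass(config),
    n_runs = attr(design, "n_runs"),
    n_trials = nrow(design),
    n_selected_sets = length(subset),
    mean_accuracy = mean(decoding$accuracy$accuracy),
    n_significant_decoding_clusters =
      if (!is.null(decode_cluster)) sum(decode_cluster$significant) else NA,
    peak_model_rho = model_rsa |>
      dplyr::group_by(.data$model) |>
      dplyr::summarise(
        peak_rho = max(.data$rho), peak_time = .data$time[which.max(.data$rho)]
      ) |>
      as.list()
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )

  invisible(list(
    design = design, behavior = behavior, selected = subset, epochs = epochs,
    decoding = decoding, decode_cluster = decode_cluster, rdms = rdms,
    dissimilarity = dissim, intra_rdm = intra, separability_diag = sep_diag,
    separability_offdiag = sep_offdiag, models = models,
    model_rsa = model_rsa, fusion = fusion, summary = summary,
    out_dir = out_dir
  ))
}
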