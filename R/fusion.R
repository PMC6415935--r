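#' ROI representational dissimilarity matrices
#'
#' One symmetric 1 - Pearson-r matrix per region, computed across that
#' region's features (voxels) between the activation patterns of every
#' (condition, image) entry, in the same fixed label order as the sensor RDM
#' series. Main diagonal is `NA`.
#'
#' @param roi_patterns a [simulate_roi_patterns()] object, or a named list of
#'   entries x features matrices.
#' @return Named list of square matrices.
#' @export
roi_rdm <- function(roi_patterns) {
  pats <- if (inherits(roi_patterns, "roi_patterns")) roi_patterns$patterns else roi_patterns
  lapply(pats, function(p) {
    if (any(apply(p, 1, sd) == 0)) {
      abort("zero-variance activation pattern: 1 - r is undefined")
    }
    m <- 1 - cor(t(p))
    diag(m) <- NA_real_
    m
  })
}

# Upper-triangle support shared by a set of matrices (positions that are
# non-missing in every one of them).
shared_support <- function(...) {
  mats <- list(...)
  ok <- upper.tri(mats[[1]])
  for (m in mats) ok <- ok & !is.na(m)
  which(ok)
}

rank_vec <- function(x) rank(x, ties.method = "average")

# R^2 of y regressed on the columns of X (with intercept). Rank-deficient
# predictor sets are handled by QR pivoting (pseudoinverse convention) with a
# warning.
r_squared <- function(y, X) {
  X <- cbind(1, X)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    warn("rank-deficient predictor set: R^2 computed on the column space")
  }
  res <- qr.resid(qrx, y)
  yc <- y - mean(y)
  1 - sum(res^2) / sum(yc^2)
}

#' Model correlation time course (model-based RSA)
#'
#' Per time point, the Spearman correlation between the upper-triangle
#' entries of a group-averaged sensor RDM and a theoretical model RDM,
#' excluding cells the model marks `NA`.
#'
#' @param rs an [rdm_series()] (averaged across subjects first if needed).
#' @param model a [build_model_rdm()] matrix.
#' @return Tibble with columns `time`, `rho`.
#' @export
model_rsa_timecourse <- function(rs, model) {
  rs <- rdm_group_average(rs)
  arr <- rs$values[[1]]
  support <- shared_support(arr[, , 1], model)
  if (length(support) < 3) abort("fewer than 3 usable RDM cells")
  mv <- rank_vec(model[support])
  rho <- vapply(seq_along(rs$times), function(t) {
    slab <- arr[, , t]
    cor(rank_vec(slab[support]), mv)
  }, numeric(1))
  tibble::tibble(time = rs$times, rho = rho)
}

commonality_r2_sets <- function(type = c("shared", "unique")) {
  type <- match.arg(type)
  if (type == "shared") {
    list(
      r2_fmri = "f", r2_m1 = "m1", r2_fmri_m1 = c("f", "m1")
    )
  } else {
    list(
      r2_fmri_m2 = c("f", "m2"), r2_m1_m2 = c("m1", "m2"),
      r2_m2 = "m2", r2_fmri_m1_m2 = c("f", "m1", "m2")
    )
  }
}

commonality_terms <- function(meg, fmri, m1, m2 = NULL,
                              type = c("shared", "unique"),
                              rank_transform = TRUE, support = NULL) {
  type <- match.arg(type)
  mats <- c(list(meg, fmri, m1), if (!is.null(m2)) list(m2))
  support <- support %||% do.call(shared_support, mats)
  if (length(support) < 4) abort("fewer than 4 usable RDM cells")
  tf <- if (rank_transform) rank_vec else identity
  y <- tf(meg[support])
  pred <- list(f = tf(fmri[support]), m1 = tf(m1[support]))
  if (!is.null(m2)) pred$m2 <- tf(m2[support])
  sets <- commonality_r2_sets(type)
  r2 <- vapply(sets, function(nm) {
    r_squared(y, do.call(cbind, pred[nm]))
  }, numeric(1))
  C <- if (type == "shared") {
    r2[["r2_fmri"]] + r2[["r2_m1"]] - r2[["r2_fmri_m1"]]
  } else {
    r2[["r2_fmri_m2"]] + r2[["r2_m1_m2"]] - r2[["r2_m2"]] - r2[["r2_fmri_m1_m2"]]
  }
  structure(
    list(r2 = as.list(r2), commonality = C, type = type,
      n_cells = length(support)
    ),
    class = "commonality_terms"
  )
}

#' Shared variance between sensor RDM, ROI RDM, and one model
#'
#' Commonality analysis: the variance of the sensor (MEG) RDM vector shared
#' with both the fMRI ROI RDM and the model, computed as
#' `C = R2(MEG ~ fMRI) + R2(MEG ~ M1) - R2(MEG ~ fMRI + M1)`. All vectors are
#' rank-transformed first (average ranks for ties), so single-predictor R2
#' equals squared Spearman rho; set `rank_transform = FALSE` for raw values.
#' Cells missing in any involved matrix are excluded listwise.
#'
#' @param meg_rdm square sensor RDM (one time slice).
#' @param fmri_rdm square ROI RDM.
#' @param model a [build_model_rdm()] matrix.
#' @param rank_transform logical.
#' @return A `commonality_terms` object: the R2 terms, `commonality`,
#'   and the cell count. Negative commonalities are possible (suppression)
#'   and are not clipped.
#' @export
commonality_shared <- function(meg_rdm, fmri_rdm, model, rank_transform = TRUE) {
  commonality_terms(meg_rdm, fmri_rdm, model,
    type = "shared", rank_transform = rank_transform
  )
}

#' Model-unique shared variance between sensor and ROI RDMs
#'
#' The part of the MEG-fMRI shared variance attributable to model `m1` but
#' not to a competing model `m2`:
#' `C = R2(MEG ~ fMRI + M2) + R2(MEG ~ M1 + M2) - R2(MEG ~ M2) -
#' R2(MEG ~ fMRI + M1 + M2)`.
#'
#' @inheritParams commonality_shared
#' @param m1 model of interest.
#' @param m2 competing model whose contribution is partialled out.
#' @return A `commonality_terms` object.
#' @export
commonality_unique <- function(meg_rdm, fmri_rdm, m1, m2, rank_transform = TRUE) {
  commonality_terms(meg_rdm, fmri_rdm, m1, m2 = m2,
    type = "unique", rank_transform = rank_transform
  )
}

# Fast commonality time course: the predictor-set projections are fixed
# across time, so they are QR-factorized once on the shared support.
commonality_timecourse <- function(meg_arr, fmri_rdm, m1, m2 = NULL,
                                   type = c("shared", "unique"),
                                   support = NULL) {
  type <- match.arg(type)
  mats <- c(list(meg_arr[, , 1], fmri_rdm, m1), if (!is.null(m2)) list(m2))
  support <- support %||% do.call(shared_support, mats)
  pred <- list(f = rank_vec(fmri_rdm[support]), m1 = rank_vec(m1[support]))
  if (!is.null(m2)) pred$m2 <- rank_vec(m2[support])
  sets <- commonality_r2_sets(type)
  qs <- lapply(sets, function(nm) {
    X <- cbind(1, do.call(cbind, pred[nm]))
    qr.Q(qr(X))
  })
  nt <- dim(meg_arr)[3]
  vapply(seq_len(nt), function(t) {
    y <- rank_vec(meg_arr[, , t][support])
    yc <- y - mean(y)
    tss <- sum(yc^2)
    r2 <- vapply(qs, function(q) {
      v <- crossprod(q, yc)
      sum(v^2) / tss
    }, numeric(1))
    if (type == "shared") {
      r2[[1]] + r2[[2]] - r2[[3]]
    } else {
      r2[[1]] + r2[[2]] - r2[[3]] - r2[[4]]
    }
  }, numeric(1))
}

#' Upper bound on model-explained MEG-fMRI shared variance
#'
#' Per time point, the squared Spearman correlation between the
#' group-averaged sensor RDM and an ROI RDM. No model can account for more
#' MEG-fMRI shared variance than this bound.
#'
#' @param rs a group-averaged [rdm_series()].
#' @param roi_rdm_matrix one ROI's square RDM.
#' @return Tibble with columns `time`, `bound`.
#' @export
fusion_upper_bound <- function(rs, roi_rdm_matrix) {
  rs <- rdm_group_average(rs)
  arr <- rs$values[[1]]
  support <- shared_support(arr[, , 1], roi_rdm_matrix)
  fv <- rank_vec(roi_rdm_matrix[support])
  bound <- vapply(seq_along(rs$times), function(t) {
    cor(rank_vec(arr[, , t][support]), fv)^2
  }, numeric(1))
  tibble::tibble(time = rs$times, bound = bound)
}

#' Model-driven sensor-fMRI fusion map
#'
#' For every ROI and time point, computes the commonality between the
#' group-averaged sensor RDM, the ROI's RDM, and each theoretical model:
#' unique commonality for the stimulus and recognition models (each
#' partialling out the other, since their neural correlates overlap in time)
#' and shared commonality for the attention model. Significance is assessed
#' by the entry-order permutation cluster test on each commonality time
#' course, and additionally masked by requiring that both the sensor-model
#' and the ROI-model correlations are significant (the dual-significance
#' rule): the sensor-model correlation via its own cluster test, the
#' ROI-model Spearman correlation via an image-order permutation p-value.
#'
#' @param rs a group-averaged [rdm_series()] (metric `one_minus_r`).
#' @param roi_rdms named list from [roi_rdm()].
#' @param models named list with elements `stimulus`, `recognition`,
#'   `attention` (defaults to [build_model_rdm()] outputs matched to the RDM
#'   size).
#' @param n_perm permutations for every permutation test involved.
#' @param seed integer seed.
#' @return A list of class `fusion_map`: `map` tibble (`roi`, `model`,
#'   `time`, `commonality`, `cluster_significant`, `significant`),
#'   `upper_bound` tibble (`roi`, `time`, `bound`), `meg_model`
#'   (sensor-model rho time courses with cluster masks), and `roi_model`
#'   (ROI-model correlations with permutation p-values).
#' @export
fusion_map <- function(rs, roi_rdms, models = NULL, n_perm = 200, seed = 1) {
  rs <- rdm_group_average(rs)
  n <- length(rs$image_ids)
  if (is.null(models)) {
    models <- list(
      stimulus = build_model_rdm("stimulus", n, image_ids = rs$image_ids),
      recognition = build_model_rdm("recognition", n, image_ids = rs$image_ids),
      attention = build_model_rdm("attention", n, image_ids = rs$image_ids)
    )
  }
  arr <- rs$values[[1]]
  nn <- 3 * n
  nt <- dim(arr)[3]
  arrmat <- matrix(arr, nn * nn, nt)

  # Each statistic lives on a fixed upper-triangle support (cells non-missing
  # in everything it involves); all image-order permutations are shared, and
  # per permutation each support is rank-transformed once across all time
  # points, so the whole family of nulls costs one rank pass per support.
  combos <- purrr::map_dfr(names(models), function(mod) {
    if (mod == "attention") {
      tibble::tibble(model = mod, type = "shared", m2 = NA_character_)
    } else {
      tibble::tibble(
        model = mod, type = "unique",
        m2 = setdiff(c("stimulus", "recognition"), mod)
      )
    }
  })
  model_support <- lapply(models, function(m) shared_support(arr[, , 1], m))
  combo_support <- lapply(seq_len(nrow(combos)), function(k) {
    ms <- c(list(arr[, , 1], models[[combos$model[k]]]),
      if (!is.na(combos$m2[k])) list(models[[combos$m2[k]]])
    )
    do.call(shared_support, ms)
  })
  supports <- unique(c(model_support, combo_support))
  sup_of_model <- vapply(model_support, function(s) {
    which(vapply(supports, identical, logical(1), s))
  }, integer(1))
  sup_of_combo <- vapply(combo_support, function(s) {
    which(vapply(supports, identical, logical(1), s))
  }, integer(1))
  sup_rc <- lapply(supports, function(s) {
    cbind(row = (s - 1L) %% nn + 1L, col = (s - 1L) %/% nn + 1L)
  })

  # fixed projections per (roi, combo) and model rank vectors per support
  model_rank <- lapply(seq_along(models), function(j) {
    v <- rank_vec(models[[j]][supports[[sup_of_model[j]]]])
    v - mean(v)
  })
  names(model_rank) <- names(models)
  proj <- list()
  for (roi in names(roi_rdms)) {
    for (k in seq_len(nrow(combos))) {
      s <- supports[[sup_of_combo[k]]]
      pred <- list(
        f = rank_vec(roi_rdms[[roi]][s]),
        m1 = rank_vec(models[[combos$model[k]]][s])
      )
      if (!is.na(combos$m2[k])) pred$m2 <- rank_vec(models[[combos$m2[k]]][s])
      sets <- commonality_r2_sets(combos$type[k])
      proj[[paste(roi, k)]] <- lapply(sets, function(nm) {
        qr.Q(qr(cbind(1, do.call(cbind, pred[nm]))))
      })
    }
  }

  eval_stats <- function(idx) {
    # rank-transformed, centered support matrices for this image order
    rmats <- lapply(seq_along(supports), function(si) {
      rc <- sup_rc[[si]]
      src <- (idx[rc[, "col"]] - 1L) * nn + idx[rc[, "row"]]
      y <- apply(arrmat[src, , drop = FALSE], 2, rank)
      sweep(y, 2, colMeans(y))
    })
    ss <- lapply(rmats, function(m) colSums(m^2))
    rho <- lapply(seq_along(models), function(j) {
      mv <- model_rank[[j]]
      rm <- rmats[[sup_of_model[j]]]
      as.vector(crossprod(rm, mv)) / sqrt(ss[[sup_of_model[j]]] * sum(mv^2))
    })
    names(rho) <- names(models)
    comm <- list()
    for (roi in names(roi_rdms)) {
      for (k in seq_len(nrow(combos))) {
        rm <- rmats[[sup_of_combo[k]]]
        tss <- ss[[sup_of_combo[k]]]
        r2 <- vapply(proj[[paste(roi, k)]], function(q) {
          colSums(crossprod(q, rm)^2) / tss
        }, numeric(nt))
        r2 <- matrix(r2, nrow = nt)
        comm[[paste(roi, k)]] <- if (combos$type[k] == "shared") {
          r2[, 1] + r2[, 2] - r2[, 3]
        } else {
          r2[, 1] + r2[, 2] - r2[, 3] - r2[, 4]
        }
      }
    }
    list(rho = rho, comm = comm)
  }

  obs <- eval_stats(seq_len(nn))
  perms <- with_seed(seed, {
    lapply(seq_len(n_perm), function(b) eval_stats(sample(nn)))
  })

  meg_model <- purrr::imap(models, function(m, name) {
    null <- do.call(rbind, lapply(perms, function(pp) pp$rho[[name]]))
    cl <- cluster_from_null(obs$rho[[name]], null)
    list(rho = obs$rho[[name]], mask = cl$mask, clusters = cl$clusters)
  })

  # ROI-model correlation significance (image-order permutation p)
  roi_model <- purrr::map_dfr(names(roi_rdms), function(roi) {
    purrr::map_dfr(names(models), function(mod) {
      m <- models[[mod]]
      rmat <- roi_rdms[[roi]]
      support <- shared_support(rmat, m)
      mv <- rank_vec(m[support])
      obs_r <- cor(rank_vec(rmat[support]), mv)
      null <- with_seed(
        derive_seed(seed, 100 + match(roi, names(roi_rdms)) * 7 +
          match(mod, names(models))),
        vapply(seq_len(n_perm), function(b) {
          idx <- sample(nrow(rmat))
          pm <- rmat[idx, idx]
          cor(rank_vec(pm[support]), mv)
        }, numeric(1))
      )
      tibble::tibble(
        roi = roi, model = mod, rho = obs_r,
        p = (1 + sum(null >= obs_r)) / (n_perm + 1)
      )
    })
  })

  map <- purrr::map_dfr(names(roi_rdms), function(roi) {
    purrr::map_dfr(seq_len(nrow(combos)), function(k) {
      mod <- combos$model[k]
      key <- paste(roi, k)
      null <- do.call(rbind, lapply(perms, function(pp) pp$comm[[key]]))
      cl <- cluster_from_null(obs$comm[[key]], null)
      dual <- meg_model[[mod]]$mask &
        (roi_model$p[roi_model$roi == roi & roi_model$model == mod] < 0.05)
      tibble::tibble(
        roi = roi, model = mod, time = rs$times,
        commonality = obs$comm[[key]],
        cluster_significant = cl$mask,
        significant = cl$mask & dual
      )
    })
  })

  upper_bound <- purrr::map_dfr(names(roi_rdms), function(roi) {
    dplyr::mutate(fusion_upper_bound(rs, roi_rdms[[roi]]), roi = roi,
      .before = 1
    )
  })

  structure(
    list(
      map = map, upper_bound = upper_bound, meg_model = meg_model,
      roi_model = roi_model, times = rs$times
    ),
    class = "fusion_map"
  )
}
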