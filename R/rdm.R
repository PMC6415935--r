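#' Average the first k presentations of each image in a condition
#'
#' For the correlation and plain-Euclidean RDMs, each image's pattern in a
#' condition is the mean of its first `k` presentations in presentation order
#' (`k = 3` for the Mooney conditions, matching the three grayscale
#' presentations; grayscale images contribute all three).
#'
#' @param epochs a [sensor_epochs()] object.
#' @param condition `"pre"`, `"post"`, or `"gray"`.
#' @param k number of presentations to average.
#' @param subject subject index.
#' @return images x sensors x time array, image ids as first dimnames, in
#'   sorted image-set order (real sets only).
#' @export
average_presentations <- function(epochs, condition, k = 3, subject = 1) {
  rows <- condition_trial_rows(epochs$events, condition)
  ids <- sort(unique(rows$set_id))
  x <- epochs$values[[subject]]
  d <- dim(x)
  out <- array(0, dim = c(length(ids), d[2], d[3]),
    dimnames = list(ids, NULL, NULL)
  )
  for (i in seq_along(ids)) {
    tr <- rows$trial_row[rows$set_id == ids[i]]
    tr <- tr[order(rows$presentation[rows$set_id == ids[i]])]
    if (length(tr) < k) {
      abort(sprintf(
        "image %s has %d presentations in condition %s, need %d",
        ids[i], length(tr), condition, k
      ))
    }
    tr <- tr[seq_len(k)]
    out[i, , ] <- colMeans(x[tr, , , drop = FALSE], dims = 1)
  }
  out
}

# Trial bookkeeping: rows of the events table belonging to one condition
# (real sets only), with their positions in the trial dimension.
condition_trial_rows <- function(events, condition) {
  ev <- dplyr::mutate(events, trial_row = dplyr::row_number())
  if (condition == "gray") {
    ev <- dplyr::filter(ev, .data$image_type == "grayscale", .data$set_type == "real")
  } else {
    ev <- dplyr::filter(
      ev, .data$image_type == "mooney", .data$set_type == "real",
      .data$stage == condition
    )
  }
  if (nrow(ev) == 0) abort(paste0("no trials found for condition ", condition))
  dplyr::select(ev, "set_id", "presentation", "trial_row")
}

# 99 x sensors x time stack of per-image condition patterns, fixed block order.
stack_condition_patterns <- function(epochs, k = 3, subject = 1) {
  parts <- lapply(rdm_conditions(), function(cond) {
    kk <- if (cond == "gray") 3 else k
    average_presentations(epochs, cond, k = kk, subject = subject)
  })
  ids <- dimnames(parts[[1]])[[1]]
  for (p in parts) stopifnot(identical(dimnames(p)[[1]], ids))
  d <- dim(parts[[1]])
  out <- array(0, dim = c(3 * d[1], d[2], d[3]),
    dimnames = list(rdm_labels(ids), NULL, NULL)
  )
  for (j in 1:3) out[(j - 1) * d[1] + seq_len(d[1]), , ] <- parts[[j]]
  out
}

#' Dissimilarity between two sensor patterns
#'
#' Three metrics are supported. `"one_minus_r"` is 1 minus the Pearson
#' correlation across sensors. `"euclidean"` is the squared Euclidean
#' distance, `sum((x - y)^2)`. `"cv_euclidean"` is the cross-validated squared
#' Euclidean distance: trials of each image are split into folds; for fold j
#' the pattern difference computed from fold j is multiplied with the
#' difference computed from the held-out trials, and the products are
#' averaged over folds. Because independent noise in the two partitions is
#' uncorrelated, its contribution cancels in expectation and only the signal
#' shared across partitions remains; unlike the plain metrics the
#' cross-validated distance is therefore unbiased around zero for identical
#' true patterns. Distances are raw sums over sensors, not normalized by
#' sensor count.
#'
#' @param x,y sensor vectors (for `"cv_euclidean"`, the per-image means are
#'   derived from `x_trials`/`y_trials` and `x`/`y` may be omitted).
#' @param metric one of `"one_minus_r"`, `"euclidean"`, `"cv_euclidean"`.
#' @param x_trials,y_trials trials x sensors matrices of the two images'
#'   single trials (required for `"cv_euclidean"`).
#' @param n_folds number of cross-validation folds (trials are assigned to
#'   folds in presentation order).
#' @return A scalar dissimilarity.
#' @export
pattern_distance <- function(x = NULL, y = NULL,
                             metric = c("one_minus_r", "euclidean", "cv_euclidean"),
                             x_trials = NULL, y_trials = NULL, n_folds = 3) {
  metric <- match.arg(metric)
  if (metric == "one_minus_r") {
    if (sd(x) == 0 || sd(y) == 0) {
      abort("zero-variance vector: 1 - r dissimilarity is undefined")
    }
    return(1 - cor(x, y))
  }
  if (metric == "euclidean") {
    return(sum((x - y)^2))
  }
  stopifnot(!is.null(x_trials), !is.null(y_trials))
  fx <- fold_means(x_trials, n_folds)
  fy <- fold_means(y_trials, n_folds)
  d <- 0
  for (j in seq_len(n_folds)) {
    a <- fx$fold[j, ] - fy$fold[j, ]
    b <- fx$rest[j, ] - fy$rest[j, ]
    d <- d + sum(a * b)
  }
  d / n_folds
}

# Per-fold means and held-out means; trials assigned to folds in order.
fold_means <- function(trials, n_folds = 3) {
  m <- nrow(trials)
  if (m < n_folds) {
    abort(sprintf("need at least %d trials for %d folds, got %d", n_folds, n_folds, m))
  }
  # contiguous assignment in presentation order: 6 trials -> (1,1,2,2,3,3)
  fold_of <- sort(rep(seq_len(n_folds), length.out = m))
  fold <- t(vapply(seq_len(n_folds), function(j) {
    colMeans(trials[fold_of == j, , drop = FALSE])
  }, numeric(ncol(trials))))
  total <- colSums(trials)
  nper <- tabulate(fold_of, n_folds)
  rest <- t(vapply(seq_len(n_folds), function(j) {
    (total - colSums(trials[fold_of == j, , drop = FALSE])) / (m - nper[j])
  }, numeric(ncol(trials))))
  list(fold = fold, rest = rest, fold_of = fold_of)
}

#' Time-resolved representational dissimilarity matrices
#'
#' Builds, per subject and time point, the symmetric matrix of pairwise
#' dissimilarities between all (condition, image) entries, in the fixed block
#' order Pre, Post, Gray (a 99 x 99 matrix for the default 33 real image
#' sets). Catch sets are excluded. For `"one_minus_r"` and `"euclidean"` the
#' entries compare per-image averaged patterns ([average_presentations()],
#' first `k` presentations); `"cv_euclidean"` and `"separability"` operate on
#' single trials (all 6 Mooney presentations per stage, all 3 grayscale
#' presentations). The main diagonal is stored as `NA` and excluded from all
#' summaries.
#'
#' @param epochs a normalized [sensor_epochs()] object.
#' @param metric one of `"one_minus_r"`, `"euclidean"`, `"cv_euclidean"`,
#'   `"separability"`.
#' @param k presentations averaged per Mooney entry for the averaged-pattern
#'   metrics.
#' @return An object of class `rdm_series`: `values` is a list (per subject)
#'   of n x n x time arrays with entry labels, plus `times`, `metric`,
#'   `image_ids`.
#' @export
rdm_series <- function(epochs, metric = c("one_minus_r", "euclidean",
                                          "cv_euclidean", "separability"),
                       k = 3) {
  metric <- match.arg(metric)
  for (cond in rdm_conditions()) condition_trial_rows(epochs$events, cond)
  values <- lapply(seq_len(n_subjects(epochs)), function(s) {
    switch(metric,
      one_minus_r = ,
      euclidean = rdm_from_patterns(
        stack_condition_patterns(epochs, k = k, subject = s), metric
      ),
      cv_euclidean = rdm_cv_euclidean(epochs, subject = s),
      separability = rdm_separability(epochs, subject = s)
    )
  })
  ids <- sub("^pre:", "", grep("^pre:", dimnames(values[[1]])[[1]], value = TRUE))
  structure(
    list(
      values = values, times = epochs$times, metric = metric, image_ids = ids
    ),
    class = "rdm_series"
  )
}

#' @export
print.rdm_series <- function(x, ...) {
  d <- dim(x$values[[1]])
  cat(sprintf(
    "<rdm_series> metric %s, %d subject(s), %d x %d entries, %d time points\n",
    x$metric, length(x$values), d[1], d[2], d[3]
  ))
  invisible(x)
}

# RDM stack from a (3n) x sensors x time pattern array.
rdm_from_patterns <- function(patterns, metric = c("one_minus_r", "euclidean")) {
  metric <- match.arg(metric)
  d <- dim(patterns)
  labels <- dimnames(patterns)[[1]]
  out <- array(NA_real_, dim = c(d[1], d[1], d[3]),
    dimnames = list(labels, labels, NULL)
  )
  for (t in seq_len(d[3])) {
    m <- patterns[, , t]
    rdm <- if (metric == "one_minus_r") {
      1 - cor(t(m))
    } else {
      g <- tcrossprod(m)
      sq <- diag(g)
      outer(sq, sq, "+") - 2 * g
    }
    diag(rdm) <- NA_real_
    out[, , t] <- rdm
  }
  out
}

# Trial-level bookkeeping shared by the cv-Euclidean and separability RDMs:
# per (condition, image) entry, the trial rows in presentation order.
entry_trials <- function(events) {
  entries <- list()
  for (cond in rdm_conditions()) {
    rows <- condition_trial_rows(events, cond)
    ids <- sort(unique(rows$set_id))
    for (id in ids) {
      tr <- rows$trial_row[rows$set_id == id]
      tr <- tr[order(rows$presentation[rows$set_id == id])]
      entries[[paste0(cond, ":", id)]] <- tr
    }
  }
  n <- length(entries) / 3
  ids <- sort(unique(sub("^pre:", "", names(entries)[seq_len(n)])))
  entries[rdm_labels(ids)]
}

rdm_cv_euclidean <- function(epochs, subject = 1, n_folds = 3) {
  x <- epochs$values[[subject]]
  entries <- entry_trials(epochs$events)
  ne <- length(entries)
  nt <- dim(x)[3]
  labels <- names(entries)
  out <- array(NA_real_, dim = c(ne, ne, nt), dimnames = list(labels, labels, NULL))
  one <- rep(1, ne)
  for (t in seq_len(nt)) {
    slab <- x[, , t] # trials x sensors
    fm <- lapply(entries, function(tr) fold_means(slab[tr, , drop = FALSE], n_folds))
    acc <- matrix(0, ne, ne)
    for (j in seq_len(n_folds)) {
      fj <- t(vapply(fm, function(f) f$fold[j, ], numeric(dim(x)[2])))
      cj <- t(vapply(fm, function(f) f$rest[j, ], numeric(dim(x)[2])))
      g <- tcrossprod(fj, cj)
      dg <- diag(g)
      acc <- acc + outer(dg, one) + outer(one, dg) - g - t(g)
    }
    rdm <- acc / n_folds
    rdm <- (rdm + t(rdm)) / 2 # symmetrize (g is not symmetric)
    diag(rdm) <- NA_real_
    out[, , t] <- rdm
  }
  out
}

rdm_separability <- function(epochs, subject = 1) {
  x <- epochs$values[[subject]]
  entries <- entry_trials(epochs$events)
  ne <- length(entries)
  nt <- dim(x)[3]
  labels <- names(entries)
  sizes <- lengths(entries)
  all_tr <- unlist(entries, use.names = FALSE)
  grp <- rep(seq_len(ne), sizes)
  gmat <- matrix(0, length(all_tr), ne)
  gmat[cbind(seq_along(all_tr), grp)] <- 1
  out <- array(NA_real_, dim = c(ne, ne, nt), dimnames = list(labels, labels, NULL))
  for (t in seq_len(nt)) {
    slab <- x[all_tr, , t]
    z <- fisher_z(cor(t(slab)))
    diag(z) <- 0
    bs <- crossprod(gmat, z %*% gmat) # block sums
    within <- diag(bs) / (sizes * (sizes - 1)) # mean over ordered pairs = mean over unordered
    between <- bs / outer(sizes, sizes)
    sep <- (outer(within, rep(1, ne)) + outer(rep(1, ne), within)) / 2 - between
    diag(sep) <- NA_real_
    out[, , t] <- sep
  }
  out
}

#' Extract a condition block of an RDM
#'
#' Returns the 33 x 33 (generally n x n) submatrix with rows from condition
#' `condA` and columns from condition `condB`, in the fixed image order. The
#' diagonal of a between-condition block aligns matching images (the same
#' Mooney image across stages, or a Mooney image and its matching grayscale
#' image).
#'
#' @param rdm a square matrix with `rdm_labels()` dimnames (one time slice of
#'   an [rdm_series()], or a [build_model_rdm()] matrix).
#' @param condA,condB condition labels in `c("pre", "post", "gray")`.
#' @return The submatrix, dimnames retained.
#' @export
block_view <- function(rdm, condA, condB) {
  n <- nrow(rdm) / 3
  stopifnot(n == round(n))
  rdm[block_index(condA, n), block_index(condB, n), drop = FALSE]
}

#' Mean across-image dissimilarity time course within a condition
#'
#' Per subject and time point, the mean over the upper-triangle off-diagonal
#' entries of the chosen within-condition square of the RDM (528 image pairs
#' for 33 images).
#'
#' @param rs an [rdm_series()] (metrics `one_minus_r`, `euclidean`, or
#'   `cv_euclidean`).
#' @param conditions condition labels to summarise.
#' @return Tibble with columns `subject`, `condition`, `time`, `dissimilarity`.
#' @export
within_condition_dissimilarity_timecourse <- function(rs,
                                                      conditions = rdm_conditions()) {
  if (rs$metric == "separability") {
    abort("within-condition dissimilarity is defined for distance metrics, not separability")
  }
  purrr::map_dfr(seq_along(rs$values), function(s) {
    arr <- rs$values[[s]]
    purrr::map_dfr(conditions, function(cond) {
      idx <- block_index(cond, length(rs$image_ids))
      vals <- apply(arr[idx, idx, , drop = FALSE], 3, function(m) {
        mean(m[upper.tri(m)], na.rm = TRUE)
      })
      tibble::tibble(
        subject = s, condition = cond, time = rs$times, dissimilarity = vals
      )
    })
  })
}

#' Correlation between the geometries of two within-condition squares
#'
#' Converts the RDM to a similarity matrix (1 - RDM), Fisher-z transforms the
#' upper-triangle entries of the two named within-condition squares, computes
#' their Pearson correlation per time point, and Fisher-z transforms the
#' resulting r. The Pre-Pre vs Post-Post correlation indexes stimulus-feature
#' geometry (same images, same order, different perceptual state); the
#' Post-Post vs Gray-Gray correlation indexes recognition-content geometry.
#'
#' @param rs an [rdm_series()] with metric `one_minus_r`.
#' @param blockA,blockB condition labels of the two within-condition squares.
#' @return Tibble with columns `subject`, `time`, `z` (Fisher-z of the
#'   geometry correlation; `NA` where a triangle is degenerate).
#' @export
intra_rdm_correlation <- function(rs, blockA = "pre", blockB = "post") {
  n <- length(rs$image_ids)
  ia <- block_index(blockA, n)
  ib <- block_index(blockB, n)
  purrr::map_dfr(seq_along(rs$values), function(s) {
    arr <- rs$values[[s]]
    z <- vapply(seq_along(rs$times), function(t) {
      a <- fisher_z(1 - upper_tri_vals(arr[ia, ia, t]))
      b <- fisher_z(1 - upper_tri_vals(arr[ib, ib, t]))
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      fisher_z(cor(a, b))
    }, numeric(1))
    tibble::tibble(subject = s, time = rs$times, z = z)
  })
}

#' Average an RDM series across subjects
#'
#' @param rs an [rdm_series()].
#' @return An `rdm_series` with a single, subject-averaged array.
#' @export
rdm_group_average <- function(rs) {
  if (length(rs$values) == 1) return(rs)
  avg <- Reduce(`+`, rs$values) / length(rs$values)
  rs$values <- list(avg)
  rs
}
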