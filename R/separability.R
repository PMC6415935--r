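#' Single-trial separability between two images
#'
#' Quantifies how much neural similarity across repeated presentations of the
#' same image exceeds similarity between two different images, at the single-
#' trial level. With trials `x_1..x_m` of image A and `y_1..y_n` of image B,
#' `r_within` is the average of (i) the mean Fisher-z-transformed Pearson
#' correlation over all within-A trial pairs and (ii) the same over all
#' within-B pairs; `r_between` is the mean Fisher-z correlation over all
#' `m * n` cross pairs. The score is `r_within - r_between`, stays in Fisher-z
#' space (no back-transform), is symmetric in A and B, and has expectation 0
#' when the two trial sets are exchangeable.
#'
#' @param x_trials,y_trials trials x sensors matrices (`m >= 2`, `n >= 2`).
#' @return The separability score (z difference).
#' @export
separability_score <- function(x_trials, y_trials) {
  m <- nrow(x_trials)
  n <- nrow(y_trials)
  if (m < 2 || n < 2) {
    abort("separability needs at least 2 trials per image")
  }
  stopifnot(ncol(x_trials) == ncol(y_trials))
  sds <- c(apply(x_trials, 1, sd), apply(y_trials, 1, sd))
  if (any(sds == 0)) abort("zero-variance trial vector")
  z <- fisher_z(cor(t(rbind(x_trials, y_trials))))
  ia <- seq_len(m)
  ib <- m + seq_len(n)
  za <- z[ia, ia]
  zb <- z[ib, ib]
  r_within <- (mean(upper_tri_vals(za)) + mean(upper_tri_vals(zb))) / 2
  r_between <- mean(z[ia, ib])
  r_within - r_between
}

#' Time-resolved separability RDMs
#'
#' Convenience wrapper: [rdm_series()] with `metric = "separability"`. Every
#' entry pair is scored with [separability_score()] over single trials (all 6
#' Mooney presentations per stage, all 3 grayscale presentations); the
#' diagonal of a between-condition square holds the same/matching image
#' presented in two conditions.
#'
#' @param epochs a normalized [sensor_epochs()] object.
#' @return An `rdm_series` with metric tag `"separability"`.
#' @export
separability_rdm_series <- function(epochs) {
  rdm_series(epochs, metric = "separability")
}

condition_pair_index <- function(pair) {
  parts <- strsplit(pair, "-", fixed = TRUE)[[1]]
  stopifnot(length(parts) == 2)
  tolower(parts)
}

#' Mean diagonal of a between-condition square over time
#'
#' Per subject and time point, the mean of the n diagonal entries of the
#' named between-condition square of a separability RDM series: the
#' separability of the same Mooney image across stages (`"pre-post"`), or of
#' a Mooney image and its matching grayscale image (`"pre-gray"`,
#' `"post-gray"`). Values near 0 mean the matching patterns are
#' indistinguishable at the single-trial level.
#'
#' @param rs an [rdm_series()] (typically metric `"separability"`).
#' @param cond_pairs character vector of condition pairs, e.g. `"post-gray"`.
#' @return Tibble with columns `subject`, `pair`, `time`, `value`.
#' @export
cross_condition_diagonal_timecourse <- function(rs,
                                                cond_pairs = c(
                                                  "pre-post", "pre-gray",
                                                  "post-gray"
                                                )) {
  n <- length(rs$image_ids)
  purrr::map_dfr(seq_along(rs$values), function(s) {
    arr <- rs$values[[s]]
    purrr::map_dfr(cond_pairs, function(pair) {
      cc <- condition_pair_index(pair)
      ia <- block_index(cc[1], n)
      ib <- block_index(cc[2], n)
      vals <- vapply(seq_along(rs$times), function(t) {
        mean(diag(arr[ia, ib, t]))
      }, numeric(1))
      tibble::tibble(subject = s, pair = pair, time = rs$times, value = vals)
    })
  })
}

#' Off-diagonal minus diagonal separability over time
#'
#' Per subject and time point, the mean of the off-diagonal entries of a
#' between-condition square minus the mean of its diagonal entries. Large
#' positive values mean an image is much closer to itself (or its matching
#' counterpart) in the other condition than to other images there — an
#' image-specific representation.
#'
#' @inheritParams cross_condition_diagonal_timecourse
#' @return Tibble with columns `subject`, `pair`, `time`, `value`.
#' @export
offdiagonal_minus_diagonal_timecourse <- function(rs,
                                                  cond_pairs = c(
                                                    "pre-post", "pre-gray",
                                                    "post-gray"
                                                  )) {
  n <- length(rs$image_ids)
  purrr::map_dfr(seq_along(rs$values), function(s) {
    arr <- rs$values[[s]]
    purrr::map_dfr(cond_pairs, function(pair) {
      cc <- condition_pair_index(pair)
      ia <- block_index(cc[1], n)
      ib <- block_index(cc[2], n)
      vals <- vapply(seq_along(rs$times), function(t) {
        blk <- arr[ia, ib, t]
        dg <- diag(blk)
        (sum(blk) - sum(dg)) / (n * n - n) - mean(dg)
      }, numeric(1))
      tibble::tibble(subject = s, pair = pair, time = rs$times, value = vals)
    })
  })
}
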