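#' Theoretical model RDMs
#'
#' Builds the three a-priori model dissimilarity matrices over the
#' (condition, image) entries, with high dissimilarity coded 1, low coded 0,
#' intermediate 0.5, and excluded cells `NA`:
#'
#' * **stimulus** — physical image features: the same Mooney image across
#'   stages is identical (Pre-Post diagonal 0); different Mooney images and
#'   different grayscale images are intermediately dissimilar (off-diagonals
#'   of the Pre-Pre, Pre-Post, Post-Post, and Gray-Gray squares 0.5); Mooney
#'   vs. non-matching grayscale images are maximally dissimilar (off-diagonals
#'   of Pre-Gray and Post-Gray squares 1). The Pre-Gray and Post-Gray
#'   diagonals are excluded (`NA`) — no a-priori ordering for matching
#'   Mooney/grayscale pairs.
#' * **recognition** — image-specific recognition content: two unrecognized
#'   images are most similar (Pre-Pre off-diagonals 0), as is a
#'   post-disambiguation Mooney image and its matching grayscale image
#'   (Post-Gray diagonal 0; the equivalence of these two levels is a modelling
#'   convention, adjustable via `low_unrecognized` / `low_matched`);
#'   recognized vs. unrecognized is intermediate (entire Pre-Post and
#'   Pre-Gray squares 0.5); two recognized images with different content are
#'   most dissimilar (off-diagonals of Post-Post, Post-Gray, and Gray-Gray
#'   squares 1).
#' * **attention** — recognition status regardless of content: within-status
#'   squares (Pre-Pre, Post-Post, Gray-Gray, Post-Gray, including the
#'   Post-Gray diagonal) 0; across-status squares (Pre-Post, Pre-Gray) 1. No
#'   intermediate entries.
#'
#' The main diagonal is always `NA`. Analyses combining models exclude the
#' union of `NA` cells across all matrices involved.
#'
#' @param kind `"stimulus"`, `"recognition"`, or `"attention"`.
#' @param n_images number of image sets (>= 2); default 33.
#' @param image_ids optional image ids used for the dimnames.
#' @param low_unrecognized,low_matched the recognition model's two low levels
#'   (Pre-Pre off-diagonals and Post-Gray diagonal).
#' @return A `3 * n_images` square matrix of class `model_rdm` with entries in
#'   `{0, 0.5, 1, NA}` and a `kind` attribute.
#' @export
build_model_rdm <- function(kind = c("stimulus", "recognition", "attention"),
                            n_images = 33, image_ids = NULL,
                            low_unrecognized = 0, low_matched = 0) {
  kind <- match.arg(kind)
  stopifnot(n_images >= 2)
  n <- n_images
  ids <- image_ids %||% sprintf("s%02d", seq_len(n))
  labels <- rdm_labels(ids)
  m <- matrix(NA_real_, 3 * n, 3 * n, dimnames = list(labels, labels))

  idx <- lapply(setNames(rdm_conditions(), rdm_conditions()), block_index,
    n_images = n
  )
  set_block <- function(a, b, value, diag_value = value) {
    blk <- matrix(value, n, n)
    diag(blk) <- diag_value
    m[idx[[a]], idx[[b]]] <<- blk
    m[idx[[b]], idx[[a]]] <<- t(blk)
  }

  if (kind == "stimulus") {
    set_block("pre", "pre", 0.5)
    set_block("post", "post", 0.5)
    set_block("gray", "gray", 0.5)
    set_block("pre", "post", 0.5, diag_value = 0)
    set_block("pre", "gray", 1, diag_value = NA_real_)
    set_block("post", "gray", 1, diag_value = NA_real_)
  } else if (kind == "recognition") {
    set_block("pre", "pre", low_unrecognized)
    set_block("post", "post", 1)
    set_block("gray", "gray", 1)
    set_block("pre", "post", 0.5)
    set_block("pre", "gray", 0.5)
    set_block("post", "gray", 1, diag_value = low_matched)
  } else {
    set_block("pre", "pre", 0)
    set_block("post", "post", 0)
    set_block("gray", "gray", 0)
    set_block("post", "gray", 0)
    set_block("pre", "post", 1)
    set_block("pre", "gray", 1)
  }
  diag(m) <- NA_real_

  structure(m, kind = kind, class = c("model_rdm", class(m)))
}
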