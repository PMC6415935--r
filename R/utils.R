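#' @importFrom rlang .data abort warn %||%
#' @importFrom stats cor sd quantile rnorm runif rbinom p.adjust setNames
#' @importFrom utils head tail
NULL

# Clip correlations away from +/-1 so atanh stays finite on degenerate
# (noise-free) fixtures.
FISHER_CLIP <- 1 - 1e-10

#' Fisher z-transform with clipping at +/- (1 - 1e-10)
#'
#' @param r numeric vector of correlation values in \[-1, 1\].
#' @return atanh of the clipped values.
#' @keywords internal
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -FISHER_CLIP), FISHER_CLIP))
}

# Deterministic per-stream sub-seed derivation from one master seed.
# Keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483563) + 1L
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483563), code)
}

#' Condition labels in canonical block order
#'
#' The fixed ordering of condition blocks used by every 99 x 99 matrix in the
#' package: pre-disambiguation Mooney, post-disambiguation Mooney, grayscale.
#' @return character vector `c("pre", "post", "gray")`.
#' @export
rdm_conditions <- function() c("pre", "post", "gray")

# Row/column labels of an n_images x 3-condition RDM, block order
# Pre 1..n, Post 1..n, Gray 1..n.
rdm_labels <- function(image_ids) {
  as.vector(vapply(
    rdm_conditions(),
    function(cond) paste0(cond, ":", image_ids),
    character(length(image_ids))
  ))
}

# Indices of a condition block inside the 3n x 3n matrix.
block_index <- function(cond, n_images) {
  k <- match(cond, rdm_conditions())
  if (is.na(k)) abort(paste0("unknown condition label: ", cond))
  (k - 1L) * n_images + seq_len(n_images)
}

upper_tri_vals <- function(m) m[upper.tri(m)]
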