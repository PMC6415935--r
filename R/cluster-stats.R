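# --- exact one-sample Wilcoxon signed-rank machinery -------------------------
#
# The cluster tests need a per-sample signed-rank p at every time point of
# every sign-flip permutation. stats::wilcox.test is far too slow for that,
# and under sign flips the ranks of |d| never change -- only which entries are
# positive. So ranks are computed once per column and W under any flip is a
# masked column sum; p-values come from the exact null distribution of
# W = sum of a random subset of the realized ranks (computed by dynamic
# programming on a half-integer grid, cached by rank multiset).

signed_rank_tail <- local({
  cache <- new.env(parent = emptyenv())
  function(ranks2) { # integer vector of 2 * rank values
    key <- paste(sort(ranks2), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    total <- sum(ranks2)
    p <- numeric(total + 1)
    p[1] <- 1
    for (v in ranks2) {
      shifted <- c(numeric(v), p[seq_len(total + 1 - v)])
      p <- (p + shifted) / 2
    }
    tail_p <- rev(cumsum(rev(p))) # tail_p[k+1] = P(2W >= k)
    cache[[key]] <- tail_p
    tail_p
  }
})

# Per-column ranks of |d| (zeros excluded, ties averaged) and tail lookup.
column_rank_info <- function(d) {
  nsub <- nrow(d)
  ranks <- matrix(0, nsub, ncol(d))
  tails <- vector("list", ncol(d))
  for (t in seq_len(ncol(d))) {
    nz <- which(d[, t] != 0)
    if (length(nz) == 0) {
      tails[[t]] <- c(1) # degenerate: W always 0
      next
    }
    r <- rank(abs(d[nz, t]))
    ranks[nz, t] <- r
    tails[[t]] <- signed_rank_tail(as.integer(round(2 * r)))
  }
  list(ranks = ranks, tails = tails)
}

# W statistics (per column) for data with positivity mask `pos` (logical).
column_w <- function(ranks, pos) colSums(ranks * pos)

column_p <- function(w, tails) {
  vapply(seq_along(w), function(t) {
    tp <- tails[[t]]
    idx <- as.integer(round(2 * w[t])) + 1L
    if (idx > length(tp)) 0 else tp[idx]
  }, numeric(1))
}

# Contiguous runs of TRUE in a logical vector -> list of index vectors.
runs_of <- function(mask) {
  if (!any(mask)) return(list())
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  purrr::map2(starts[r$values], ends[r$values], seq)
}

# 4-neighbour connected components of a logical matrix -> list of index sets.
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  comps <- list()
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      nxt <- nxt + 1L
      queue <- c(i + (j - 1L) * nr)
      lab[i, j] <- nxt
      members <- integer(0)
      while (length(queue) > 0) {
        cur <- queue[length(queue)]
        queue <- queue[-length(queue)]
        members <- c(members, cur)
        ci <- (cur - 1L) %% nr + 1L
        cj <- (cur - 1L) %/% nr + 1L
        for (nb in list(c(ci - 1L, cj), c(ci + 1L, cj), c(ci, cj - 1L), c(ci, cj + 1L))) {
          if (nb[1] < 1 || nb[1] > nr || nb[2] < 1 || nb[2] > nc) next
          if (mask[nb[1], nb[2]] && lab[nb[1], nb[2]] == 0L) {
            lab[nb[1], nb[2]] <- nxt
            queue <- c(queue, nb[1] + (nb[2] - 1L) * nr)
          }
        }
      }
      comps[[nxt]] <- sort(members)
    }
  }
  comps
}

cluster_engine <- function(d, n_perm, alpha, seed, clusters_fn) {
  info <- column_rank_info(d)
  pos <- d > 0
  neg <- d < 0
  a_mat <- info$ranks * pos
  b_mat <- info$ranks * neg

  w_obs <- column_w(info$ranks, pos)
  p_obs <- column_p(w_obs, info$tails)
  obs_clusters <- clusters_fn(p_obs < alpha)
  summaries <- vapply(obs_clusters, function(ix) sum(w_obs[ix]), numeric(1))

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      flip <- runif(nrow(d)) < 0.5
      w <- colSums(a_mat[!flip, , drop = FALSE]) +
        colSums(b_mat[flip, , drop = FALSE])
      p <- column_p(w, info$tails)
      cl <- clusters_fn(p < alpha)
      if (length(cl) == 0) 0 else max(vapply(cl, function(ix) sum(w[ix]), numeric(1)))
    }, numeric(1))
  })

  crit <- as.numeric(quantile(null_max, 0.95))
  p_cluster <- vapply(summaries, function(s) {
    (1 + sum(null_max >= s)) / (n_perm + 1)
  }, numeric(1))
  list(
    w = w_obs, p_pointwise = p_obs, clusters = obs_clusters,
    summaries = summaries, null_max = null_max, critical = crit,
    significant = summaries > crit, p_cluster = p_cluster
  )
}

#' Cluster-based permutation test on a group time course
#'
#' Tests, at every time point, whether the group values exceed a chance level
#' with a one-tailed one-sample Wilcoxon signed-rank test (exact null
#' distribution of the W statistic). Contiguous runs of pointwise p <
#' `alpha` form clusters; a cluster's summary statistic is its summed W. The
#' family-wise null distribution is built by randomly sign-flipping each
#' subject's deviation from chance (`n_perm` permutations) and taking the
#' maximum cluster summary of each permutation; observed clusters whose
#' summary exceeds the 95th percentile of that null are significant
#' (p < 0.05, cluster-corrected). Paired condition contrasts use the same
#' machinery on per-subject differences with `chance = 0`.
#'
#' @param values subjects x time matrix, or a tibble with `subject`, `time`
#'   and a value column (e.g. a `decoding_result$accuracy` tibble).
#' @param chance chance level subtracted before testing.
#' @param n_perm number of sign-flip permutations (warning below 100).
#' @param alpha cluster-forming pointwise threshold.
#' @param seed integer seed for the permutation draws.
#' @return A list of class `cluster_result`: per-time `w` and `p_pointwise`,
#'   `clusters` (index sets), `summaries`, `null_max`, `critical`,
#'   `significant`, `p_cluster`, and a pointwise logical `mask` restricted to
#'   significant clusters.
#' @export
cluster_permutation_timecourse <- function(values, chance = 0.5, n_perm = 500,
                                           alpha = 0.05, seed = 1) {
  if (is.data.frame(values)) {
    valcol <- setdiff(names(values), c("subject", "time", "condition", "pair"))[1]
    values <- values |>
      dplyr::select("subject", "time", dplyr::all_of(valcol)) |>
      tidyr::pivot_wider(names_from = "time", values_from = dplyr::all_of(valcol))
    values <- as.matrix(values[, -1])
  }
  if (nrow(values) < 2) abort("need at least 2 subjects")
  if (n_perm < 100) warn("n_perm < 100: permutation tail is unstable")
  d <- values - chance
  res <- cluster_engine(d, n_perm, alpha, seed, clusters_fn = runs_of)
  mask <- rep(FALSE, ncol(values))
  for (k in seq_along(res$clusters)) {
    if (res$significant[k]) mask[res$clusters[[k]]] <- TRUE
  }
  res$mask <- mask
  res$n_perm <- n_perm
  class(res) <- "cluster_result"
  res
}

#' Cluster-based permutation test on temporal generalization matrices
#'
#' Two-dimensional analogue of [cluster_permutation_timecourse()]: clusters
#' are 4-neighbour connected components over the train-time x test-time
#' plane.
#'
#' @param tgms list of per-subject train x test matrices (as in a
#'   `tgm_result`), or a subjects x train x test array.
#' @inheritParams cluster_permutation_timecourse
#' @return A `cluster_result` whose `clusters` hold linear indices into the
#'   matrix and whose `mask` is a train x test logical matrix.
#' @export
cluster_permutation_tgm <- function(tgms, chance = 0.5, n_perm = 500,
                                    alpha = 0.05, seed = 1) {
  if (is.list(tgms)) {
    dims <- dim(tgms[[1]])
    tgms <- aperm(simplify2array(tgms), c(3, 1, 2))
  } else {
    dims <- dim(tgms)[2:3]
  }
  if (dim(tgms)[1] < 2) abort("need at least 2 subjects")
  if (n_perm < 100) warn("n_perm < 100: permutation tail is unstable")
  d <- matrix(tgms - chance, nrow = dim(tgms)[1])
  clusters_fn <- function(sig) label_components(matrix(sig, dims[1], dims[2]))
  res <- cluster_engine(d, n_perm, alpha, seed, clusters_fn = clusters_fn)
  mask <- matrix(FALSE, dims[1], dims[2])
  for (k in seq_along(res$clusters)) {
    if (res$significant[k]) mask[res$clusters[[k]]] <- TRUE
  }
  res$mask <- mask
  res$n_perm <- n_perm
  class(res) <- "cluster_result"
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d cluster(s), %d significant (critical summary %.2f, %d permutations)\n",
    length(x$clusters), sum(x$significant), x$critical, x$n_perm
  ))
  invisible(x)
}

#' Image-order permutation null for RDM statistics
#'
#' Builds the permutation null for any statistic computed from an RDM series
#' (e.g. a model correlation time course) by shuffling the order of the
#' (condition, image) entries: each permutation draws one random order of all
#' `3 * n_images` entry labels and applies it to the rows and columns of the
#' RDM, identically at every time point (so one shuffle is shared by the
#' whole series). Shuffling whole entries (rather than images within
#' condition blocks) destroys both the image alignment and the condition
#' block structure, which purely block-structured statistics require for a
#' non-degenerate null. Clusters are contiguous time points where the observed statistic
#' exceeds the per-time 95th percentile of the null; significance is by the
#' maximum-cluster-size criterion at the 95th percentile of the per-
#' permutation maxima.
#'
#' @param rs a group-averaged [rdm_series()].
#' @param statistic_fn function mapping an entries x entries x time array to
#'   a numeric time course.
#' @param n_perm number of image-order permutations.
#' @param seed integer seed.
#' @return A list of class `rdm_perm_result`: `observed`, `null` (n_perm x
#'   time), `threshold` (per-time 95th percentile), `clusters` tibble
#'   (`start`, `end`, `size`, `significant`), `size_critical`, `mask`, and
#'   the recorded permutation `orders` matrix.
#' @export
rdm_order_permutation_null <- function(rs, statistic_fn, n_perm = 1000,
                                       seed = 1) {
  arr <- rs$values[[1]]
  nn <- dim(arr)[1]
  observed <- statistic_fn(arr)
  nt <- length(observed)
  orders <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) sample(nn), integer(nn)))
  })
  null <- matrix(0, n_perm, nt)
  for (b in seq_len(n_perm)) {
    idx <- orders[b, ]
    null[b, ] <- statistic_fn(arr[idx, idx, , drop = FALSE])
  }
  out <- cluster_from_null(observed, null)
  out$orders <- orders
  out
}

# Shared cluster-size inference for image-order permutation nulls: per-time
# 95th-percentile threshold, contiguous supra-threshold clusters, and a
# max-cluster-size criterion at the 95th percentile of the permutation maxima.
cluster_from_null <- function(observed, null) {
  threshold <- apply(null, 2, quantile, 0.95)
  obs_runs <- runs_of(observed > threshold)
  max_null_size <- vapply(seq_len(nrow(null)), function(b) {
    r <- runs_of(null[b, ] > threshold)
    if (length(r) == 0) 0L else max(lengths(r))
  }, integer(1))
  size_critical <- as.numeric(quantile(max_null_size, 0.95))
  clusters <- tibble::tibble(
    start = vapply(obs_runs, min, integer(1)),
    end = vapply(obs_runs, max, integer(1)),
    size = lengths(obs_runs)
  )
  clusters$significant <- clusters$size > size_critical
  mask <- rep(FALSE, length(observed))
  for (k in seq_len(nrow(clusters))) {
    if (clusters$significant[k]) mask[clusters$start[k]:clusters$end[k]] <- TRUE
  }
  structure(
    list(
      observed = observed, null = null, threshold = threshold,
      clusters = clusters, size_critical = size_critical, mask = mask
    ),
    class = "rdm_perm_result"
  )
}

#' Benjamini-Hochberg significance mask
#'
#' @param p_values numeric vector of p-values.
#' @param q false-discovery-rate level.
#' @return Logical vector: `TRUE` where the BH-adjusted p-value is <= `q`.
#' @export
fdr_mask <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH") <= q
}
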