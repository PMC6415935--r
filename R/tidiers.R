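#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decoding result
#'
#' @param x a `decoding_result`.
#' @param ... unused.
#' @return The accuracy tibble (`subject`, `time`, `accuracy`).
#' @export
tidy.decoding_result <- function(x, ...) x$accuracy

#' One-row summary of a decoding result
#'
#' @param x a `decoding_result`.
#' @param ... unused.
#' @return Tibble with the grand mean accuracy, the group peak accuracy and
#'   its latency, and counts.
#' @export
glance.decoding_result <- function(x, ...) {
  grp <- x$accuracy |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(accuracy = mean(.data$accuracy))
  tibble::tibble(
    mean_accuracy = mean(x$accuracy$accuracy),
    peak_accuracy = max(grp$accuracy),
    peak_time = grp$time[which.max(grp$accuracy)],
    n_subjects = dplyr::n_distinct(x$accuracy$subject),
    n_times = length(x$times)
  )
}

#' Tidy a cluster permutation result
#'
#' @param x a `cluster_result`.
#' @param ... unused.
#' @return Tibble with one row per cluster: extent, summed W, and corrected
#'   p-value.
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::tibble(
    cluster = seq_along(x$clusters),
    start = vapply(x$clusters, min, numeric(1)),
    end = vapply(x$clusters, max, numeric(1)),
    n_cells = lengths(x$clusters),
    summary_w = x$summaries,
    p = x$p_cluster,
    significant = x$significant
  )
}

#' One-row summary of a cluster permutation result
#'
#' @param x a `cluster_result`.
#' @param ... unused.
#' @return Tibble with cluster counts and the critical summary statistic.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = length(x$clusters),
    n_significant = sum(x$significant),
    critical = x$critical,
    n_perm = x$n_perm
  )
}

#' Tidy a fusion map
#'
#' @param x a `fusion_map`.
#' @param ... unused.
#' @return The ROI x model x time commonality tibble.
#' @export
tidy.fusion_map <- function(x, ...) x$map

#' One-row-per-ROI-model summary of a fusion map
#'
#' @param x a `fusion_map`.
#' @param ... unused.
#' @return Tibble with peak commonality and earliest significant latency per
#'   (ROI, model).
#' @export
glance.fusion_map <- function(x, ...) {
  x$map |>
    dplyr::group_by(.data$roi, .data$model) |>
    dplyr::summarise(
      peak_commonality = max(.data$commonality),
      onset = if (any(.data$significant)) {
        min(.data$time[.data$significant])
      } else NA_real_,
      .groups = "drop"
    )
}
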