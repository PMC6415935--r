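#' Plot a decoding accuracy time course
#'
#' Group mean balanced accuracy with an s.e.m. ribbon and the 0.5 chance
#' line.
#'
#' @param object a `decoding_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.decoding_result <- function(object, ...) {
  grp <- object$accuracy |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(
      mean = mean(.data$accuracy),
      sem = sd(.data$accuracy) / sqrt(dplyr::n())
    )
  ggplot2::ggplot(grp, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(
      x = "time (s)", y = "balanced accuracy",
      title = "Perceptual-state decoding"
    )
}

#' Plot one time slice of an RDM series
#'
#' @param object an `rdm_series`.
#' @param time time point (s) of the slice to show (nearest sample is used).
#' @param subject subject index.
#' @param ... unused.
#' @return A ggplot heatmap with condition-block separators.
#' @export
autoplot.rdm_series <- function(object, time = 0.2, subject = 1, ...) {
  ti <- which.min(abs(object$times - time))
  m <- object$values[[subject]][, , ti]
  n <- length(object$image_ids)
  df <- tibble::tibble(
    row = rep(seq_len(3 * n), times = 3 * n),
    col = rep(seq_len(3 * n), each = 3 * n),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::geom_hline(yintercept = c(n, 2 * n) + 0.5, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = c(n, 2 * n) + 0.5, linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = NULL, y = NULL, fill = object$metric,
      title = sprintf("RDM at %.2f s", object$times[ti])
    )
}

#' Plot a model RDM
#'
#' @param object a `model_rdm`.
#' @param ... unused.
#' @return A ggplot heatmap.
#' @export
autoplot.model_rdm <- function(object, ...) {
  n <- nrow(object) / 3
  df <- tibble::tibble(
    row = rep(seq_len(3 * n), times = 3 * n),
    col = rep(seq_len(3 * n), each = 3 * n),
    value = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", midpoint = 0.5,
      na.value = "black"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "dissimilarity",
      title = paste(attr(object, "kind"), "model")
    )
}

#' Plot a temporal generalization matrix
#'
#' @param object a `tgm_result`.
#' @param ... unused.
#' @return A ggplot heatmap of the subject-averaged TGM.
#' @export
autoplot.tgm_result <- function(object, ...) {
  avg <- Reduce(`+`, object$tgm) / length(object$tgm)
  df <- tibble::tibble(
    train = rep(object$times, times = length(object$times)),
    test = rep(object$times, each = length(object$times)),
    accuracy = as.vector(avg)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test, y = .data$train, fill = .data$accuracy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "test time (s)", y = "train time (s)",
      title = "Temporal generalization"
    )
}

#' Plot a fusion commonality map
#'
#' @param object a `fusion_map`.
#' @param ... unused.
#' @return A ggplot of commonality time courses faceted by model, one line
#'   per ROI, significant samples emphasized.
#' @export
autoplot.fusion_map <- function(object, ...) {
  ggplot2::ggplot(
    object$map,
    ggplot2::aes(x = .data$time, y = .data$commonality, colour = .data$roi)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = dplyr::filter(object$map, .data$significant), size = 0.6
    ) +
    ggplot2::facet_wrap(~model, scales = "free_y") +
    ggplot2::labs(
      x = "time (s)", y = "commonality (shared R²)",
      title = "Model-driven sensor-fMRI fusion"
    )
}

#' Plot condition dissimilarity or separability time courses
#'
#' @param curves tibble from [within_condition_dissimilarity_timecourse()],
#'   [cross_condition_diagonal_timecourse()], or
#'   [offdiagonal_minus_diagonal_timecourse()].
#' @return A ggplot with group mean and s.e.m. ribbon per curve.
#' @export
plot_condition_curves <- function(curves) {
  key <- intersect(c("condition", "pair"), names(curves))[1]
  val <- setdiff(names(curves), c("subject", "time", key))[1]
  grp <- curves |>
    dplyr::group_by(.data[[key]], .data$time) |>
    dplyr::summarise(
      mean = mean(.data[[val]]), sem = sd(.data[[val]]) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(grp, ggplot2::aes(
    x = .data$time, y = .data$mean, colour = .data[[key]], fill = .data[[key]]
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = val)
}
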