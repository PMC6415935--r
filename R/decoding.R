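#' Decoder configuration
#'
#' @param cost SVM cost parameter (must be positive; the analyses fix it at
#'   1 with no per-time hyperparameter search).
#' @return A list of class `decoder_config`.
#' @export
decoder_config <- function(cost = 1) {
  stopifnot(cost > 0)
  structure(list(cost = cost), class = "decoder_config")
}

# Per-image stage-averaged patterns for the decoder: images x sensors x time
# per class, averaged over all per-stage presentations, restricted to
# `image_subset` when given.
decoder_samples <- function(epochs, image_subset = NULL, subject = 1) {
  n_pres <- max(epochs$events$presentation[epochs$events$image_type == "mooney"])
  pre <- average_presentations(epochs, "pre", k = n_pres, subject = subject)
  post <- average_presentations(epochs, "post", k = n_pres, subject = subject)
  ids <- dimnames(pre)[[1]]
  if (!is.null(image_subset)) {
    ids <- intersect(ids, image_subset)
    pre <- pre[ids, , , drop = FALSE]
    post <- post[ids, , , drop = FALSE]
  }
  if (length(ids) < 4) {
    abort("need at least 4 image sets (2 per fold) in both classes")
  }
  list(pre = pre, post = post, ids = ids)
}

# Odd-even split of image-set indices (by position in sorted id order).
parity_folds <- function(ids) {
  i <- seq_along(ids)
  list(odd = i[i %% 2 == 1], even = i[i %% 2 == 0])
}

# Train a linear SVM at one time point; return a linear decision rule.
fit_linear_svm <- function(xtr, ytr, cost) {
  fit <- e1071::svm(
    x = xtr, y = ytr, kernel = "linear", cost = cost, scale = FALSE
  )
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  dv <- as.vector(xtr %*% w) - fit$rho
  pred <- as.character(predict(fit, xtr))
  i <- which(abs(dv) > 1e-12)[1]
  lev <- levels(ytr)
  if (is.na(i)) {
    pos <- lev[1] # degenerate rule; accuracy handled downstream
  } else if (dv[i] > 0) {
    pos <- pred[i]
  } else {
    pos <- setdiff(lev, pred[i])
  }
  list(w = w, rho = fit$rho, pos = pos, neg = setdiff(lev, pos))
}

balanced_accuracy <- function(pred, truth) {
  mean(vapply(unique(truth), function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1)))
}

# Core per-subject decoding: accuracy time course, optional weights/patterns
# and temporal generalization matrix. Folds are deterministic parity folds;
# decision ties (score == 0) go to the negative class.
decode_subject <- function(pre, post, cost = 1, tgm = FALSE,
                           patterns = FALSE) {
  nt <- dim(pre)[3]
  ns <- dim(pre)[2]
  folds <- parity_folds(dimnames(pre)[[1]])
  acc <- matrix(0, nrow = if (tgm) nt else 1, ncol = nt)
  wsum <- matrix(0, ns, nt)
  psum <- matrix(0, ns, nt)
  for (f in 1:2) {
    tr <- folds[[f]]
    te <- folds[[3 - f]]
    if (length(tr) < 2 || length(te) < 2) {
      abort("each fold needs at least 2 image sets")
    }
    ytr <- factor(rep(c("pre", "post"), each = length(tr)),
      levels = c("pre", "post")
    )
    truth <- rep(c("pre", "post"), each = length(te))
    for (t in seq_len(nt)) {
      xtr <- rbind(pre[tr, , t, drop = FALSE][, , 1], post[tr, , t, drop = FALSE][, , 1])
      rule <- fit_linear_svm(xtr, ytr, cost)
      wsum[, t] <- wsum[, t] + rule$w
      if (patterns) {
        psum[, t] <- psum[, t] + as.vector(cov(xtr) %*% rule$w)
      }
      test_times <- if (tgm) seq_len(nt) else t
      for (tt in test_times) {
        xte <- rbind(
          pre[te, , tt, drop = FALSE][, , 1], post[te, , tt, drop = FALSE][, , 1]
        )
        score <- as.vector(xte %*% rule$w) - rule$rho
        pred <- ifelse(score > 0, rule$pos, rule$neg)
        row <- if (tgm) t else 1
        acc[row, tt] <- acc[row, tt] + balanced_accuracy(pred, truth) / 2
      }
    }
  }
  list(
    accuracy = if (tgm) diag(acc) else acc[1, ],
    tgm = if (tgm) acc else NULL,
    weights = wsum / 2,
    patterns = if (patterns) psum / 2 else NULL
  )
}

#' Time-resolved decoding of perceptual state
#'
#' Decodes presentation stage (pre- vs. post-disambiguation) from sensor
#' patterns at every time point. Samples are per-image patterns averaged
#' across all per-stage presentations; classes are the stage labels. A linear
#' SVM (cost fixed by `config`) is trained and tested under a deterministic
#' odd-even cross-validation over image sets (parity of the sorted image
#' index, so both stage averages of one image stay in the same fold), and
#' accuracy is reported as balanced accuracy averaged over the two folds
#' (chance 0.5).
#'
#' @param epochs a normalized [sensor_epochs()] object.
#' @param image_subset optional character vector of image ids (e.g. from
#'   [select_disambiguated_sets()]); default all real sets.
#' @param config a [decoder_config()].
#' @param return_weights,return_patterns also return per-subject decoder
#'   weight vectors / activation patterns (fold-averaged) per time point.
#' @return Object of class `decoding_result`: `accuracy` tibble (`subject`,
#'   `time`, `accuracy`), optional `weights` / `patterns` (lists of
#'   sensors x time matrices), `times`, `config`.
#' @export
decode_timecourse <- function(epochs, image_subset = NULL,
                              config = decoder_config(),
                              return_weights = FALSE,
                              return_patterns = FALSE) {
  res <- lapply(seq_len(n_subjects(epochs)), function(s) {
    smp <- decoder_samples(epochs, image_subset, subject = s)
    decode_subject(smp$pre, smp$post, cost = config$cost,
      patterns = return_patterns
    )
  })
  accuracy <- purrr::map_dfr(seq_along(res), function(s) {
    tibble::tibble(subject = s, time = epochs$times, accuracy = res[[s]]$accuracy)
  })
  structure(
    list(
      accuracy = accuracy,
      weights = if (return_weights) lapply(res, `[[`, "weights") else NULL,
      patterns = if (return_patterns) lapply(res, `[[`, "patterns") else NULL,
      times = epochs$times, config = config
    ),
    class = "decoding_result"
  )
}

#' Activation patterns from decoder weights
#'
#' Transforms backward-model decoder weights into forward-model activation
#' patterns by multiplying the weight vector with the covariance matrix of
#' the training data, per time point. Unlike raw weights, activation patterns
#' are interpretable as the sensor topography of the decoded signal.
#'
#' @param weights sensors x time matrix (or a single weight vector).
#' @param training_data samples x sensors x time array (or samples x sensors
#'   matrix) of the data the decoder was trained on.
#' @return sensors x time matrix (or vector) of activation patterns.
#' @export
activation_patterns <- function(weights, training_data) {
  if (is.null(dim(weights))) weights <- matrix(weights, ncol = 1)
  if (length(dim(training_data)) == 2) {
    training_data <- array(training_data, dim = c(dim(training_data), 1))
  }
  if (dim(training_data)[1] < 2) {
    abort("activation patterns need at least 2 training samples")
  }
  stopifnot(dim(training_data)[2] == nrow(weights))
  nt <- ncol(weights)
  out <- matrix(0, nrow(weights), nt)
  for (t in seq_len(nt)) {
    out[, t] <- cov(training_data[, , t]) %*% weights[, t]
  }
  if (nt == 1) as.vector(out) else out
}

#' Temporal generalization of perceptual-state decoders
#'
#' Trains the [decode_timecourse()] classifier at every time point and tests
#' it at all time points under the same fold scheme, yielding a train-time x
#' test-time matrix of balanced accuracy whose diagonal equals the
#' within-time decoding curve.
#'
#' @inheritParams decode_timecourse
#' @return Object of class `tgm_result`: `tgm` (list per subject of
#'   train x test accuracy matrices), `accuracy` (diagonal tibble), `times`,
#'   `config`.
#' @export
temporal_generalization <- function(epochs, image_subset = NULL,
                                    config = decoder_config()) {
  res <- lapply(seq_len(n_subjects(epochs)), function(s) {
    smp <- decoder_samples(epochs, image_subset, subject = s)
    decode_subject(smp$pre, smp$post, cost = config$cost, tgm = TRUE)
  })
  accuracy <- purrr::map_dfr(seq_along(res), function(s) {
    tibble::tibble(subject = s, time = epochs$times, accuracy = res[[s]]$accuracy)
  })
  structure(
    list(
      tgm = lapply(res, `[[`, "tgm"), accuracy = accuracy,
      times = epochs$times, config = config
    ),
    class = "tgm_result"
  )
}
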