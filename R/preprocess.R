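#' Band specification for sensor-level filtering
#'
#' Two analysis bands are predefined: slow cortical potentials (`"scp"`,
#' band-pass 0.05-5 Hz, downsampled to 10 Hz) and the event-related field
#' range (`"erf"`, low-pass at 35 Hz with no high-pass, downsampled to
#' 100 Hz). Both use 3rd-order Butterworth filters applied forward-backward.
#'
#' @param name `"scp"` or `"erf"`, or any label when edges are given
#'   explicitly.
#' @param high_pass high-pass edge in Hz, or `NULL` for none.
#' @param low_pass low-pass edge in Hz.
#' @param target_rate sampling rate after decimation, in Hz.
#' @param order filter order.
#' @return A list of class `band_spec`.
#' @export
band_spec <- function(name = c("scp", "erf"), high_pass = NULL,
                      low_pass = NULL, target_rate = NULL, order = 3) {
  if (is.null(low_pass)) {
    name <- match.arg(name)
    spec <- switch(name,
      scp = list(name = "scp", high_pass = 0.05, low_pass = 5, target_rate = 10),
      erf = list(name = "erf", high_pass = NULL, low_pass = 35, target_rate = 100)
    )
  } else {
    spec <- list(
      name = name[[1]], high_pass = high_pass, low_pass = low_pass,
      target_rate = target_rate %||% (4 * low_pass)
    )
  }
  spec$order <- order
  if (spec$low_pass > spec$target_rate / 2) {
    abort("band's upper edge must be below the Nyquist frequency of the target rate")
  }
  structure(spec, class = "band_spec")
}

#' Zero-phase band filtering and downsampling of a continuous recording
#'
#' The recording is demeaned and linearly detrended per channel, filtered with
#' a 3rd-order Butterworth filter (band-pass, or low-pass only when the band
#' has no high-pass edge) applied forward and backward (zero phase), then
#' anti-alias filtered and decimated to the band's target rate. The time grid
#' is anchored at the first sample so that decimation keeps sample times on
#' the original grid.
#'
#' @param continuous a `continuous_recording` (see
#'   [simulate_continuous_recording()]) or a compatible list with `values`
#'   (sensors x samples), `sampling_rate`, `times`, `onsets`, `events`.
#' @param band a [band_spec()].
#' @param detrend logical; demean/detrend each channel first.
#' @return The filtered recording at the band's target rate, with a `band`
#'   element recording the spec.
#' @export
filter_band <- function(continuous, band, detrend = TRUE) {
  fs <- continuous$sampling_rate
  if (band$low_pass >= fs / 2) {
    abort("passband exceeds the Nyquist frequency of the input")
  }
  x <- continuous$values
  if (detrend) {
    n <- ncol(x)
    tt <- seq_len(n) - (n + 1) / 2
    x <- x - rowMeans(x)
    slope <- (x %*% tt) / sum(tt^2)
    x <- x - tcrossprod(as.vector(slope), tt)
  }

  if (is.null(band$high_pass)) {
    flt <- signal::butter(band$order, band$low_pass / (fs / 2), type = "low")
  } else {
    flt <- signal::butter(
      band$order, c(band$high_pass, band$low_pass) / (fs / 2), type = "pass"
    )
  }
  x <- t(apply(x, 1, function(ch) signal::filtfilt(flt, ch)))

  k <- fs / band$target_rate
  if (abs(k - round(k)) > 1e-8) {
    abort("input rate must be an integer multiple of the band's target rate")
  }
  k <- as.integer(round(k))
  if (k > 1) {
    aa <- signal::butter(4, 0.8 / k, type = "low") # anti-alias at 0.8 x target Nyquist
    x <- t(apply(x, 1, function(ch) signal::filtfilt(aa, ch)))
    idx <- seq(1, ncol(x), by = k)
    x <- x[, idx, drop = FALSE]
    continuous$times <- continuous$times[idx]
  }
  continuous$values <- x
  continuous$sampling_rate <- band$target_rate
  continuous$band <- band
  continuous
}

#' Epoch a continuous recording and baseline-correct
#'
#' Cuts 3.5 s epochs (-0.5 s to +3.0 s around each onset by default) and
#' subtracts, per sensor and trial, the mean over the pre-stimulus window
#' (tmin..0, inclusive). Onsets too close to the recording edges are dropped
#' with a warning. The epoch grid is anchored so that t = 0 falls on a
#' sample.
#'
#' @param continuous a (possibly band-filtered) continuous recording with
#'   `onsets` in seconds and an `events` table aligned to the onsets.
#' @param tmin,tmax epoch limits in seconds.
#' @return A [sensor_epochs()] object (one subject).
#' @export
epoch_and_baseline <- function(continuous, tmin = -0.5, tmax = 3.0) {
  fs <- continuous$sampling_rate
  x <- continuous$values
  n_samp <- ncol(x)
  n_pre <- round(-tmin * fs)
  n_post <- round(tmax * fs)
  rel <- seq(-n_pre, n_post)
  times <- rel / fs

  t0 <- continuous$times[1]
  onset_idx <- round((continuous$onsets - t0) * fs) + 1L
  keep <- onset_idx - n_pre >= 1 & onset_idx + n_post <= n_samp
  if (!all(keep)) {
    warn(sprintf(
      "dropping %d trial(s) too close to the recording edges", sum(!keep)
    ))
  }
  onset_idx <- onset_idx[keep]
  events <- continuous$events[keep, , drop = FALSE]

  arr <- array(0, dim = c(length(onset_idx), nrow(x), length(rel)))
  bl <- times <= 0
  for (i in seq_along(onset_idx)) {
    ep <- x[, onset_idx[i] + rel, drop = FALSE]
    ep <- ep - rowMeans(ep[, bl, drop = FALSE])
    arr[i, , ] <- ep
  }
  band <- if (!is.null(continuous$band)) continuous$band$name else "raw"
  sensor_epochs(
    values = arr, times = times, sampling_rate = fs, events = events,
    band = band
  )
}
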