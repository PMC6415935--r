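#' Construct a sensor-epochs container
#'
#' The package's central data structure: epoched multichannel sensor data for
#' one or more subjects, with a per-trial events table. Values are stored as
#' one `trials x sensors x time` array per subject (all subjects share the
#' trial schedule, time grid, and sensor count).
#'
#' @param values list (one element per subject) of 3-D numeric arrays with
#'   dimensions trials x sensors x time, or a single such array.
#' @param times numeric vector of peristimulus times in seconds, strictly
#'   increasing and uniform.
#' @param sampling_rate sampling rate in Hz.
#' @param events tibble with one row per trial (matching the first array
#'   dimension), as produced by [build_design()].
#' @param band band tag, e.g. `"raw"`, `"scp"`, `"erf"`.
#' @param normalized logical, whether sensor vectors have been z-scored.
#' @return An object of class `sensor_epochs`.
#' @export
sensor_epochs <- function(values, times, sampling_rate, events, band = "raw",
                          normalized = FALSE) {
  if (is.array(values) && length(dim(values)) == 3) values <- list(values)
  stopifnot(is.list(values), length(values) >= 1)
  d <- dim(values[[1]])
  for (v in values) {
    stopifnot(length(dim(v)) == 3, identical(dim(v), d))
  }
  if (d[3] != length(times)) {
    abort("time axis length does not match the third array dimension")
  }
  if (is.null(events)) abort("events table is required ('events' is missing)")
  if (nrow(events) != d[1]) {
    abort("events table rows do not match the trial dimension")
  }
  dt <- diff(times)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6) {
    abort("time axis must be strictly increasing and uniform")
  }
  structure(
    list(
      values = values, times = times, sampling_rate = sampling_rate,
      events = tibble::as_tibble(events), band = band, normalized = normalized
    ),
    class = "sensor_epochs"
  )
}

#' @export
print.sensor_epochs <- function(x, ...) {
  d <- dim(x$values[[1]])
  cat(sprintf(
    "<sensor_epochs> %d subject(s), %d trials, %d sensors, %d samples (%.2f..%.2f s @ %g Hz, band %s%s)\n",
    length(x$values), d[1], d[2], d[3], min(x$times), max(x$times),
    x$sampling_rate, x$band, if (x$normalized) ", normalized" else ""
  ))
  invisible(x)
}

n_subjects <- function(epochs) length(epochs$values)

#' Z-score sensor vectors at every time sample
#'
#' At every (subject, trial, time) the vector of sensor values is centred and
#' scaled to unit standard deviation, so that downstream pattern correlations
#' compare shapes rather than amplitudes. Idempotent up to numerical
#' precision.
#'
#' @param epochs a [sensor_epochs()] object with at least 2 sensors.
#' @return The normalized `sensor_epochs` object.
#' @export
normalize_across_sensors <- function(epochs) {
  d <- dim(epochs$values[[1]])
  if (d[2] < 2) abort("normalization across sensors needs >= 2 sensors")
  epochs$values <- lapply(seq_along(epochs$values), function(s) {
    x <- epochs$values[[s]]
    xp <- aperm(x, c(2, 1, 3)) # sensors first
    n <- d[2]
    m <- colMeans(xp) # trials x time
    ss <- colSums(xp^2)
    sdv <- sqrt(pmax(ss - n * m^2, 0) / (n - 1))
    bad <- which(sdv == 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(sprintf(
        "zero-variance sensor vector (subject %d, trial %d, sample %d)",
        s, bad[1, 1], bad[1, 2]
      ))
    }
    xp <- (xp - rep(as.vector(m), each = n)) / rep(as.vector(sdv), each = n)
    aperm(xp, c(2, 1, 3))
  })
  epochs$normalized <- TRUE
  epochs
}
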