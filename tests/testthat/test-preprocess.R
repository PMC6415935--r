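# analytic magnitude response of an order-n digital Butterworth filter
# applied forward-backward (zero phase squares the magnitude); the bilinear
# transform warps frequencies, so the analog ratio f/fc becomes a ratio of
# tangents when the sampling rate is given
butter_mag2 <- function(f, fc, order = 3, fs = NULL) {
  ratio <- if (is.null(fs)) f / fc else tan(pi * f / fs) / tan(pi * fc / fs)
  1 / (1 + ratio^(2 * order))
}

make_continuous <- function(values, fs) {
  list(
    values = values, sampling_rate = fs,
    times = (seq_len(ncol(values)) - 1) / fs,
    onsets = numeric(0), events = tibble::tibble()
  )
}

# least-squares amplitude of a sinusoid at frequency f (robust to the sample
# grid not hitting the peaks)
sine_amp <- function(x, tt, f) {
  fit <- lm(x ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt))
  sqrt(sum(coef(fit)[2:3]^2))
}

test_that("ERF band preserves DC and attenuates per the Butterworth response", {
  fs <- 600
  tt <- (0:(fs * 8 - 1)) / fs
  const <- make_continuous(matrix(2.5, 1, length(tt)), fs)
  out <- filter_band(const, band_spec("erf"), detrend = FALSE)
  expect_equal(out$sampling_rate, 100)
  mid <- seq(round(0.25 * ncol(out$values)), round(0.75 * ncol(out$values)))
  expect_true(all(abs(out$values[1, mid] - 2.5) < 1e-6))

  sine <- make_continuous(rbind(sin(2 * pi * 20 * tt)), fs)
  out20 <- filter_band(sine, band_spec("erf"), detrend = FALSE)
  mid <- seq(round(0.25 * ncol(out20$values)), round(0.75 * ncol(out20$values)))
  gain20 <- sine_amp(out20$values[1, mid], out20$times[mid], 20)
  # double-pass 3rd-order Butterworth at 35 Hz times the double-pass
  # 4th-order anti-alias filter at 0.8 x the 50 Hz target Nyquist
  expect_equal(gain20, butter_mag2(20, 35) * butter_mag2(20, 40, order = 4),
    tolerance = 0.02
  )

  # 50 Hz attenuation measured before decimation (target rate = input rate)
  sine50 <- make_continuous(rbind(sin(2 * pi * 50 * tt)), fs)
  bs <- band_spec("custom", low_pass = 35, target_rate = 600)
  out50 <- filter_band(sine50, bs, detrend = FALSE)
  mid <- seq(round(0.25 * ncol(out50$values)), round(0.75 * ncol(out50$values)))
  gain50 <- sine_amp(out50$values[1, mid], out50$times[mid], 50)
  expect_equal(gain50, butter_mag2(50, 35, fs = 600), tolerance = 0.02)
})

test_that("SCP band strongly attenuates drifts below the high-pass edge", {
  fs <- 100
  tt <- (0:(fs * 400 - 1)) / fs # 400 s to resolve 0.01 Hz
  sine <- make_continuous(rbind(sin(2 * pi * 0.01 * tt)), fs)
  out <- filter_band(sine, band_spec("scp"), detrend = FALSE)
  n <- ncol(out$values)
  mid <- round(n * 0.25):round(n * 0.75)
  expect_lt(sine_amp(out$values[1, mid], out$times[mid], 0.01), 0.5)
  # and passes mid-band frequencies essentially unchanged
  sine1 <- make_continuous(rbind(sin(2 * pi * 1 * tt)), fs)
  out1 <- filter_band(sine1, band_spec("scp"), detrend = FALSE)
  n <- ncol(out1$values)
  mid <- round(n * 0.25):round(n * 0.75)
  expect_equal(sine_amp(out1$values[1, mid], out1$times[mid], 1), 1,
    tolerance = 0.05
  )
})

test_that("band specifications validate their edges", {
  expect_error(band_spec("custom", low_pass = 40, target_rate = 60), "Nyquist")
  sine <- make_continuous(matrix(0, 1, 100), 50)
  expect_error(filter_band(sine, band_spec("erf")), "Nyquist")
})

test_that("epoching slices the recording exactly and baselines to zero", {
  fs <- 20
  n <- 400
  values <- matrix(rnorm(2 * n), 2, n)
  cont <- make_continuous(values, fs)
  cont$onsets <- c(2, 9.05) # second onset off-grid: rounded to nearest sample
  cont$events <- tibble::tibble(trial = 1:2)
  ep <- epoch_and_baseline(cont)
  expect_s3_class(ep, "sensor_epochs")
  # duration 3.5 s inclusive grid
  expect_equal(max(ep$times) - min(ep$times), 3.5)
  expect_equal(dim(ep$values[[1]])[3], 3.5 * fs + 1)
  # direct index-arithmetic oracle for trial 1, sensor 2
  i0 <- 2 * fs + 1
  sl <- values[2, (i0 - 10):(i0 + 60)]
  sl <- sl - mean(sl[1:11])
  expect_equal(ep$values[[1]][1, 2, ], sl)
  # baseline window mean is 0 for every sensor and trial
  bl <- ep$times <= 0
  for (i in 1:2) for (s in 1:2) {
    expect_equal(mean(ep$values[[1]][i, s, bl]), 0, tolerance = 1e-12)
  }
  # constant channel epochs to all zeros
  cont$values[1, ] <- 7
  ep2 <- epoch_and_baseline(cont)
  expect_true(all(abs(ep2$values[[1]][, 1, ]) < 1e-12))
})

test_that("events too close to the recording edges are dropped with a warning", {
  fs <- 20
  cont <- make_continuous(matrix(rnorm(100), 1, 100), fs)
  cont$onsets <- c(0.2, 1) # first onset lacks 0.5 s of history
  cont$events <- tibble::tibble(trial = 1:2)
  expect_warning(ep <- epoch_and_baseline(cont), "dropping 1")
  expect_equal(dim(ep$values[[1]])[1], 1)
  expect_equal(ep$events$trial, 2)
})

test_that("sensor-vector normalization is exact and idempotent", {
  arr <- array(rnorm(5 * 8 * 10, mean = 3, sd = 2), dim = c(5, 8, 10))
  ep <- normalize_across_sensors(manual_epochs(arr))
  for (i in c(1, 5)) for (t in c(1, 10)) {
    v <- ep$values[[1]][i, , t]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  ep2 <- normalize_across_sensors(ep)
  expect_equal(ep2$values[[1]], ep$values[[1]], tolerance = 1e-12)
  # Pearson r between normalized vectors equals dot product / (n - 1)
  a <- ep$values[[1]][1, , 1]
  b <- ep$values[[1]][2, , 1]
  expect_equal(cor(a, b), sum(a * b) / (length(a) - 1), tolerance = 1e-12)
  # zero-variance vector is an error naming the location
  arr[2, , 3] <- 5
  expect_error(normalize_across_sensors(manual_epochs(arr)), "trial 2, sample 3")
})

test_that("filtering then epoching preserves planted band-limited geometry", {
  d <- tiny_design(n_real = 2, n_runs = 3)
  gt <- make_ground_truth(d, n_sensors = 12, noise_sd = 0, seed = 11)
  # replace the default (onset-gated) envelopes with smooth ones so every
  # component is genuinely band-limited well below the 35 Hz edge
  gt$envelopes$evoked <- function(t) exp(-(t - 0.15)^2 / (2 * 0.1^2))
  gt$envelopes$stimulus <- function(t) exp(-(t - 0.25)^2 / (2 * 0.12^2))
  gt$envelopes$recognition <- function(t) exp(-(t - 1)^2 / (2 * 0.3^2))
  gt$envelopes$attention <- function(t) exp(-(t - 0.5)^2 / (2 * 0.15^2))
  cont <- simulate_continuous_recording(d, gt, sampling_rate = 100, seed = 1)
  ep_direct <- simulate_sensor_epochs(d, gt, sampling_rate = 100, seed = 1)
  ep_filt <- epoch_and_baseline(filter_band(cont, band_spec("erf")))
  expect_equal(ep_filt$sampling_rate, 100)
  # pairwise pattern correlations at a mid-epoch sample change by < 1%,
  # once the direct epochs get the same baseline correction
  bl <- ep_direct$times <= 0
  direct_bc <- ep_direct$values[[1]]
  for (i in seq_len(dim(direct_bc)[1])) {
    direct_bc[i, , ] <- direct_bc[i, , ] - rowMeans(direct_bc[i, , bl])
  }
  # compare at the stimulus peak, where every trial type carries signal
  ti <- which.min(abs(ep_direct$times - 0.25))
  tf <- which.min(abs(ep_filt$times - 0.25))
  p1 <- cor(t(direct_bc[1:10, , ti]))
  p2 <- cor(t(ep_filt$values[[1]][1:10, , tf]))
  expect_lt(max(abs(p1 - p2)), 0.01)
})

test_that("downsampling preserves the 3.5 s epoch span at both target rates", {
  d <- tiny_design(n_real = 1, n_catch = 0, n_runs = 2)
  gt <- make_ground_truth(d, n_sensors = 8, noise_sd = 0.1, seed = 3)
  cont <- simulate_continuous_recording(d, gt, sampling_rate = 600, seed = 2)
  for (band in c("scp", "erf")) {
    ep <- epoch_and_baseline(filter_band(cont, band_spec(band)))
    expect_equal(max(ep$times) - min(ep$times), 3.5)
    expect_equal(ep$sampling_rate, band_spec(band)$target_rate)
    expect_equal(ep$band, band)
  }
})
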