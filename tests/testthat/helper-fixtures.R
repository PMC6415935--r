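# Shared small fixtures, built in code. A session-level cache avoids
# re-simulating the same mid-sized fixture in several test files.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

# Tiny design: 4 real sets, no catch, 3 runs (block = 10 trials).
tiny_design <- function(seed = 1, n_real = 4, n_catch = 0, n_runs = 3) {
  build_design(n_real, n_catch, n_runs, seed = seed)
}

# Mid-sized normalized epochs with default planted structure.
small_epochs <- function() {
  cached("small_epochs", {
    d <- build_design(6, 2, 5, seed = 1)
    gt <- make_ground_truth(d, n_sensors = 24, seed = 2)
    normalize_across_sensors(
      simulate_sensor_epochs(d, gt, n_subjects = 3, sampling_rate = 20, seed = 3)
    )
  })
}

# Noise-free epochs (deterministic planted geometry).
noiseless_epochs <- function() {
  cached("noiseless_epochs", {
    d <- build_design(4, 1, 6, seed = 4)
    gt <- make_ground_truth(d, n_sensors = 16, noise_sd = 0, seed = 5)
    simulate_sensor_epochs(d, gt, n_subjects = 1, sampling_rate = 20, seed = 6)
  })
}

# Epochs container assembled by hand from an arbitrary array.
manual_epochs <- function(arr, srate = 20, tmin = -0.5) {
  nt <- dim(arr)[3]
  times <- tmin + (seq_len(nt) - 1) / srate
  events <- tibble::tibble(
    run = 1L, block = 1L, trial_in_block = seq_len(dim(arr)[1]),
    trial = seq_len(dim(arr)[1]), set_id = "s01", image_id = "s01",
    image_type = "mooney", stage = "pre", set_type = "real",
    presentation = seq_len(dim(arr)[1])
  )
  sensor_epochs(arr, times, srate, events)
}

# Brute-force separability oracle: explicit double loops, Fisher z per pair.
oracle_separability <- function(x, y) {
  fz <- function(r) atanh(pmin(pmax(r, -(1 - 1e-10)), 1 - 1e-10))
  m <- nrow(x); n <- nrow(y)
  wx <- c(); for (i in 1:(m - 1)) for (j in (i + 1):m) wx <- c(wx, fz(cor(x[i, ], x[j, ])))
  wy <- c(); for (i in 1:(n - 1)) for (j in (i + 1):n) wy <- c(wy, fz(cor(y[i, ], y[j, ])))
  bt <- c(); for (i in 1:m) for (j in 1:n) bt <- c(bt, fz(cor(x[i, ], y[j, ])))
  (mean(wx) + mean(wy)) / 2 - mean(bt)
}

# Brute-force cross-validated squared Euclidean oracle (explicit fold loop,
# fold j against the held-out mean).
oracle_cv_euclidean <- function(x_trials, y_trials, n_folds = 3) {
  m <- nrow(x_trials); n <- nrow(y_trials)
  fx <- sort(rep(seq_len(n_folds), length.out = m))
  fy <- sort(rep(seq_len(n_folds), length.out = n))
  total <- 0
  for (j in seq_len(n_folds)) {
    xa <- colMeans(x_trials[fx == j, , drop = FALSE])
    ya <- colMeans(y_trials[fy == j, , drop = FALSE])
    xb <- colMeans(x_trials[fx != j, , drop = FALSE])
    yb <- colMeans(y_trials[fy != j, , drop = FALSE])
    total <- total + sum((xa - ya) * (xb - yb))
  }
  total / n_folds
}

# Commonality oracle via explicit normal-equation regressions (solve()).
oracle_r2 <- function(y, X) {
  X <- cbind(1, X)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  1 - sum(res^2) / sum((y - mean(y))^2)
}

oracle_commonality_shared <- function(meg, fmri, m1) {
  r <- function(v) rank(v, ties.method = "average")
  y <- r(meg)
  oracle_r2(y, cbind(r(fmri))) + oracle_r2(y, cbind(r(m1))) -
    oracle_r2(y, cbind(r(fmri), r(m1)))
}

oracle_commonality_unique <- function(meg, fmri, m1, m2) {
  r <- function(v) rank(v, ties.method = "average")
  y <- r(meg); f <- r(fmri); a <- r(m1); b <- r(m2)
  oracle_r2(y, cbind(f, b)) + oracle_r2(y, cbind(a, b)) -
    oracle_r2(y, cbind(b)) - oracle_r2(y, cbind(f, a, b))
}
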