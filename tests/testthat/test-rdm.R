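test_that("pattern distances match hand-expanded formulas", {
  x <- c(1, 0, 2)
  y <- c(0, 1, 2)
  # 1 - Pearson r by hand: centered x = (0,-1,1), y = (-1,0,1)
  r_hand <- sum(c(0, -1, 1) * c(-1, 0, 1)) /
    (sqrt(sum(c(0, -1, 1)^2)) * sqrt(sum(c(-1, 0, 1)^2)))
  expect_equal(pattern_distance(x, y, "one_minus_r"), 1 - r_hand)
  expect_equal(pattern_distance(x, y, "euclidean"), 1 + 1 + 0)
  expect_equal(pattern_distance(x, x, "one_minus_r"), 0)
  expect_equal(pattern_distance(x, x, "euclidean"), 0)
  expect_error(pattern_distance(c(1, 1, 1), y, "one_minus_r"), "zero-variance")
})

test_that("cross-validated Euclidean distance collapses to the plain squared
           distance on identical folds and matches the fold-loop oracle", {
  withr::with_seed(21, {
    x <- rnorm(6)
    y <- rnorm(6)
    xt <- matrix(rep(x, each = 6), 6) # six identical trials
    yt <- matrix(rep(y, each = 6), 6)
    expect_equal(
      pattern_distance(metric = "cv_euclidean", x_trials = xt, y_trials = yt),
      sum((x - y)^2),
      tolerance = 1e-12
    )
    expect_equal(
      pattern_distance(metric = "cv_euclidean", x_trials = xt, y_trials = xt), 0
    )
    # noisy trials with fold-specific offsets against the explicit oracle
    for (k in 1:20) {
      xt <- matrix(rnorm(6 * 4), 6)
      yt <- matrix(rnorm(6 * 4), 6)
      expect_equal(
        pattern_distance(metric = "cv_euclidean", x_trials = xt, y_trials = yt),
        oracle_cv_euclidean(xt, yt),
        tolerance = 1e-10
      )
    }
  })
})

test_that("cv distance is unbiased under identical true patterns while the
           plain distance is positively biased", {
  withr::with_seed(31, {
    mu <- rnorm(8)
    cvs <- plain <- numeric(300)
    for (k in seq_len(300)) {
      xt <- matrix(mu, 6, 8, byrow = TRUE) + matrix(rnorm(48, sd = 1), 6)
      yt <- matrix(mu, 6, 8, byrow = TRUE) + matrix(rnorm(48, sd = 1), 6)
      cvs[k] <- pattern_distance(metric = "cv_euclidean", x_trials = xt, y_trials = yt)
      plain[k] <- pattern_distance(colMeans(xt), colMeans(yt), "euclidean")
    }
    expect_lt(abs(mean(cvs)), 3 * sd(cvs) / sqrt(300))
    expect_gt(mean(plain), 10 * sd(plain) / sqrt(300))
  })
})

test_that("presentation averaging matches direct arithmetic and validates k", {
  ep <- noiseless_epochs()
  pre <- average_presentations(ep, "pre", k = 3)
  ev <- ep$events
  rows <- which(ev$image_type == "mooney" & ev$stage == "pre" &
    ev$set_id == "s01" & ev$presentation <= 3)
  ti <- 15
  expect_equal(
    pre["s01", , ti],
    (ep$values[[1]][rows[1], , ti] + ep$values[[1]][rows[2], , ti] +
      ep$values[[1]][rows[3], , ti]) / 3
  )
  one <- average_presentations(ep, "pre", k = 1)
  first <- which(ev$image_type == "mooney" & ev$stage == "pre" &
    ev$set_id == "s01" & ev$presentation == 1)
  expect_equal(one["s01", , ], ep$values[[1]][first, , ])
  expect_error(average_presentations(ep, "gray", k = 5), "presentations")
})

test_that("RDM series has the full 99 x 99 layout with consistent blocks", {
  skip_if_not(requireNamespace("testthat", quietly = TRUE))
  d <- build_design(33, 6, 14, seed = 2)
  gt <- make_ground_truth(d, n_sensors = 12, seed = 3)
  ep <- normalize_across_sensors(
    simulate_sensor_epochs(d, gt, sampling_rate = 10, tmax = 0.5, seed = 4)
  )
  rs <- rdm_series(ep, "one_minus_r")
  m <- rs$values[[1]][, , 3]
  expect_equal(dim(m), c(99, 99))
  expect_equal(m, t(m))
  expect_true(all(is.na(diag(m))))
  # catch sets excluded
  expect_equal(length(rs$image_ids), 33)
  # spot-check 5 random cells against the pairwise oracle
  pats <- mooneyrsa:::stack_condition_patterns(ep, subject = 1)
  withr::with_seed(5, {
    for (k in 1:5) {
      ij <- sample(99, 2)
      expect_equal(
        m[ij[1], ij[2]],
        pattern_distance(pats[ij[1], , 3], pats[ij[2], , 3], "one_minus_r"),
        tolerance = 1e-12
      )
    }
  })
  # block views
  expect_equal(block_view(m, "pre", "pre"), t(block_view(m, "pre", "pre")))
  expect_equal(block_view(m, "pre", "gray"), t(block_view(m, "gray", "pre")))
  pg <- block_view(m, "post", "gray")
  expect_equal(rownames(pg), paste0("post:", rs$image_ids))
  expect_equal(colnames(pg), paste0("gray:", rs$image_ids))
  # diagonal of the Post-Gray block addresses matching image pairs
  expect_equal(
    sub("^post:", "", rownames(pg)), sub("^gray:", "", colnames(pg))
  )
  expect_error(block_view(m, "pre", "nope"), "unknown condition")
})

test_that("row/column permutation of the patterns conjugates the RDM", {
  withr::with_seed(8, {
    pats <- array(rnorm(9 * 6 * 2), dim = c(9, 6, 2),
      dimnames = list(rdm_labels(c("a", "b", "c")), NULL, NULL)
    )
    m1 <- mooneyrsa:::rdm_from_patterns(pats, "one_minus_r")
    perm <- c(2, 3, 1)
    idx <- c(perm, 3 + perm, 6 + perm)
    m2 <- mooneyrsa:::rdm_from_patterns(pats[idx, , , drop = FALSE], "one_minus_r")
    expect_equal(m2[, , 1], m1[idx, idx, 1])
  })
})

test_that("correlation RDMs are invariant to per-time affine sensor rescaling", {
  ep <- small_epochs()
  rs1 <- rdm_series(ep, "one_minus_r")
  ep2 <- ep
  ep2$values <- lapply(ep$values, function(v) 3.7 * v + 2)
  rs2 <- rdm_series(ep2, "one_minus_r")
  expect_equal(rs1$values[[1]], rs2$values[[1]], tolerance = 1e-10)
})

test_that("within-condition dissimilarity summarises the upper triangle", {
  # hand-filled 3-image block: mean of the three distinct pairs
  ep <- small_epochs()
  rs <- rdm_series(ep, "one_minus_r")
  n <- length(rs$image_ids)
  idx <- mooneyrsa:::block_index("post", n)
  blk <- rs$values[[2]][idx, idx, 4]
  tc <- within_condition_dissimilarity_timecourse(rs, "post")
  expect_equal(
    tc$dissimilarity[tc$subject == 2 & tc$time == rs$times[4]],
    mean(blk[upper.tri(blk)])
  )
})

test_that("intra-RDM geometry correlations behave at the limits", {
  ep <- small_epochs()
  rs <- rdm_series(ep, "one_minus_r")
  # identical blocks -> r = 1 before the final transform
  z <- intra_rdm_correlation(rs, "pre", "pre")
  expect_true(all(tanh(z$z) > 1 - 1e-6))
  # independent random blocks -> near zero on average
  withr::with_seed(12, {
    rr <- replicate(50, {
      pats <- array(rnorm(9 * 10), dim = c(9, 10, 1),
        dimnames = list(rdm_labels(c("a", "b", "c")), NULL, NULL)
      )
      fake <- structure(
        list(
          values = list(mooneyrsa:::rdm_from_patterns(pats, "one_minus_r")),
          times = 0, metric = "one_minus_r", image_ids = c("a", "b", "c")
        ),
        class = "rdm_series"
      )
      tanh(intra_rdm_correlation(fake, "pre", "gray")$z)
    })
    expect_lt(abs(mean(rr)), 3 * sd(rr) / sqrt(length(rr)))
  })
})

test_that("planted stimulus geometry peaks before recognition geometry", {
  ep <- small_epochs()
  rs <- rdm_group_average(rdm_series(ep, "one_minus_r"))
  stim <- intra_rdm_correlation(rs, "pre", "post")
  recog <- intra_rdm_correlation(rs, "post", "gray")
  t_stim <- stim$time[stim$time > 0][which.max(stim$z[stim$time > 0])]
  t_recog <- recog$time[recog$time > 0][which.max(recog$z[recog$time > 0])]
  expect_lt(t_stim, t_recog)
  # stimulus geometry is strong between stages; absent against grayscale early
  early <- stim$time > 0.1 & stim$time < 0.35
  ctrl <- intra_rdm_correlation(rs, "pre", "gray")
  expect_gt(mean(stim$z[early]), mean(ctrl$z[early]))
})
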