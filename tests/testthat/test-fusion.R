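test_that("ROI RDMs are 1 - r with hand-checkable entries", {
  pats <- rbind(
    a = c(1, 0, 2, 1), b = c(1, 0, 2, 1), c = c(0, 2, 1, 3)
  )
  rr <- roi_rdm(list(R = pats))$R
  expect_equal(rr["a", "b"], 0, tolerance = 1e-12) # duplicate patterns
  expect_equal(rr["a", "c"], 1 - cor(pats["a", ], pats["c", ]))
  expect_equal(rr["b", "c"], rr["c", "b"])
  expect_true(all(is.na(diag(rr))))
  pats2 <- rbind(a = rep(1, 4), b = c(1, 2, 3, 4))
  expect_error(roi_rdm(list(R = pats2)), "zero-variance")
})

test_that("model RSA hits the limiting cases", {
  model <- build_model_rdm("attention", 4)
  # model used as its own data -> rho 1 wherever defined
  arr <- array(unclass(model), dim = c(12, 12, 2))
  rs <- structure(
    list(values = list(arr), times = c(0, 0.1), metric = "one_minus_r",
      image_ids = sprintf("s%02d", 1:4)
    ),
    class = "rdm_series"
  )
  tc <- model_rsa_timecourse(rs, model)
  expect_equal(tc$rho, c(1, 1))
  # independent random data -> rho near 0 on average
  withr::with_seed(81, {
    rhos <- replicate(60, {
      a <- matrix(rnorm(144), 12)
      a <- a + t(a)
      arr <- array(a, dim = c(12, 12, 1))
      rs$values <- list(arr)
      rs$times <- 0
      model_rsa_timecourse(rs, model)$rho
    })
    expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(length(rhos)))
  })
})

test_that("commonality terms match the normal-equations oracle", {
  withr::with_seed(82, {
    n <- 4 # 12 x 12 matrices, plenty of usable cells
    for (k in 1:40) {
      sym <- function() {
        m <- matrix(rnorm(144), 12)
        m <- m + t(m)
        diag(m) <- NA
        m
      }
      meg <- sym(); fmri <- sym(); m1 <- sym(); m2 <- sym()
      sup <- mooneyrsa:::shared_support(meg, fmri, m1)
      cs <- commonality_shared(meg, fmri, m1)
      expect_lt(
        abs(cs$commonality - oracle_commonality_shared(meg[sup], fmri[sup], m1[sup])),
        1e-10
      )
      sup4 <- mooneyrsa:::shared_support(meg, fmri, m1, m2)
      cu <- commonality_unique(meg, fmri, m1, m2)
      expect_lt(
        abs(cu$commonality -
          oracle_commonality_unique(meg[sup4], fmri[sup4], m1[sup4], m2[sup4])),
        1e-10
      )
      # R^2 never decreases when predictors are added
      expect_gte(cs$r2$r2_fmri_m1, cs$r2$r2_fmri - 1e-12)
      expect_gte(cs$r2$r2_fmri_m1, cs$r2$r2_m1 - 1e-12)
      expect_gte(cu$r2$r2_fmri_m1_m2, cu$r2$r2_fmri_m2 - 1e-12)
      expect_gte(cu$r2$r2_fmri_m1_m2, cu$r2$r2_m1_m2 - 1e-12)
      expect_gte(cu$r2$r2_m1_m2, cu$r2$r2_m2 - 1e-12)
    }
  })
})

test_that("commonality limiting cases behave as the algebra requires", {
  withr::with_seed(83, {
    sym <- function() {
      m <- matrix(rnorm(144), 12)
      m <- m + t(m)
      diag(m) <- NA
      m
    }
    meg <- sym(); fmri <- sym(); m2 <- sym()
    # model identical to the fMRI RDM: C equals R2(MEG ~ fMRI) exactly
    expect_warning(cs <- commonality_shared(meg, fmri, fmri), "rank-deficient")
    expect_equal(cs$commonality, cs$r2$r2_fmri, tolerance = 1e-10)
    # m1 == m2: no unique variance (two predictor sets are rank-deficient)
    cu <- suppressWarnings(commonality_unique(meg, fmri, m2, m2))
    expect_equal(cu$commonality, 0, tolerance = 1e-10)
    # near-orthogonal fMRI: shared commonality collapses toward 0
    ortho <- replicate(200, {
      meg <- sym(); fmri <- sym(); m1 <- sym()
      commonality_shared(meg, fmri, m1)$commonality
    })
    expect_lt(abs(mean(ortho)), 3 * sd(ortho) / sqrt(length(ortho)) + 1e-3)
  })
})

test_that("variance partition closes: shared + unique terms recombine", {
  withr::with_seed(84, {
    sym <- function() {
      m <- matrix(rnorm(100), 10)
      m <- m + t(m)
      diag(m) <- NA
      m
    }
    for (k in 1:20) {
      meg <- sym(); fmri <- sym(); m1 <- sym(); m2 <- sym()
      sup <- mooneyrsa:::shared_support(meg, fmri, m1, m2)
      r <- function(v) rank(v)
      y <- r(meg[sup]); f <- r(fmri[sup]); a <- r(m1[sup]); b <- r(m2[sup])
      # decompose R2(y ~ f) into 4 commonality components over {m1, m2}:
      # unique-to-f + shared(f,m1 | m2) + shared(f,m2 | m1) + shared(f,m1,m2)
      r2 <- function(X) oracle_r2(y, X)
      u_f <- r2(cbind(f, a, b)) - r2(cbind(a, b))
      c_fa <- r2(cbind(f, b)) + r2(cbind(a, b)) - r2(cbind(b)) - r2(cbind(f, a, b))
      c_fb <- r2(cbind(f, a)) + r2(cbind(a, b)) - r2(cbind(a)) - r2(cbind(f, a, b))
      c_fab <- r2(cbind(f)) + r2(cbind(a)) + r2(cbind(b)) -
        r2(cbind(f, a)) - r2(cbind(f, b)) - r2(cbind(a, b)) + r2(cbind(f, a, b))
      expect_equal(u_f + c_fa + c_fb + c_fab, r2(cbind(f)), tolerance = 1e-10)
      # and the package's unique commonality equals the c_fa component
      expect_equal(
        commonality_unique(meg, fmri, m1, m2)$commonality, c_fa, tolerance = 1e-10
      )
    }
  })
})

test_that("fast commonality time course equals the per-slice evaluation", {
  withr::with_seed(85, {
    arr <- array(rnorm(12 * 12 * 4), dim = c(12, 12, 4))
    for (t in 1:4) {
      arr[, , t] <- arr[, , t] + t(arr[, , t])
      diag(arr[, , t]) <- NA
    }
    fmri <- matrix(rnorm(144), 12); fmri <- fmri + t(fmri); diag(fmri) <- NA
    m1 <- build_model_rdm("stimulus", 4)
    m2 <- build_model_rdm("recognition", 4)
    tc <- mooneyrsa:::commonality_timecourse(arr, fmri, m1, m2, type = "unique")
    for (t in 1:4) {
      expect_equal(
        tc[t], commonality_unique(arr[, , t], fmri, m1, m2)$commonality,
        tolerance = 1e-10
      )
    }
    tca <- mooneyrsa:::commonality_timecourse(arr, fmri, m1, type = "shared")
    for (t in 1:4) {
      expect_equal(
        tca[t], commonality_shared(arr[, , t], fmri, m1)$commonality,
        tolerance = 1e-10
      )
    }
  })
})

test_that("upper bound reaches 1 for identical RDMs and bounds commonality", {
  ep <- small_epochs()
  rs <- rdm_group_average(rdm_series(ep, "one_minus_r"))
  selfbound <- fusion_upper_bound(rs, rs$values[[1]][, , 5])
  expect_equal(selfbound$bound[5], 1, tolerance = 1e-10)

  d <- attr(ep$events, "sets")
  gt <- make_ground_truth(tiny_design(n_real = 6, n_catch = 2, n_runs = 5, seed = 1),
    n_sensors = 24, seed = 2
  )
  roi <- simulate_roi_patterns(gt, seed = 3)
  rr <- roi_rdm(roi)
  n <- length(rs$image_ids)
  models <- list(
    stimulus = build_model_rdm("stimulus", n, image_ids = rs$image_ids),
    recognition = build_model_rdm("recognition", n, image_ids = rs$image_ids),
    attention = build_model_rdm("attention", n, image_ids = rs$image_ids)
  )
  fm <- fusion_map(rs, rr, models = models, n_perm = 60, seed = 4)
  # shared commonality never exceeds the ROI's upper bound (the variance
  # partition gives C = R2f + R2m - R2fm <= R2f); audited on 20 random
  # (roi, time) cells. Unique commonalities are excluded: suppression can
  # push individual partition components above the bound.
  shared <- merge(
    fm$map[fm$map$model == "attention", ], fm$upper_bound, by = c("roi", "time")
  )
  withr::with_seed(86, {
    rows <- sample(nrow(shared), 20)
    expect_true(all(shared$commonality[rows] <= shared$bound[rows] + 1e-8))
  })
})

test_that("planted ROI profiles drive the fusion maps the right way", {
  ep <- small_epochs()
  rs <- rdm_group_average(rdm_series(ep, "one_minus_r"))
  gt_small <- make_ground_truth(
    build_design(6, 2, 5, seed = 1), n_sensors = 24, seed = 2
  )
  roi <- simulate_roi_patterns(gt_small, seed = 5)
  rr <- roi_rdm(roi)
  # stimulus-dominant ROI correlates with the stimulus model far above the
  # recognition model
  n <- length(rs$image_ids)
  stim <- build_model_rdm("stimulus", n, image_ids = rs$image_ids)
  recog <- build_model_rdm("recognition", n, image_ids = rs$image_ids)
  sup_s <- mooneyrsa:::shared_support(rr$V1, stim)
  sup_r <- mooneyrsa:::shared_support(rr$V1, recog)
  rho_s <- cor(rank(rr$V1[sup_s]), rank(stim[sup_s]))
  rho_r <- cor(rank(rr$V1[sup_r]), rank(recog[sup_r]))
  expect_gt(rho_s, rho_r + 0.2)
})
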