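# Lowest-point trace, forward-swing window, per-stride mFC, late-swing
# locations, density heatmap and the clearance trend.

test_that("lowest-point trace picks the minimum height with first-index ties", {
  h <- matrix(c(3, 1, 2, 2, 2, 2) * 1e-3, nrow = 3)   # 3 points x 2 samples
  tr <- lowest_point_trace(h, point_ids = 11:13)
  expect_equal(tr$lp, c(1e-3, 2e-3))
  expect_equal(tr$lp_index, c(12, 11))   # tie at sample 2 -> first index
})

test_that("lowest-point trace equals brute force over random poses", {
  cl <- coarse_cloud()
  calib <- frame_calibration()
  set.seed(7)
  K <- 40
  R <- array(0, c(3, 3, K))
  pos <- matrix(stats::rnorm(K * 3, sd = 0.1), K, 3)
  for (k in 1:K) {
    R[, , k] <- footclear:::rotvec_to_matrix(stats::rnorm(3, sd = 0.15))
  }
  pose <- structure(list(rotation = R, position = pos, sample_rate = 128,
                         time = (1:K) / 128), class = "pose_trajectory")
  hs <- footclear:::point_heights(pose, calib, cl, cl$sole_indices)
  tr <- lowest_point_trace(hs, cl$sole_indices)
  for (k in seq(1, K, 7)) {
    w <- transform_cloud(pose, k, calib, cl)
    expect_equal(tr$lp[k], min(w[cl$sole_indices, 3]), tolerance = 1e-12)
  }
})

test_that("forward-swing window runs from heel peak to toe peak", {
  zm <- zupt_mask(rep(c(TRUE, FALSE), c(5, 45)))
  stride <- data.frame(stride_id = 1, zupt_start = 1, zupt_end = 6,
                       stride_end = 51)
  heel <- rep(0, 50); heel[11] <- 1
  toe <- rep(0, 50); toe[31] <- 1
  w <- forward_swing_window(stride, heel, toe, zm)
  expect_true(w$valid)
  expect_equal(c(w$k_max_heel, w$k_max_toe), c(11, 31))

  # toe peak before heel peak: flagged invalid, never an error
  w2 <- forward_swing_window(stride, toe, heel, zm)
  expect_false(w2$valid)
  sc <- stride_mfc(rep(0.01, 50), rep(1L, 50), w2)
  expect_false(sc$valid)
  expect_true(is.na(sc$mfc))

  # generator oracle: window brackets the swing and the true mFC instant
  b <- sim_bout("typical", seed = 1, n_strides = 5)
  seg <- b$truth$segmentation
  for (i in 1:5) {
    s <- b$oracle$strides[[i]]
    expect_true(s$valid)
    expect_gte(s$k_max_heel, seg$zupt_end[i])
    expect_lt(s$k_max_toe, seg$stride_end[i])
    expect_true(s$k_mfc >= s$k_max_heel && s$k_mfc <= s$k_max_toe)
    # mFC is the window minimum: no lp in the window lies below it
    expect_true(all(b$oracle$lp[s$k_max_heel:s$k_max_toe] >= s$mfc))
  }
})

test_that("mFC takes the window minimum and preserves negative clearance", {
  w <- list(k_max_heel = 5, k_max_toe = 15, valid = TRUE)
  lp <- rep(0.005, 20)
  sc <- stride_mfc(lp, rep(3L, 20), w)
  expect_equal(sc$mfc, 0.005)
  expect_equal(sc$k_mfc, 5)    # first minimizing sample

  lp[10] <- -0.002
  sc2 <- stride_mfc(lp, rep(3L, 20), w)
  expect_equal(sc2$mfc, -0.002)
  expect_equal(sc2$k_mfc, 10)

  # closed loop: pipeline mFC within 1 mm of the analytic oracle
  ba <- analyzed_bout("typical", seed = 1, n_strides = 5)
  b <- sim_bout("typical", seed = 1, n_strides = 5)
  expect_lt(max(abs(mfc_of(ba$strides) - mfc_of(b$oracle$strides))), 1e-3)
})

test_that("late swing is exactly the final third of the window", {
  cl <- test_cloud()
  w <- list(k_max_heel = 1, k_max_toe = 31, valid = TRUE)
  locs <- late_swing_lowest_locations(w, rep(cl$toe_index, 40), cl)
  expect_equal(nrow(locs), 11)    # samples 21..31
  expect_true(all(locs[, 1] == cl$points[cl$toe_index, 1]))

  # window-length property over assorted windows
  for (W in c(3, 7, 10, 23)) {
    wv <- list(k_max_heel = 2, k_max_toe = 2 + W, valid = TRUE)
    n <- nrow(late_swing_lowest_locations(wv, rep(cl$toe_index, 40), cl))
    expect_gte(n, floor(W / 3))
    expect_lte(n, ceiling(W / 3) + 1)
  }

  wshort <- list(k_max_heel = 5, k_max_toe = 7, valid = TRUE)
  expect_warning(locs0 <- late_swing_lowest_locations(wshort, rep(1L, 10), cl))
  expect_equal(nrow(locs0), 0)
})

test_that("foot-drop late-swing lowest points sit in the forefoot third", {
  b <- sim_bout("foot_drop", seed = 2, n_strides = 5)
  cl <- test_cloud()
  locs <- do.call(rbind, lapply(b$oracle$strides, function(s) {
    late_swing_lowest_locations(list(k_max_heel = s$k_max_heel,
                                     k_max_toe = s$k_max_toe, valid = TRUE),
                                b$oracle$lp_index, cl)
  }))
  sole_x <- range(cl$points[cl$sole_indices, 1])
  thr <- sole_x[2] - diff(sole_x) / 3
  expect_gt(mean(locs[, 1] > thr), 0.7)
})

test_that("sole heatmap matches direct Gaussian summation and normalizes to 1", {
  cl <- coarse_cloud()
  hm0 <- sole_density_heatmap(matrix(numeric(0), 0, 2), cl)
  expect_true(all(hm0$density == 0))

  one <- matrix(c(0.02, 0.01), 1, 2)
  hm1 <- sole_density_heatmap(one, cl, spacing = 0.002, sigma = 0.01)
  expect_equal(max(hm1$density), 1)
  ix <- which.min(abs(hm1$grid_x - 0.02))
  iy <- which.min(abs(hm1$grid_y - 0.01))
  expect_equal(hm1$density[ix, iy], 1)
  expect_equal(hm1$density[ix + 1, iy], exp(-0.002^2 / (2 * 0.01^2)),
               tolerance = 1e-9)

  set.seed(3)
  locs <- rbind(matrix(stats::rnorm(40, 0.08, 0.01), 20, 2),
                matrix(stats::rnorm(40, -0.08, 0.01), 20, 2))
  locs[, 2] <- locs[, 2] / 4
  hm <- sole_density_heatmap(locs, cl, spacing = 0.004, sigma = 0.008)
  # brute-force double loop
  ref <- matrix(0, length(hm$grid_x), length(hm$grid_y))
  for (i in seq_along(hm$grid_x)) for (j in seq_along(hm$grid_y)) {
    ref[i, j] <- sum(exp(-((hm$grid_x[i] - locs[, 1])^2 +
                             (hm$grid_y[j] - locs[, 2])^2) / (2 * 0.008^2)))
  }
  expect_equal(hm$density, ref / max(ref), tolerance = 1e-9)
  expect_equal(sum(hm$marginal_x), nrow(locs))
  expect_equal(sum(hm$marginal_y), nrow(locs))

  # doubling every location's multiplicity leaves the density unchanged
  hm2 <- sole_density_heatmap(rbind(locs, locs), cl, spacing = 0.004,
                              sigma = 0.008)
  expect_equal(hm2$density, hm$density, tolerance = 1e-12)
})

test_that("clearance trend recovers constructed and noisy declines", {
  mk <- function(t, mfc) {
    s <- list(stride_id = 1L, t_start = t, k_max_heel = 1L, k_max_toe = 2L,
              mfc = mfc, k_mfc = 1L, i_mfc = 1L, valid = TRUE)
    class(s) <- "stride_clearance"
    s
  }
  const <- lapply(0:9, function(i) mk(i * 1.1, 0.02))
  tr <- clearance_trend(const)
  expect_equal(tr$slope_mm_per_min, 0, tolerance = 1e-12)
  expect_equal(tr$p_value, 1)

  lin <- lapply(0:9, function(i) mk(i * 60, 0.02 - i * 0.001))
  tr2 <- clearance_trend(lin)
  expect_equal(tr2$slope_mm_per_min, -1, tolerance = 1e-9)

  set.seed(8)
  noisy <- lapply(0:199, function(i) {
    mk(i * 1.1, 0.02 - i * 1.1 / 60 * 0.001 + stats::rnorm(1, 0, 0.002))
  })
  tr3 <- clearance_trend(noisy)
  # analytic slope SE: sigma / (sd(t) * sqrt(n)) = 2 / (1.06 * 14.1) mm/min
  expect_lt(abs(tr3$slope_mm_per_min - (-1)), 2 * 0.134)
  expect_lt(tr3$p_value, 0.001)

  expect_error(clearance_trend(const[1:2]), class = "footclear_data_error")
})
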