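# Fixture calibration, support-plane fitting, the flat-foot correction R*,
# rigid cloud propagation and the floor offset.

test_that("fixture rotation recovers exact and perturbed axis sets", {
  cl <- test_cloud()
  expect_equal(fixture_rotation(cl), diag(3), tolerance = 1e-12)

  # axes rotated 90 degrees about z: rows are IMU axes in scan coordinates
  rot90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  cl2 <- cl; cl2$fixture_axes <- rot90
  expect_equal(fixture_rotation(cl2), rot90, tolerance = 1e-12)

  # 2-degree non-orthogonality: compare with a brute-force Procrustes
  # oracle minimizing the Frobenius distance over rotation vectors
  skew <- footclear:::rotvec_to_matrix(c(0, 0, 2 * pi / 180))
  ax <- diag(3); ax[1, ] <- ax[1, ] %*% t(skew)   # x tilted toward y
  cl3 <- cl; cl3$fixture_axes <- ax
  got <- fixture_rotation(cl3)
  obj <- function(v) {
    sum((footclear:::rotvec_to_matrix(v) - ax)^2)
  }
  op <- stats::optim(c(0, 0, 0), obj, method = "BFGS",
                     control = list(reltol = 1e-14))
  oracle <- footclear:::rotvec_to_matrix(op$par)
  expect_equal(got, oracle, tolerance = 1e-6)

  cl4 <- cl; cl4$fixture_axes <- rbind(c(1, 0, 0), c(1, 0.05, 0), c(0, 0, 1))
  expect_error(fixture_rotation(cl4), class = "footclear_calibration_error")
})

test_that("support plane is flush against flat and tilted soles", {
  g <- as.matrix(expand.grid(x = seq(-0.1, 0.1, 0.02),
                             y = seq(-0.05, 0.05, 0.02)))
  flat <- cbind(g, 0.37)
  pl <- fit_support_plane(flat)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(pl$offset, 0.37, tolerance = 1e-9)

  R5 <- footclear:::rotvec_to_matrix(c(5 * pi / 180, 0, 0))
  tilted <- flat %*% t(R5)
  pl5 <- fit_support_plane(tilted)
  expect_equal(as.numeric(pl5$normal %*% R5[, 3]), 1, tolerance = 1e-9)
  expect_lt(max(abs(tilted %*% pl5$normal - pl5$offset)), 1e-9)
})

test_that("support plane of a rocker sole matches the brute-force triple search", {
  cl <- coarse_cloud()
  sole <- cl$points[cl$sole_indices, , drop = FALSE]
  Rt <- footclear:::rotvec_to_matrix(c(0.02, 0.04, 0))
  P <- sole %*% t(Rt)
  pl <- fit_support_plane(P)
  # supports the cloud, and the contact set is tight
  d <- as.numeric(P %*% pl$normal) - pl$offset
  expect_true(all(d > -1e-9))
  expect_lt(min(d), 1e-3)
  # oracle: every triple whose plane supports all points; pick the flushest
  n <- nrow(P)
  best <- NULL; best_flush <- Inf
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    v1 <- P[j, ] - P[i, ]; v2 <- P[k, ] - P[i, ]
    nn <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    l <- sqrt(sum(nn^2))
    if (l < 1e-10) next
    nn <- nn / l
    if (nn[3] < 0) nn <- -nn
    dd <- as.numeric(P %*% nn) - sum(nn * P[i, ])
    if (all(dd > -1e-9)) {
      flush <- mean(dd[dd < 0.003])
      if (flush < best_flush) { best_flush <- flush; best <- nn }
    }
  }
  ang <- acos(min(1, sum(best * pl$normal))) * 180 / pi
  expect_lt(ang, 0.2)
})

test_that("flat correction levels injected tilts and is algebraically consistent", {
  cl <- test_cloud()
  r_si <- fixture_rotation(cl)

  # already flat: identity within 1e-9
  r0 <- compute_flat_correction(cl, r_si, diag(3))
  expect_equal(r0, diag(3), tolerance = 1e-9)

  for (deg in c(1, 6)) {
    # IMU pose tilted at the first stance instant -> foot shows that tilt
    rk1 <- footclear:::rotvec_to_matrix(c(0.3 * deg, 0.954 * deg, 0) * pi / 180)
    rs <- compute_flat_correction(cl, r_si, rk1)
    w <- cl$points[cl$sole_indices, ] %*% t(rk1 %*% rs %*% r_si)
    pl <- fit_support_plane(w)
    expect_lt(acos(min(1, pl$normal[3])) * 180 / pi, 0.1)
    # matrix identity behind R*: R(k1) R* = R_flat R(k1), with R_flat
    # recomputed independently from the uncorrected support-plane normal
    pl0 <- fit_support_plane(cl$points[cl$sole_indices, ] %*% t(rk1 %*% r_si))
    r_flat <- footclear:::rotation_between(pl0$normal, c(0, 0, 1))
    expect_equal(rk1 %*% rs, r_flat %*% rk1, tolerance = 1e-12)
  }
})

test_that("cloud transformation is rigid and respects the floor offset", {
  cl <- test_cloud()
  b <- sim_bout("typical", seed = 2, n_strides = 2)
  pose <- b$truth$poses
  calib <- frame_calibration()

  # identity pose at the first stance sample: scan coords + position
  w1 <- transform_cloud(pose, 1, calib, cl)
  expect_equal(w1, sweep(cl$points, 2, pose$position[1, ], "+"),
               tolerance = 1e-12)

  calib$floor_offset <- 0.003
  w2 <- transform_cloud(pose, 1, calib, cl)
  expect_equal(w2[, 3], w1[, 3] - 0.003, tolerance = 1e-12)
  expect_equal(w2[, 1:2], w1[, 1:2])

  d0 <- stats::dist(cl$points[c(cl$toe_index, cl$heel_index,
                                cl$sole_indices[1:10]), ])
  set.seed(11)
  for (i in 1:10) {
    k <- sample(nrow(pose$position), 1)
    w <- transform_cloud(pose, k, calib, cl)
    d <- stats::dist(w[c(cl$toe_index, cl$heel_index, cl$sole_indices[1:10]), ])
    expect_equal(as.numeric(d), as.numeric(d0), tolerance = 1e-9)
  }
  expect_error(transform_cloud(pose, 0, calib, cl),
               class = "footclear_contract_error")
})

test_that("floor offset is the mean of per-stride stance medians", {
  expect_equal(compute_floor_offset(list(rep(-0.003, 10))), -0.003)
  expect_equal(compute_floor_offset(list(c(-0.002, -0.002), c(-0.004, -0.004))),
               -0.003)
  expect_error(compute_floor_offset(list()),
               class = "footclear_contract_error")

  # after applying the offset the statistic recomputes to zero
  set.seed(1)
  lp <- replicate(5, -0.06 + stats::rnorm(20, 0, 1e-4), simplify = FALSE)
  off <- compute_floor_offset(lp)
  expect_equal(compute_floor_offset(lapply(lp, function(v) v - off)), 0,
               tolerance = 1e-12)

  # simulated bout: corrected stance lowest points sit on the floor
  ba <- analyzed_bout("typical", seed = 1, n_strides = 5)
  seg <- ba$segmentation
  stance_lp <- unlist(lapply(seq_len(nrow(seg)), function(i) {
    ba$lp[seg$zupt_start[i]:(seg$zupt_end[i] - 1)]
  }))
  expect_lt(abs(stats::median(stance_lp)), 1e-4)
  expect_lt(abs(mean(stance_lp)), 1e-4)
})
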