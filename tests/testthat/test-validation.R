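# Reference resampling, stride matching, key-point extraction and the
# mixed-effects limits of agreement.

test_that("resampling is exact linear interpolation with gap propagation", {
  tt <- (0:200) / 200
  tr <- marker_trajectory(tt, cbind(tt, 2 * tt, tt^0 * 0))
  same <- resample_trajectory(tr, tt)
  expect_equal(same$position, tr$position, tolerance = 1e-12)

  mid <- resample_trajectory(marker_trajectory(c(0, 1), rbind(c(0, 0, 0),
                                                              c(0, 0, 0.002))),
                             0.5)
  expect_equal(mid$position[1, 3], 0.001, tolerance = 1e-12)

  # 200 Hz sinusoid resampled to 128 Hz: linear-interpolation error bound
  f <- 4; A <- 0.05
  tt200 <- (0:400) / 200
  z <- A * sin(2 * pi * f * tt200)
  tr2 <- marker_trajectory(tt200, cbind(0, 0, z))
  t128 <- seq(0, 1.9, by = 1 / 128)
  rs <- resample_trajectory(tr2, t128)
  bound <- (2 * pi * f)^2 / (2 * 200^2) * A
  expect_lt(max(abs(rs$position[, 3] - A * sin(2 * pi * f * t128))), bound)

  # gaps: any target inside an interval touching a gap is itself a gap
  pos <- cbind(tt, tt, tt); pos[100, ] <- NA
  trg <- marker_trajectory(tt, pos)
  rs2 <- resample_trajectory(trg, c(0.25, tt[99] + 0.001, 0.75))
  expect_equal(rs2$gap_mask, c(FALSE, TRUE, FALSE))

  expect_error(resample_trajectory(tr, 1.5), class = "footclear_data_error")
})

test_that("stride matching finds the global lag by cross-correlation", {
  b <- sim_bout("typical", seed = 4, n_strides = 5)
  ba <- analyzed_bout("typical", seed = 4, n_strides = 5)
  z <- ba$marker_z
  seg <- ba$segmentation

  m0 <- match_strides(z, seg, z)
  expect_equal(nrow(m0), 5)
  expect_true(all(m0$lag == 0))
  expect_gt(attr(m0, "correlation"), 0.999)

  delayed <- c(rep(z[1], 64), z)
  m64 <- match_strides(z, seg, delayed)
  expect_true(all(m64$lag == 64))
  expect_equal(m64$ref_start, seg$zupt_start + 64)

  set.seed(2)
  noisy_ref <- delayed + stats::rnorm(length(delayed), 0, 0.002)
  mn <- match_strides(z, seg, noisy_ref)
  expect_gte(sum(mn$lag == 64), ceiling(0.95 * nrow(seg)))

  expect_error(match_strides(z, seg, stats::rnorm(length(z), 0, 0.05)),
               class = "footclear_alignment_error")
})

test_that("key points follow the M-shape / single-peak classification", {
  s <- seq(0, 1, length.out = 101)
  m_curve <- 0.08 * exp(-((s - 0.3) / 0.12)^2) +
    0.12 * exp(-((s - 0.75) / 0.1)^2)
  kp <- extract_key_points(m_curve, prominence_min = 0.005)
  expect_equal(kp$shape, "M")
  expect_equal(kp$max_p1, 0.08, tolerance = 0.005)
  expect_equal(kp$max_p2, 0.12, tolerance = 0.005)
  expect_lt(kp$min_p, min(kp$max_p1, kp$max_p2))

  single <- 0.1 * exp(-((s - 0.5) / 0.15)^2)
  kp1 <- extract_key_points(single, prominence_min = 0.005)
  expect_equal(kp1$shape, "single")
  expect_true(is.na(kp1$max_p1) && is.na(kp1$min_p))
  expect_equal(kp1$max_p2, 0.1, tolerance = 1e-6)

  # invariance to adding a constant
  kp_c <- extract_key_points(m_curve + 0.5, prominence_min = 0.005)
  expect_equal(kp_c$max_p1 - 0.5, kp$max_p1, tolerance = 1e-12)
  expect_equal(kp_c$min_p - 0.5, kp$min_p, tolerance = 1e-12)
  expect_equal(kp_c$max_p2 - 0.5, kp$max_p2, tolerance = 1e-12)

  expect_error(extract_key_points(rep(0, 50), prominence_min = 0.005),
               class = "footclear_data_error")
})

test_that("key points survive 1 mm noise in >= 95% of strides", {
  s <- seq(0, 1, length.out = 80)
  clean <- 0.08 * exp(-((s - 0.3) / 0.12)^2) +
    0.12 * exp(-((s - 0.75) / 0.1)^2)
  set.seed(5)
  hits <- 0
  for (i in 1:100) {
    noisy <- clean + stats::rnorm(80, 0, 0.001)
    kp <- tryCatch(extract_key_points(noisy, prominence_min = 0.005),
                   footclear_data_error = function(e) NULL)
    if (!is.null(kp) && kp$shape == "M" &&
        abs(kp$max_p1 - 0.08) < 0.003 && abs(kp$max_p2 - 0.12) < 0.003) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 95)
})

test_that("limits of agreement handle degenerate and symmetric inputs", {
  z <- limits_of_agreement(rep(0, 12), rep(1:2, 6), rep(1:6, 2))
  expect_equal(c(z$bias, z$lower, z$upper), c(0, 0, 0))

  cst <- limits_of_agreement(rep(1.5, 12), rep(1:2, 6), rep(1:6, 2))
  expect_equal(c(cst$bias, cst$lower, cst$upper), c(1.5, 1.5, 1.5))

  set.seed(10)
  pid <- rep(1:3, each = 60); sid <- rep(1:60, each = 3)
  d <- -0.5 + stats::rnorm(3, 0, 2)[pid] + stats::rnorm(60, 0, 2)[sid] +
    stats::rnorm(180, 0, 3)
  a <- limits_of_agreement(d, pid, sid)
  an <- limits_of_agreement(-d, pid, sid)
  expect_equal(an$bias, -a$bias, tolerance = 1e-6)
  expect_equal(an$lower, -a$upper, tolerance = 1e-6)
  expect_equal(an$upper, -a$lower, tolerance = 1e-6)
  expect_true(a$lower <= a$bias && a$bias <= a$upper)
  expect_true(all(c(a$var_participant, a$var_stride, a$var_residual) >= 0))
})

test_that("the mixed model recovers simulated variance components", {
  set.seed(10)
  mu <- -0.05; su <- 2; sw <- 2; se <- 3
  pid <- rep(1:6, each = 120); sid <- rep(1:240, each = 3)
  d <- mu + stats::rnorm(6, 0, su)[pid] + stats::rnorm(240, 0, sw)[sid] +
    stats::rnorm(720, 0, se)
  a <- limits_of_agreement(d, pid, sid)
  se_bias <- sqrt(su^2 / 6 + sw^2 / 240 + se^2 / 720)
  expect_lt(abs(a$bias - mu), 3 * se_bias)
  tot <- a$var_participant + a$var_stride + a$var_residual
  expect_lt(abs(sqrt(tot) - sqrt(17)) / sqrt(17), 0.5)
})

test_that("with one participant the limits converge to classic Bland-Altman", {
  set.seed(99)
  d <- stats::rnorm(10000, 1, 3)
  a <- suppressWarnings(limits_of_agreement(d, rep(1, 10000), seq_len(10000)))
  lo <- mean(d) - 1.96 * stats::sd(d)
  hi <- mean(d) + 1.96 * stats::sd(d)
  expect_lt(abs(a$lower - lo) / abs(hi - lo), 0.02)
  expect_lt(abs(a$upper - hi) / abs(hi - lo), 0.02)
})
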