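# Synthetic gait: ground-truth foot poses, IMU signal synthesis, and
# grid-exact clearance oracles, so the whole pipeline is testable without
# any recorded data.
#
# Geometry conventions: scan frame x forward (heel -> toe), y to the left,
# z up; for a right foot the lateral edge is negative y. Positive pitch =
# plantarflexion (toe down), negative = dorsiflexion; positive roll =
# inversion (lateral edge down).

#' Gait-simulation parameters
#'
#' Defaults describe an unimpaired self-paced walk recorded at 128 Hz:
#' 1.1 s stride, 60% stance, 1.2 m stride length, a 5 cm swing apex of the
#' IMU, 25 deg push-off plantarflexion and 22 deg pre-landing dorsiflexion
#' (an M-shaped toe-height path). `foot_drop_factor` scales the late-swing
#' dorsiflexion: 1 = normal, 0 = absent (single-peaked toe path, the
#' clinical foot-drop pattern). `roll_amplitude_deg` > 0 holds the foot
#' inverted through swing. `scuff_depth` lowers the whole foot by a smooth
#' mid-late-swing dip, producing floor contact (negative clearance) when it
#' exceeds the apex lift at that phase.
#'
#' @param stride_time stride duration, s.
#' @param stance_fraction fraction of the stride spent in stance, in
#'   (0.3, 0.8).
#' @param step_length forward travel per stride, m.
#' @param swing_apex_height mid-swing lift of the IMU above its stance
#'   height, m.
#' @param pitch_plantarflex_deg,pitch_dorsiflex_deg pitch extremes at
#'   toe-off and before heel strike, degrees.
#' @param roll_amplitude_deg inversion roll held through swing, degrees.
#' @param foot_drop_factor late-swing dorsiflexion scale in `[0, 1]`.
#' @param scuff_depth depth of the mid-late-swing dip, m (default 0).
#' @param n_strides number of strides (the bout has one extra trailing
#'   stance period so every stride has a terminal stance run).
#' @param sample_rate IMU rate, Hz.
#' @param accel_noise_sd,gyro_noise_sd white-noise SDs (m/s^2, rad/s).
#' @param accel_bias constant accelerometer bias 3-vector, m/s^2, sensor
#'   frame.
#' @param seed RNG seed (mandatory; the generator has no hidden global
#'   randomness).
#' @return A `gait_params` list.
#' @export
gait_params <- function(stride_time = 1.1,
                        stance_fraction = 0.6,
                        step_length = 1.2,
                        swing_apex_height = 0.05,
                        pitch_plantarflex_deg = 25,
                        pitch_dorsiflex_deg = 22,
                        roll_amplitude_deg = 0,
                        foot_drop_factor = 1,
                        scuff_depth = 0,
                        n_strides = 20,
                        sample_rate = 128,
                        accel_noise_sd = 0,
                        gyro_noise_sd = 0,
                        accel_bias = c(0, 0, 0),
                        seed) {
  if (missing(seed)) fc_contract_error("gait_params: seed is mandatory")
  if (stance_fraction <= 0.3 || stance_fraction >= 0.8) {
    fc_contract_error("stance_fraction must lie in (0.3, 0.8)")
  }
  if (foot_drop_factor < 0 || foot_drop_factor > 1) {
    fc_contract_error("foot_drop_factor must lie in [0, 1]")
  }
  if (stride_time <= 0 || step_length <= 0 || swing_apex_height < 0 ||
      n_strides < 1 || sample_rate <= 0) {
    fc_contract_error("gait parameters must be positive")
  }
  structure(list(stride_time = stride_time, stance_fraction = stance_fraction,
                 step_length = step_length,
                 swing_apex_height = swing_apex_height,
                 pitch_plantarflex_deg = pitch_plantarflex_deg,
                 pitch_dorsiflex_deg = pitch_dorsiflex_deg,
                 roll_amplitude_deg = roll_amplitude_deg,
                 foot_drop_factor = foot_drop_factor,
                 scuff_depth = scuff_depth,
                 n_strides = as.integer(n_strides),
                 sample_rate = sample_rate,
                 accel_noise_sd = accel_noise_sd,
                 gyro_noise_sd = gyro_noise_sd,
                 accel_bias = accel_bias, seed = as.integer(seed)),
            class = "gait_params")
}

#' Canonical walking-style scenarios
#'
#' `"typical"`: unimpaired M-shaped swing. `"foot_drop"`: no late-swing
#' dorsiflexion (single-peaked toe path, forefoot hangs low). `"inversion"`:
#' sustained inversion roll so the lateral sole edge is lowest in late
#' swing. `"toe_drag"`: lowered apex plus a mid-late-swing dip deep enough
#' that the foot scuffs the floor (negative clearance).
#'
#' @param scenario scenario name.
#' @param seed RNG seed.
#' @param n_strides strides per bout.
#' @param ... overrides passed to [gait_params()].
#' @export
scenario_params <- function(scenario = c("typical", "foot_drop", "inversion",
                                         "toe_drag"),
                            seed, n_strides = 20, ...) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
    typical = list(),
    foot_drop = list(foot_drop_factor = 0, swing_apex_height = 0.04),
    inversion = list(roll_amplitude_deg = 8, foot_drop_factor = 0.6),
    toe_drag = list(swing_apex_height = 0.02, scuff_depth = 0.02,
                    foot_drop_factor = 0.4))
  args <- utils::modifyList(c(base, list(seed = seed, n_strides = n_strides)),
                            list(...))
  do.call(gait_params, args)
}

#' Synthetic shoe-scan point cloud
#'
#' Sole points form a uniform grid over a stadium-shaped outline (a
#' rectangle of length `length - width` capped by half-disks of diameter
#' `width`), with a smooth rocker curvature rising to `rocker_rise` at the
#' toe and heel tips outside a flat central region. Toe and heel landmarks
#' sit at the extreme x points slightly above the sole; the validation
#' marker is on the dorsum above the toe; the IMU fixture origin is on the
#' mid-dorsum with axes aligned to the scan frame.
#'
#' @param length toe-to-heel length, m.
#' @param width sole width, m.
#' @param rocker_rise tip rise of the rocker profile, m.
#' @param grid_spacing sole grid spacing, m (must be < width / 3).
#' @param dorsum_height fixture-origin height above the flat sole plane, m.
#' @param flat_fraction fraction of the half-length that stays flat.
#' @return A [scan_point_cloud()].
#' @export
make_shoe_cloud <- function(length = 0.28, width = 0.10, rocker_rise = 0.01,
                            grid_spacing = 0.01, dorsum_height = 0.06,
                            flat_fraction = 0.6) {
  if (!(length > width && width > 0)) {
    fc_contract_error("shoe cloud needs length > width > 0")
  }
  if (grid_spacing >= width / 3) {
    fc_contract_error("grid_spacing must be smaller than width / 3")
  }
  lf <- length - width                 # straight segment of the stadium
  x0 <- flat_fraction * length / 2     # rocker starts beyond the flat region
  rocker <- function(x) {
    u <- pmax(abs(x) - x0, 0) / (length / 2 - x0)
    rocker_rise * u^2
  }
  gx <- seq(-length / 2, length / 2,
            length.out = max(2, round(length / grid_spacing)) + 1)
  gy <- seq(-width / 2, width / 2,
            length.out = max(2, round(width / grid_spacing)) + 1)
  g <- expand.grid(x = gx, y = gy)
  inside <- abs(g$x) <= lf / 2 |
    (abs(g$x) - lf / 2)^2 + g$y^2 <= (width / 2)^2 + 1e-12
  sole <- cbind(g$x[inside], g$y[inside], rocker(g$x[inside]))
  tip_z <- rocker_rise + 0.002         # landmarks sit just above the sole
  toe <- c(length / 2, 0, tip_z)
  heel <- c(-length / 2, 0, tip_z)
  marker <- c(length / 2 - 0.01, 0, 0.03)
  pts <- rbind(toe, heel, marker, sole)
  scan_point_cloud(points = pts,
                   toe_index = 1L, heel_index = 2L, marker_index = 3L,
                   sole_indices = 3L + seq_len(nrow(sole)),
                   fixture_origin = c(0, 0, dorsum_height),
                   fixture_axes = diag(3),
                   labels = c("toe", "heel", "marker",
                              sprintf("sole%04d", seq_len(nrow(sole)))))
}

# C^2 bump on [0,1]: ((1 - cos 2 pi u)/2)^2, zero value/slope/curvature at
# the endpoints, peak 1 at u = 1/2
bump2 <- function(u) {
  out <- numeric(length(u))
  ok <- u > 0 & u < 1
  out[ok] <- ((1 - cos(2 * pi * u[ok])) / 2)^2
  out
}

# swing-phase profiles as functions of normalized swing phase s in [0,1]
swing_profiles <- function(params, s) {
  d2r <- pi / 180
  plantar <- params$pitch_plantarflex_deg * d2r * bump2(s / 0.5)
  # the dorsiflexion lost to foot drop partly becomes a plantar droop: the
  # forefoot hangs low in late swing instead of lifting
  late <- bump2((s - 0.55) / 0.45)
  dorsi <- params$foot_drop_factor * params$pitch_dorsiflex_deg * d2r * late
  droop <- (1 - params$foot_drop_factor) * 5 * d2r * late
  theta <- plantar - dorsi + droop
  phi <- params$roll_amplitude_deg * d2r * bump2((s - 0.25) / 0.75)
  list(
    forward = params$step_length * (s - sin(2 * pi * s) / (2 * pi)),
    lift = params$swing_apex_height * bump2(s) -
      params$scuff_depth * bump2((s - 0.40) / 0.55),
    theta = theta, phi = phi
  )
}

# analytic support height of the flat stadium footprint at depth h under
# pitch theta / roll phi: how high the IMU must sit for the sole to touch
# the floor
support_height <- function(theta, phi, h, lf, w) {
  r31 <- -sin(theta)
  r32 <- cos(theta) * sin(phi)
  r33 <- cos(theta) * cos(phi)
  h * r33 + (lf / 2) * abs(r31) + (w / 2) * sqrt(r31^2 + r32^2)
}

#' Simulate ground-truth foot poses for a walking bout
#'
#' During stance the pose is constant with the sole flat on the floor (the
#' IMU height equals the sole's support height, so the support plane sits
#' exactly at height 0). During swing the foot translates forward by a
#' smoothed ramp, lifts by a C^2 apex bump, and pitches from plantarflexion
#' at toe-off to `foot_drop_factor`-scaled dorsiflexion before landing,
#' with an optional inversion roll; the IMU height additionally tracks the
#' analytic sole support height so the foot clears the floor by the apex
#' bump alone. All profiles are twice continuously differentiable, so the
#' synthesized IMU signals contain no impulses. The bout ends with one
#' extra stance period, giving every stride a terminal stance run.
#'
#' @param params a [gait_params()].
#' @param cloud the [scan_point_cloud()] the feet wear (defines the sole
#'   geometry; default [make_shoe_cloud()]).
#' @return A `ground_truth`: `poses` (exact `pose_trajectory`),
#'   `zupt_schedule` (data.frame `start`,`end`, one row per stance run),
#'   `segmentation` (as [segment_strides()]), `params`, `cloud`.
#' @export
simulate_foot_poses <- function(params, cloud = make_shoe_cloud()) {
  fs <- params$sample_rate
  T_ <- params$stride_time
  sf <- params$stance_fraction
  n <- params$n_strides
  sole <- cloud$points[cloud$sole_indices, , drop = FALSE]
  h <- -min(sole[, 3])
  w <- diff(range(sole[, 2]))
  lf <- diff(range(sole[, 1])) - w
  t_end <- n * T_ + sf * T_
  time <- seq(0, t_end, by = 1 / fs)
  K <- length(time)
  stride_of <- pmin(floor(time / T_ + 1e-9), n)  # 0-based; trailing stance -> n
  u <- time - stride_of * T_
  in_stance <- u < sf * T_ - 1e-9 | stride_of == n
  s <- ifelse(in_stance, 0, (u - sf * T_) / ((1 - sf) * T_))
  pr <- swing_profiles(params, s)
  pos <- cbind(stride_of * params$step_length + pr$forward,
               0,
               support_height(pr$theta, pr$phi, h, lf, w) + pr$lift)
  R <- array(0, c(3, 3, K))
  for (k in seq_len(K)) {
    th <- pr$theta[k]; ph <- pr$phi[k]
    Ry <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3, 3)
    R[, , k] <- Ry %*% Rx
  }
  poses <- structure(list(rotation = R, position = unname(pos),
                          velocity = NULL, sample_rate = fs, time = time),
                     class = "pose_trajectory")
  # exact stance schedule as sample runs
  fl <- in_stance
  rr <- rle(fl)
  ends <- cumsum(rr$lengths)
  starts <- ends - rr$lengths + 1L
  sched <- data.frame(start = starts[rr$values], end = ends[rr$values] + 1L)
  seg <- segment_strides(zupt_mask(fl))
  structure(list(poses = poses, zupt_schedule = sched, segmentation = seg,
                 params = params, cloud = cloud),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d strides, %d samples @ %g Hz\n",
              x$params$n_strides, nrow(x$poses$position),
              x$params$sample_rate))
  invisible(x)
}

#' Synthesize IMU signals from ground-truth poses
#'
#' World acceleration by central second differences of position (so that
#' synthesis and strapdown reconstruction share the same discretization);
#' specific force `f(k) = R(k)^T (a_world(k) - g)`; angular rate from the
#' rotation vector of `R(k)^T R(k+1)` times the sample rate. Gaussian white
#' noise and a constant accelerometer bias are then added under the
#' parameter seed; the global RNG state is restored afterwards, and the
#' same seed always yields a bit-identical recording.
#'
#' @param truth a `ground_truth` from [simulate_foot_poses()].
#' @param params the same [gait_params()] (noise fields are used).
#' @return An [imu_recording()].
#' @export
synthesize_imu <- function(truth, params = truth$params) {
  pose <- truth$poses
  K <- nrow(pose$position)
  if (K < 3) fc_contract_error("IMU synthesis needs at least 3 samples")
  fs <- pose$sample_rate
  p <- pose$position
  a_w <- matrix(0, K, 3)
  a_w[2:(K - 1), ] <- (p[3:K, ] - 2 * p[2:(K - 1), ] + p[1:(K - 2), ]) * fs^2
  a_w[1, ] <- a_w[2, ]
  a_w[K, ] <- a_w[K - 1, ]
  f <- matrix(0, K, 3)
  gyro <- matrix(0, K, 3)
  for (k in seq_len(K)) {
    Rk <- pose$rotation[, , k]
    f[k, ] <- as.numeric(t(Rk) %*% (a_w[k, ] + c(0, 0, GRAVITY)))
    if (k < K) {
      gyro[k, ] <- matrix_to_rotvec(t(Rk) %*% pose$rotation[, , k + 1]) * fs
    }
  }
  gyro[K, ] <- gyro[K - 1, ]
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)
  if (params$accel_noise_sd > 0) {
    f <- f + matrix(stats::rnorm(3 * K, sd = params$accel_noise_sd), K, 3)
  }
  if (params$gyro_noise_sd > 0) {
    gyro <- gyro + matrix(stats::rnorm(3 * K, sd = params$gyro_noise_sd), K, 3)
  }
  f <- sweep(f, 2, params$accel_bias, "+")
  imu_recording(pose$time, f, gyro, sample_rate = fs)
}

#' Grid-exact clearance oracle from ground-truth poses
#'
#' Evaluates the lowest-point trace, forward-swing windows and per-stride
#' minimum clearance directly from the exact simulated poses - no
#' integration, no calibration, no floor estimation. This is the reference
#' the full pipeline is compared against.
#'
#' @param truth a `ground_truth`.
#' @param cloud a [scan_point_cloud()] (default: the cloud the truth was
#'   simulated with).
#' @return List with `lp`, `lp_index` (per sample) and `strides`, a list of
#'   `stride_clearance` records with scan-frame `location` (x, y) of the
#'   minimum-clearance point.
#' @export
oracle_clearance <- function(truth, cloud = truth$cloud) {
  calib <- frame_calibration()
  zm <- zupt_mask(seq_len(nrow(truth$poses$position)) %in%
                    unlist(lapply(seq_len(nrow(truth$zupt_schedule)), function(i) {
                      truth$zupt_schedule$start[i]:(truth$zupt_schedule$end[i] - 1L)
                    })))
  hs <- point_heights(truth$poses, calib, cloud, cloud$sole_indices)
  tr <- lowest_point_trace(hs, cloud$sole_indices)
  heel_z <- point_heights(truth$poses, calib, cloud, cloud$heel_index)[1, ]
  toe_z <- point_heights(truth$poses, calib, cloud, cloud$toe_index)[1, ]
  seg <- truth$segmentation
  strides <- lapply(seq_len(nrow(seg)), function(i) {
    win <- forward_swing_window(seg[i, ], heel_z, toe_z, zm)
    sc <- stride_mfc(tr$lp, tr$lp_index, win, stride_id = seg$stride_id[i],
                     t_start = truth$poses$time[seg$zupt_start[i]])
    if (isTRUE(sc$valid)) sc$location <- cloud$points[sc$i_mfc, 1:2]
    sc
  })
  list(lp = tr$lp, lp_index = tr$lp_index, heel_z = heel_z, toe_z = toe_z,
       strides = strides)
}
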