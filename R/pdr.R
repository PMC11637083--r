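# Zero-velocity-update (ZUPT) pedestrian dead reckoning: stance detection,
# stride segmentation, and drift-corrected strapdown integration of the
# foot-mounted IMU.

# centered moving average with shrinking windows at the edges
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- (window - 1) %/% 2
  k <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(k) - half, 1)
  hi <- pmin(seq_len(k) + half, k)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect zero-velocity (stance) samples
#'
#' A sample is flagged as stance when the smoothed accelerometer norm is
#' within `accel_tol` of standard gravity AND the smoothed gyroscope norm is
#' below `gyro_tol`. Both norms are smoothed with a centered moving average
#' over `smooth_window` samples before thresholding.
#'
#' @param rec an [imu_recording()].
#' @param accel_tol accelerometer-norm tolerance, m/s^2.
#' @param gyro_tol gyroscope-norm threshold, rad/s.
#' @param smooth_window moving-average window, samples.
#' @return A `zupt_mask`: list with logical `flags` (one per sample).
#' @export
detect_zupt <- function(rec, accel_tol = 0.8, gyro_tol = 0.3,
                        smooth_window = 5) {
  if (accel_tol <= 0 || gyro_tol <= 0) {
    fc_contract_error("ZUPT tolerances must be positive")
  }
  an <- moving_average(sqrt(rowSums(rec$accel^2)), smooth_window)
  gn <- moving_average(sqrt(rowSums(rec$gyro^2)), smooth_window)
  zupt_mask(abs(an - GRAVITY) < accel_tol & gn < gyro_tol)
}

#' @rdname detect_zupt
#' @param flags logical vector, `TRUE` = stance.
#' @export
zupt_mask <- function(flags) {
  structure(list(flags = as.logical(flags)), class = "zupt_mask")
}

#' @export
print.zupt_mask <- function(x, ...) {
  r <- zupt_runs(x)
  cat(sprintf("<zupt_mask> %d samples, %d stance run(s)\n",
              length(x$flags), nrow(r)))
  invisible(x)
}

#' Maximal stance runs of a ZUPT mask
#'
#' @param mask a `zupt_mask`.
#' @return data.frame with columns `start` (first stance sample) and `end`
#'   (one past the last), one row per maximal run of `TRUE`.
#' @export
zupt_runs <- function(mask) {
  r <- rle(mask$flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep] + 1L)
}

#' Delete short stance runs
#'
#' Every maximal run of stance samples shorter than `min_len` is set to
#' swing; runs of `min_len` or more are kept verbatim. Removes spurious
#' stance detections (e.g. mid-swing near-gravity instants). Idempotent.
#'
#' @param mask a `zupt_mask`.
#' @param min_len minimum run length in samples to keep (default 15).
#' @return The filtered `zupt_mask`.
#' @export
smooth_zupt <- function(mask, min_len = 15) {
  r <- rle(mask$flags)
  r$values[r$values & r$lengths < min_len] <- FALSE
  zupt_mask(inverse.rle(r))
}

#' Segment strides from a ZUPT mask
#'
#' Stride n spans from the start of stance run n to the start of stance run
#' n+1 (half-open), so each stride contains its own stance phase followed by
#' the swing; samples after the last run start are not assigned to a stride.
#'
#' @param mask a smoothed `zupt_mask` with at least two stance runs.
#' @return A `stride_segmentation`: data.frame with columns `stride_id`,
#'   `zupt_start`, `zupt_end`, `stride_end` (all 1-based; `zupt_end` and
#'   `stride_end` are one past the last sample of the stance run / stride).
#' @export
segment_strides <- function(mask) {
  runs <- zupt_runs(mask)
  if (nrow(runs) < 2) {
    fc_data_error("stride segmentation needs at least two stance runs")
  }
  n <- nrow(runs) - 1L
  seg <- data.frame(stride_id = seq_len(n),
                    zupt_start = runs$start[seq_len(n)],
                    zupt_end = runs$end[seq_len(n)],
                    stride_end = runs$start[seq_len(n) + 1L])
  class(seg) <- c("stride_segmentation", "data.frame")
  seg
}

#' Reconstruct the IMU pose trajectory by drift-corrected strapdown
#' integration
#'
#' The world frame has z up and gravity (0, 0, -9.80665) m/s^2; heading is
#' arbitrary (initialized to zero) and left uncorrected, since clearance
#' depends only on height and relative geometry. The algorithm:
#'
#' 1. Initial orientation: tilt from the mean specific force over the first
#'    stance run (gravity points opposite the measured specific force);
#'    heading zero.
#' 2. Orientation propagated by rotation-vector integration of the gyroscope,
#'    treating each sample as the mean rate over the following sample
#'    interval. During stance runs the tilt is relaxed toward the
#'    gravity-measured tilt with a first-order complementary gain per sample.
#' 3. World acceleration `a_w = R f + g`; velocity by trapezoidal
#'    integration, anchored to zero over every stance run.
#' 4. Per stride, a constant world-frame acceleration bias is estimated by
#'    least squares so that bias-corrected velocity vanishes over the
#'    stride's terminal stance run; the corresponding velocity ramp is
#'    subtracted.
#' 5. Any residual mean velocity over the terminal run is removed as a step
#'    from the heel-strike sample (first sample of the terminal run)
#'    onward - the impulsive velocity error at heel strike.
#' 6. Position by trapezoidal integration of the corrected velocity;
#'    position is held constant during stance runs, and the zero height is
#'    re-initialized at every stance run (the foot returns to the same floor
#'    each stance, so height accumulated across a stride is drift).
#'
#' Because an accelerometer bias is indistinguishable from an initial tilt
#' error in the gravity measurement, and a residual tilt couples the
#' forward travel into height, steps 3-6 are run twice when the bout has
#' at least three stance runs: a re-leveling rotation fit to the per-stride
#' height drifts (against horizontal displacements) is applied to the
#' orientation history before the second pass.
#'
#' @param rec an [imu_recording()].
#' @param mask a smoothed `zupt_mask` with at least one stance run.
#' @param tilt_gain complementary tilt-correction gain per stance sample.
#' @param drift_correction disable (diagnostic only) to skip the per-stride
#'   bias/impulse removal (steps 4-5) and the re-leveling pass.
#' @return A `pose_trajectory`: list with `rotation` (3 x 3 x K, IMU frame to
#'   world frame), `position` (K x 3, meters, IMU origin, starts at 0),
#'   `velocity` (K x 3), `sample_rate`, plus diagnostics: `accel_bias_world`
#'   (mean per-stride bias estimate), `releveling` (applied re-leveling
#'   rotation vector) and `anchors_pass1` (first-pass positions at stance-run
#'   starts).
#' @export
reconstruct_pose <- function(rec, mask, tilt_gain = 0.02,
                             drift_correction = TRUE) {
  k_tot <- length(rec$time)
  if (length(mask$flags) != k_tot) {
    fc_contract_error("ZUPT mask and recording length differ")
  }
  runs <- zupt_runs(mask)
  if (nrow(runs) < 1) {
    fc_data_error("pose reconstruction needs at least one stance run")
  }
  dt <- diff(rec$time)
  up <- c(0, 0, 1)

  ## (1) initial tilt from mean specific force over the first stance run
  r1 <- runs$start[1]:(runs$end[1] - 1L)
  f_mean <- colMeans(rec$accel[r1, , drop = FALSE])
  R0 <- rotation_between(f_mean, up)    # world R sensor at start

  ## (2) orientation propagation + complementary tilt relaxation in stance
  R <- array(0, c(3, 3, k_tot))
  R[, , 1] <- R0
  flags <- mask$flags
  relax <- function(Rk, f) {
    v <- Rk %*% unit3(f)
    ax <- c(v[2] * up[3] - v[3] * up[2],
            v[3] * up[1] - v[1] * up[3],
            v[1] * up[2] - v[2] * up[1])
    s <- vnorm(ax)
    if (s < 1e-14) return(Rk)
    ang <- atan2(s, v[3])
    rotvec_to_matrix(ax / s * (tilt_gain * ang)) %*% Rk
  }
  # relax only in run interiors: stance detection is reliable to a few
  # samples at each transition, and transition samples carry non-gravity
  # acceleration that would be mistaken for tilt
  guard <- 3L
  relax_ok <- rep(FALSE, k_tot)
  for (j in seq_len(nrow(runs))) {
    lo <- runs$start[j] + guard
    hi <- runs$end[j] - 1L - guard
    if (lo <= hi) relax_ok[lo:hi] <- TRUE
  }
  if (relax_ok[1]) R[, , 1] <- relax(R[, , 1], rec$accel[1, ])
  for (k in 2:k_tot) {
    # each gyro sample is treated as the mean angular rate over the
    # following sample interval, so the step from k-1 to k uses gyro[k-1]
    Rk <- R[, , k - 1] %*% rotvec_to_matrix(rec$gyro[k - 1, ] * dt[k - 1])
    if (relax_ok[k]) Rk <- relax(Rk, rec$accel[k, ])
    R[, , k] <- Rk
  }

  ## (3)-(6) velocity and position from a given orientation history
  n_runs <- nrow(runs)
  integrate_bout <- function(R) {
    a_w <- t(vapply(seq_len(k_tot),
                    function(k) as.numeric(R[, , k] %*% rec$accel[k, ]),
                    numeric(3)))
    a_w[, 3] <- a_w[, 3] - GRAVITY
    vel <- matrix(0, k_tot, 3)
    integrate_segment <- function(vel, k0, k1) {
      # trapezoid from anchor k0 (vel[k0,] assumed set) through k1
      if (k1 <= k0) return(vel)
      for (k in (k0 + 1):k1) {
        vel[k, ] <- vel[k - 1, ] + dt[k - 1] * (a_w[k - 1, ] + a_w[k, ]) / 2
      }
      vel
    }
    # leading samples before the first run: integrate forward from rest
    if (runs$start[1] > 1L) vel <- integrate_segment(vel, 1L, runs$start[1] - 1L)
    # movement segments between consecutive runs, with bias + impulse removal
    bias_est <- matrix(0, 0, 3)
    if (n_runs >= 2) {
      for (j in seq_len(n_runs - 1L)) {
        k0 <- runs$end[j] - 1L              # last sample of run j, v = 0
        k1 <- runs$end[j + 1L] - 1L         # last sample of run j+1
        vel[k0, ] <- 0
        vel <- integrate_segment(vel, k0, k1)
        if (!drift_correction) next
        term <- runs$start[j + 1L]:k1       # terminal stance run
        tau <- rec$time[term] - rec$time[k0]
        ## (4) constant-acceleration bias: LS fit v ~ b * tau over the run
        b <- colSums(tau * vel[term, , drop = FALSE]) / sum(tau^2)
        bias_est <- rbind(bias_est, b)
        ramp <- outer(rec$time[(k0 + 1):k1] - rec$time[k0], b)
        vel[(k0 + 1):k1, ] <- vel[(k0 + 1):k1, ] - ramp
        ## (5) impulsive velocity error: residual mean removed from heel strike
        m <- colMeans(vel[term, , drop = FALSE])
        vel[term, ] <- sweep(vel[term, , drop = FALSE], 2, m)
      }
    }
    # trailing samples after the last run: integrate forward, uncorrected
    kL <- runs$end[n_runs] - 1L
    if (kL < k_tot) {
      vel[kL, ] <- 0
      vel <- integrate_segment(vel, kL, k_tot)
    }
    # stance anchoring: velocity identically zero on every stance sample
    vel[flags, ] <- 0
    ## (6) position by trapezoidal integration of the corrected velocity
    pos <- matrix(0, k_tot, 3)
    for (k in 2:k_tot) {
      pos[k, ] <- pos[k - 1, ] + dt[k - 1] * (vel[k - 1, ] + vel[k, ]) / 2
    }
    # pose at the start of every stance run, before height re-initialization
    anchors <- pos[runs$start, , drop = FALSE]
    # zero height is re-initialized at every stance run: the foot returns to
    # the same floor each stance, so the height accumulated up to each run
    # start is treated as drift and removed from that run and its following
    # swing (x, y keep their dead-reckoned path)
    for (j in seq_len(n_runs)) {
      dz <- pos[runs$start[j], 3]
      if (dz == 0) next
      k_hi <- if (j < n_runs) runs$start[j + 1L] - 1L else k_tot
      pos[runs$start[j]:k_hi, 3] <- pos[runs$start[j]:k_hi, 3] - dz
    }
    list(vel = vel, pos = pos, bias = bias_est, anchors = anchors)
  }

  pass1 <- integrate_bout(R)
  relevel_q <- c(0, 0, 0)
  anchors1 <- pass1$anchors
  # An accelerometer bias is indistinguishable from an initial tilt error
  # in the stance gravity measurement, and the tilt error it induces couples
  # the (large) forward travel into height: a level-ground tilt of delta
  # rad climbs/sinks delta * stride_length per stride. The per-stride
  # height drifts against horizontal displacements therefore observe the
  # tilt directly; a small re-leveling rotation is fit by ridge least
  # squares and the integration repeated once.
  if (drift_correction && n_runs >= 3) {
    d_anchor <- diff(pass1$anchors)
    A <- cbind(d_anchor[, 2], -d_anchor[, 1])   # d z = qx*dy - qy*dx
    rhs <- -d_anchor[, 3]
    # ridge scaled to the total horizontal path: a component with little
    # displacement to observe it (e.g. cross-track tilt on a straight walk)
    # is shrunk to zero instead of fit to noise
    AtA <- crossprod(A) + diag(1e-3 * max(sum(A^2), 1e-6), 2)
    q <- solve(AtA, crossprod(A, rhs))
    ang <- vnorm(q)
    if (ang > 1e-9 && ang < 0.1) {
      relevel_q <- c(q[1], q[2], 0)
      Q <- rotvec_to_matrix(relevel_q)
      for (k in seq_len(k_tot)) R[, , k] <- Q %*% R[, , k]
      pass1 <- integrate_bout(R)
    }
  }

  structure(list(rotation = R, position = pass1$pos, velocity = pass1$vel,
                 sample_rate = rec$sample_rate, time = rec$time,
                 accel_bias_world = if (nrow(pass1$bias)) colMeans(pass1$bias)
                                    else c(0, 0, 0),
                 releveling = relevel_q, anchors_pass1 = anchors1),
            class = "pose_trajectory")
}

#' @export
print.pose_trajectory <- function(x, ...) {
  cat(sprintf("<pose_trajectory> %d samples @ %.6g Hz\n",
              nrow(x$position), x$sample_rate))
  invisible(x)
}
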