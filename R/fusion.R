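# Scan-to-IMU frame fusion: fixture calibration, the flat-foot tilt
# correction R*, rigid propagation of the shoe cloud into the world frame,
# and the trial-level floor-height offset.

#' Frame calibration container
#'
#' @param r_scan_to_imu proper rotation taking scan-frame vectors into IMU
#'   coordinates (from [fixture_rotation()]).
#' @param r_star flat-foot correction rotation expressed in the IMU frame at
#'   the first stance instant (from [compute_flat_correction()]).
#' @param floor_offset trial-level vertical offset in meters (from
#'   [compute_floor_offset()]); subtracted from every world z.
#' @param max_rstar_deg largest admissible correction angle; beyond this the
#'   fixture or the reconstruction is considered broken.
#' @export
frame_calibration <- function(r_scan_to_imu = diag(3), r_star = diag(3),
                              floor_offset = 0, max_rstar_deg = 15) {
  if (!is_rotation(r_scan_to_imu, 1e-9) || !is_rotation(r_star, 1e-9)) {
    fc_calibration_error("calibration rotations must be proper orthogonal")
  }
  ang <- rotation_angle(r_star) * 180 / pi
  if (ang > max_rstar_deg) {
    fc_calibration_error(sprintf(
      "flat-foot correction of %.1f deg exceeds the %.0f deg limit",
      ang, max_rstar_deg))
  }
  structure(list(r_scan_to_imu = r_scan_to_imu, r_star = r_star,
                 floor_offset = floor_offset),
            class = "frame_calibration")
}

#' Scan-to-IMU rotation from the fixture axes
#'
#' The fixture's x/y/z direction rows give IMU axes in scan coordinates;
#' the returned matrix is the nearest proper rotation (orthogonal
#' Procrustes / polar projection) to the matrix whose rows are the
#' unit-normalized axes. It maps scan-frame vectors into IMU coordinates.
#'
#' @param cloud a [scan_point_cloud()].
#' @return 3x3 rotation matrix, scan frame -> IMU frame.
#' @export
fixture_rotation <- function(cloud) {
  ax <- cloud$fixture_axes
  nrm <- sqrt(rowSums(ax^2))
  if (any(nrm < 0.9 | nrm > 1.1)) {
    fc_calibration_error("fixture axis norm outside [0.9, 1.1]")
  }
  u <- ax / nrm
  sv <- svd(u)
  if (sv$d[3] < 0.5) {
    fc_calibration_error("fixture axes are nearly parallel (degenerate)")
  }
  nearest_rotation(u)
}

#' Fit the support plane flush against the bottom of a point set
#'
#' Iterative contact-set scheme: initialize the contact set as the points
#' within `contact_tol` of the minimum height, fit a total-least-squares
#' plane through the contact set, re-select the contact set as the points
#' within `contact_tol` of the plane along its normal, and repeat to a fixed
#' point (at most `max_iter` iterations). The plane is finally translated
#' along its normal so that every point lies on or above it, and the normal
#' is oriented upward.
#'
#' @param points_world M x 3 matrix of world positions at one sample.
#' @param contact_tol contact-band half-width, meters (default 3 mm).
#' @param max_iter maximum refinement iterations.
#' @return A `support_plane`: list with unit `normal` (n_z > 0) and scalar
#'   `offset` such that the plane is `{p : n . p = offset}`.
#' @export
fit_support_plane <- function(points_world, contact_tol = 0.003,
                              max_iter = 20) {
  P <- as.matrix(points_world)
  if (nrow(P) < 3) fc_data_error("support-plane fit needs at least 3 points")
  ls_plane <- function(idx) {
    Q <- P[idx, , drop = FALSE]
    ctr <- colMeans(Q)
    C <- crossprod(sweep(Q, 2, ctr)) / nrow(Q)
    e <- eigen(C, symmetric = TRUE)
    if (e$values[2] <= 1e-12 * max(e$values[1], 1e-30)) {
      fc_calibration_error("degenerate (collinear) contact set in plane fit")
    }
    n <- e$vectors[, 3]
    if (n[3] < 0) n <- -n
    if (abs(n[3]) < 1e-9) {
      fc_calibration_error("support plane is vertical; contact set degenerate")
    }
    list(normal = n, offset = sum(n * ctr))
  }
  contact <- which(P[, 3] <= min(P[, 3]) + contact_tol)
  if (length(contact) < 3) contact <- order(P[, 3])[1:3]
  pl <- ls_plane(contact)
  for (it in seq_len(max_iter)) {
    d <- as.numeric(P %*% pl$normal) - pl$offset
    new_contact <- which(abs(d - min(d)) <= contact_tol)
    if (length(new_contact) < 3) new_contact <- order(d)[1:3]
    if (identical(new_contact, contact)) break
    contact <- new_contact
    pl <- ls_plane(contact)
  }
  # translate so all points lie on or above the plane
  pl$offset <- min(as.numeric(P %*% pl$normal))
  structure(list(normal = pl$normal, offset = pl$offset,
                 contact = contact),
            class = "support_plane")
}

#' Flat-foot correction rotation R*
#'
#' The reconstructed foot can appear tilted by several degrees during stance
#' (fixture/scan processing error, IMU shifting in its pouch). The
#' correction finds, at the first stance instant `k1`, the minimal world
#' rotation `R_flat` that brings the support plane of the transformed cloud
#' to horizontal, and re-expresses it in the IMU frame at `k1`:
#' `R* = R_wIMU(k1)^T R_flat R_wIMU(k1)`. Being IMU-frame, `R*` is applied
#' between the per-sample IMU rotation and the scan-to-IMU rotation at every
#' sample without recomputing `R_flat`.
#'
#' @param cloud a [scan_point_cloud()].
#' @param r_scan_to_imu scan-to-IMU rotation from [fixture_rotation()].
#' @param pose_at_zupt1 3x3 IMU-to-world rotation at the first stance sample.
#' @param contact_tol,max_iter support-plane parameters, see
#'   [fit_support_plane()].
#' @return 3x3 rotation matrix `r_star` (IMU frame).
#' @export
compute_flat_correction <- function(cloud, r_scan_to_imu, pose_at_zupt1,
                                    contact_tol = 0.003, max_iter = 20) {
  Rk <- pose_at_zupt1
  sole <- cloud$points[cloud$sole_indices, , drop = FALSE]
  world <- sole %*% t(Rk %*% r_scan_to_imu)
  pl <- fit_support_plane(world, contact_tol, max_iter)
  r_flat <- rotation_between(pl$normal, c(0, 0, 1))
  r_star <- t(Rk) %*% r_flat %*% Rk
  # post-condition: corrected cloud is flat at k1
  world2 <- sole %*% t(Rk %*% r_star %*% r_scan_to_imu)
  pl2 <- fit_support_plane(world2, contact_tol, max_iter)
  resid <- acos(min(1, max(-1, pl2$normal[3]))) * 180 / pi
  if (resid > 0.05) {
    fc_calibration_error(sprintf(
      "flat-foot correction left %.3f deg of residual support-plane tilt",
      resid))
  }
  r_star
}

#' Transform the scan cloud to world coordinates at one sample
#'
#' `p_world_i = position(k) + R(k) (R* R_scan_to_imu) p_scan_i`, then the
#' floor offset is subtracted from z. Point order is preserved; the
#' transform is rigid (all pairwise distances preserved).
#'
#' @param pose a `pose_trajectory` from [reconstruct_pose()].
#' @param k sample index (1-based).
#' @param calib a [frame_calibration()].
#' @param cloud a [scan_point_cloud()].
#' @return N x 3 matrix of world positions, meters.
#' @export
transform_cloud <- function(pose, k, calib, cloud) {
  k_tot <- nrow(pose$position)
  if (k < 1 || k > k_tot) {
    fc_contract_error(sprintf("sample index %d out of range [1, %d]", k, k_tot))
  }
  Q <- pose$rotation[, , k] %*% calib$r_star %*% calib$r_scan_to_imu
  out <- cloud$points %*% t(Q)
  out <- sweep(out, 2, pose$position[k, ], "+")
  out[, 3] <- out[, 3] - calib$floor_offset
  out
}

# Heights (world z) of selected cloud points at every sample, as an
# n_points x K matrix. Vectorized over samples: z_i(k) =
# pos_z(k) + row3(R(k) R* R_si) . p_i.
point_heights <- function(pose, calib, cloud, indices) {
  P <- cloud$points[indices, , drop = FALSE]
  K <- nrow(pose$position)
  Rsi <- calib$r_star %*% calib$r_scan_to_imu
  # third row of R(k) %*% Rsi for every k -> 3 x K
  rows3 <- vapply(seq_len(K),
                  function(k) as.numeric(pose$rotation[3, , k] %*% Rsi),
                  numeric(3))
  Z <- P %*% rows3
  sweep(Z, 2, pose$position[, 3] - calib$floor_offset, "+")
}

#' Trial-level floor-height offset
#'
#' The reconstruction pins the IMU's initial height at zero, so the foot
#' appears to penetrate the floor during stance. For each stride the median
#' lowest-point height over that stride's stance samples is taken; the mean
#' of these per-stride medians is the vertical offset. After subtracting it,
#' the same statistic recomputes to zero.
#'
#' @param lp_by_zupt list with one numeric vector per stride: lowest-point
#'   heights over that stride's stance samples.
#' @return Scalar offset in meters.
#' @export
compute_floor_offset <- function(lp_by_zupt) {
  if (!length(lp_by_zupt) || any(!vapply(lp_by_zupt, length, 1L))) {
    fc_contract_error("floor offset needs >= 1 stride with >= 1 stance sample")
  }
  mean(vapply(lp_by_zupt, stats::median, numeric(1)))
}
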