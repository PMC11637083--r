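# Typed containers and delimited-text readers/writers for the three input
# formats (IMU recording, shoe-scan point list, optional marker trajectory)
# and the per-stride results table.
#
# Unit conventions: all internal lengths are meters and all internal angles
# radians; clearances are converted to millimeters only at the output
# boundary. Sample and point indices are 1-based (R convention); index
# windows are stored as `start`/`end` with `end` one past the last sample.

#' Construct an IMU recording
#'
#' @param time numeric vector of sample times in seconds, strictly
#'   increasing and uniform to within 10% of the nominal sample interval.
#' @param accel K x 3 matrix of specific force in m/s^2, sensor frame.
#'   Specific force is what an accelerometer measures: body acceleration
#'   minus gravity, so a stationary sensor reads +9.80665 m/s^2 "up".
#' @param gyro K x 3 matrix of angular rate in rad/s, sensor frame.
#' @param sample_rate nominal rate in Hz; inferred from the median time step
#'   when `NULL`.
#' @return An object of class `imu_recording` with fields `time`, `accel`,
#'   `gyro`, `sample_rate`.
#' @examples
#' rec <- imu_recording(seq(0, 1, by = 1 / 128),
#'                      matrix(c(0, 0, 9.80665), 129, 3, byrow = TRUE),
#'                      matrix(0, 129, 3))
#' rec$sample_rate
#' @export
imu_recording <- function(time, accel, gyro, sample_rate = NULL) {
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  k <- length(time)
  if (k < 2) fc_data_error("an IMU recording needs at least 2 samples")
  if (!all(dim(accel) == c(k, 3)) || !all(dim(gyro) == c(k, 3))) {
    fc_contract_error("accel and gyro must be K x 3 with K = length(time)")
  }
  if (!all(is.finite(time)) || !all(is.finite(accel)) || !all(is.finite(gyro))) {
    fc_data_error("IMU recording contains non-finite values")
  }
  dt <- diff(time)
  bad <- which(dt <= 0)
  if (length(bad)) {
    fc_data_error(sprintf(
      "IMU time must be strictly increasing; first violation at sample %d",
      bad[1] + 1L))
  }
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(dt)
  if (max(abs(dt - 1 / sample_rate)) >= 0.1 / sample_rate) {
    fc_data_error("IMU time steps deviate more than 10% from 1/sample_rate")
  }
  structure(list(time = time, accel = unname(accel), gyro = unname(gyro),
                 sample_rate = sample_rate),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %.6g Hz (%.3g s)\n",
              length(x$time), x$sample_rate, diff(range(x$time))))
  invisible(x)
}

#' @export
length.imu_recording <- function(x) length(x$time)

#' Column/unit dialect for IMU CSV files
#'
#' @param time,accel,gyro column names (accel and gyro each length 3).
#' @param accel_unit `"m/s^2"` or `"g"` (multiplies by 9.80665).
#' @param gyro_unit `"rad/s"` or `"deg/s"` (multiplies by pi/180).
#' @param sample_rate optional nominal rate in Hz; inferred when `NULL`.
#' @export
imu_dialect <- function(time = "time",
                        accel = c("ax", "ay", "az"),
                        gyro = c("gx", "gy", "gz"),
                        accel_unit = c("m/s^2", "g"),
                        gyro_unit = c("rad/s", "deg/s"),
                        sample_rate = NULL) {
  list(time = time, accel = accel, gyro = gyro,
       accel_unit = match.arg(accel_unit),
       gyro_unit = match.arg(gyro_unit),
       sample_rate = sample_rate)
}

#' Read an IMU recording from a delimited text file
#'
#' The file must have a header row; columns and units are named by the
#' dialect. Values are converted to m/s^2 and rad/s on read.
#'
#' @param path file path.
#' @param dialect an [imu_dialect()].
#' @return An [imu_recording()].
#' @export
read_imu_recording <- function(path, dialect = imu_dialect()) {
  if (!file.exists(path)) fc_format_error(paste0("no such file: ", path))
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c(dialect$time, dialect$accel, dialect$gyro)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    fc_format_error(paste0("IMU file is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  acc_scale <- if (dialect$accel_unit == "g") GRAVITY else 1
  gyr_scale <- if (dialect$gyro_unit == "deg/s") pi / 180 else 1
  imu_recording(df[[dialect$time]],
                as.matrix(df[dialect$accel]) * acc_scale,
                as.matrix(df[dialect$gyro]) * gyr_scale,
                sample_rate = dialect$sample_rate)
}

#' Write an IMU recording as CSV (m/s^2, rad/s)
#' @param rec an [imu_recording()].
#' @param path output file path.
#' @export
write_imu_recording <- function(rec, path) {
  m <- cbind(rec$time, rec$accel, rec$gyro)
  write_numeric_csv(m, c("time", "ax", "ay", "az", "gx", "gy", "gz"), path)
  invisible(path)
}

# full-precision numeric CSV writer used by all output tables
write_numeric_csv <- function(m, header, path) {
  txt <- apply(m, 1, function(r) paste(sprintf("%.15g", r), collapse = ","))
  ok <- tryCatch({
    writeLines(c(paste(header, collapse = ","), txt), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) fc_error("footclear_io_error", paste0("cannot write ", path))
  invisible(path)
}

#' Construct a shoe-scan point cloud
#'
#' Coordinates are stored relative to the IMU fixture origin, so the fixture
#' origin is the zero of the scan frame; downstream pose propagation adds the
#' IMU world position to rotated scan-relative coordinates.
#'
#' @param points N x 3 matrix of point positions in meters (any frame with
#'   consistent axes; the fixture origin is subtracted).
#' @param toe_index,heel_index 1-based row indices of the toe and heel
#'   landmarks (the anterior-most and posterior-most points of the shoe).
#' @param sole_indices integer vector of rows forming the grid over the
#'   bottom surface of the shoe.
#' @param marker_index optional row index of the reflective toe-marker
#'   center (used only for motion-capture validation).
#' @param fixture_origin 3-vector, the IMU center in the same coordinates as
#'   `points`.
#' @param fixture_axes 3 x 3 matrix whose rows are the IMU x/y/z directions
#'   in the scan frame (approximately orthonormal; see [fixture_rotation()]).
#' @param labels optional character vector of point labels.
#' @return An object of class `scan_point_cloud`.
#' @export
scan_point_cloud <- function(points, toe_index, heel_index, sole_indices,
                             marker_index = NULL,
                             fixture_origin = c(0, 0, 0),
                             fixture_axes = diag(3),
                             labels = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 4) fc_data_error("scan cloud needs at least 4 points")
  idx <- c(toe_index, heel_index, marker_index, sole_indices)
  if (any(idx < 1 | idx > n)) fc_contract_error("scan point index out of range")
  if (length(sole_indices) < 3) {
    fc_data_error("scan cloud needs at least 3 sole points")
  }
  sole <- points[sole_indices, , drop = FALSE]
  ev <- eigen(stats::cov(sole), symmetric = TRUE, only.values = TRUE)$values
  if (length(sole_indices) >= 3 && ev[2] <= 1e-16 * max(ev[1], 1e-30)) {
    fc_data_error("sole points are collinear")
  }
  nrm <- sqrt(rowSums(fixture_axes^2))
  if (any(nrm < 0.9 | nrm > 1.1)) {
    fc_calibration_error("fixture axis norm outside [0.9, 1.1]")
  }
  u <- fixture_axes / nrm
  dots <- abs(c(sum(u[1, ] * u[2, ]), sum(u[1, ] * u[3, ]), sum(u[2, ] * u[3, ])))
  if (any(dots >= 0.1)) {
    fc_calibration_error("fixture axes are not close to orthogonal")
  }
  rel <- sweep(points, 2, fixture_origin)
  structure(list(points = unname(rel),
                 toe_index = as.integer(toe_index),
                 heel_index = as.integer(heel_index),
                 marker_index = if (is.null(marker_index)) NULL else as.integer(marker_index),
                 sole_indices = as.integer(sole_indices),
                 fixture_origin = as.numeric(fixture_origin),
                 fixture_axes = unname(as.matrix(fixture_axes)),
                 labels = labels),
            class = "scan_point_cloud")
}

#' @export
print.scan_point_cloud <- function(x, ...) {
  cat(sprintf(paste0("<scan_point_cloud> %d points (%d sole), toe #%d, ",
                     "heel #%d%s\n"),
              nrow(x$points), length(x$sole_indices), x$toe_index,
              x$heel_index,
              if (is.null(x$marker_index)) "" else
                sprintf(", marker #%d", x$marker_index)))
  invisible(x)
}

SCAN_ROLES <- c("origin", "xaxis", "yaxis", "zaxis", "toe", "heel",
                "marker", "sole")

#' Read a shoe-scan point list (CSV dialect `label,role,x,y,z`)
#'
#' Roles: exactly one each of `origin`, `xaxis`, `yaxis`, `zaxis`, `toe`,
#' `heel`; at most one `marker`; one or more `sole`. Axis rows hold unit
#' direction vectors; all other rows hold positions in scanner millimeters,
#' converted to meters on read. Content-point indices follow file order.
#'
#' @param path file path.
#' @return A [scan_point_cloud()].
#' @export
read_scan_points <- function(path) {
  if (!file.exists(path)) fc_format_error(paste0("no such file: ", path))
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(label = "character", role = "character"))
  need <- c("label", "role", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    fc_format_error(paste0("scan file is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  if (any(!df$role %in% SCAN_ROLES)) {
    fc_format_error(paste0("unknown scan role(s): ",
                           paste(unique(setdiff(df$role, SCAN_ROLES)),
                                 collapse = ", ")))
  }
  for (role in c("origin", "xaxis", "yaxis", "zaxis", "toe", "heel")) {
    k <- sum(df$role == role)
    if (k != 1) {
      fc_format_error(sprintf(
        "scan file must contain exactly one '%s' row (found %d)", role, k))
    }
  }
  if (sum(df$role == "marker") > 1) {
    fc_format_error("scan file contains more than one 'marker' row")
  }
  if (sum(df$role == "sole") < 1) {
    fc_format_error("scan file contains no 'sole' rows")
  }
  xyz <- as.matrix(df[, c("x", "y", "z")])
  axes <- rbind(xyz[df$role == "xaxis", ],
                xyz[df$role == "yaxis", ],
                xyz[df$role == "zaxis", ])
  nrm <- sqrt(rowSums(axes^2))
  if (any(nrm < 0.9 | nrm > 1.1)) {
    fc_calibration_error("fixture axis norm outside [0.9, 1.1]")
  }
  origin <- xyz[df$role == "origin", ] / 1000
  content <- which(df$role %in% c("toe", "heel", "marker", "sole"))
  pts <- xyz[content, , drop = FALSE] / 1000
  roles <- df$role[content]
  mk <- which(roles == "marker")
  scan_point_cloud(points = pts,
                   toe_index = which(roles == "toe"),
                   heel_index = which(roles == "heel"),
                   sole_indices = which(roles == "sole"),
                   marker_index = if (length(mk)) mk else NULL,
                   fixture_origin = origin,
                   fixture_axes = axes,
                   labels = df$label[content])
}

#' Write a shoe-scan point cloud in the `label,role,x,y,z` dialect
#' @param cloud a [scan_point_cloud()].
#' @param path output file path.
#' @export
write_scan_points <- function(cloud, path) {
  pts_mm <- sweep(cloud$points, 2, -cloud$fixture_origin) * 1000
  roles <- rep("sole", nrow(pts_mm))
  roles[cloud$toe_index] <- "toe"
  roles[cloud$heel_index] <- "heel"
  if (!is.null(cloud$marker_index)) roles[cloud$marker_index] <- "marker"
  labels <- if (is.null(cloud$labels)) {
    sprintf("p%04d", seq_len(nrow(pts_mm)))
  } else cloud$labels
  row_of <- function(label, role, v) {
    paste(label, role, sprintf("%.15g", v[1]), sprintf("%.15g", v[2]),
          sprintf("%.15g", v[3]), sep = ",")
  }
  lines <- c(
    "label,role,x,y,z",
    row_of("imu", "origin", cloud$fixture_origin * 1000),
    row_of("imu_x", "xaxis", cloud$fixture_axes[1, ]),
    row_of("imu_y", "yaxis", cloud$fixture_axes[2, ]),
    row_of("imu_z", "zaxis", cloud$fixture_axes[3, ]),
    vapply(seq_len(nrow(pts_mm)), function(i) {
      row_of(labels[i], roles[i], pts_mm[i, ])
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Construct a marker trajectory (lab frame, meters)
#'
#' @param time numeric sample times, seconds, strictly increasing.
#' @param position K x 3 matrix, meters; rows may be `NA` where occluded.
#' @param gap_mask logical per sample, `TRUE` where the marker is occluded;
#'   defaults to rows with any `NA`.
#' @export
marker_trajectory <- function(time, position, gap_mask = NULL) {
  position <- as.matrix(position)
  if (any(diff(time) <= 0)) {
    fc_data_error("marker time must be strictly increasing")
  }
  if (is.null(gap_mask)) gap_mask <- apply(position, 1, function(r) any(!is.finite(r)))
  if (any(!gap_mask & !is.finite(position[, 3]))) {
    fc_data_error("non-finite marker position outside gaps")
  }
  structure(list(time = time, position = unname(position),
                 gap_mask = as.logical(gap_mask)),
            class = "marker_trajectory")
}

#' Read a marker trajectory (`time,x,y,z` CSV, meters, empty cells = gaps)
#' @param path file path.
#' @export
read_marker_trajectory <- function(path) {
  if (!file.exists(path)) fc_format_error(paste0("no such file: ", path))
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(c("time", "x", "y", "z"), names(df))
  if (length(missing_cols)) {
    fc_format_error(paste0("marker file is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  marker_trajectory(df$time, as.matrix(df[, c("x", "y", "z")]))
}

#' Write a marker trajectory (`time,x,y,z`, empty cells for gaps)
#' @param traj a [marker_trajectory()].
#' @param path output file path.
#' @export
write_marker_trajectory <- function(traj, path) {
  fmt <- function(v, gap) ifelse(gap, "", sprintf("%.15g", v))
  lines <- paste(sprintf("%.15g", traj$time),
                 fmt(traj$position[, 1], traj$gap_mask),
                 fmt(traj$position[, 2], traj$gap_mask),
                 fmt(traj$position[, 3], traj$gap_mask), sep = ",")
  writeLines(c("time,x,y,z", lines), path)
  invisible(path)
}

#' Write per-stride clearance results
#'
#' One row per stride: `stride_id,t_start_s,valid,mfc_mm,k_mfc,i_mfc,
#' k_max_heel,k_max_toe`. Invalid strides keep their row with empty metric
#' cells. Clearances are written in millimeters.
#'
#' @param strides a list of `stride_clearance` records (see [stride_mfc()]),
#'   each carrying a `t_start` field in seconds.
#' @param path output file path.
#' @export
write_stride_results <- function(strides, path) {
  if (!length(strides)) fc_contract_error("no strides to write")
  cell <- function(v, f = "%.15g") if (is.null(v) || is.na(v)) "" else sprintf(f, v)
  lines <- vapply(strides, function(s) {
    paste(s$stride_id,
          sprintf("%.15g", s$t_start),
          as.character(isTRUE(s$valid)),
          if (isTRUE(s$valid)) cell(s$mfc * 1000) else "",
          if (isTRUE(s$valid)) cell(s$k_mfc, "%d") else "",
          if (isTRUE(s$valid)) cell(s$i_mfc, "%d") else "",
          cell(s$k_max_heel, "%d"),
          cell(s$k_max_toe, "%d"),
          sep = ",")
  }, character(1))
  ok <- tryCatch({
    writeLines(c("stride_id,t_start_s,valid,mfc_mm,k_mfc,i_mfc,k_max_heel,k_max_toe",
                 lines), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) fc_error("footclear_io_error", paste0("cannot write ", path))
  invisible(path)
}
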