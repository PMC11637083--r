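# End-to-end pipeline: configuration, the full bout analysis (detect ->
# smooth -> segment -> reconstruct -> calibrate -> clearance), and the
# file-based runner used by the command-line wrapper.

#' Default run configuration
#'
#' Nested list mirroring the YAML config consumed by the runners. All
#' numeric parameters are config-exposed with the package defaults.
#' @param ... top-level overrides (named lists are merged recursively).
#' @export
default_config <- function(...) {
  cfg <- list(
    io = list(imu = NULL, scan = NULL, marker = NULL,
              imu_dialect = list(accel_unit = "m/s^2", gyro_unit = "rad/s")),
    pdr = list(accel_tol = 0.8, gyro_tol = 0.3, smooth_window = 5,
               min_zupt_len = 15, tilt_gain = 0.02),
    fusion = list(contact_tol_mm = 3, max_iter = 20, max_rstar_deg = 15),
    clearance = list(heatmap_spacing_mm = 2, heatmap_sigma_mm = 10,
                     trend = TRUE),
    validation = list(prominence_mm = 5, min_corr = 0.5),
    out_dir = ".",
    log_level = "info")
  utils::modifyList(cfg, list(...))
}

#' Read a YAML run configuration
#' @param path YAML file; missing keys take package defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) fc_format_error(paste0("no such config: ", path))
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

fc_log <- function(cfg, level, fmt, ...) {
  lv <- c(debug = 1, info = 2, warn = 3)
  if (lv[[level]] >= lv[[cfg$log_level %||% "info"]]) {
    message(sprintf("[footclear %s] %s", level, sprintf(fmt, ...)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyze a complete walking bout
#'
#' The full clearance pipeline on in-memory objects: ZUPT detection and
#' smoothing, stride segmentation, drift-corrected pose reconstruction,
#' fixture calibration, flat-foot correction at the first stance instant,
#' floor-height offset from stance-phase lowest points, per-stride
#' forward-swing windows and minimum foot clearance, and the pooled
#' late-swing lowest-point locations.
#'
#' @param rec an [imu_recording()].
#' @param cloud a [scan_point_cloud()].
#' @param config a [default_config()]-shaped list.
#' @return A `bout_analysis`: `mask`, `segmentation`, `pose`, `calib`,
#'   `lp`, `lp_index`, `heel_z`, `toe_z`, `marker_z` (when the cloud has a
#'   marker), `strides` (list of `stride_clearance`), `late_locations`
#'   (pooled over valid strides), `windows`.
#' @export
analyze_bout <- function(rec, cloud, config = default_config()) {
  p <- config$pdr
  fu <- config$fusion
  mask <- smooth_zupt(
    detect_zupt(rec, p$accel_tol, p$gyro_tol, p$smooth_window),
    p$min_zupt_len)
  runs <- zupt_runs(mask)
  if (nrow(runs) < 2) {
    fc_data_error("bout has fewer than two stance runs after smoothing")
  }
  seg <- segment_strides(mask)
  fc_log(config, "info", "%d stance runs, %d strides", nrow(runs), nrow(seg))
  pose <- reconstruct_pose(rec, mask, tilt_gain = p$tilt_gain)
  r_si <- fixture_rotation(cloud)
  r_star <- compute_flat_correction(cloud, r_si,
                                    pose$rotation[, , runs$start[1]],
                                    contact_tol = fu$contact_tol_mm / 1000,
                                    max_iter = fu$max_iter)
  calib <- frame_calibration(r_si, r_star, floor_offset = 0,
                             max_rstar_deg = fu$max_rstar_deg)
  # lowest point over the sole (equivalent to the full cloud when the sole
  # dominates; fall back to every point otherwise)
  lp_ids <- if (sole_dominates(cloud)) cloud$sole_indices
            else seq_len(nrow(cloud$points))
  hs <- point_heights(pose, calib, cloud, lp_ids)
  tr <- lowest_point_trace(hs, lp_ids)
  lp_by_zupt <- lapply(seq_len(nrow(seg)), function(i) {
    tr$lp[seg$zupt_start[i]:(seg$zupt_end[i] - 1L)]
  })
  calib$floor_offset <- compute_floor_offset(lp_by_zupt)
  fc_log(config, "info", "floor offset %.2f mm", calib$floor_offset * 1000)
  tr$lp <- tr$lp - calib$floor_offset
  heel_z <- point_heights(pose, calib, cloud, cloud$heel_index)[1, ]
  toe_z <- point_heights(pose, calib, cloud, cloud$toe_index)[1, ]
  marker_z <- if (!is.null(cloud$marker_index)) {
    point_heights(pose, calib, cloud, cloud$marker_index)[1, ]
  } else NULL
  windows <- lapply(seq_len(nrow(seg)), function(i) {
    forward_swing_window(seg[i, ], heel_z, toe_z, mask)
  })
  strides <- lapply(seq_len(nrow(seg)), function(i) {
    stride_mfc(tr$lp, tr$lp_index, windows[[i]],
               stride_id = seg$stride_id[i],
               t_start = rec$time[seg$zupt_start[i]])
  })
  n_invalid <- sum(!vapply(strides, function(s) isTRUE(s$valid), TRUE))
  if (n_invalid) fc_log(config, "info", "%d invalid stride(s)", n_invalid)
  late <- do.call(rbind, lapply(windows[vapply(windows, `[[`, TRUE, "valid")],
                                late_swing_lowest_locations,
                                lp_index = tr$lp_index, cloud = cloud))
  structure(list(mask = mask, segmentation = seg, pose = pose, calib = calib,
                 lp = tr$lp, lp_index = tr$lp_index,
                 heel_z = heel_z, toe_z = toe_z, marker_z = marker_z,
                 windows = windows, strides = strides,
                 late_locations = late %||% matrix(numeric(0), 0, 2)),
            class = "bout_analysis")
}

#' @export
print.bout_analysis <- function(x, ...) {
  v <- vapply(x$strides, function(s) isTRUE(s$valid), TRUE)
  m <- vapply(x$strides[v], function(s) s$mfc, numeric(1)) * 1000
  cat(sprintf("<bout_analysis> %d strides (%d valid), mFC %.1f-%.1f mm (median %.1f)\n",
              length(x$strides), sum(v),
              if (length(m)) min(m) else NA, if (length(m)) max(m) else NA,
              if (length(m)) stats::median(m) else NA))
  invisible(x)
}

write_manifest <- function(cfg, out_dir, inputs) {
  inputs <- inputs[vapply(inputs, function(p) is.character(p) && file.exists(p),
                          TRUE)]
  md5 <- if (length(inputs)) as.list(tools::md5sum(unlist(inputs))) else list()
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("footclear")),
         config = cfg,
         input_md5 = md5),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
}

#' Simulate a scenario and write its files
#'
#' Writes the IMU CSV, scan CSV, truth JSON (per-sample rotation vector +
#' position) and a scenario manifest into `out_dir`.
#'
#' @param scenario scenario name, see [scenario_params()].
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed.
#' @param n_strides strides per bout.
#' @param config optional run configuration (for logging only).
#' @return Invisibly, the `ground_truth`.
#' @export
run_simulate <- function(scenario = "typical", out_dir = ".", seed = 1,
                         n_strides = 20, config = default_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- scenario_params(scenario, seed = seed, n_strides = n_strides)
  cloud <- make_shoe_cloud()
  truth <- simulate_foot_poses(params, cloud)
  rec <- synthesize_imu(truth)
  write_imu_recording(rec, file.path(out_dir, "imu.csv"))
  write_scan_points(cloud, file.path(out_dir, "scan.csv"))
  K <- nrow(truth$poses$position)
  jsonlite::write_json(
    list(scenario = scenario, seed = seed,
         rotvec = t(vapply(seq_len(K), function(k) {
           matrix_to_rotvec(truth$poses$rotation[, , k])
         }, numeric(3))),
         position = truth$poses$position,
         zupt_schedule = truth$zupt_schedule),
    file.path(out_dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  write_manifest(config, out_dir, list())
  fc_log(config, "info", "simulated %d strides of '%s' into %s",
         n_strides, scenario, out_dir)
  invisible(truth)
}

#' Run reconstruction from files
#'
#' Reads the IMU CSV named in the config, reconstructs the pose trajectory
#' and stride segmentation, and writes `pose.csv` (time, position,
#' rotation vector) and `strides.csv` to the output directory.
#' @param config a configuration list or YAML path.
#' @return Invisibly, a list with `pose`, `mask`, `segmentation`.
#' @export
run_reconstruct <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  rec <- read_imu_recording(cfg$io$imu, do.call(imu_dialect, cfg$io$imu_dialect))
  p <- cfg$pdr
  mask <- smooth_zupt(detect_zupt(rec, p$accel_tol, p$gyro_tol,
                                  p$smooth_window), p$min_zupt_len)
  seg <- segment_strides(mask)
  pose <- reconstruct_pose(rec, mask, tilt_gain = p$tilt_gain)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  K <- nrow(pose$position)
  rv <- t(vapply(seq_len(K), function(k) matrix_to_rotvec(pose$rotation[, , k]),
                 numeric(3)))
  write_numeric_csv(cbind(pose$time, pose$position, rv),
                    c("time", "px", "py", "pz", "rx", "ry", "rz"),
                    file.path(cfg$out_dir, "pose.csv"))
  write_numeric_csv(as.matrix(seg),
                    c("stride_id", "zupt_start", "zupt_end", "stride_end"),
                    file.path(cfg$out_dir, "strides.csv"))
  write_manifest(cfg, cfg$out_dir, list(cfg$io$imu))
  fc_log(cfg, "info", "reconstructed %d samples, %d strides", K, nrow(seg))
  invisible(list(pose = pose, mask = mask, segmentation = seg))
}

#' Run the full clearance analysis from files
#'
#' Reads the IMU and scan CSVs named in the config, runs [analyze_bout()],
#' and writes `results.csv` (per-stride clearance), `heatmap.csv` (+ JSON
#' sidecar) and, when configured, `trend.json`.
#' @param config a configuration list or YAML path.
#' @return Invisibly, the `bout_analysis`.
#' @export
run_clearance <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  rec <- read_imu_recording(cfg$io$imu, do.call(imu_dialect, cfg$io$imu_dialect))
  cloud <- read_scan_points(cfg$io$scan)
  ba <- analyze_bout(rec, cloud, cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_stride_results(ba$strides, file.path(cfg$out_dir, "results.csv"))
  hm <- sole_density_heatmap(ba$late_locations, cloud,
                             spacing = cfg$clearance$heatmap_spacing_mm / 1000,
                             sigma = cfg$clearance$heatmap_sigma_mm / 1000)
  write_heatmap(hm, file.path(cfg$out_dir, "heatmap.csv"))
  if (isTRUE(cfg$clearance$trend) &&
      sum(vapply(ba$strides, function(s) isTRUE(s$valid), TRUE)) >= 3) {
    jsonlite::write_json(clearance_trend(ba$strides),
                         file.path(cfg$out_dir, "trend.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_manifest(cfg, cfg$out_dir, list(cfg$io$imu, cfg$io$scan))
  invisible(ba)
}

#' Run the motion-capture agreement analysis from files
#'
#' Reads IMU, scan and marker CSVs, reconstructs the bout, resamples the
#' reference onto the IMU timebase, matches strides by cross-correlation,
#' extracts swing key points (MaxP1/MinP/MaxP2) from both sources, and fits
#' the mixed-effects limits of agreement on their differences
#' (reconstruction minus reference, in mm). Strides whose two sources
#' disagree on shape class (M vs single-peak) are excluded and counted.
#'
#' @param config a configuration list or YAML path.
#' @param participant_id identifier used in the agreement model.
#' @return Invisibly, a list with `agreement`, `pairs` (per-key-point
#'   table), `n_shape_mismatch`.
#' @export
run_validate <- function(config, participant_id = "P1") {
  cfg <- if (is.character(config)) read_config(config) else config
  rec <- read_imu_recording(cfg$io$imu, do.call(imu_dialect, cfg$io$imu_dialect))
  cloud <- read_scan_points(cfg$io$scan)
  if (is.null(cloud$marker_index)) {
    fc_calibration_error("scan has no toe-marker point; cannot validate")
  }
  ref <- read_marker_trajectory(cfg$io$marker)
  ba <- analyze_bout(rec, cloud, cfg)
  res <- validate_against_reference(ba, ref, participant_id,
                                    prominence = cfg$validation$prominence_mm / 1000,
                                    min_corr = cfg$validation$min_corr)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ag <- res$agreement
  jsonlite::write_json(
    list(bias_mm = ag$bias, lower_mm = ag$lower, upper_mm = ag$upper,
         var_components_mm2 = list(participant = ag$var_participant,
                                   stride = ag$var_stride,
                                   residual = ag$var_residual),
         n = ag$n, r_squared = ag$r_squared,
         n_shape_mismatch = res$n_shape_mismatch,
         lag = res$lag, correlation = res$correlation),
    file.path(cfg$out_dir, "agreement.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(res$pairs, file.path(cfg$out_dir, "pairs.csv"),
                   row.names = FALSE)
  write_manifest(cfg, cfg$out_dir,
                 list(cfg$io$imu, cfg$io$scan, cfg$io$marker))
  invisible(res)
}

#' Key-point agreement between a bout analysis and a reference trajectory
#'
#' In-memory core of [run_validate()]. Differences are reconstruction minus
#' reference, in millimeters.
#' @param ba a `bout_analysis` (from a cloud with a marker point).
#' @param ref a [marker_trajectory()] in the lab frame; only heights are
#'   compared (the reconstruction heading is arbitrary).
#' @param participant_id identifier for the agreement model.
#' @param prominence key-point peak prominence, meters.
#' @param min_corr minimum stride-matching correlation.
#' @export
validate_against_reference <- function(ba, ref, participant_id = "P1",
                                       prominence = 0.005, min_corr = 0.5) {
  t_imu <- ba$pose$time
  keep <- t_imu >= ref$time[1] & t_imu <= ref$time[length(ref$time)]
  rez <- rep(NA_real_, length(t_imu))
  rs <- resample_trajectory(ref, t_imu[keep])
  rez[keep] <- rs$position[, 3]
  # reference heights are expected floor-referenced (lab origin on the
  # floor), the same datum the reconstruction uses; any datum discrepancy
  # shows up as agreement bias, which is what the analysis measures
  pairs_df <- NULL
  seg <- ba$segmentation
  matches <- match_strides(ba$marker_z, seg, rez, min_corr = min_corr)
  n_mismatch <- 0L
  for (i in seq_len(nrow(matches))) {
    sid <- matches$stride_id[i]
    srow <- seg[seg$stride_id == sid, ]
    ks <- srow$zupt_start:(srow$stride_end - 1L)
    swing <- !ba$mask$flags[ks]
    kp_rec <- tryCatch(
      extract_key_points(ba$marker_z[ks], prominence, swing),
      footclear_data_error = function(e) NULL)
    rks <- matches$ref_start[i]:(matches$ref_end[i] - 1L)
    kp_ref <- tryCatch(
      extract_key_points(rez[rks], prominence, swing),
      footclear_data_error = function(e) NULL)
    if (is.null(kp_rec) || is.null(kp_ref)) next
    if (kp_rec$shape != kp_ref$shape) {
      n_mismatch <- n_mismatch + 1L
      next
    }
    kp <- if (kp_rec$shape == "M") c("max_p1", "min_p", "max_p2") else "max_p2"
    pairs_df <- rbind(pairs_df, data.frame(
      participant_id = participant_id, stride_id = sid, keypoint = kp,
      recon_mm = vapply(kp, function(f) kp_rec[[f]], 1) * 1000,
      ref_mm = vapply(kp, function(f) kp_ref[[f]], 1) * 1000))
  }
  if (is.null(pairs_df) || nrow(pairs_df) < 2) {
    fc_alignment_error("fewer than 2 matched key points; cannot assess agreement")
  }
  pairs_df$diff_mm <- pairs_df$recon_mm - pairs_df$ref_mm
  ag <- limits_of_agreement(pairs_df$diff_mm, pairs_df$participant_id,
                            pairs_df$stride_id,
                            recon = pairs_df$recon_mm, ref = pairs_df$ref_mm)
  list(agreement = ag, pairs = pairs_df, n_shape_mismatch = n_mismatch,
       lag = if (nrow(matches)) matches$lag[1] else NA_integer_,
       correlation = attr(matches, "correlation"))
}
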