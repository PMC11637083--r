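# Instantaneous lowest point, forward-swing window, per-stride minimum foot
# clearance (mFC), late-swing lowest-point mapping, and the within-bout
# clearance trend.

#' Instantaneous lowest point over the sole
#'
#' `lp(k) = min_i z_i(k)` over the sole points, with the minimizing point
#' index (earliest index on ties). Restricting the minimum to sole points
#' equals the minimum over the whole cloud whenever every non-sole point
#' lies above some sole point (checked by [sole_dominates()]), since dorsal
#' points can never be lowest on a rigid shoe.
#'
#' @param heights n_points x K matrix of world heights (rows follow
#'   `point_ids`).
#' @param point_ids integer vector mapping rows of `heights` to cloud point
#'   indices.
#' @return List with `lp` (height per sample, meters) and `lp_index` (cloud
#'   point index per sample).
#' @export
lowest_point_trace <- function(heights, point_ids = seq_len(nrow(heights))) {
  if (!nrow(heights)) fc_contract_error("no points in lowest-point trace")
  which_min <- max.col(-t(heights), ties.method = "first")
  list(lp = heights[cbind(which_min, seq_len(ncol(heights)))],
       lp_index = point_ids[which_min])
}

#' Does the sole dominate the rest of the cloud?
#'
#' `TRUE` when, in the scan frame, every non-sole point lies strictly above
#' the sole's supporting plane, so the instantaneous lowest point can be
#' searched over sole points only.
#' @param cloud a [scan_point_cloud()].
#' @export
sole_dominates <- function(cloud) {
  sole <- cloud$points[cloud$sole_indices, , drop = FALSE]
  others <- setdiff(seq_len(nrow(cloud$points)), cloud$sole_indices)
  if (!length(others)) return(TRUE)
  pl <- fit_support_plane(sole)
  d <- as.numeric(cloud$points[others, , drop = FALSE] %*% pl$normal) - pl$offset
  all(d > 0)
}

#' Forward-swing window of one stride
#'
#' Forward swing runs from the stride's maximum heel height to its maximum
#' toe height (the interval in which the foot moves forward); both argmaxes
#' are over the whole stride, first index on ties. The window is invalid
#' (flag, never an error) when the toe peak does not follow the heel peak or
#' a peak falls inside stance - which can happen for atypical gait.
#'
#' @param stride one row of a `stride_segmentation`.
#' @param heel_z,toe_z heights per sample (full-bout vectors, meters).
#' @param zupt the smoothed `zupt_mask`.
#' @return List with `k_max_heel`, `k_max_toe` (1-based sample indices into
#'   the bout) and `valid`.
#' @export
forward_swing_window <- function(stride, heel_z, toe_z, zupt) {
  ks <- stride$zupt_start:(stride$stride_end - 1L)
  k_heel <- ks[which.max(heel_z[ks])]
  k_toe <- ks[which.max(toe_z[ks])]
  valid <- (k_heel < k_toe) && !zupt$flags[k_heel] && !zupt$flags[k_toe]
  list(k_max_heel = k_heel, k_max_toe = k_toe, valid = valid)
}

#' Per-stride minimum foot clearance
#'
#' `mFC = min lp(k)` over the closed forward-swing window; negative values
#' are preserved (they indicate floor contact / scuffing).
#'
#' @param lp,lp_index lowest-point trace from [lowest_point_trace()].
#' @param window a window from [forward_swing_window()].
#' @param stride_id stride identifier.
#' @param t_start stride start time in seconds (for the results table).
#' @return A `stride_clearance` record: `stride_id`, `t_start`,
#'   `k_max_heel`, `k_max_toe`, `mfc` (meters), `k_mfc`, `i_mfc`, `valid`.
#' @export
stride_mfc <- function(lp, lp_index, window, stride_id = 1L, t_start = NA_real_) {
  out <- list(stride_id = stride_id, t_start = t_start,
              k_max_heel = window$k_max_heel, k_max_toe = window$k_max_toe,
              mfc = NA_real_, k_mfc = NA_integer_, i_mfc = NA_integer_,
              valid = FALSE)
  if (isTRUE(window$valid)) {
    ks <- window$k_max_heel:window$k_max_toe
    j <- which.min(lp[ks])
    out$k_mfc <- ks[j]
    out$mfc <- lp[ks[j]]
    out$i_mfc <- lp_index[ks[j]]
    out$valid <- TRUE
  }
  class(out) <- "stride_clearance"
  out
}

#' @export
print.stride_clearance <- function(x, ...) {
  if (isTRUE(x$valid)) {
    cat(sprintf("<stride_clearance> #%s mFC = %.2f mm at sample %d (point %d)\n",
                x$stride_id, x$mfc * 1000, x$k_mfc, x$i_mfc))
  } else {
    cat(sprintf("<stride_clearance> #%s invalid window\n", x$stride_id))
  }
  invisible(x)
}

#' Scan-frame locations of the late-swing lowest points
#'
#' Late swing is the final third of the forward-swing window:
#' `k` from `k_max_heel + ceiling(2 (k_max_toe - k_max_heel) / 3)` to
#' `k_max_toe`. For each such sample the scan-frame x, y of the
#' instantaneous lowest point is emitted; this is where on the sole the shoe
#' comes closest to the floor when dorsiflexion should be greatest.
#'
#' @param window a valid window from [forward_swing_window()].
#' @param lp_index per-sample lowest-point indices.
#' @param cloud a [scan_point_cloud()].
#' @return m x 2 matrix of scan-frame (x, y) coordinates, meters.
#' @export
late_swing_lowest_locations <- function(window, lp_index, cloud) {
  if (!isTRUE(window$valid)) fc_contract_error("window is not valid")
  w <- window$k_max_toe - window$k_max_heel
  if (w < 3) {
    warning("forward-swing window shorter than 3 samples; no late swing")
    return(matrix(numeric(0), 0, 2))
  }
  ks <- (window$k_max_heel + ceiling(2 * w / 3)):window$k_max_toe
  cloud$points[lp_index[ks], 1:2, drop = FALSE]
}

#' Gaussian density of lowest-point locations over the sole grid
#'
#' A uniform grid is laid over the sole's bounding box padded by three
#' bandwidths; each location contributes an isotropic Gaussian kernel, and
#' the summed density is normalized by its maximum (all-zero when there are
#' no locations). Marginal histograms of the raw locations are binned at
#' the grid spacing.
#'
#' @param locations m x 2 matrix of scan-frame (x, y), meters (e.g. pooled
#'   [late_swing_lowest_locations()] over strides).
#' @param cloud a [scan_point_cloud()] (defines the sole bounding box).
#' @param spacing grid spacing, meters (default 2 mm).
#' @param sigma kernel bandwidth, meters (default 10 mm).
#' @return A `sole_heatmap`: `grid_x`, `grid_y`, `density` (length(grid_x) x
#'   length(grid_y), max 1), `bandwidth`, `marginal_x`, `marginal_y`
#'   (counts per grid cell), `n_locations`.
#' @export
sole_density_heatmap <- function(locations, cloud, spacing = 0.002,
                                 sigma = 0.010) {
  if (spacing <= 0 || sigma <= 0) {
    fc_contract_error("heatmap spacing and sigma must be positive")
  }
  locations <- matrix(as.numeric(locations), ncol = 2)
  sole <- cloud$points[cloud$sole_indices, , drop = FALSE]
  pad <- 3 * sigma
  gx <- seq(min(sole[, 1]) - pad, max(sole[, 1]) + pad, by = spacing)
  gy <- seq(min(sole[, 2]) - pad, max(sole[, 2]) + pad, by = spacing)
  dens <- matrix(0, length(gx), length(gy))
  m <- nrow(locations)
  if (m) {
    dx2 <- outer(gx, locations[, 1], "-")^2   # |gx| x m
    dy2 <- outer(gy, locations[, 2], "-")^2   # |gy| x m
    for (j in seq_len(m)) {
      dens <- dens + exp(-(outer(dx2[, j], dy2[, j], "+")) / (2 * sigma^2))
    }
    dens <- dens / max(dens)
  }
  bin <- function(v, g) {
    breaks <- c(g - spacing / 2, g[length(g)] + spacing / 2)
    as.integer(table(cut(pmin(pmax(v, g[1]), g[length(g)]), breaks)))
  }
  structure(list(grid_x = gx, grid_y = gy, density = dens, bandwidth = sigma,
                 spacing = spacing,
                 marginal_x = if (m) bin(locations[, 1], gx) else integer(length(gx)),
                 marginal_y = if (m) bin(locations[, 2], gy) else integer(length(gy)),
                 n_locations = m),
            class = "sole_heatmap")
}

#' @export
print.sole_heatmap <- function(x, ...) {
  cat(sprintf("<sole_heatmap> %d x %d grid @ %.1f mm, sigma %.1f mm, %d locations\n",
              length(x$grid_x), length(x$grid_y), x$spacing * 1000,
              x$bandwidth * 1000, x$n_locations))
  invisible(x)
}

#' Write a heatmap as a dense matrix CSV plus a JSON sidecar
#' @param hm a `sole_heatmap`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @export
write_heatmap <- function(hm, path) {
  write_numeric_csv(hm$density, sprintf("y%d", seq_along(hm$grid_y)), path)
  jsonlite::write_json(
    list(grid_origin = c(hm$grid_x[1], hm$grid_y[1]),
         spacing = hm$spacing, bandwidth = hm$bandwidth,
         n_x = length(hm$grid_x), n_y = length(hm$grid_y),
         n_locations = hm$n_locations,
         marginal_x = hm$marginal_x, marginal_y = hm$marginal_y),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Within-bout trend of minimum foot clearance
#'
#' Ordinary least-squares fit of mFC (mm) against stride start time
#' (minutes), with the exact t-test p-value for zero slope. Summarizes
#' fatigue-related clearance decline over e.g. a six-minute walk test.
#'
#' @param strides list of `stride_clearance` records (invalid ones are
#'   dropped).
#' @return List with `slope_mm_per_min`, `intercept_mm`, `p_value`,
#'   `n_strides`.
#' @export
clearance_trend <- function(strides) {
  valid <- Filter(function(s) isTRUE(s$valid), strides)
  if (length(valid) < 3) {
    fc_data_error("clearance trend needs at least 3 valid strides")
  }
  t_min <- vapply(valid, function(s) s$t_start, numeric(1)) / 60
  mfc_mm <- vapply(valid, function(s) s$mfc, numeric(1)) * 1000
  if (stats::sd(mfc_mm) == 0) {
    return(list(slope_mm_per_min = 0, intercept_mm = mfc_mm[1], p_value = 1,
                n_strides = length(valid)))
  }
  fit <- stats::lm(mfc_mm ~ t_min)
  co <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(co) >= 2 && !is.nan(co[2, 4])) co[2, 4] else 1
  list(slope_mm_per_min = unname(stats::coef(fit)[2]),
       intercept_mm = unname(stats::coef(fit)[1]),
       p_value = p, n_strides = length(valid))
}
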