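# Validation against optical motion capture: reference resampling, stride
# matching by cross-correlation, swing-phase key-point extraction
# (MaxP1/MinP/MaxP2), and mixed-effects limits of agreement.

#' Resample a marker trajectory by linear interpolation
#'
#' Piecewise-linear interpolation per coordinate onto `target_times`
#' (typically the IMU timebase, downsampling a 200 Hz lab recording to
#' 128 Hz). A target sample whose bracketing source interval touches an
#' occlusion gap is itself flagged as a gap.
#'
#' @param traj a [marker_trajectory()].
#' @param target_times times to sample at, seconds; must lie within the
#'   source time span.
#' @return A [marker_trajectory()] on `target_times`.
#' @export
resample_trajectory <- function(traj, target_times) {
  t0 <- traj$time[1]
  t1 <- traj$time[length(traj$time)]
  if (any(target_times < t0 - 1e-12) || any(target_times > t1 + 1e-12)) {
    fc_data_error("target times fall outside the marker time span")
  }
  tt <- pmin(pmax(target_times, t0), t1)
  idx <- findInterval(tt, traj$time, rightmost.closed = TRUE)
  idx <- pmin(idx, length(traj$time) - 1L)
  w <- (tt - traj$time[idx]) / (traj$time[idx + 1L] - traj$time[idx])
  pos <- (1 - w) * traj$position[idx, , drop = FALSE] +
    w * traj$position[idx + 1L, , drop = FALSE]
  gap <- traj$gap_mask[idx] | traj$gap_mask[idx + 1L]
  pos[gap, ] <- NA_real_
  marker_trajectory(target_times, pos, gap)
}

#' Match reconstruction strides to a reference height signal
#'
#' A single global lag is estimated by maximizing the Pearson
#' cross-correlation between the reconstructed toe height and the reference
#' toe height (both on the common timebase); each stride is then paired with
#' the reference window at that lag. Pairs whose reference window overlaps a
#' gap, or extends outside the reference, are dropped.
#'
#' @param recon_toe_z reconstructed toe height per sample, meters.
#' @param seg a `stride_segmentation`.
#' @param ref_toe_z reference toe height per sample (same sample rate);
#'   `NA` where gapped.
#' @param max_lag largest |lag| searched, samples.
#' @param min_corr minimum acceptable peak correlation.
#' @return data.frame with `stride_id`, `ref_start`, `ref_end`, `lag`, plus
#'   attribute `correlation`. Reference window index = stride index + lag.
#' @export
match_strides <- function(recon_toe_z, seg, ref_toe_z,
                          max_lag = NULL, min_corr = 0.5) {
  n <- length(recon_toe_z)
  m <- length(ref_toe_z)
  if (is.null(max_lag)) max_lag <- max(n, m) %/% 2
  best <- c(lag = 0, corr = -Inf)
  for (lag in -max_lag:max_lag) {
    i0 <- max(1L, 1L - lag)
    i1 <- min(n, m - lag)
    if (i1 - i0 < 16L) next
    a <- recon_toe_z[i0:i1]
    b <- ref_toe_z[(i0 + lag):(i1 + lag)]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 16L) next
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) next
    r <- stats::cor(a[ok], b[ok])
    if (r > best["corr"]) best <- c(lag = lag, corr = r)
  }
  if (!is.finite(best["corr"]) || best["corr"] < min_corr) {
    fc_alignment_error(sprintf(
      "stride matching failed: peak cross-correlation %.3f below %.2f",
      max(best["corr"], -1), min_corr))
  }
  lag <- as.integer(best["lag"])
  rows <- lapply(seq_len(nrow(seg)), function(i) {
    a <- seg$zupt_start[i] + lag
    b <- seg$stride_end[i] + lag
    if (a < 1L || b - 1L > m) return(NULL)
    if (anyNA(ref_toe_z[a:(b - 1L)])) return(NULL)
    data.frame(stride_id = seg$stride_id[i], ref_start = a, ref_end = b,
               lag = lag)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(stride_id = integer(0), ref_start = integer(0),
                      ref_end = integer(0), lag = integer(0))
  }
  attr(out, "correlation") <- unname(best["corr"])
  out
}

# topographic prominence of each local maximum of x (returned as data.frame)
local_maxima_prominence <- function(x) {
  n <- length(x)
  # local maxima incl. plateau starts: rising (or start) then falling
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left_up <- if (i == 1) FALSE else x[i] > x[i - 1]
    # walk right over any plateau
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    right_down <- if (j == n) FALSE else x[i] > x[j + 1]
    first_of_plateau <- i == 1 || x[i] != x[i - 1]
    is_peak[i] <- first_of_plateau &&
      ((left_up && right_down) ||
         (i == 1 && right_down) || (j == n && left_up))
  }
  # boundary samples are not treated as peaks
  peaks <- which(is_peak)
  peaks <- peaks[peaks > 1 & peaks < n]
  prom <- vapply(peaks, function(p) {
    h <- x[p]
    lm <- Inf
    i <- p - 1
    while (i >= 1 && x[i] <= h) { lm <- min(lm, x[i]); i <- i - 1 }
    left_col <- if (i >= 1) lm else min(lm, x[1])
    rm_ <- Inf
    i <- p + 1
    while (i <= n && x[i] <= h) { rm_ <- min(rm_, x[i]); i <- i + 1 }
    right_col <- if (i <= n) rm_ else min(rm_, x[n])
    h - max(min(left_col, h), min(right_col, h))
  }, numeric(1))
  data.frame(index = peaks, height = x[peaks], prominence = prom)
}

#' Extract swing-phase key points (MaxP1, MinP, MaxP2)
#'
#' Toe-height trajectories during swing are typically M-shaped (two maxima
#' with a valley between); impaired gait may show a single maximum. Local
#' maxima with topographic prominence of at least `prominence_min` are
#' located among the stride's non-stance samples. With two or more
#' qualifying maxima the first is MaxP1, the last MaxP2, and MinP is the
#' minimum strictly between them; with exactly one, only MaxP2 is set.
#'
#' @param toe_z toe height over one stride, meters (stance samples excluded
#'   by the caller or via `swing_mask`).
#' @param prominence_min minimum peak prominence, meters (default 5 mm).
#' @param swing_mask optional logical vector: which samples of `toe_z` are
#'   swing (non-stance); peaks are only accepted there.
#' @return A `key_point_set`: `max_p1`, `min_p` (both `NA` for single-peak
#'   strides), `max_p2` (meters), `n_peaks`, `shape` ("M" or "single").
#' @export
extract_key_points <- function(toe_z, prominence_min = 0.005,
                               swing_mask = NULL) {
  if (length(toe_z) < 5) fc_data_error("key-point extraction needs >= 5 samples")
  pk <- local_maxima_prominence(toe_z)
  pk <- pk[pk$prominence >= prominence_min, , drop = FALSE]
  if (!is.null(swing_mask)) pk <- pk[swing_mask[pk$index], , drop = FALSE]
  if (!nrow(pk)) {
    fc_data_error("no swing-phase maximum with the required prominence")
  }
  if (nrow(pk) == 1) {
    out <- list(max_p1 = NA_real_, min_p = NA_real_, max_p2 = pk$height[1],
                k_max_p2 = pk$index[1], n_peaks = 1L, shape = "single")
  } else {
    i1 <- pk$index[1]
    i2 <- pk$index[nrow(pk)]
    between <- toe_z[(i1 + 1):(i2 - 1)]
    out <- list(max_p1 = pk$height[1],
                min_p = min(between),
                max_p2 = pk$height[nrow(pk)],
                k_max_p1 = i1, k_min_p = i1 + which.min(between),
                k_max_p2 = i2,
                n_peaks = nrow(pk), shape = "M")
  }
  class(out) <- "key_point_set"
  out
}

# nested method-of-moments variance components (fallback for singular fits)
moments_variance_components <- function(d, pid, sid) {
  pid <- as.character(pid)
  sid <- paste(pid, as.character(sid), sep = "/")
  # residual: pooled within-stride variance (strides with >= 2 obs)
  by_stride <- split(d, sid)
  reps <- vapply(by_stride, length, 1L)
  if (any(reps >= 2)) {
    ss <- sum(vapply(by_stride, function(v) sum((v - mean(v))^2), numeric(1)))
    var_e <- ss / sum(pmax(reps - 1L, 0L))
  } else var_e <- 0
  stride_means <- vapply(by_stride, mean, numeric(1))
  stride_pid <- vapply(strsplit(names(by_stride), "/"), `[`, "", 1)
  by_pid <- split(stride_means, stride_pid)
  nstr <- vapply(by_pid, length, 1L)
  if (any(nstr >= 2)) {
    ss <- sum(vapply(by_pid, function(v) sum((v - mean(v))^2), numeric(1)))
    var_sm <- ss / sum(pmax(nstr - 1L, 0L))          # var of stride means
    var_w <- max(var_sm - var_e / mean(reps), 0)
  } else var_w <- 0
  pid_means <- vapply(by_pid, mean, numeric(1))
  if (length(pid_means) >= 2) {
    var_pm <- stats::var(pid_means)
    var_u <- max(var_pm - var_w / mean(nstr) - var_e / mean(reps * nstr[1]), 0)
  } else var_u <- 0
  if (var_e == 0 && var_w == 0 && var_u == 0) var_e <- stats::var(d)
  if (!is.finite(var_e)) var_e <- 0
  list(var_participant = var_u, var_stride = var_w, var_residual = var_e)
}

#' Mixed-effects limits of agreement
#'
#' Fits `difference ~ 1` with random intercepts for stride nested within
#' participant by REML (`nlme::lme`), the model used for method-comparison
#' data where repeated key points per stride and repeated strides per
#' participant violate the independence assumption of classic Bland-Altman
#' limits. The bias is the fixed intercept; the 95% limits are
#' `bias +- 1.96 * sqrt(var_participant + var_stride + var_residual)`.
#' Degenerate zero-variance input returns the constant with collapsed
#' limits; a singular fit falls back to method-of-moments variance
#' components with a warning.
#'
#' @param differences numeric, reconstruction minus reference, millimeters.
#' @param participant_ids,stride_ids grouping factors; each stride id must
#'   be nested under one participant.
#' @param recon,ref optional paired heights (same length) used only to
#'   report the squared Pearson correlation.
#' @return An `agreement_result`: `bias`, `lower`, `upper` (mm),
#'   `var_participant`, `var_stride`, `var_residual` (mm^2), `n`,
#'   `r_squared`.
#' @export
limits_of_agreement <- function(differences, participant_ids, stride_ids,
                                recon = NULL, ref = NULL) {
  d <- as.numeric(differences)
  n <- length(d)
  if (n < 2) fc_data_error("limits of agreement need at least 2 differences")
  if (length(participant_ids) != n || length(stride_ids) != n) {
    fc_contract_error("grouping vectors must match the differences in length")
  }
  r2 <- if (!is.null(recon) && !is.null(ref)) stats::cor(recon, ref)^2 else NA_real_
  finish <- function(bias, vu, vw, ve) {
    tot_sd <- sqrt(vu + vw + ve)
    structure(list(bias = bias, lower = bias - 1.96 * tot_sd,
                   upper = bias + 1.96 * tot_sd,
                   var_participant = vu, var_stride = vw, var_residual = ve,
                   n = n, r_squared = r2),
              class = "agreement_result")
  }
  if (stats::var(d) == 0) return(finish(d[1], 0, 0, 0))
  df <- data.frame(d = d, pid = factor(participant_ids),
                   sid = factor(stride_ids))
  fit <- tryCatch(
    nlme::lme(d ~ 1, random = ~ 1 | pid / sid, data = df),
    error = function(e) NULL)
  if (!is.null(fit)) {
    vc <- suppressWarnings(nlme::VarCorr(fit))
    vals <- suppressWarnings(as.numeric(vc[, "Variance"]))
    # rows: pid intercept, sid-in-pid intercept, residual (with headers)
    vu <- vals[which(rownames(vc) == "(Intercept)")[1]]
    vw <- vals[which(rownames(vc) == "(Intercept)")[2]]
    ve <- vals[rownames(vc) == "Residual"]
    if (all(is.finite(c(vu, vw, ve)))) {
      return(finish(unname(nlme::fixef(fit)[1]), vu, vw, ve))
    }
  }
  warning("singular mixed-model fit; using method-of-moments variance components")
  mm <- moments_variance_components(d, participant_ids, stride_ids)
  finish(mean(d), mm$var_participant, mm$var_stride, mm$var_residual)
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> bias %.2f mm, 95%% limits [%.2f, %.2f] mm (n = %d)\n",
    x$bias, x$lower, x$upper, x$n))
  cat(sprintf("  variance components (mm^2): participant %.3g, stride %.3g, residual %.3g\n",
              x$var_participant, x$var_stride, x$var_residual))
  if (is.finite(x$r_squared)) cat(sprintf("  R^2 (paired heights) %.3f\n", x$r_squared))
  invisible(x)
}
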