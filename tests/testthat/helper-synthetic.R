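# Shared fixtures, memoized so expensive simulations run once per session.

.fc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fc_cache[[key]])) assign(key, force(expr), envir = .fc_cache)
  .fc_cache[[key]]
}

test_cloud <- function() cached("cloud", make_shoe_cloud())

# coarse cloud for brute-force oracles
coarse_cloud <- function() {
  cached("coarse_cloud", make_shoe_cloud(grid_spacing = 0.02))
}

sim_bout <- function(scenario = "typical", seed = 1, n_strides = 5, ...) {
  extra <- list(...)
  key <- paste("bout", scenario, seed, n_strides,
               paste(names(extra), vapply(extra, paste, "", collapse = "/"),
                     collapse = ","))
  cached(key, {
    params <- scenario_params(scenario, seed = seed, n_strides = n_strides, ...)
    truth <- simulate_foot_poses(params, test_cloud())
    list(params = params, truth = truth,
         rec = synthesize_imu(truth),
         oracle = oracle_clearance(truth))
  })
}

quiet_config <- function(...) default_config(log_level = "warn", ...)

analyzed_bout <- function(scenario = "typical", seed = 1, n_strides = 5, ...) {
  b <- sim_bout(scenario, seed, n_strides, ...)
  extra <- list(...)
  key <- paste("ba", scenario, seed, n_strides,
               paste(names(extra), vapply(extra, paste, "", collapse = "/"),
                     collapse = ","))
  cached(key, analyze_bout(b$rec, test_cloud(), quiet_config()))
}

# exact stance mask from a ground truth
truth_mask <- function(truth) {
  fl <- rep(FALSE, nrow(truth$poses$position))
  for (i in seq_len(nrow(truth$zupt_schedule))) {
    fl[truth$zupt_schedule$start[i]:(truth$zupt_schedule$end[i] - 1L)] <- TRUE
  }
  zupt_mask(fl)
}

# a stationary recording: level sensor measuring exactly gravity
static_recording <- function(n = 64, sample_rate = 128) {
  imu_recording(time = (seq_len(n) - 1) / sample_rate,
                accel = matrix(rep(c(0, 0, 9.80665), each = n), n, 3),
                gyro = matrix(0, n, 3))
}

random_rotation <- function() {
  v <- stats::rnorm(3)
  footclear:::rotvec_to_matrix(v / sqrt(sum(v^2)) * stats::runif(1, 0, pi * 0.9))
}

mfc_of <- function(strides) vapply(strides, function(s) s$mfc, numeric(1))
valid_of <- function(strides) vapply(strides, function(s) isTRUE(s$valid), TRUE)
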