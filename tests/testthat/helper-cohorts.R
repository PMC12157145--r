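# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_cohort <- function() {
  cached("default_cohort", simulate_cohort(gait_sim_config(seed = 11)))
}

default_features <- function() {
  cached("default_features", build_feature_table(default_cohort()))
}

quiet_cohort <- function() {
  cached("quiet_cohort",
         simulate_cohort(zero_noise(gait_sim_config(n_participants = 4,
                                                    seed = 3))))
}

# one zero-noise single-trial recording with a known mounting rotation
single_trial <- function(seed, misalignment_deg = 20, gyro_noise_sd = 0,
                         cycles = 10) {
  cfg <- gait_sim_config(n_participants = 1, trials_per_participant = 1,
                         cycles_per_trial = cycles,
                         misalignment_deg = misalignment_deg,
                         gyro_noise_sd = gyro_noise_sd, accel_noise_sd = 0,
                         sta_amp = 0, hip_noise_sd = 0,
                         pelvis_tilt_amp_sd = 0, seed = seed)
  simulate_cohort(cfg)$trials[[1]]
}

angle_between_deg <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, abs(sum(a * b)))) * 180 / pi
}
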