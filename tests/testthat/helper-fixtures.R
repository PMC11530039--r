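# Small simulated walks and feature sets shared across test files.
# Everything is generated in code at test time; nothing is stored on disk.

# cadence_cv = 0 gives strictly periodic gait with exactly known times
quiet_walk <- function(duration_s = 10, cadence = 1, noise_sd = 0,
                       duty_factor = 0.6, progression_speed = 0, seed = 1L,
                       sampling_rate = 150, cadence_cv = 0) {
  simulate_walk(gait_sim_config(
    sampling_rate = sampling_rate, duration_s = duration_s,
    cadence = cadence, cadence_cv = cadence_cv, noise_sd = noise_sd,
    duty_factor = duty_factor, progression_speed = progression_speed,
    seed = seed
  ))
}

# Feature series + window pairs for one side of a walk, standardized on its
# own trajectory.
walk_features <- function(walk, side = "left") {
  std <- fit_standardization(list(relative_positions(walk[[side]]$trajectory)))
  list(std = std,
       feat = feature_series(walk[[side]]$trajectory, std))
}

# Independent single-window forward pass: plain loops over the layer
# definitions, no matrix batching. Oracle for the vectorized implementation.
naive_forward <- function(params, window) {
  a <- window
  for (l in 1:4) {
    z <- numeric(ncol(params[[l]]$W))
    for (j in seq_along(z)) {
      z[j] <- sum(a * params[[l]]$W[, j]) + params[[l]]$b[j]
    }
    a <- tanh(z)
  }
  for (l in 5:6) {
    z <- numeric(ncol(params[[l]]$W))
    for (j in seq_along(z)) {
      z[j] <- sum(a * params[[l]]$W[, j]) + params[[l]]$b[j]
    }
    a <- z
  }
  a
}

# Rotate a unit 2-vector by theta (rotation-matrix oracle).
rotate2 <- function(u, theta) {
  c(cos(theta) * u[1] - sin(theta) * u[2],
    sin(theta) * u[1] + cos(theta) * u[2])
}
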