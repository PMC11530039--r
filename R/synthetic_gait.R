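#' Configuration for the synthetic gait simulator
#'
#' Bundles and validates the parameters of the planar gait model used to
#' generate marker trajectories with known continuous phase and known
#' heel-strike/toe-off times. Defaults emulate normal treadmill walking
#' recorded by an optical motion-capture system at 150 Hz: an ankle
#' forward--back excursion of a few hundred millimetres relative to the
#' pelvis, a stance fraction near 60% of the cycle, and sub-millimetre
#' marker noise.
#'
#' @param sampling_rate sampling frequency in Hz.
#' @param duration_s walk duration in seconds.
#' @param cadence stride rate in strides/s. Either a single number or a
#'   data.frame with columns `duration_s` and `cadence` giving a
#'   piecewise-constant schedule (used to emulate multiple speed conditions
#'   within one record); schedule durations must sum to at least
#'   `duration_s`.
#' @param cadence_cv stride-to-stride coefficient of variation of the
#'   cadence (default 0.03, in the 2--4% range of natural stride-time
#'   variability in healthy adults). Each stride's cadence is drawn as
#'   `cadence * (1 + cadence_cv * z)` with standard-normal `z` truncated at
#'   +/- 3, from the seeded stream, and realized as a piecewise-constant
#'   schedule, so ground-truth phase and event times stay analytically
#'   exact. Set 0 for strictly periodic gait. Ignored when `cadence` is
#'   already a schedule data.frame.
#' @param amplitude_x forward--back ankle excursion amplitude relative to the
#'   iliac crest, mm.
#' @param amplitude_y swing foot-lift height, mm.
#' @param baseline_y ankle height reference, mm.
#' @param duty_factor fraction of the cycle spent in stance, in (0, 1).
#' @param progression_speed iliac-crest forward speed in mm/s; 0 gives a
#'   treadmill-like record, > 0 an overground-like one.
#' @param sway_amplitude optional fore-aft pelvic sway amplitude in mm at
#'   stride frequency (0 disables it).
#' @param noise_sd additive Gaussian measurement noise per marker
#'   coordinate, mm.
#' @param phase_offset_right phase of the right limb relative to the left,
#'   radians; the default pi makes the limbs anti-phase.
#' @param seed integer seed controlling the noise; identical config and seed
#'   give bit-identical output.
#' @return an object of class `gait_sim_config`.
#' @export
gait_sim_config <- function(sampling_rate = 150,
                            duration_s = 30,
                            cadence = 1.0,
                            cadence_cv = 0.03,
                            amplitude_x = 180,
                            amplitude_y = 120,
                            baseline_y = 90,
                            duty_factor = 0.6,
                            progression_speed = 0,
                            sway_amplitude = 0,
                            noise_sd = 0.5,
                            phase_offset_right = pi,
                            seed = 1L) {
  cfg <- list(
    sampling_rate = sampling_rate, duration_s = duration_s,
    cadence = cadence, cadence_cv = cadence_cv, amplitude_x = amplitude_x,
    amplitude_y = amplitude_y, baseline_y = baseline_y,
    duty_factor = duty_factor, progression_speed = progression_speed,
    sway_amplitude = sway_amplitude, noise_sd = noise_sd,
    phase_offset_right = phase_offset_right, seed = as.integer(seed)
  )
  .check_scalar <- function(name, positive = FALSE, nonneg = FALSE) {
    v <- cfg[[name]]
    ok <- is.numeric(v) && length(v) == 1L && is.finite(v) &&
      (!positive || v > 0) && (!nonneg || v >= 0)
    if (!ok) stop("invalid gait_sim_config field '", name, "'", call. = FALSE)
  }
  .check_scalar("sampling_rate", positive = TRUE)
  .check_scalar("duration_s", positive = TRUE)
  .check_scalar("amplitude_x")
  .check_scalar("amplitude_y")
  .check_scalar("baseline_y")
  .check_scalar("progression_speed", nonneg = TRUE)
  .check_scalar("sway_amplitude", nonneg = TRUE)
  .check_scalar("noise_sd", nonneg = TRUE)
  .check_scalar("cadence_cv", nonneg = TRUE)
  .check_scalar("phase_offset_right")
  if (!is.numeric(cfg$duty_factor) || length(cfg$duty_factor) != 1L ||
      !is.finite(cfg$duty_factor) ||
      cfg$duty_factor <= 0 || cfg$duty_factor >= 1) {
    stop("invalid gait_sim_config field 'duty_factor'", call. = FALSE)
  }
  if (is.data.frame(cadence)) {
    if (!all(c("duration_s", "cadence") %in% names(cadence)) ||
        nrow(cadence) < 1L ||
        any(!is.finite(cadence$duration_s)) || any(cadence$duration_s <= 0) ||
        any(!is.finite(cadence$cadence)) || any(cadence$cadence < 0) ||
        sum(cadence$duration_s) < duration_s - 1e-9) {
      stop("invalid gait_sim_config field 'cadence'", call. = FALSE)
    }
  } else if (!is.numeric(cadence) || length(cadence) != 1L ||
             !is.finite(cadence) || cadence < 0) {
    stop("invalid gait_sim_config field 'cadence'", call. = FALSE)
  }
  structure(cfg, class = "gait_sim_config")
}

# Realize stride-to-stride cadence variability as an explicit
# piecewise-constant schedule (one segment per stride). Must be called
# inside the seeded RNG scope; a schedule or zero-cv scalar passes through.
.materialize_cadence <- function(config) {
  if (is.data.frame(config$cadence) || config$cadence_cv == 0 ||
      config$cadence == 0) {
    return(config)
  }
  base <- config$cadence
  cads <- numeric(0)
  total <- 0
  while (total < config$duration_s) {
    z <- max(-3, min(3, stats::rnorm(1)))
    ck <- max(0.05 * base, base * (1 + config$cadence_cv * z))
    cads <- c(cads, ck)
    total <- total + 1 / ck
  }
  config$cadence_base <- base
  config$cadence <- data.frame(duration_s = 1 / cads, cadence = cads)
  config
}

# Piecewise-constant cadence schedule as segments with start times and the
# unwrapped phase accumulated at each segment start.
.cadence_segments <- function(config) {
  if (is.data.frame(config$cadence)) {
    dur <- config$cadence$duration_s
    cad <- config$cadence$cadence
  } else {
    dur <- config$duration_s
    cad <- config$cadence
  }
  t0 <- cumsum(c(0, dur[-length(dur)]))
  phase0 <- cumsum(c(0, (2 * pi * cad * dur)[-length(dur)]))
  data.frame(t0 = t0, t1 = t0 + dur, cadence = cad, phase0 = phase0)
}

# Unwrapped left-limb phase (radians, starting at 0) at arbitrary times.
.unwrapped_phase_at <- function(t, config) {
  seg <- .cadence_segments(config)
  idx <- findInterval(pmin(t, max(seg$t1) - 1e-12), seg$t0)
  idx[idx < 1L] <- 1L
  seg$phase0[idx] + 2 * pi * seg$cadence[idx] * (t - seg$t0[idx])
}

#' Noiseless ankle coordinates at a given gait phase
#'
#' Closed-form kinematic model of one limb. The cycle phase `phi` (heel
#' strike at 0) is warped so that stance occupies the fraction
#' `duty_factor` of the cycle; the forward--back excursion is a cosine of
#' the warped angle, putting its global maximum (heel strike) at phase 0
#' and its global minimum (toe-off) at the stance/swing boundary. Ankle
#' height stays at `baseline_y` through stance and rises as a squared-sine
#' bump of height `amplitude_y` through swing.
#'
#' @param phi phase in radians (any value; reduced modulo 2 pi); may be a
#'   vector.
#' @param config a [gait_sim_config()].
#' @return list with numeric vectors `x_rel` (mm, relative to the iliac
#'   crest) and `y` (mm).
#' @export
#' @examples
#' cfg <- gait_sim_config(noise_sd = 0)
#' ankle_coordinates_at_phase(0, cfg)        # heel strike: x maximal
ankle_coordinates_at_phase <- function(phi, config) {
  stopifnot(inherits(config, "gait_sim_config"))
  d <- config$duty_factor
  p <- phi %% (2 * pi)
  stance <- p < 2 * pi * d
  u <- ifelse(stance, p / (2 * d), pi + (p - 2 * pi * d) / (2 * (1 - d)))
  swing_progress <- ifelse(stance, 0, (p - 2 * pi * d) / (2 * pi * (1 - d)))
  list(
    x_rel = config$amplitude_x * cos(u),
    y = config$baseline_y + config$amplitude_y * sin(pi * swing_progress)^2
  )
}

.event_set <- function(hs_times, to_times, sampling_rate, n_samples, side,
                       source) {
  mk <- function(times) {
    times <- sort(times)
    data.frame(
      index = pmin(as.integer(round(times * sampling_rate)), n_samples - 1L),
      time_s = times
    )
  }
  structure(
    list(heel_strikes = mk(hs_times), toe_offs = mk(to_times),
         side = side, source = source),
    class = "event_set"
  )
}

# All times in [0, t_max] where the side's unwrapped phase crosses
# `level + 2*pi*k`. Exact for the piecewise-linear phase ramp.
.phase_crossing_times <- function(config, side_offset, level, t_max) {
  seg <- .cadence_segments(config)
  out <- numeric(0)
  for (i in seq_len(nrow(seg))) {
    if (seg$cadence[i] <= 0) next
    p_lo <- seg$phase0[i] + side_offset
    p_hi <- p_lo + 2 * pi * seg$cadence[i] * (min(seg$t1[i], t_max) - seg$t0[i])
    if (p_hi < p_lo) next
    k <- seq(ceiling((p_lo - level) / (2 * pi) - 1e-9),
             floor((p_hi - level) / (2 * pi) + 1e-9))
    if (length(k) == 0) next
    tt <- seg$t0[i] + (level + 2 * pi * k - p_lo) / (2 * pi * seg$cadence[i])
    out <- c(out, tt[tt >= seg$t0[i] - 1e-12 & tt <= t_max + 1e-12])
  }
  sort(unique(round(out, 12)))
}

#' Simulate a two-sided gait walk with known phase and events
#'
#' Generates planar left and right ankle trajectories plus the iliac-crest
#' forward position from the closed-form model in
#' [ankle_coordinates_at_phase()], with the right limb phase-shifted by
#' `phase_offset_right`. The continuous true phase, exact heel-strike and
#' toe-off times, and the noiseless coordinates are all retained, so every
#' downstream stage can be scored against ground truth.
#'
#' @param config a [gait_sim_config()].
#' @return an object of class `simulated_walk`: a list with `time_s`,
#'   per-side components `left` and `right` (each holding a
#'   `marker_trajectory`, `true_phase` wrapped to (-pi, pi\],
#'   `true_phase_unwrapped`, noiseless coordinates and a ground-truth
#'   `event_set`), and the `config`.
#' @export
simulate_walk <- function(config) {
  stopifnot(inherits(config, "gait_sim_config"))
  fs <- config$sampling_rate
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  out <- withr::with_seed(config$seed, {
    config <- .materialize_cadence(config)
    x_iliac <- config$progression_speed * t
    base_phase <- .unwrapped_phase_at(t, config)
    if (config$sway_amplitude > 0) {
      x_iliac <- x_iliac + config$sway_amplitude * sin(base_phase)
    }
    one_side <- function(side) {
      offset <- if (side == "right") config$phase_offset_right else 0
      phase_u <- base_phase + offset
      coords <- ankle_coordinates_at_phase(phase_u, config)
      .event_side(config, side, offset, coords, phase_u, x_iliac, t, n)
    }
    list(config = config, left = one_side("left"), right = one_side("right"))
  })
  structure(
    list(time_s = t, left = out$left, right = out$right, config = out$config),
    class = "simulated_walk"
  )
}

.event_side <- function(config, side, offset, coords, phase_u, x_iliac, t, n) {
  fs <- config$sampling_rate
  t_max <- t[n]
  events <- .event_set(
    hs_times = .phase_crossing_times(config, offset, 0, t_max),
    to_times = .phase_crossing_times(config, offset,
                                     2 * pi * config$duty_factor, t_max),
    sampling_rate = fs, n_samples = n, side = side, source = "ground_truth"
  )
  x_ankle_clean <- x_iliac + coords$x_rel
  y_ankle_clean <- coords$y
  noise <- function(x) x + stats::rnorm(n, 0, config$noise_sd)
  if (config$noise_sd > 0) {
    x_ankle <- noise(x_ankle_clean)
    y_ankle <- noise(y_ankle_clean)
    x_iliac_n <- noise(x_iliac)
  } else {
    x_ankle <- x_ankle_clean
    y_ankle <- y_ankle_clean
    x_iliac_n <- x_iliac
  }
  list(
    trajectory = marker_trajectory(
      time_s = t, x_ankle = x_ankle, y_ankle = y_ankle, x_iliac = x_iliac_n,
      side = side, sampling_rate = fs
    ),
    true_phase = wrap_angle(phase_u),
    true_phase_unwrapped = phase_u,
    x_rel_clean = coords$x_rel,
    y_clean = y_ankle_clean,
    true_events = events
  )
}

#' Ground-truth event times of a simulated walk
#'
#' Heel strikes are the exact solutions of the true phase crossing 0
#' (mod 2 pi) and toe-offs the crossings of the stance/swing boundary
#' `2 pi * duty_factor`, computed analytically from the cadence schedule —
#' not read off the sampled series.
#'
#' @param walk a `simulated_walk`.
#' @param side `"left"` or `"right"`.
#' @return an `event_set` with exact times in seconds and nearest sample
#'   indices.
#' @export
true_event_times <- function(walk, side = c("left", "right")) {
  stopifnot(inherits(walk, "simulated_walk"))
  side <- match.arg(side)
  config <- walk$config
  n <- length(walk$time_s)
  offset <- if (side == "right") config$phase_offset_right else 0
  .event_set(
    hs_times = .phase_crossing_times(config, offset, 0, walk$time_s[n]),
    to_times = .phase_crossing_times(config, offset,
                                     2 * pi * config$duty_factor,
                                     walk$time_s[n]),
    sampling_rate = config$sampling_rate, n_samples = n,
    side = side, source = "ground_truth"
  )
}

#' Write a simulated walk as a marker-trajectory CSV

#' @param walk a `simulated_walk`.
#' @param path output CSV path. Columns: `time_s`, `side`, `x_ankle_mm`,
#'   `y_ankle_mm`, `x_iliac_mm`, long format with both sides stacked.
#' @return `path`, invisibly.
#' @export
write_walk_csv <- function(walk, path) {
  stopifnot(inherits(walk, "simulated_walk"))
  one <- function(s) {
    tr <- walk[[s]]$trajectory
    data.frame(time_s = tr$time_s, side = s, x_ankle_mm = tr$x_ankle,
               y_ankle_mm = tr$y_ankle, x_iliac_mm = tr$x_iliac)
  }
  utils::write.csv(rbind(one("left"), one("right")), path, row.names = FALSE)
  invisible(path)
}

#' Write ground-truth phase and events of a simulated walk as JSON
#'
#' @param walk a `simulated_walk`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(walk, path) {
  stopifnot(inherits(walk, "simulated_walk"))
  one <- function(s) list(
    true_phase = walk[[s]]$true_phase,
    heel_strike_s = walk[[s]]$true_events$heel_strikes$time_s,
    toe_off_s = walk[[s]]$true_events$toe_offs$time_s
  )
  jsonlite::write_json(
    list(sampling_rate = walk$config$sampling_rate,
         left = one("left"), right = one("right")),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
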