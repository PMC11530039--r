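#' Align a learned phase series to a reference phase
#'
#' A phase learned without labels is determined only up to a global
#' rotation and a possible reflection of the circle. This finds the
#' direction (sign) and offset that best map the learned phase onto the
#' reference, and reports the Fisher--Lee circular correlation after that
#' alignment (reflection makes it non-negative; rotation never changes it).
#'
#' @param learned,reference numeric vectors of angles in radians, equal
#'   length.
#' @return list with `direction` (+1 or -1), `rotation` (radians),
#'   `circular_correlation`, and `aligned` (the transformed learned phase).
#' @export
align_phase <- function(learned, reference) {
  rho <- circ_cor(learned, reference)
  dir <- if (!is.na(rho) && rho < 0) -1 else 1
  adj <- wrap_angle(dir * learned)
  off <- circ_mean(wrap_angle(reference - adj))$mean
  list(direction = dir, rotation = off,
       circular_correlation = circ_cor(adj, reference),
       aligned = wrap_angle(adj + off))
}

# Simulate one synthetic subject; per-subject base cadence with natural
# stride-to-stride variability, noise seeded.
.subject_walk <- function(cadence, duration_s, sampling_rate, noise_sd,
                          progression_speed, seed) {
  simulate_walk(gait_sim_config(
    sampling_rate = sampling_rate, duration_s = duration_s,
    cadence = cadence, noise_sd = noise_sd,
    progression_speed = progression_speed, seed = seed
  ))
}

# Per-subject evaluation of a trained model on one walk: inference, in-band
# progression fraction, circular correlation to the true phase, and HS/TO
# time errors through calibrated constant-phase detection.
.evaluate_walk <- function(params, std, walk, calibration, weights,
                           side = "left", labels = NULL) {
  feat <- feature_series(walk[[side]]$trajectory, std)
  ph <- infer_stream(params, feat)
  nu <- wrap_angle(diff(ph$angle) * calibration$direction)
  band <- mean(nu > weights$a & nu <= weights$b + 2 * pi / 180)
  truth_phase <- walk[[side]]$true_phase[ph$end_index + 1L]
  rho <- align_phase(ph$angle, truth_phase)$circular_correlation
  det <- detect_events_from_phase(ph, calibration,
                                  walk$config$sampling_rate, side)
  rep <- compute_time_errors(det, true_event_times(walk, side),
                             walk$config$sampling_rate, labels = labels)
  list(phase = ph, truth_phase = truth_phase, in_band = band,
       circular_correlation = rho, report = rep)
}

#' End-to-end synthetic phase-recovery experiment
#'
#' The full pipeline on simulated subjects: a cohort of walks with cadences
#' spread over `cadence_range`, a subject-wise 3:1:1 split, feature
#' standardization fitted on the pooled training subjects, unsupervised
#' training of the phase network, calibration of constant heel-strike /
#' toe-off reference phases on the training subjects (using kinematic-peak
#' ground truth), and evaluation on the held-out test subjects: in-band
#' progression fraction, circular correlation between learned and true
#' phase, and heel-strike / toe-off time errors in milliseconds.
#'
#' @param n_subjects number of simulated subjects.
#' @param duration_s walk duration per subject, seconds.
#' @param sampling_rate Hz.
#' @param cadence_range range of stride rates (strides/s); subjects are
#'   spaced evenly across it.
#' @param noise_sd marker noise, mm.
#' @param progression_speed iliac-crest speed, mm/s (0 = treadmill-like).
#' @param iterations,batch_size,learning_rate,adam_epsilon training
#'   settings; minibatches are contiguous single-subject segments (see
#'   [train_config()]).
#' @param weights a [loss_weights()].
#' @param side which limb's pipeline to run.
#' @param seed master seed: drives the subject noise seeds, the split and
#'   the training run.
#' @return object of class `phase_experiment`: trained `params`,
#'   standardization `std`, `calibration`, the `plan`, per-test-subject
#'   `evaluations`, pooled `report` (a `time_error_report`), the pooled
#'   `in_band_fraction`, and the circular correlation between learned and
#'   true phase over the concatenated test streams
#'   (`circular_correlation`; `circular_correlation_min` is the worst
#'   single subject).
#' @export
run_phase_experiment <- function(n_subjects = 20L,
                                 duration_s = 30,
                                 sampling_rate = 150,
                                 cadence_range = c(0.7, 1.3),
                                 noise_sd = 0.5,
                                 progression_speed = 0,
                                 iterations = 2000L,
                                 batch_size = 2048L,
                                 learning_rate = 1e-3,
                                 adam_epsilon = 1e-2,
                                 weights = loss_weights(),
                                 side = "left",
                                 seed = 1L) {
  seed <- as.integer(seed)
  cadences <- seq(cadence_range[1], cadence_range[2],
                  length.out = n_subjects)
  walks <- lapply(seq_len(n_subjects), function(i)
    .subject_walk(cadences[i], duration_s, sampling_rate, noise_sd,
                  progression_speed, seed = seed * 1000L + i))
  plan <- crossval_split(seq_len(n_subjects), k = 1L, seed = seed)
  train_ids <- plan$subject[plan$group == "train"]
  test_ids <- plan$subject[plan$group == "test"]

  rel_train <- lapply(walks[train_ids], function(w)
    relative_positions(w[[side]]$trajectory))
  std <- fit_standardization(rel_train)
  pairs_train <- bind_window_pairs(lapply(walks[train_ids], function(w)
    build_window_pairs(feature_series(w[[side]]$trajectory, std))))

  fit <- train_phase_model(
    pairs_train,
    train_config(iterations = iterations, learning_rate = learning_rate,
                 batch_size = batch_size, adam_epsilon = adam_epsilon,
                 seed = seed),
    weights = weights
  )

  train_streams <- lapply(walks[train_ids], function(w)
    infer_stream(fit$params, feature_series(w[[side]]$trajectory, std)))
  train_truth <- lapply(walks[train_ids], function(w) {
    rel <- relative_positions(w[[side]]$trajectory)
    detect_events_ground_truth(rel$R_x, sampling_rate, side)
  })
  calibration <- calibrate_event_phases(train_streams, train_truth,
                                        streams = TRUE)

  evals <- lapply(test_ids, function(i)
    .evaluate_walk(fit$params, std, walks[[i]], calibration, weights,
                   side = side, labels = list(subject = i)))
  events <- do.call(rbind, lapply(evals, function(e) e$report$events))
  pooled <- .pool_report(evals, events)
  structure(
    list(params = fit$params, history = fit$history, std = std,
         calibration = calibration, plan = plan, weights = weights,
         side = side, cadences = cadences, walks_test = walks[test_ids],
         test_ids = test_ids, seed = seed,
         sim = list(duration_s = duration_s, sampling_rate = sampling_rate,
                    noise_sd = noise_sd, iterations = iterations),
         evaluations = evals, report = pooled$report,
         in_band_fraction = pooled$in_band,
         circular_correlation = pooled$circ_cor,
         circular_correlation_min = pooled$circ_cor_min),
    class = "phase_experiment"
  )
}

.pool_report <- function(evals, events) {
  summarize <- function(e) data.frame(
    n_matched = nrow(e),
    mean_ms = if (nrow(e)) mean(e$error_ms) else NA_real_,
    sd_ms = if (nrow(e) > 1L) stats::sd(e$error_ms) else NA_real_
  )
  summary <- rbind(
    cbind(event_type = "heel_strike",
          summarize(events[events$event_type == "heel_strike", , drop = FALSE])),
    cbind(event_type = "toe_off",
          summarize(events[events$event_type == "toe_off", , drop = FALSE])),
    cbind(event_type = "all", summarize(events))
  )
  report <- structure(
    list(events = events, summary = summary,
         n_unmatched_truth = sum(vapply(evals, function(e)
           e$report$n_unmatched_truth, 0L)),
         n_unmatched_detected = sum(vapply(evals, function(e)
           e$report$n_unmatched_detected, 0L))),
    class = "time_error_report"
  )
  # In-band fraction pooled over all consecutive pairs of all test subjects.
  n_nu <- vapply(evals, function(e) nrow(e$phase) - 1L, 0L)
  in_band <- sum(vapply(evals, function(e) e$in_band, 0) * n_nu) / sum(n_nu)
  # Pooled circular correlation: learned and true phase concatenated across
  # test subjects (Fisher-Lee is rotation invariant; one reflection for all).
  learned <- unlist(lapply(evals, function(e) e$phase$angle))
  truth <- unlist(lapply(evals, function(e) e$truth_phase))
  rho <- circ_cor(learned, truth)
  if (!is.na(rho) && rho < 0) rho <- circ_cor(wrap_angle(-learned), truth)
  list(report = report, in_band = in_band, circ_cor = rho,
       circ_cor_min = min(vapply(evals, function(e) e$circular_correlation, 0)))
}

#' Evaluate a trained experiment under a transferred walking condition
#'
#' Re-simulates the held-out test subjects under a different progression
#' condition (e.g. overground-like, `progression_speed > 0`, after training
#' on treadmill-like data) with matched cadences, and evaluates the already
#' trained and calibrated model on them. Because the features are
#' pelvis-referenced, progression is removed upstream and performance
#' should carry over.
#'
#' @param experiment a [run_phase_experiment()] result.
#' @param progression_speed mm/s for the transferred condition.
#' @param noise_seed_offset offset added to the subject seeds so the
#'   transferred walks carry fresh noise.
#' @return list like the evaluation part of `phase_experiment`: `report`,
#'   `in_band_fraction`, `circular_correlation`, `evaluations`.
#' @export
evaluate_transfer <- function(experiment, progression_speed = 1200,
                              noise_seed_offset = 500L) {
  stopifnot(inherits(experiment, "phase_experiment"))
  sim <- experiment$sim
  walks <- lapply(experiment$test_ids, function(i)
    .subject_walk(experiment$cadences[i], sim$duration_s, sim$sampling_rate,
                  sim$noise_sd, progression_speed,
                  seed = experiment$seed * 1000L + i + noise_seed_offset))
  evals <- lapply(seq_along(walks), function(j)
    .evaluate_walk(experiment$params, experiment$std, walks[[j]],
                   experiment$calibration, experiment$weights,
                   side = experiment$side,
                   labels = list(subject = experiment$test_ids[j])))
  events <- do.call(rbind, lapply(evals, function(e) e$report$events))
  pooled <- .pool_report(evals, events)
  list(report = pooled$report, in_band_fraction = pooled$in_band,
       circular_correlation = pooled$circ_cor,
       circular_correlation_min = pooled$circ_cor_min, evaluations = evals)
}

#' @export
print.time_error_report <- function(x, ...) {
  cat("Time-error report")
  if (!is.null(x$side)) cat(" (", x$side, " side)", sep = "")
  cat("\n")
  print(x$summary, row.names = FALSE)
  cat("unmatched: ", x$n_unmatched_truth, " truth, ",
      x$n_unmatched_detected, " detected\n", sep = "")
  invisible(x)
}

#' @export
print.phase_experiment <- function(x, ...) {
  cat("Synthetic phase-recovery experiment\n")
  cat(sprintf("  test subjects: %d, in-band fraction: %.4f, circular correlation: %.4f (pooled), %.4f (worst subject)\n",
              length(x$evaluations), x$in_band_fraction,
              x$circular_correlation, x$circular_correlation_min))
  print(x$report)
  invisible(x)
}
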