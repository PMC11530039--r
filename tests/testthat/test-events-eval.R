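test_that("kinematic detector finds cosine extrema at the half-periods", {
  fs <- 150
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * t)
  ev <- detect_events_ground_truth(x, fs)
  # the peak at t = 0 sits on the series boundary, where a two-sided peak
  # criterion is undefined; all interior extrema must be found
  expect_equal(ev$heel_strikes$time_s, 1:4, tolerance = 1.01 / fs)
  expect_equal(ev$toe_offs$time_s, 0:4 + 0.5, tolerance = 1.01 / fs)
  expect_s3_class(ev, "event_set")
  expect_identical(ev$source, "ground_truth")

  expect_warning(flat <- detect_events_ground_truth(rep(1, 100), fs),
                 "flat|short")
  expect_equal(nrow(flat$heel_strikes), 0L)
})

test_that("peak criterion coincides with the velocity sign-change criterion", {
  fs <- 150
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * t)
  peaks <- detect_events_ground_truth(x, fs)
  # independent rule: heel strike where velocity crosses + to -, toe-off - to +
  v <- diff(x)
  hs_vel <- which(v[-1] < 0 & v[-length(v)] >= 0)
  to_vel <- which(v[-1] > 0 & v[-length(v)] <= 0)
  match_within <- function(a, b, tol = 1) {
    all(vapply(a, function(ai) min(abs(b - ai)) <= tol, TRUE))
  }
  expect_true(match_within(peaks$heel_strikes$index, hs_vel))
  expect_true(match_within(peaks$toe_offs$index, to_vel))
})

test_that("detector recovers simulated events within one sample on noiseless walks", {
  w <- quiet_walk(duration_s = 8, cadence = 1.1, noise_sd = 0, seed = 3L)
  rel <- relative_positions(w$left$trajectory)
  ev <- detect_events_ground_truth(rel$R_x, w$config$sampling_rate)
  truth <- true_event_times(w, "left")
  # drop boundary truth events the peak detector cannot see (series edges)
  interior <- function(idx, n) idx[idx > 2 & idx < n - 3]
  n <- length(rel$R_x)
  for (slot in c("heel_strikes", "toe_offs")) {
    ti <- interior(truth[[slot]]$index, n)
    for (i in ti) {
      expect_lte(min(abs(ev[[slot]]$index - i)), 1)
    }
  }
})

test_that("event-phase calibration takes circular means and flags degeneracy", {
  ph <- data.frame(end_index = 0:99,
                   angle = wrap_angle(2 * pi * (0:99) / 50))
  truth <- gaitphase:::.event_set(
    hs_times = c(0, 50) / 150, to_times = c(30, 80) / 150,
    sampling_rate = 150, n_samples = 100, side = "left",
    source = "ground_truth"
  )
  cal <- calibrate_event_phases(ph, truth)
  expect_equal(cal$ref_phase_hs, 0, tolerance = 1e-9)
  expect_equal(cal$ref_phase_to, wrap_angle(2 * pi * 30 / 50),
               tolerance = 1e-9)
  expect_equal(cal$direction, 1)

  # wraparound: phases straddling pi average to pi, not 0
  ph2 <- data.frame(end_index = 0:3, angle = c(pi - 0.1, -pi + 0.1,
                                               pi - 0.1, -pi + 0.1))
  truth2 <- gaitphase:::.event_set(
    hs_times = (0:3) / 150, to_times = (0:3) / 150,
    sampling_rate = 150, n_samples = 4, side = "left", source = "ground_truth"
  )
  cal2 <- calibrate_event_phases(ph2, truth2)
  expect_equal(abs(cal2$ref_phase_hs), pi, tolerance = 1e-9)

  # antipodal event phases: resultant below 0.1, calibration refuses
  ph3 <- data.frame(end_index = 0:3, angle = c(0, pi, 0, pi))
  expect_error(calibrate_event_phases(ph3, truth2), "dispersed|resultant")
})

test_that("phase-based detection crosses reference levels once per cycle", {
  fs <- 150
  # phase ramp: one cycle per second
  idx <- 0:(5 * fs - 1)
  ph <- data.frame(end_index = idx, angle = wrap_angle(2 * pi * idx / fs))
  cal <- structure(list(ref_phase_hs = 0, ref_phase_to = pi / 2,
                        direction = 1),
                   class = "phase_calibration")
  ev <- detect_events_from_phase(ph, cal, fs)
  # ramp starts exactly on the reference, so the first completed crossing
  # is one cycle in; detections then recur every second
  expect_equal(ev$heel_strikes$time_s, 1:4, tolerance = 1.01 / fs)
  expect_equal(ev$toe_offs$time_s, 0:4 + 0.25, tolerance = 1.01 / fs)
  expect_identical(ev$source, "phase_detected")

  # small backward jitter across the reference must not double-fire
  ang <- 2 * pi * idx / fs
  jit <- ang
  k0 <- which(ang > 2 * pi + 0.02)[1]
  jit[k0 + 0:2] <- jit[k0] - 0.05    # dip back below the level, then resume
  ph_j <- data.frame(end_index = idx, angle = wrap_angle(jit))
  ev_j <- detect_events_from_phase(ph_j, cal, fs)
  in_window <- ev_j$heel_strikes$time_s[ev_j$heel_strikes$time_s > 0.5 &
                                          ev_j$heel_strikes$time_s < 1.5]
  expect_length(in_window, 1L)
})

test_that("time errors are absolute, in milliseconds, with unmatched counted", {
  fs <- 150
  mk <- function(hs, to, source) gaitphase:::.event_set(
    hs_times = hs / fs, to_times = to / fs, sampling_rate = fs,
    n_samples = 2000, side = "left", source = source
  )
  truth <- mk(c(150, 300, 450), c(200, 350, 500), "ground_truth")
  det <- mk(c(151, 299, 450), c(201, 352, 499), "phase_detected")
  rep <- compute_time_errors(det, truth, fs)
  expect_equal(rep$events$error_ms[rep$events$event_type == "heel_strike"],
               c(1, 1, 0) * 1000 / 150, tolerance = 1e-9)
  s <- rep$summary
  expect_equal(s$mean_ms[s$event_type == "all"], mean(rep$events$error_ms))
  expect_equal(s$sd_ms[s$event_type == "all"], sd(rep$events$error_ms))
  expect_equal(rep$n_unmatched_truth, 0L)

  # identical sets give zero error
  rep0 <- compute_time_errors(truth, truth, fs)
  expect_equal(rep0$summary$mean_ms[3], 0)
  expect_equal(rep0$summary$sd_ms[3], 0)

  # a missing detection is counted, not scored
  det_miss <- mk(c(151, 450), c(201, 352, 499), "phase_detected")
  rep_m <- compute_time_errors(det_miss, truth, fs)
  expect_equal(rep_m$n_unmatched_truth, 1L)
  expect_equal(sum(rep_m$events$event_type == "heel_strike"), 2L)
})

test_that("matching is one-to-one and windowed by half the event period", {
  fs <- 100
  truth <- gaitphase:::.event_set(
    hs_times = c(1, 2, 3), to_times = numeric(0), sampling_rate = fs,
    n_samples = 400, side = "left", source = "ground_truth"
  )
  # one detection sits between two truth events; it may serve only one
  det <- gaitphase:::.event_set(
    hs_times = c(1.2), to_times = numeric(0), sampling_rate = fs,
    n_samples = 400, side = "left", source = "phase_detected"
  )
  rep <- compute_time_errors(det, truth, fs)
  expect_equal(nrow(rep$events), 1L)
  expect_equal(rep$events$t_truth, 1)
  expect_equal(rep$n_unmatched_truth, 2L)

  # a detection farther than half the period is not matched at all
  det_far <- gaitphase:::.event_set(
    hs_times = c(3.6), to_times = numeric(0), sampling_rate = fs,
    n_samples = 400, side = "left", source = "phase_detected"
  )
  rep_far <- compute_time_errors(det_far, truth, fs)
  expect_equal(nrow(rep_far$events), 0L)
})

test_that("cross-validation plan reproduces the 3:1:1 rotated design", {
  plan <- crossval_split(sprintf("S%02d", 1:40), k = 4L, seed = 2L)
  expect_equal(sort(unique(plan$fold)), 1:4)
  for (f in 1:4) {
    pf <- plan[plan$fold == f, ]
    expect_equal(sum(pf$group == "train"), 24L)
    expect_equal(sum(pf$group == "validation"), 8L)
    expect_equal(sum(pf$group == "test"), 8L)
    expect_equal(sort(pf$subject), sprintf("S%02d", 1:40))
    expect_length(intersect(pf$subject[pf$group == "train"],
                            pf$subject[pf$group == "test"]), 0L)
  }
  # test groups rotate: no subject is tested in two folds
  tested <- lapply(1:4, function(f)
    plan$subject[plan$fold == f & plan$group == "test"])
  expect_length(unique(unlist(tested)), 32L)

  expect_identical(crossval_split(sprintf("S%02d", 1:40), k = 4L, seed = 2L),
                   plan)
  expect_error(crossval_split(1:3, k = 4L), "subjects")
})

test_that("feeding the true phase through detection yields sub-sample errors", {
  w <- quiet_walk(duration_s = 12, cadence = 1, noise_sd = 0, seed = 7L)
  fs <- w$config$sampling_rate
  idx <- 12:(length(w$time_s) - 1)
  ph <- data.frame(end_index = idx, angle = w$left$true_phase[idx + 1])
  truth <- true_event_times(w, "left")
  cal <- calibrate_event_phases(ph, truth)
  expect_equal(cal$ref_phase_hs, 0, tolerance = 1e-6)
  det <- detect_events_from_phase(ph, cal, fs)
  rep <- compute_time_errors(det, truth, fs)
  expect_lte(rep$summary$mean_ms[rep$summary$event_type == "all"], 1000 / fs)
})
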