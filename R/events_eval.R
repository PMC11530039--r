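#' Dominant period of a quasi-periodic series
#'
#' Lag of the first autocorrelation peak, in samples; drives the minimum
#' peak separation, the refractory interval of phase-based detection and
#' the event-matching window.
#'
#' @param x numeric series.
#' @return period in samples, or `NA` if no periodicity is found.
#' @export
dominant_period <- function(x) {
  n <- length(x)
  if (n < 8L || stats::sd(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 1L, 5000L), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  pk <- pracma::findpeaks(ac, minpeakheight = 0.2, nups = 1, ndowns = 1)
  if (is.null(pk)) return(NA_real_)
  lag <- min(pk[, 2]) - 1L
  if (lag < 2L) NA_real_ else as.numeric(lag)
}

#' Kinematic ground-truth event detection
#'
#' Heel strikes are the positive peaks of the ankle's forward position
#' relative to the pelvis (where the foot's horizontal velocity passes from
#' positive to negative) and toe-offs its negative peaks (velocity negative
#' to positive). Candidate extrema are filtered by a minimum separation of
#' half the dominant period and a prominence floor of 25% of the series'
#' peak-to-peak range.
#'
#' @param R_x relative forward position series, mm.
#' @param sampling_rate Hz.
#' @param side side label carried into the result.
#' @return an `event_set` with `source = "ground_truth"`. A flat or
#'   too-short series returns an empty set with a warning.
#' @export
detect_events_ground_truth <- function(R_x, sampling_rate,
                                       side = c("left", "right")) {
  side <- match.arg(side)
  empty <- function() {
    warning("flat or too-short series: no events detected")
    .event_set(numeric(0), numeric(0), sampling_rate, length(R_x), side,
               "ground_truth")
  }
  period <- dominant_period(R_x)
  if (is.na(period)) return(empty())
  min_sep <- max(2L, floor(period / 2))
  prom <- 0.25 * (max(R_x) - min(R_x))
  peaks_of <- function(v) {
    pk <- pracma::findpeaks(v, minpeakdistance = min_sep,
                            minpeakheight = min(v) + prom)
    if (is.null(pk)) integer(0) else sort(pk[, 2])
  }
  hs_idx <- peaks_of(R_x)
  to_idx <- peaks_of(-R_x)
  .event_set((hs_idx - 1L) / sampling_rate, (to_idx - 1L) / sampling_rate,
             sampling_rate, length(R_x), side, "ground_truth")
}

#' Calibrate constant reference phases at gait events
#'
#' Computes, on training data, the circular mean of the model's phase at
#' the ground-truth heel-strike and toe-off samples, plus the model's
#' progression direction (sign of the median per-step phase progression).
#' These constant reference phases are what phase-based event recognition
#' later watches for.
#'
#' @param phase a data.frame from [infer_stream()] (or one with columns
#'   `end_index` and `angle`). May be the concatenation of several streams,
#'   in which case `direction` uses each stream's internal ordering only if
#'   concatenated per trajectory; pass single-trajectory streams via
#'   `streams` to be safe.
#' @param truth an `event_set` of ground-truth events aligned to the same
#'   sample clock (or a list of them matching `streams`).
#' @param streams optional list of per-trajectory phase data.frames; when
#'   given, `phase`/`truth` must be lists of equal length and calibration
#'   pools events across all of them.
#' @return object of class `phase_calibration`: `ref_phase_hs`,
#'   `ref_phase_to` (radians), `direction` (+1 anticlockwise, -1
#'   clockwise) and the resultant lengths of the two circular means.
#' @export
calibrate_event_phases <- function(phase, truth, streams = NULL) {
  phases <- if (is.null(streams)) list(phase) else phase
  truths <- if (is.null(streams)) list(truth) else truth
  stopifnot(length(phases) == length(truths))
  angle_at <- function(ph, idx) {
    m <- match(idx, ph$end_index)
    ph$angle[m[!is.na(m)]]
  }
  hs <- unlist(lapply(seq_along(phases), function(i)
    angle_at(phases[[i]], truths[[i]]$heel_strikes$index)))
  to <- unlist(lapply(seq_along(phases), function(i)
    angle_at(phases[[i]], truths[[i]]$toe_offs$index)))
  if (length(hs) < 2L || length(to) < 2L) {
    stop("calibration needs at least two aligned events of each type",
         call. = FALSE)
  }
  mh <- circ_mean(hs); mt <- circ_mean(to)
  if (mh$resultant_length < 0.1 || mt$resultant_length < 0.1) {
    stop("calibration failed: event phases are too dispersed ",
         "(resultant length below 0.1)", call. = FALSE)
  }
  nus <- unlist(lapply(phases, function(ph) wrap_angle(diff(ph$angle))))
  structure(
    list(ref_phase_hs = mh$mean, ref_phase_to = mt$mean,
         direction = if (stats::median(nus) >= 0) 1 else -1,
         resultant_hs = mh$resultant_length,
         resultant_to = mt$resultant_length),
    class = "phase_calibration"
  )
}

# First-crossing detector for one reference phase on a causally unwrapped,
# direction-corrected phase series. At most one detection per cycle: the
# target level advances by 2*pi after every crossing, and a refractory
# interval of half a period suppresses re-triggers.
.detect_crossings <- function(u, ref, refractory) {
  target <- ref + 2 * pi * (floor((u[1] - ref) / (2 * pi)) + 1)
  hits <- integer(0)
  last <- -Inf
  for (k in seq_along(u)) {
    if (u[k] >= target) {
      if (k - last >= refractory) {
        hits <- c(hits, k)
        last <- k
      }
      target <- target + 2 * pi * max(1, floor((u[k] - target) / (2 * pi)) + 1)
    }
  }
  hits
}

#' Detect gait events from a phase stream
#'
#' Causal constant-reference-phase recognition: the phase series is
#' direction-corrected and unwrapped sample by sample, and an event is
#' declared the first time the unwrapped phase crosses the calibrated
#' reference level of each event type, at most once per cycle (refractory
#' interval of half the dominant period, estimated from the stream's own
#' median progression rate).
#'
#' @param phase a data.frame from [infer_stream()].
#' @param calibration a [calibrate_event_phases()] result.
#' @param sampling_rate Hz.
#' @param side side label carried into the result.
#' @return an `event_set` with `source = "phase_detected"`.
#' @export
detect_events_from_phase <- function(phase, calibration, sampling_rate,
                                     side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(calibration, "phase_calibration"))
  dir <- calibration$direction
  u <- unwrap_phase(dir * phase$angle)
  # mean progression rate, robust to bursty phase advance within a cycle
  step <- (u[length(u)] - u[1]) / (length(u) - 1)
  refractory <- if (is.finite(step) && step > 0) pi / step else 1
  idx_hs <- .detect_crossings(u, dir * calibration$ref_phase_hs, refractory)
  idx_to <- .detect_crossings(u, dir * calibration$ref_phase_to, refractory)
  n_total <- max(phase$end_index) + 1L
  .event_set(phase$end_index[idx_hs] / sampling_rate,
             phase$end_index[idx_to] / sampling_rate,
             sampling_rate, n_total, side, "phase_detected")
}

# Greedy one-to-one nearest matching of truth to detected times within
# max_gap seconds. Returns data.frame(t_truth, t_detected).
.match_events <- function(t_truth, t_det, max_gap) {
  if (length(t_truth) == 0L || length(t_det) == 0L) {
    return(data.frame(t_truth = numeric(0), t_detected = numeric(0)))
  }
  cand <- expand.grid(i = seq_along(t_truth), j = seq_along(t_det))
  cand$gap <- abs(t_truth[cand$i] - t_det[cand$j])
  cand <- cand[cand$gap <= max_gap, , drop = FALSE]
  cand <- cand[order(cand$gap), , drop = FALSE]
  used_i <- logical(length(t_truth)); used_j <- logical(length(t_det))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!used_i[cand$i[r]] && !used_j[cand$j[r]]) {
      keep[r] <- TRUE
      used_i[cand$i[r]] <- TRUE
      used_j[cand$j[r]] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$i), , drop = FALSE]
  data.frame(t_truth = t_truth[cand$i], t_detected = t_det[cand$j])
}

#' Time errors between detected and ground-truth events
#'
#' Each ground-truth event is matched one-to-one to the nearest detected
#' event of the same type within half the dominant period (the median
#' inter-event interval of the truth set); the error is the absolute time
#' difference in milliseconds. Unmatched events are counted and excluded
#' from the mean and standard deviation.
#'
#' @param detected,truth `event_set` objects on the same clock.
#' @param sampling_rate Hz (carried into the report).
#' @param labels optional named list of grouping labels (fold, condition,
#'   ...) attached to every per-event row.
#' @return object of class `time_error_report`: `events` (one row per
#'   matched event: `event_type`, `t_truth`, `t_detected`, `error_ms`,
#'   labels), `summary` (mean/sd/n per event type and overall), and
#'   unmatched counts.
#' @export
compute_time_errors <- function(detected, truth, sampling_rate,
                                labels = NULL) {
  stopifnot(inherits(detected, "event_set"), inherits(truth, "event_set"))
  rows <- list(); unmatched_truth <- 0L; unmatched_det <- 0L
  for (type in c("heel_strike", "toe_off")) {
    slot <- if (type == "heel_strike") "heel_strikes" else "toe_offs"
    tt <- truth[[slot]]$time_s
    td <- detected[[slot]]$time_s
    gaps <- diff(tt)
    max_gap <- if (length(gaps) >= 1L) stats::median(gaps) / 2 else Inf
    m <- .match_events(tt, td, max_gap)
    unmatched_truth <- unmatched_truth + (length(tt) - nrow(m))
    unmatched_det <- unmatched_det + (length(td) - nrow(m))
    if (nrow(m) > 0L) {
      m$event_type <- type
      m$error_ms <- abs(m$t_detected - m$t_truth) * 1000
      rows[[type]] <- m
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t_truth = numeric(0), t_detected = numeric(0),
               event_type = character(0), error_ms = numeric(0))
  rownames(events) <- NULL
  if (!is.null(labels)) for (nm in names(labels)) events[[nm]] <- labels[[nm]]
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
  structure(
    list(events = events, summary = summary, side = truth$side,
         n_unmatched_truth = unmatched_truth,
         n_unmatched_detected = unmatched_det,
         sampling_rate = sampling_rate),
    class = "time_error_report"
  )
}

#' Subject-wise cross-validation plan
#'
#' Randomly assigns subjects to disjoint training / validation / test
#' groups in the given ratio, with the test (and validation) blocks
#' rotating across folds. For 40 subjects and ratio 3:1:1 this reproduces a
#' 24/8/8 split in each of 4 folds.
#'
#' @param subject_ids vector of subject identifiers.
#' @param k number of folds.
#' @param ratio train:validation:test ratio (three positive integers).
#' @param seed integer seed; the same seed reproduces the plan.
#' @return object of class `cv_plan`: data.frame with columns `fold`,
#'   `subject`, `group` (train/validation/test).
#' @export
crossval_split <- function(subject_ids, k = 4L, ratio = c(3, 1, 1),
                           seed = 1L) {
  n <- length(subject_ids)
  stopifnot(length(ratio) == 3L, all(ratio > 0))
  units <- sum(ratio)
  if (n < units || n < k) {
    stop("need at least max(sum(ratio), k) subjects", call. = FALSE)
  }
  shuffled <- withr::with_seed(as.integer(seed), sample(subject_ids))
  block_of <- sort(rep_len(seq_len(units), n))  # nearly equal block sizes
  plan <- do.call(rbind, lapply(seq_len(k), function(f) {
    test_b <- ((f - 1L) %% units) + 1L
    val_b <- (test_b %% units) + 1L
    group <- ifelse(block_of == test_b, "test",
                    ifelse(block_of == val_b, "validation", "train"))
    data.frame(fold = f, subject = shuffled, group = group)
  }))
  rownames(plan) <- NULL
  structure(plan, class = c("cv_plan", "data.frame"))
}
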