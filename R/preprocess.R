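#' Construct a marker trajectory
#'
#' Container for one limb's planar marker series: ankle x/y and iliac-crest
#' x forward position, uniformly sampled. Units are millimetres and seconds.
#'
#' @param time_s time stamps in seconds, uniformly spaced.
#' @param x_ankle,y_ankle ankle marker positions, mm.
#' @param x_iliac iliac-crest forward position, mm.
#' @param side `"left"` or `"right"`.
#' @param sampling_rate sampling frequency in Hz; validated against
#'   `time_s` (max deviation of successive intervals from `1/sampling_rate`
#'   must be below 1e-6 s).
#' @return an object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(time_s, x_ankle, y_ankle, x_iliac,
                              side = c("left", "right"), sampling_rate) {
  side <- match.arg(side)
  n <- length(time_s)
  if (length(x_ankle) != n || length(y_ankle) != n || length(x_iliac) != n) {
    stop("malformed trajectory: series lengths differ", call. = FALSE)
  }
  if (n >= 2L && max(abs(diff(time_s) - 1 / sampling_rate)) >= 1e-6) {
    stop("malformed trajectory: sampling is not uniform at the stated rate",
         call. = FALSE)
  }
  structure(
    list(time_s = time_s, x_ankle = x_ankle, y_ankle = y_ankle,
         x_iliac = x_iliac, side = side, sampling_rate = sampling_rate),
    class = "marker_trajectory"
  )
}

#' Read a marker-trajectory CSV
#'
#' Reads the long-format CSV written by [write_walk_csv()] (columns
#' `time_s`, `side`, `x_ankle_mm`, `y_ankle_mm`, `x_iliac_mm`) and returns
#' one side as a `marker_trajectory`. The sampling rate is inferred from
#' the time column.
#'
#' @param path CSV path.
#' @param side which side to extract.
#' @return a `marker_trajectory`.
#' @export
read_marker_csv <- function(path, side = c("left", "right")) {
  side <- match.arg(side)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "side", "x_ankle_mm", "y_ankle_mm", "x_iliac_mm")
  if (!all(need %in% names(d))) {
    stop("malformed trajectory CSV: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  d <- d[d$side == side, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for side '", side, "'", call. = FALSE)
  fs <- 1 / stats::median(diff(d$time_s))
  marker_trajectory(d$time_s, d$x_ankle_mm, d$y_ankle_mm, d$x_iliac_mm,
                    side = side, sampling_rate = fs)
}

#' Ankle positions relative to the iliac crest
#'
#' The forward--back coordinate is referenced to the pelvis, which removes
#' whole-body progression (treadmill and overground walks of equal cadence
#' give the same relative series); the vertical coordinate is kept as is.
#'
#' @param traj a [marker_trajectory()].
#' @return an object of class `relative_series` with fields `R_x`, `R_y`
#'   (mm) and `sampling_rate`.
#' @export
relative_positions <- function(traj) {
  stopifnot(inherits(traj, "marker_trajectory"))
  structure(
    list(R_x = traj$x_ankle - traj$x_iliac, R_y = traj$y_ankle,
         sampling_rate = traj$sampling_rate),
    class = "relative_series"
  )
}

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Heading direction of one 7-sample window
#'
#' Ordinary least-squares slope of the window values against the sample
#' index 0..6 within the window, i.e. the directional trend of the signal
#' in units of (value per sample).
#'
#' @param window_values exactly 7 consecutive values.
#' @return the OLS slope.
#' @export
heading_direction <- function(window_values) {
  if (length(window_values) != 7L) {
    stop("heading window must contain exactly 7 values", call. = FALSE)
  }
  k <- 0:6 - 3
  sum(k * window_values) / sum(k^2)
}

# Per-sample heading series: slope of the trailing 7-sample window ending at
# each sample (causal). The first six samples, where no full trailing window
# exists, repeat the first defined value; only windows ending before sample
# 12 ever see those padded values.
.heading_series <- function(values) {
  n <- length(values)
  if (n < 7L) stop("need at least 7 samples for headings", call. = FALSE)
  k <- (0:6 - 3) / 28
  h <- stats::filter(values, rev(k), sides = 1)
  h <- as.numeric(h)
  h[seq_len(6L)] <- h[7L]
  h
}

#' Fit standardization parameters on training data
#'
#' Computes, over the pooled samples of all supplied training series, the
#' means and population (divide-by-n) standard deviations of the relative
#' x/y positions, then — on the position-standardized series — the pooled
#' means and standard deviations of the per-sample heading directions.
#' These eight numbers are frozen at training time and applied unchanged to
#' validation and test data.
#'
#' @param train_series list of [relative_positions()] outputs
#'   (`relative_series`) from the training set.
#' @return an object of class `standardization_params`.
#' @export
fit_standardization <- function(train_series) {
  if (inherits(train_series, "relative_series")) {
    train_series <- list(train_series)
  }
  stopifnot(length(train_series) >= 1L,
            all(vapply(train_series, inherits, TRUE, "relative_series")))
  rx <- unlist(lapply(train_series, `[[`, "R_x"))
  ry <- unlist(lapply(train_series, `[[`, "R_y"))
  if (length(rx) < 2L) stop("need at least 2 pooled training samples",
                            call. = FALSE)
  p <- list(mean_x = mean(rx), mean_y = mean(ry),
            sd_x = .pop_sd(rx), sd_y = .pop_sd(ry))
  if (p$sd_x <= 0 || p$sd_y <= 0) {
    stop("degenerate training set: zero variance in a position dimension",
         call. = FALSE)
  }
  hx <- unlist(lapply(train_series, function(s)
    .heading_series((s$R_x - p$mean_x) / p$sd_x)))
  hy <- unlist(lapply(train_series, function(s)
    .heading_series((s$R_y - p$mean_y) / p$sd_y)))
  p$heading_mean_x <- mean(hx)
  p$heading_mean_y <- mean(hy)
  p$heading_sd_x <- .pop_sd(hx)
  p$heading_sd_y <- .pop_sd(hy)
  if (p$heading_sd_x <= 0 || p$heading_sd_y <= 0) {
    stop("degenerate training set: zero variance in a heading dimension",
         call. = FALSE)
  }
  structure(p, class = "standardization_params")
}

#' Standardize a relative series with fitted parameters
#'
#' @param series a `relative_series`.
#' @param params a [fit_standardization()] result, applied unchanged
#'   (training-set statistics are never refitted on new data).
#' @return list with standardized `x` and `y` and the `sampling_rate`.
#' @export
standardize <- function(series, params) {
  stopifnot(inherits(series, "relative_series"),
            inherits(params, "standardization_params"))
  list(x = (series$R_x - params$mean_x) / params$sd_x,
       y = (series$R_y - params$mean_y) / params$sd_y,
       sampling_rate = series$sampling_rate)
}

#' Full feature pipeline for one trajectory
#'
#' Relative positions, standardization, per-sample heading directions of the
#' standardized series, and heading normalization with the training heading
#' statistics — the four per-sample channels the phase network consumes.
#'
#' @param traj a [marker_trajectory()].
#' @param params a [fit_standardization()] result.
#' @return list of equal-length numeric vectors `x`, `y`, `hx`, `hy` plus
#'   `sampling_rate`, class `feature_series`.
#' @export
feature_series <- function(traj, params) {
  std <- standardize(relative_positions(traj), params)
  structure(
    list(
      x = std$x, y = std$y,
      hx = (.heading_series(std$x) - params$heading_mean_x) / params$heading_sd_x,
      hy = (.heading_series(std$y) - params$heading_mean_y) / params$heading_sd_y,
      sampling_rate = std$sampling_rate
    ),
    class = "feature_series"
  )
}

# 28-value network input for windows ending at the given 0-based indices:
# x, y, hx, hy over in-window samples end-6 .. end.
.window_matrix <- function(feat, end_idx) {
  offs <- -6:0
  cols <- lapply(list(feat$x, feat$y, feat$hx, feat$hy), function(v) {
    m <- outer(end_idx, offs, function(i, o) v[i + o + 1L])
    if (length(end_idx) == 1L) m <- matrix(m, nrow = 1L)
    m
  })
  do.call(cbind, cols)
}

#' Build consecutive window pairs for training
#'
#' For every 0-based end index `i >= 12` one pair is produced: the current
#' window covers samples `i-6 .. i` and the previous window is the
#' window one sample earlier, `i-7 .. i-1` — consecutive stride-1 windows,
#' so the phase progression between a pair's two outputs is the per-sample
#' progression the penalty band is calibrated for (a cycle of L samples
#' progresses 2 pi / L per pair). Each window is flattened to the 28
#' network inputs (7 x, 7 y, 7 heading-x, 7 heading-y values).
#'
#' @param feat a [feature_series()].
#' @return object of class `window_pairs`: list with matrices `prev` and
#'   `curr` (one row per pair, 28 columns) and the 0-based `end_index` of
#'   each pair's current window. A series shorter than 13 samples yields
#'   zero pairs with a warning.
#' @export
build_window_pairs <- function(feat) {
  stopifnot(inherits(feat, "feature_series"))
  n <- length(feat$x)
  if (n < 13L) {
    warning("series shorter than 13 samples: no window pairs")
    return(structure(
      list(prev = matrix(numeric(0), 0, 28), curr = matrix(numeric(0), 0, 28),
           end_index = integer(0)),
      class = "window_pairs"
    ))
  }
  end_idx <- 12:(n - 1)
  structure(
    list(prev = .window_matrix(feat, end_idx - 1L),
         curr = .window_matrix(feat, end_idx),
         end_index = end_idx),
    class = "window_pairs"
  )
}

#' Concatenate window pairs from several trajectories
#'
#' Stacks the pair matrices of multiple [build_window_pairs()] results into
#' one training batch; pairs never span trajectory boundaries.
#'
#' @param ... `window_pairs` objects, or a single list of them.
#' @return a `window_pairs` object (with `end_index` dropped, as indices are
#'   only meaningful within one trajectory).
#' @export
bind_window_pairs <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && !inherits(ps[[1]], "window_pairs")) ps <- ps[[1]]
  stopifnot(all(vapply(ps, inherits, TRUE, "window_pairs")))
  structure(
    list(prev = do.call(rbind, lapply(ps, `[[`, "prev")),
         curr = do.call(rbind, lapply(ps, `[[`, "curr")),
         end_index = NULL,
         group = rep(seq_along(ps), vapply(ps, function(p) nrow(p$curr), 0L))),
    class = "window_pairs"
  )
}

#' Write / read standardization parameters as JSON
#'
#' @param params a `standardization_params` object.
#' @param path JSON file path.
#' @return `path` (write) or the restored `standardization_params` (read).
#' @export
write_standardization_json <- function(params, path) {
  stopifnot(inherits(params, "standardization_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_standardization_json
#' @export
read_standardization_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(p, class = "standardization_params")
}
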