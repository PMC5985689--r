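#' Detect saccades in an eye-position trace
#'
#' Velocity-threshold detector for simulated traces: the smoothed velocity
#' (central differences, 5-sample moving average) must exceed `v_thresh`
#' for at least `min_dur`; events separated by less than `merge_interval`
#' are merged. Amplitude is the signed position difference between offset
#' and onset. Thresholds default low because the simulated intersaccadic
#' trace is nearly noiseless (the model contains no ocular drift).
#'
#' @param x A `saccsim_result`, or a numeric eye-position trace (deg).
#' @param dt Sampling interval in seconds (taken from the result object if
#'   `x` is one).
#' @param params Parameter object supplying `v_thresh`, `min_dur` and
#'   `merge_interval` (taken from the result object if available).
#' @return A data frame of class `saccade_events`, one row per event:
#'   `onset`, `offset` (s), `amplitude` (signed deg), `magnitude` (deg),
#'   `peak_velocity` (deg/s), `direction` (`"left"`/`"right"`).
#' @export
detect_saccades <- function(x, dt = NULL, params = NULL) {
  if (inherits(x, "saccsim_result")) {
    pos <- x$traces$eye_pos
    if (is.null(dt)) dt <- x$dt
    if (is.null(params)) params <- x$params
  } else {
    pos <- as.numeric(x)
    if (is.null(dt)) stop("dt required for a raw trace", call. = FALSE)
    if (is.null(params)) params <- default_parameters()
  }
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      amplitude = numeric(0), magnitude = numeric(0),
                      peak_velocity = numeric(0),
                      direction = character(0))
  class(empty) <- c("saccade_events", "data.frame")
  n <- length(pos)
  min_samples <- max(1L, round(params$min_dur / dt))
  if (n < min_samples + 2L) return(empty)

  vel <- c(0, (pos[3:n] - pos[1:(n - 2)]) / (2 * dt), 0)
  vel <- as.numeric(stats::filter(vel, rep(1 / 5, 5), sides = 2))
  vel[is.na(vel)] <- 0

  above <- abs(vel) > params$v_thresh
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values]

  # merge events separated by less than merge_interval
  gap_samples <- round(params$merge_interval / dt)
  if (length(on) > 1) {
    keep_on <- on[1]
    merged_on <- c()
    merged_off <- c()
    cur_off <- off[1]
    for (k in 2:length(on)) {
      if (on[k] - cur_off < gap_samples) {
        cur_off <- off[k]
      } else {
        merged_on <- c(merged_on, keep_on)
        merged_off <- c(merged_off, cur_off)
        keep_on <- on[k]
        cur_off <- off[k]
      }
    }
    on <- c(merged_on, keep_on)
    off <- c(merged_off, cur_off)
  }

  dur_ok <- (off - on + 1L) >= min_samples
  on <- on[dur_ok]
  off <- off[dur_ok]
  if (length(on) == 0) return(empty)

  amplitude <- pos[off] - pos[on]
  peak_velocity <- vapply(seq_along(on), function(k) {
    max(abs(vel[on[k]:off[k]]))
  }, numeric(1))
  ev <- data.frame(
    onset = (on - 1L) * dt,
    offset = (off - 1L) * dt,
    amplitude = amplitude,
    magnitude = abs(amplitude),
    peak_velocity = peak_velocity,
    direction = ifelse(amplitude >= 0, "right", "left")
  )
  class(ev) <- c("saccade_events", "data.frame")
  ev
}

#' Summary statistics of fixational eye movements
#'
#' Computes the standard descriptors of a fixation epoch: event rate,
#' magnitude and intersaccadic-interval quantiles, the main-sequence slope
#' (least-squares fit of peak velocity on magnitude through the origin),
#' the mean eye position, and counts of square-wave jerks and macrosaccadic
#' oscillation runs.
#'
#' @param events A [detect_saccades()] data frame.
#' @param pos Eye-position trace in degrees (for the mean position), or a
#'   `saccsim_result`.
#' @param duration Epoch duration in seconds.
#' @return A list of class `fixation_statistics`: `n_events`, `rate`
#'   (events/s), `magnitude_quantiles` and `isi_quantiles` (25/50/75%, `NA`
#'   when there are no events / fewer than two events),
#'   `main_sequence_slope` ((deg/s)/deg, `NA` with fewer than two events),
#'   `mean_eye_position` (deg), `swj_count`, `oscillation_count`.
#' @export
summarize_fixation <- function(events, pos, duration) {
  if (inherits(pos, "saccsim_result")) {
    if (missing(duration)) duration <- pos$duration
    pos <- pos$traces$eye_pos
  }
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  n <- nrow(events)
  qs <- c(0.25, 0.5, 0.75)
  mag_q <- if (n > 0) stats::quantile(events$magnitude, qs, names = FALSE)
    else rep(NA_real_, 3)
  isi <- if (n > 1) diff(events$onset) else numeric(0)
  isi_q <- if (length(isi) > 0) stats::quantile(isi, qs, names = FALSE)
    else rep(NA_real_, 3)
  slope <- if (n >= 2) {
    sum(events$peak_velocity * events$magnitude) / sum(events$magnitude^2)
  } else NA_real_
  out <- list(
    n_events = n,
    rate = n / duration,
    magnitude_quantiles = stats::setNames(mag_q, c("q25", "q50", "q75")),
    isi_quantiles = stats::setNames(isi_q, c("q25", "q50", "q75")),
    main_sequence_slope = slope,
    mean_eye_position = mean(pos),
    swj_count = detect_swj(events)$count,
    oscillation_count = detect_oscillations(events)
  )
  class(out) <- "fixation_statistics"
  out
}

#' @export
print.fixation_statistics <- function(x, ...) {
  cat(sprintf("<fixation_statistics> %d events, %.2f /s\n", x$n_events,
              x$rate))
  cat(sprintf("  median magnitude %.3f deg, median ISI %.3f s\n",
              x$magnitude_quantiles[["q50"]], x$isi_quantiles[["q50"]]))
  cat(sprintf("  main-sequence slope %.1f (deg/s)/deg, mean position %.3f deg\n",
              x$main_sequence_slope, x$mean_eye_position))
  cat(sprintf("  SWJs %d, oscillation runs %d\n", x$swj_count,
              x$oscillation_count))
  invisible(x)
}

#' Detect square-wave jerks
#'
#' A consecutive event pair is counted as a square-wave jerk when the two
#' saccades go in opposite directions, the interval between them (onset of
#' the second minus offset of the first) is at most `max_isi`, and their
#' magnitudes are within a factor of two of each other.
#'
#' @param events A time-ordered [detect_saccades()] data frame.
#' @param max_isi Maximum interval between the pair in seconds.
#' @param ratio_limits Allowed magnitude ratio (second / first) range.
#' @return List with `count` and `pairs` (two-column matrix of row indices).
#' @export
detect_swj <- function(events, max_isi = 0.5, ratio_limits = c(0.5, 2)) {
  n <- nrow(events)
  if (n < 2) return(list(count = 0L, pairs = matrix(integer(0), ncol = 2)))
  i <- seq_len(n - 1L)
  opposite <- events$direction[i] != events$direction[i + 1L]
  isi <- events$onset[i + 1L] - events$offset[i]
  ratio <- events$magnitude[i + 1L] / events$magnitude[i]
  ok <- opposite & isi <= max_isi & isi >= 0 &
    ratio >= ratio_limits[1] & ratio <= ratio_limits[2]
  ok[is.na(ok)] <- FALSE
  list(count = sum(ok), pairs = cbind(which(ok), which(ok) + 1L))
}

#' Count macrosaccadic oscillation runs
#'
#' A run of at least `min_run` consecutive events with strictly alternating
#' directions and inter-event intervals of at most `max_isi` counts as one
#' oscillation, however long the run (R, L, R, L, R is a single run).
#'
#' @param events A time-ordered [detect_saccades()] data frame.
#' @param max_isi Maximum inter-event interval (onset-to-onset minus the
#'   first event's offset, i.e. gap) in seconds.
#' @param min_run Minimum number of alternating events.
#' @return Integer count of oscillation runs.
#' @export
detect_oscillations <- function(events, max_isi = 0.5, min_run = 3L) {
  n <- nrow(events)
  if (n < min_run) return(0L)
  alt <- events$direction[-1] != events$direction[-n]
  gap_ok <- (events$onset[-1] - events$offset[-n]) <= max_isi
  link <- alt & gap_ok          # event i+1 continues a run from event i
  count <- 0L
  run_len <- 1L
  for (k in seq_along(link)) {
    if (link[k]) {
      run_len <- run_len + 1L
      if (run_len == min_run) count <- count + 1L
    } else {
      run_len <- 1L
    }
  }
  count
}
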