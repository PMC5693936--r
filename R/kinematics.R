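#' Zero-phase Butterworth low-pass filtering of a joystick trace
#'
#' Applies a 4th-order Butterworth low-pass filter with a 12 Hz cut-off,
#' forward-backward (`signal::filtfilt`) so the filtering is zero phase and
#' movement-onset times are not lag-biased. DC gain is exactly 1.
#'
#' @param trace a `joystick_trace` (sample rate at least 100 Hz).
#' @param cutoff_hz low-pass cut-off frequency (Hz).
#' @param order filter order.
#' @return the filtered `joystick_trace`.
#' @export
filter_trace <- function(trace, cutoff_hz = 12, order = 4) {
  stopifnot(inherits(trace, "joystick_trace"))
  fs <- trace$sample_rate
  if (fs < 100) stop("sample rate must be at least 100 Hz")
  n <- length(trace$positions)
  # filtfilt needs samples beyond threefold the filter warm-up
  if (n <= 3 * (order + 1))
    stop("trace shorter than the filter warm-up (", n, " samples)")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # odd-reflection padding and mean removal around the forward-backward
  # pass so start-up transients decay inside the pads, not the data
  x <- trace$positions
  m <- mean(x)
  x <- x - m
  pad <- min(n - 1L, ceiling(3 * fs / cutoff_hz))
  pre <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  trace$positions <- y[(pad + 1L):(pad + n)] + m
  trace
}

#' Baseline (offset) correction of a trace
#'
#' Subtracts the mean position over the pre-stimulus baseline window, so the
#' corrected trace has exactly zero mean over that window.
#'
#' @param trace a `joystick_trace`.
#' @param baseline_window numeric length 2, window in seconds relative to
#'   trial start; must precede stimulus onset and contain at least one
#'   sample.
#' @return the offset-corrected `joystick_trace`.
#' @export
baseline_correct <- function(trace, baseline_window) {
  stopifnot(inherits(trace, "joystick_trace"), length(baseline_window) == 2)
  tt <- trace$t0 + (seq_along(trace$positions) - 1) / trace$sample_rate
  in_win <- tt >= baseline_window[1] & tt < baseline_window[2]
  if (!any(in_win)) stop("empty baseline window")
  trace$positions <- trace$positions - mean(trace$positions[in_win])
  trace
}

#' Extract movement kinematics from a conditioned trace
#'
#' On the filtered, baseline-corrected trace, computes within the answer
#' window `[go_cue, go_cue + answer_dur]`:
#' \itemize{
#'   \item amplitude: the signed extremum of position (push positive, pull
#'     negative);
#'   \item peak speed: the maximum absolute centered finite-difference
#'     velocity (one-sided at the window edges);
#'   \item onset: the first time position exceeds `onset_rule$threshold_mm`
#'     in absolute value, sustained for `onset_rule$min_dur_s`, in seconds
#'     after the go cue;
#'   \item direction: the sign of the amplitude.
#' }
#' If the absolute amplitude stays below the onset threshold, the direction
#' is `"none"` and the onset absent.
#'
#' @param trace a `joystick_trace` (filter and baseline-correct it first).
#' @param go_cue_time go-cue time (s, relative to trial start).
#' @param answer_dur answer window duration (s).
#' @param onset_rule list with `threshold_mm` (default 1) and `min_dur_s`
#'   (default 0.020).
#' @return a one-row data.frame: `amplitude_mm`, `peak_speed_mm_s`,
#'   `onset_s`, `direction`.
#' @export
extract_kinematics <- function(trace, go_cue_time, answer_dur = 1,
                               onset_rule = list(threshold_mm = 1,
                                                 min_dur_s = 0.020)) {
  stopifnot(inherits(trace, "joystick_trace"))
  fs <- trace$sample_rate
  tt <- trace$t0 + (seq_along(trace$positions) - 1) / fs
  in_win <- tt >= go_cue_time & tt <= go_cue_time + answer_dur
  if (!any(in_win)) stop("answer window lies outside the trace")
  x <- trace$positions[in_win]
  tw <- tt[in_win]

  i_ext <- which.max(abs(x))
  amplitude <- x[i_ext]

  v <- centered_velocity(x, fs)
  peak_speed <- max(abs(v))

  thr <- onset_rule$threshold_mm
  min_n <- max(1L, round(onset_rule$min_dur_s * fs))
  onset <- NA_real_
  direction <- "none"
  if (abs(amplitude) >= thr) {
    above <- abs(x) > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= min_n)
    if (length(ok)) onset <- tw[starts[ok[1]]] - go_cue_time
    direction <- if (amplitude > 0) "push" else "pull"
  }
  data.frame(amplitude_mm = amplitude, peak_speed_mm_s = peak_speed,
             onset_s = onset, direction = direction, stringsAsFactors = FALSE)
}

centered_velocity <- function(x, fs) {
  n <- length(x)
  if (n < 3) return(rep(0, n))
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  v
}

#' Kinematics table for a whole session
#'
#' Filters, baseline-corrects and summarizes every stored trace of a
#' session; the result merges into the trial table by `index`.
#'
#' @param session a `session_log` with traces.
#' @param onset_rule see [extract_kinematics()].
#' @return a data.frame with columns `index`, `amplitude_mm`,
#'   `peak_speed_mm_s`, `onset_s`, `direction`.
#' @export
session_kinematics <- function(session,
                               onset_rule = list(threshold_mm = 1,
                                                 min_dur_s = 0.020)) {
  stopifnot(inherits(session, "session_log"))
  if (length(session$traces) == 0)
    return(data.frame(index = integer(0), amplitude_mm = numeric(0),
                      peak_speed_mm_s = numeric(0), onset_s = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  cfg <- session$meta$config
  rows <- lapply(names(session$traces), function(key) {
    i <- as.integer(key)
    row <- session$trials[session$trials$index == i, ]
    tr <- filter_trace(session$traces[[key]])
    tr <- baseline_correct(tr, c(0, row$t_stim_on_s))
    k <- extract_kinematics(tr, row$t_go_cue_s, cfg$answer_dur, onset_rule)
    cbind(data.frame(index = i), k)
  })
  do.call(rbind, rows)
}
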