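#' Task configuration
#'
#' Parameters of the delayed-response joystick task: trial phase durations,
#' the movement amplitude criterion, stimulus frequencies, the adaptive
#' staircase, the anti-bias trial sequencer, and the inactivation trial
#' fraction.
#'
#' Defaults follow the published task: a 0.5-2 s baseline, a 1 s vibrotactile
#' stimulus at 10 or 40 Hz, a 1 s delay, a 1 s answer window, a final 10 mm
#' amplitude criterion, a 50 ms staircase step capped at 1 s, a maximum run
#' of 3 same-type trials, a failure-repeat rule of more than
#' `repeat_rule_threshold` non-correct trials among the last 9 of a type, and
#' inactivation on 1/3 of trials. The time-out after non-correct trials is
#' drawn uniformly from `timeout_range`; the wider printed range of 1-3 s is
#' the default.
#'
#' @param baseline_range numeric length 2, baseline period bounds (s).
#' @param vibration_dur vibrotactile stimulus duration (s).
#' @param delay_dur_target final delay duration (s).
#' @param answer_dur answer window duration (s).
#' @param timeout_range numeric length 2, time-out bounds (s).
#' @param amplitude_threshold final required movement amplitude (mm).
#' @param stim_freqs numeric length 2, the two stimulus frequencies (Hz);
#'   the first maps to push trials, the second to pull trials.
#' @param staircase_step delay increment per correct trial (s).
#' @param staircase_cap maximum staircased delay (s).
#' @param amplitude_start initial amplitude requirement (mm).
#' @param amplitude_step amplitude increment per correct trial (mm); the
#'   schedule on which the amplitude requirement advances is not pinned down
#'   by the task description beyond "progressively", so it is configurable.
#' @param sequencer_run_cap maximum run of identical trial types.
#' @param repeat_rule_window trials of a type inspected by the repeat rule.
#' @param repeat_rule_threshold repeat a type when more than this many of its
#'   last `repeat_rule_window` trials were not correct; must be in 4-6.
#' @param inactivation_fraction probability a trial is an inactivation trial.
#' @param onset_threshold_mm movement-onset detection threshold (mm).
#' @param onset_min_dur_s sustained duration for onset detection (s).
#' @param sample_rate joystick trace sampling rate (Hz).
#' @return an object of class `task_config` (a validated list).
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$delay_dur_target
task_config <- function(baseline_range = c(0.5, 2.0),
                        vibration_dur = 1.0,
                        delay_dur_target = 1.0,
                        answer_dur = 1.0,
                        timeout_range = c(1, 3),
                        amplitude_threshold = 10,
                        stim_freqs = c(10, 40),
                        staircase_step = 0.050,
                        staircase_cap = 1.0,
                        amplitude_start = 1,
                        amplitude_step = 0.5,
                        sequencer_run_cap = 3,
                        repeat_rule_window = 9,
                        repeat_rule_threshold = 5,
                        inactivation_fraction = 1 / 3,
                        onset_threshold_mm = 1,
                        onset_min_dur_s = 0.020,
                        sample_rate = 5000) {
  cfg <- list(
    baseline_range = as.numeric(baseline_range),
    vibration_dur = vibration_dur,
    delay_dur_target = delay_dur_target,
    answer_dur = answer_dur,
    timeout_range = as.numeric(timeout_range),
    amplitude_threshold = amplitude_threshold,
    stim_freqs = as.numeric(stim_freqs),
    staircase_step = staircase_step,
    staircase_cap = staircase_cap,
    amplitude_start = amplitude_start,
    amplitude_step = amplitude_step,
    sequencer_run_cap = as.integer(sequencer_run_cap),
    repeat_rule_window = as.integer(repeat_rule_window),
    repeat_rule_threshold = as.integer(repeat_rule_threshold),
    inactivation_fraction = inactivation_fraction,
    onset_threshold_mm = onset_threshold_mm,
    onset_min_dur_s = onset_min_dur_s,
    sample_rate = sample_rate
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
}

#' Validate a task configuration
#'
#' @param cfg a `task_config`.
#' @return `cfg`, invisibly unchanged, or an error naming the violated field.
#' @export
validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  durs <- c(cfg$vibration_dur, cfg$delay_dur_target, cfg$answer_dur,
            cfg$baseline_range, cfg$timeout_range, cfg$staircase_step,
            cfg$staircase_cap)
  if (any(durs <= 0)) stop("all durations must be > 0")
  if (cfg$baseline_range[1] > cfg$baseline_range[2])
    stop("baseline_range must be increasing")
  if (cfg$timeout_range[1] > cfg$timeout_range[2])
    stop("timeout_range must be increasing")
  if (cfg$amplitude_start > cfg$amplitude_threshold)
    stop("amplitude_start must not exceed amplitude_threshold")
  if (cfg$repeat_rule_threshold < 4L || cfg$repeat_rule_threshold > 6L)
    stop("repeat_rule_threshold must be in [4, 6]")
  if (cfg$inactivation_fraction < 0 || cfg$inactivation_fraction > 1)
    stop("inactivation_fraction must be in [0, 1]")
  if (length(cfg$stim_freqs) != 2L) stop("stim_freqs must have length 2")
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("Delayed-response task configuration\n")
  cat(sprintf("  baseline %.2g-%.2g s | vibration %.2g s | delay %.2g s | answer %.2g s\n",
              x$baseline_range[1], x$baseline_range[2], x$vibration_dur,
              x$delay_dur_target, x$answer_dur))
  cat(sprintf("  amplitude criterion %g mm (start %g, step %g) | staircase %g s -> %g s\n",
              x$amplitude_threshold, x$amplitude_start, x$amplitude_step,
              x$staircase_step, x$staircase_cap))
  cat(sprintf("  run cap %d | repeat rule >%d of %d | inactivation fraction %.3g\n",
              x$sequencer_run_cap, x$repeat_rule_threshold,
              x$repeat_rule_window, x$inactivation_fraction))
  invisible(x)
}

#' Write / read a task configuration as flat YAML
#'
#' Keys are exactly the field names of [task_config()].
#'
#' @param cfg a `task_config`.
#' @param path file path.
#' @return `read_task_config` returns a validated `task_config`.
#' @export
write_task_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "task_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(task_config, x)
}
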