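#' Default stereotaxic coordinates of the silenced cortical areas
#'
#' (ML, AP) in millimeters relative to bregma, contralateral hemisphere:
#' caudal forelimb area (CFA), rostral forelimb area (RFA), barrel cortex
#' (BCx), anterior cingulate cortex (ACC), posterior parietal cortex (PPC).
#'
#' @return a data.frame with columns `site`, `ml_mm`, `ap_mm`.
#' @export
site_coordinates <- function() {
  data.frame(
    site = c("CFA", "RFA", "BCx", "ACC", "PPC"),
    ml_mm = c(1.8, 0.9, 3.5, 0.15, 1.7),
    ap_mm = c(0.8, 2.7, -1.5, 0, -2),
    stringsAsFactors = FALSE
  )
}

#' Inactivation condition
#'
#' One optogenetic silencing condition: the set of targeted sites, the trial
#' period in which the laser is on, and the per-site power. The control
#' (unperturbed) condition is `sites = character(0)`, `period = "none"`.
#'
#' @param sites character vector, subset of CFA/RFA/ACC/PPC/BCx; empty for
#'   control.
#' @param period one of `"vibration"`, `"delay"`, `"answer"`, `"none"`.
#' @param power_per_site laser power per site (mW); 9 for single-site, 3 per
#'   site for dual-site silencing by default.
#' @param coordinates data.frame of per-site (ML, AP) in mm; defaults to
#'   [site_coordinates()].
#' @return an object of class `inactivation_condition`.
#' @export
#' @examples
#' inactivation_condition(c("CFA", "RFA"), "delay", power_per_site = 3)
#' control_condition()
inactivation_condition <- function(sites = character(0),
                                   period = "none",
                                   power_per_site = if (length(sites) > 1) 3 else 9,
                                   coordinates = site_coordinates()) {
  sites <- as.character(sites)
  known <- site_coordinates()$site
  if (length(sites) && !all(sites %in% known))
    stop("unknown site(s): ", paste(setdiff(sites, known), collapse = ", "))
  period <- match.arg(period, c("vibration", "delay", "answer", "none"))
  if ((period == "none") != (length(sites) == 0L))
    stop("period is 'none' if and only if sites is empty")
  structure(
    list(sites = sites, period = period,
         power_per_site = if (length(sites)) power_per_site else NA_real_,
         coordinates = coordinates[coordinates$site %in% sites, , drop = FALSE]),
    class = "inactivation_condition"
  )
}

#' @rdname inactivation_condition
#' @export
control_condition <- function() inactivation_condition()

#' Label of an inactivation condition, e.g. "CFA+RFA"
#' @param condition an `inactivation_condition`.
#' @return a character scalar; `""` for control.
#' @export
condition_label <- function(condition) {
  paste(condition$sites, collapse = "+")
}

#' @export
print.inactivation_condition <- function(x, ...) {
  if (length(x$sites) == 0) cat("<control condition>\n")
  else cat(sprintf("<inactivation: %s during %s, %g mW/site>\n",
                   condition_label(x), x$period, x$power_per_site))
  invisible(x)
}

is_control <- function(condition) length(condition$sites) == 0L

#' Anti-bias trial-type sequencer
#'
#' Chooses the next trial type (push or pull) from the session history.
#' Rule order: (1) if, among the last `repeat_rule_window` trials of one
#' type, more than `repeat_rule_threshold` were not correct, that type is
#' repeated; (2) otherwise, if the last `sequencer_run_cap` trials were all
#' of the same type, the type is switched; (3) otherwise the type is drawn
#' uniformly. If the failure rule fires for both types, the type with more
#' failures is chosen (ties broken uniformly).
#'
#' @param history data.frame (or list) with elements `trial_type` and
#'   `outcome`, parallel vectors in session order; may be empty.
#' @param config a [task_config()].
#' @param stream an [rng_stream()] for the uniform draws.
#' @param repeat_rule set `FALSE` to disable the failure-repeat rule.
#' @return `"push"` or `"pull"`.
#' @export
next_trial_type <- function(history, config = task_config(), stream,
                            repeat_rule = TRUE) {
  types <- c("push", "pull")
  n <- if (is.null(history)) 0L else length(history$trial_type)
  if (n > 0L) {
    if (repeat_rule) {
      fails <- vapply(types, function(ty) {
        idx <- which(history$trial_type == ty)
        idx <- utils::tail(idx, config$repeat_rule_window)
        sum(history$outcome[idx] != "correct")
      }, numeric(1))
      firing <- fails > config$repeat_rule_threshold
      if (any(firing)) {
        cand <- types[firing]
        if (length(cand) == 2L) {
          cand <- if (fails[1] != fails[2]) types[which.max(fails)]
                  else with_stream(stream, sample(types, 1L))
        }
        return(cand)
      }
    }
    k <- config$sequencer_run_cap
    if (n >= k) {
      last_k <- utils::tail(history$trial_type, k)
      if (length(unique(last_k)) == 1L)
        return(setdiff(types, last_k[1]))
    }
  }
  with_stream(stream, sample(types, 1L))
}

#' Outcome classes of a trial
#' @return character vector of the five outcome labels.
#' @export
outcome_levels <- function() {
  c("correct", "incorrect", "no_movement", "anticipated_lick", "premature_move")
}

#' Run one trial of the state machine
#'
#' Walks the trial timeline baseline -> vibration (1 s) -> delay -> go cue ->
#' answer window and classifies the outcome from the agent response, with
#' event precedence: a supra-threshold joystick movement before the go cue
#' and a lick before the first joystick movement are abort events, the
#' earlier one winning (`premature_move` / `anticipated_lick` respectively).
#' Otherwise a supra-threshold movement inside the answer window is
#' `correct` (matching direction, reward cue emitted) or `incorrect`;
#' sub-threshold movements are ignored and the trial is `no_movement`.
#' Non-correct outcomes receive a time-out drawn uniformly from
#' `config$timeout_range`; each further movement/lick during the time-out
#' re-initializes it (`agent_response$timeout_restarts` additional draws are
#' accumulated).
#'
#' @param spec list with `index`, `trial_type` ("push"/"pull"), `stim_freq`
#'   (Hz), `baseline_dur` (s), `delay_dur` (s), and optionally `inactivation`
#'   (an [inactivation_condition()], default control).
#' @param agent_response list with `move_time` (s from trial start, or `NA`),
#'   `direction` ("push"/"pull"/"none"), `amplitude` (mm, peak excursion),
#'   `peak_speed` (mm/s), `lick_times` (numeric vector, s from trial start),
#'   `timeout_restarts` (count, default 0), and optionally `fine_motor`
#'   (named logical vector).
#' @param config a [task_config()].
#' @param amplitude_requirement supra-threshold criterion for this trial
#'   (mm); defaults to `config$amplitude_threshold`. During training the
#'   staircased requirement is passed instead.
#' @param timeout_stream [rng_stream()] used for the time-out draw; when
#'   missing, a non-correct trial gets the midpoint of `timeout_range`.
#' @return a one-row data.frame (the trial record) with columns
#'   `index, trial_type, stim_freq_hz, baseline_dur_s, delay_dur_s,
#'   t_stim_on_s, t_go_cue_s, response_dir, t_first_move_s, t_first_lick_s,
#'   outcome, reward, sites, period, power_mw, timeout_s`.
#' @export
run_trial <- function(spec, agent_response, config = task_config(),
                      amplitude_requirement = config$amplitude_threshold,
                      timeout_stream = NULL) {
  resp <- agent_response
  if (is.null(resp$timeout_restarts)) resp$timeout_restarts <- 0L
  times <- c(resp$move_time, resp$lick_times)
  if (any(!is.na(times) & times < 0))
    stop("agent response contains negative event times")

  cond <- spec$inactivation
  if (is.null(cond)) cond <- control_condition()

  t_stim_on <- spec$baseline_dur
  t_go <- spec$baseline_dur + config$vibration_dur + spec$delay_dur
  t_answer_end <- t_go + config$answer_dur

  move_t <- resp$move_time
  supra <- !is.na(move_t) && !is.null(resp$amplitude) &&
    abs(resp$amplitude) >= amplitude_requirement
  first_lick <- if (length(resp$lick_times)) min(resp$lick_times) else NA_real_

  # abort events, earliest wins
  premature_t <- if (supra && move_t < t_go) move_t else NA_real_
  antic_t <- if (!is.na(first_lick) &&
                 (is.na(move_t) || first_lick < move_t) &&
                 first_lick < t_answer_end) first_lick else NA_real_

  outcome <-
    if (!is.na(premature_t) && (is.na(antic_t) || premature_t <= antic_t)) {
      "premature_move"
    } else if (!is.na(antic_t)) {
      "anticipated_lick"
    } else if (supra && move_t >= t_go && move_t <= t_answer_end) {
      if (identical(resp$direction, spec$trial_type)) "correct" else "incorrect"
    } else {
      "no_movement"
    }

  timeout_s <- NA_real_
  if (outcome != "correct") {
    n_draws <- resp$timeout_restarts + 1L
    timeout_s <-
      if (is.null(timeout_stream)) n_draws * mean(config$timeout_range)
      else with_stream(timeout_stream,
                       sum(stats::runif(n_draws, config$timeout_range[1],
                                        config$timeout_range[2])))
  }

  answered <- outcome %in% c("correct", "incorrect")
  data.frame(
    index = spec$index,
    trial_type = spec$trial_type,
    stim_freq_hz = spec$stim_freq,
    baseline_dur_s = spec$baseline_dur,
    delay_dur_s = spec$delay_dur,
    t_stim_on_s = t_stim_on,
    t_go_cue_s = t_go,
    response_dir = if (answered) resp$direction else "none",
    t_first_move_s = if (!is.na(move_t) && (supra || outcome == "no_movement"))
      move_t else NA_real_,
    t_first_lick_s = first_lick,
    outcome = outcome,
    reward = outcome == "correct",
    sites = condition_label(cond),
    period = cond$period,
    power_mw = cond$power_per_site,
    timeout_s = timeout_s,
    stringsAsFactors = FALSE
  )
}

#' Adaptive training staircase
#'
#' State of the within-session staircase on the delay duration and the
#' required movement amplitude. Each correct trial lengthens the delay by
#' `staircase_step` (50 ms) up to `staircase_cap` (1 s) and raises the
#' amplitude requirement by `amplitude_step` up to `amplitude_threshold`;
#' non-correct trials leave the state unchanged.
#'
#' @param current_delay current delay requirement (s).
#' @param current_amplitude current amplitude requirement (mm).
#' @param config a [task_config()].
#' @return an object of class `staircase_state`.
#' @export
staircase_state <- function(current_delay = 0.050,
                            current_amplitude = NULL,
                            config = task_config()) {
  if (is.null(current_amplitude)) current_amplitude <- config$amplitude_start
  stopifnot(current_delay >= 0.050 - 1e-12,
            current_delay <= config$staircase_cap + 1e-12)
  structure(list(current_delay = current_delay,
                 current_amplitude = current_amplitude),
            class = "staircase_state")
}

#' @rdname staircase_state
#' @param state a `staircase_state`.
#' @param outcome outcome label of the finished trial.
#' @export
update_staircase <- function(state, outcome, config = task_config()) {
  stopifnot(inherits(state, "staircase_state"))
  if (identical(outcome, "correct")) {
    state$current_delay <- min(state$current_delay + config$staircase_step,
                               config$staircase_cap)
    state$current_amplitude <- min(state$current_amplitude + config$amplitude_step,
                                   config$amplitude_threshold)
  }
  state
}

#' Session-to-session delay carry-over
#'
#' The initial delay of a session is the mean per-trial delay of the previous
#' session, clipped to the staircase range; with no previous session the
#' first-session default of 50 ms is used.
#'
#' @param previous_delays numeric vector of the previous session's per-trial
#'   delays (s); may be empty.
#' @param config a [task_config()].
#' @return initial delay for the next session (s).
#' @export
carry_over_delay <- function(previous_delays, config = task_config()) {
  if (length(previous_delays) == 0L) return(0.050)
  min(max(mean(previous_delays), 0.050), config$staircase_cap)
}

#' Randomly assign an inactivation condition to a trial
#'
#' With probability `config$inactivation_fraction` the trial is an
#' inactivation trial with a condition drawn uniformly from `conditions`;
#' otherwise it is a control trial.
#'
#' @param conditions list of [inactivation_condition()] objects configured
#'   for the session.
#' @param config a [task_config()].
#' @param stream an [rng_stream()].
#' @return an `inactivation_condition`.
#' @export
assign_inactivation <- function(conditions, config = task_config(), stream) {
  if (length(conditions) == 0L || config$inactivation_fraction <= 0)
    return(control_condition())
  with_stream(stream, {
    if (stats::runif(1) < config$inactivation_fraction)
      conditions[[sample.int(length(conditions), 1L)]]
    else control_condition()
  })
}
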