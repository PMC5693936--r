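#' Simulate one behavioral session
#'
#' Runs the full trial loop: the anti-bias sequencer picks each trial type,
#' the synthetic mouse responds, the state machine classifies the outcome,
#' and (in learning mode) the staircase advances the delay and amplitude
#' requirements. All randomness flows from `seed` through named substreams
#' (`sequencer`, `baseline`, `inactivation`, `agent`, `timeout`, `trace`,
#' `stim`), so the session is reproducible end to end and per component.
#'
#' @param mouse_id,session_id identifiers stored in the metadata.
#' @param params an [agent_params()], usually mouse-realized via
#'   [realize_mouse()].
#' @param config a [task_config()].
#' @param n_trials number of trials to run.
#' @param mode `"learning"` (staircase active, no inactivation) or
#'   `"inactivation"` (final task parameters, conditions interleaved).
#' @param conditions list of [inactivation_condition()]s used in
#'   inactivation mode.
#' @param seed integer session seed.
#' @param initial_delay starting delay (s) in learning mode; typically
#'   [carry_over_delay()] of the previous session.
#' @param include_traces synthesize 5 kHz joystick traces (and laser
#'   schedules) per trial. Off by default: traces dominate memory/runtime
#'   and most analyses need only the trial table.
#' @param noise_sd trace sensor noise SD (mm), when traces are synthesized.
#' @return a `session_log`: list with `meta` (ids, seed, mode, schema
#'   version, config snapshot), `trials` (data.frame, one row per trial,
#'   including per-trial fine-motor label columns `fm_*` and the staircased
#'   `amplitude_req_mm`), `traces` (named list of `joystick_trace` keyed by
#'   trial index, possibly empty), `licks` (named list of lick-time vectors),
#'   `laser` (named list of laser epoch data.frames).
#' @export
#' @examples
#' s <- simulate_session("m1", "s1", realize_mouse(agent_params(), 7),
#'                       n_trials = 20, seed = 42)
#' table(s$trials$outcome)
simulate_session <- function(mouse_id, session_id, params,
                             config = task_config(), n_trials = 500,
                             mode = c("inactivation", "learning"),
                             conditions = list(), seed = 1,
                             initial_delay = 0.050,
                             include_traces = FALSE, noise_sd = 0.05) {
  mode <- match.arg(mode)
  streams <- lapply(
    stats::setNames(nm = c("sequencer", "baseline", "inactivation", "agent",
                           "timeout", "trace", "stim")),
    function(nm) rng_stream(seed, nm))

  sc <- staircase_state(current_delay = initial_delay, config = config)
  trials <- vector("list", n_trials)
  traces <- list(); licks <- list(); laser <- list()
  ty_hist <- character(n_trials)
  out_hist <- character(n_trials)

  for (i in seq_len(n_trials)) {
    prev <- seq_len(i - 1L)
    ty <- next_trial_type(list(trial_type = ty_hist[prev],
                               outcome = out_hist[prev]),
                          config, streams$sequencer)
    stim_freq <- config$stim_freqs[if (ty == "push") 1L else 2L]
    baseline <- with_stream(streams$baseline,
                            stats::runif(1, config$baseline_range[1],
                                         config$baseline_range[2]))
    if (mode == "learning") {
      delay <- sc$current_delay
      amp_req <- sc$current_amplitude
      cond <- control_condition()
    } else {
      delay <- config$delay_dur_target
      amp_req <- config$amplitude_threshold
      cond <- assign_inactivation(conditions, config, streams$inactivation)
    }
    spec <- list(index = i, trial_type = ty, stim_freq = stim_freq,
                 baseline_dur = baseline, delay_dur = delay,
                 inactivation = cond)
    resp <- sample_response(ty, cond, params, spec, config, streams$agent,
                            amplitude_requirement = amp_req)
    rec <- run_trial(spec, resp, config, amplitude_requirement = amp_req,
                     timeout_stream = streams$timeout)
    rec$delay_req_s <- delay
    rec$amplitude_req_mm <- amp_req
    for (lbl in names(resp$fine_motor))
      rec[[paste0("fm_", lbl)]] <- unname(resp$fine_motor[[lbl]])
    trials[[i]] <- rec
    licks[[as.character(i)]] <- resp$lick_times
    if (include_traces) {
      traces[[as.character(i)]] <-
        synthesize_trace(resp, rec, config, noise_sd = noise_sd,
                         stream = streams$trace)
      laser[[as.character(i)]] <- schedule_laser(cond, rec, config)
    }
    if (mode == "learning") sc <- update_staircase(sc, rec$outcome, config)
    ty_hist[i] <- ty
    out_hist[i] <- rec$outcome
  }

  trials_df <- if (n_trials > 0) do.call(rbind, trials)
               else empty_trials_df(names(params$fine_motor))
  structure(
    list(meta = list(mouse_id = mouse_id, session_id = session_id,
                     date = "1970-01-01", seed = seed, mode = mode,
                     schema_version = SESSION_SCHEMA_VERSION,
                     config = unclass(config)),
         trials = trials_df,
         traces = traces, licks = licks, laser = laser),
    class = "session_log"
  )
}

empty_trials_df <- function(fm_labels = character(0)) {
  df <- data.frame(
    index = integer(0), trial_type = character(0), stim_freq_hz = numeric(0),
    baseline_dur_s = numeric(0), delay_dur_s = numeric(0),
    t_stim_on_s = numeric(0), t_go_cue_s = numeric(0),
    response_dir = character(0), t_first_move_s = numeric(0),
    t_first_lick_s = numeric(0), outcome = character(0), reward = logical(0),
    sites = character(0), period = character(0), power_mw = numeric(0),
    timeout_s = numeric(0), delay_req_s = numeric(0),
    amplitude_req_mm = numeric(0), stringsAsFactors = FALSE)
  for (lbl in fm_labels) df[[paste0("fm_", lbl)]] <- logical(0)
  df
}

SESSION_SCHEMA_VERSION <- "1.0"

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log %s/%s: %d trials (%s mode), %d traces>\n",
              x$meta$mouse_id, x$meta$session_id, nrow(x$trials),
              x$meta$mode, length(x$traces)))
  tab <- table(factor(x$trials$outcome, levels = outcome_levels()))
  print(tab)
  invisible(x)
}
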