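#' Generative behavioral parameters of the synthetic mouse
#'
#' The synthetic mouse is a parametric stand-in for the animal: per trial it
#' decides whether to abort (premature movement or anticipated lick), whether
#' to answer, in which direction, with what reaction time, movement amplitude
#' and peak speed, how it licks after reward, and which fine-motor labels a
#' video scorer would have assigned. Every probability can be modified per
#' inactivation condition through the `effect_map`.
#'
#' Control defaults are set to the published expert-performance condition
#' means: p(correct) = 0.853 (a d-prime of 2.1), p(answer) = 0.84, 5%
#' paw-prevented trials. `mouse_z_sd` and `mouse_pa_logit_sd` put
#' between-animal variability on the sensitivity (z) and answer-probability
#' (logit) scales so that cohort-level SEMs are on the scale the task
#' produces in real animals (about 0.2 d-prime units and 2-3 percentage
#' points of PA for 9 mice).
#'
#' @param p_correct control probability of a correct direction given an
#'   answer.
#' @param p_answer control probability of producing a supra-threshold answer.
#' @param p_premature probability of a supra-threshold movement before the
#'   go cue.
#' @param p_anticipated_lick probability that a trial the agent does not
#'   answer is aborted by a lick before any joystick movement.
#' @param reaction_meanlog,reaction_sdlog lognormal reaction-time parameters
#'   (s after go cue), truncated to the answer window.
#' @param amplitude_meanlog,amplitude_sdlog lognormal movement amplitude (mm),
#'   truncated to at least the amplitude criterion for answered trials.
#' @param speed_meanlog,speed_sdlog lognormal peak movement speed (mm/s).
#' @param lick_rate_reward reward-consumption lick rate (Hz).
#' @param p_subthreshold probability that a non-answered trial still contains
#'   a sub-threshold movement.
#' @param fine_motor named numeric vector of control per-trial probabilities
#'   of the video-scored labels `paw_prevented`, `slip`, `drop`,
#'   `digit_extension`.
#' @param mouse_z_sd between-mouse SD of the sensitivity offset (z scale).
#' @param mouse_pa_logit_sd between-mouse SD of the answer-probability offset
#'   (logit scale).
#' @param effect_map list of per-condition modifiers; see
#'   [default_effect_map()].
#' @return an object of class `agent_params`.
#' @export
agent_params <- function(p_correct = 0.853,
                         p_answer = 0.84,
                         p_premature = 0.03,
                         p_anticipated_lick = 0.03,
                         reaction_meanlog = log(0.25),
                         reaction_sdlog = 0.35,
                         amplitude_meanlog = log(12),
                         amplitude_sdlog = 0.12,
                         speed_meanlog = log(60),
                         speed_sdlog = 0.18,
                         lick_rate_reward = 6,
                         p_subthreshold = 0.2,
                         fine_motor = c(paw_prevented = 0.050, slip = 0.05,
                                        drop = 0.02, digit_extension = 0.02),
                         mouse_z_sd = 0.3,
                         mouse_pa_logit_sd = 0.55,
                         effect_map = default_effect_map()) {
  p <- list(p_correct = p_correct, p_answer = p_answer,
            p_premature = p_premature,
            p_anticipated_lick = p_anticipated_lick,
            reaction_meanlog = reaction_meanlog, reaction_sdlog = reaction_sdlog,
            amplitude_meanlog = amplitude_meanlog,
            amplitude_sdlog = amplitude_sdlog,
            speed_meanlog = speed_meanlog, speed_sdlog = speed_sdlog,
            lick_rate_reward = lick_rate_reward,
            p_subthreshold = p_subthreshold,
            fine_motor = fine_motor,
            mouse_z_sd = mouse_z_sd, mouse_pa_logit_sd = mouse_pa_logit_sd,
            effect_map = effect_map)
  probs <- c(p_correct, p_answer, p_premature, p_anticipated_lick,
             p_subthreshold, fine_motor)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  class(p) <- "agent_params"
  p
}

#' Default per-condition effect map
#'
#' One entry per (site set, period) inactivation condition, keyed by
#' `"<sites>:<period>"`. Entries modify the control parameters:
#' \describe{
#'   \item{dz}{additive shift of the sensitivity z = qnorm(p_correct);
#'     negative values degrade choice.}
#'   \item{pa_mult}{multiplier on p_answer.}
#'   \item{amp_mult, speed_mult}{multipliers on movement amplitude and peak
#'     speed (log scale shifts).}
#'   \item{dz_sd, pa_mult_sd}{between-mouse SDs of the realized effect,
#'     for conditions whose published SEMs exceed what baseline variability
#'     alone produces.}
#'   \item{fine_motor}{replacement label probabilities.}
#' }
#'
#' Magnitudes reproduce the published condition means: combined CFA+RFA
#' silencing drops d-prime to 0.5 (vibration period) and 0.9 (delay period);
#' answer-period silencing leaves direction choice above chance (d-prime 1.4)
#' but multiplies p_answer by 0.46 (84% -> 38.6%), 0.696 for CFA alone
#' (83.6% -> 58.2%) and 0.79 for RFA alone (-> 66%); paw-prevented
#' probabilities are 0.203 (CFA), 0.089 (RFA) versus 0.05 in control.
#' Delay-period PA multipliers reflect the published (null) ratios.
#'
#' @return a named list of effect entries.
#' @export
default_effect_map <- function() {
  z0 <- stats::qnorm(0.853)
  zt <- function(p) stats::qnorm(p) - z0   # dz needed to reach target p
  list(
    "CFA+RFA:vibration" = list(dz = zt(0.5987), pa_mult = 1),
    "CFA+RFA:delay"     = list(dz = zt(0.6736), pa_mult = 86.4 / 84),
    "CFA+RFA:answer"    = list(dz = zt(0.758), dz_sd = 0.35,
                               pa_mult = 0.46, pa_mult_sd = 0.15,
                               amp_mult = 0.8, speed_mult = 0.8),
    "CFA:vibration"     = list(dz = -0.55, pa_mult = 1),
    "CFA:delay"         = list(dz = -0.12, pa_mult = 86.1 / 84),
    "CFA:answer"        = list(dz = 0, pa_mult = 58.2 / 83.6, pa_mult_sd = 0.2,
                               amp_mult = 0.9, speed_mult = 0.9,
                               fine_motor = c(paw_prevented = 0.203,
                                              slip = 0.25, drop = 0.10,
                                              digit_extension = 0.10)),
    "RFA:vibration"     = list(dz = -0.35, pa_mult = 1),
    "RFA:delay"         = list(dz = -0.10, pa_mult = 83.5 / 84),
    "RFA:answer"        = list(dz = 0, pa_mult = 66.0 / 83.6, pa_mult_sd = 0.2,
                               fine_motor = c(paw_prevented = 0.089,
                                              slip = 0.07, drop = 0.03,
                                              digit_extension = 0.03)),
    "ACC:vibration" = list(), "ACC:delay" = list(),
    "PPC:vibration" = list(), "PPC:delay" = list(), "PPC:answer" = list(),
    "BCx:vibration" = list(), "BCx:delay" = list(), "BCx:answer" = list()
  )
}

effect_key <- function(condition) {
  paste0(condition_label(condition), ":", condition$period)
}

#' Realize one mouse from population-level agent parameters
#'
#' Draws the mouse's sensitivity and answer-probability offsets and, per
#' effect-map entry, the realized condition effects. Each entry's draws use
#' an RNG substream keyed by the entry name, so editing one condition's
#' parameters never perturbs draws for any other condition.
#'
#' @param params an [agent_params()].
#' @param seed integer seed identifying the mouse.
#' @return an `agent_params` with added fields `mouse_z`, `mouse_pa_logit`
#'   and realized `effect_map` entries (`dz`, `pa_mult` collapsed to the
#'   drawn per-mouse values).
#' @export
realize_mouse <- function(params, seed) {
  stopifnot(inherits(params, "agent_params"))
  s <- rng_stream(seed, "mouse")
  params$mouse_z <- with_stream(s, stats::rnorm(1, 0, params$mouse_z_sd))
  params$mouse_pa_logit <- with_stream(
    s, stats::rnorm(1, 0, params$mouse_pa_logit_sd))
  params$effect_map <- lapply(
    stats::setNames(names(params$effect_map), names(params$effect_map)),
    function(key) {
      e <- params$effect_map[[key]]
      es <- rng_stream(seed, paste0("effect:", key))
      if (!is.null(e$dz_sd))
        e$dz <- with_stream(es, stats::rnorm(1, e$dz, e$dz_sd))
      if (!is.null(e$pa_mult_sd))
        e$pa_mult <- with_stream(
          es, max(0.05, stats::rnorm(1, e$pa_mult, e$pa_mult_sd)))
      e
    })
  params$realized <- TRUE
  params
}

#' Effective per-condition parameters for one mouse
#'
#' Applies the mouse offsets and the (realized) effect-map entry for the
#' given condition to the control parameters.
#'
#' @param params an [agent_params()], usually from [realize_mouse()].
#' @param condition an [inactivation_condition()].
#' @return a list with the effective `p_correct`, `p_answer`,
#'   `amplitude_meanlog`, `speed_meanlog`, `fine_motor` and the unchanged
#'   remaining fields.
#' @export
condition_params <- function(params, condition = control_condition()) {
  mz <- if (is.null(params$mouse_z)) 0 else params$mouse_z
  mpa <- if (is.null(params$mouse_pa_logit)) 0 else params$mouse_pa_logit
  eff <- list()
  if (!is_control(condition)) {
    eff <- params$effect_map[[effect_key(condition)]]
    if (is.null(eff)) eff <- list()
  }
  dz <- if (is.null(eff$dz)) 0 else eff$dz
  pa_mult <- if (is.null(eff$pa_mult)) 1 else eff$pa_mult
  amp_mult <- if (is.null(eff$amp_mult)) 1 else eff$amp_mult
  speed_mult <- if (is.null(eff$speed_mult)) 1 else eff$speed_mult
  out <- params
  out$p_correct <- stats::pnorm(stats::qnorm(params$p_correct) + mz + dz)
  out$p_answer <- min(1, stats::plogis(stats::qlogis(params$p_answer) + mpa) *
                        pa_mult)
  out$amplitude_meanlog <- params$amplitude_meanlog + log(amp_mult)
  out$speed_meanlog <- params$speed_meanlog + log(speed_mult)
  if (!is.null(eff$fine_motor)) out$fine_motor <- eff$fine_motor
  unclass(out)
}

#' Sample one agent response
#'
#' Draws the synthetic mouse's behavior on one trial: abort events, answer
#' and direction, reaction time (lognormal truncated to the answer window),
#' movement amplitude and peak speed (jointly feasible inside the answer
#' window), reward-consumption licks (Poisson train), and fine-motor labels
#' (independent Bernoulli draws given the condition).
#'
#' @param trial_type `"push"` or `"pull"`.
#' @param condition an [inactivation_condition()].
#' @param params an [agent_params()] (population or mouse-realized).
#' @param spec trial timing list with `baseline_dur` and `delay_dur` (s).
#' @param config a [task_config()].
#' @param stream an [rng_stream()].
#' @param amplitude_requirement supra-threshold criterion for this trial (mm).
#' @return an agent-response list as consumed by [run_trial()], with the
#'   drawn `amplitude` signed by convention (push positive, pull negative)
#'   in `amplitude_signed` and unsigned in `amplitude`.
#' @export
sample_response <- function(trial_type, condition, params, spec,
                            config = task_config(), stream,
                            amplitude_requirement = config$amplitude_threshold) {
  cp <- condition_params(params, condition)
  t_go <- spec$baseline_dur + config$vibration_dur + spec$delay_dur
  with_stream(stream, {
    resp <- list(move_time = NA_real_, direction = "none", amplitude = 0,
                 peak_speed = 0, lick_times = numeric(0),
                 timeout_restarts = 0L)
    u <- stats::runif(3)
    if (u[1] < cp$p_premature) {
      # supra-threshold movement before the go cue
      resp$direction <- sample(c("push", "pull"), 1L)
      resp$amplitude <- rlnorm_min(1, cp$amplitude_meanlog, cp$amplitude_sdlog,
                                   amplitude_requirement)
      resp$peak_speed <- stats::rlnorm(1, cp$speed_meanlog, cp$speed_sdlog)
      resp$move_time <- stats::runif(1, spec$baseline_dur, t_go)
    } else if (u[3] < cp$p_answer) {
      correct <- stats::runif(1) < cp$p_correct
      resp$direction <- if (correct) trial_type
                        else setdiff(c("push", "pull"), trial_type)
      resp$amplitude <- rlnorm_min(1, cp$amplitude_meanlog, cp$amplitude_sdlog,
                                   amplitude_requirement)
      resp$peak_speed <- stats::rlnorm(1, cp$speed_meanlog, cp$speed_sdlog)
      # movement duration implied by the minimum-jerk profile
      t_move <- 15 * resp$amplitude / (8 * resp$peak_speed)
      if (t_move > config$answer_dur - 0.02) {
        t_move <- config$answer_dur - 0.02
        resp$peak_speed <- 15 * resp$amplitude / (8 * t_move)
      }
      rt_max <- config$answer_dur - t_move - 0.01
      rt <- stats::rlnorm(1, cp$reaction_meanlog, cp$reaction_sdlog)
      rt <- min(max(rt, 0.02), rt_max)
      resp$move_time <- t_go + rt
      # reward-consumption licks
      t_rw <- resp$move_time + t_move
      first <- t_rw + stats::runif(1, 0.05, 0.15)
      n <- stats::rpois(1, cp$lick_rate_reward * 1.0)
      resp$lick_times <- sort(c(first, first + stats::runif(n, 0, 1)))
    } else if (u[2] < cp$p_anticipated_lick) {
      # a non-answered trial aborted by an early lick, around the go cue;
      # conditioning on not answering keeps the long-run answered fraction
      # equal to p_answer (premature and anticipated trials are outside the
      # proportion-answered denominator / excluded, respectively)
      resp$lick_times <- t_go + stats::runif(1, -0.2, 0.2)
    } else if (stats::runif(1) < cp$p_subthreshold) {
      # sub-threshold fidgeting: ignored by the classifier
      resp$direction <- sample(c("push", "pull"), 1L)
      resp$amplitude <- stats::runif(1, 0, 0.9 * amplitude_requirement)
      resp$peak_speed <- stats::rlnorm(1, cp$speed_meanlog, cp$speed_sdlog)
      resp$move_time <- t_go + stats::runif(1, 0, config$answer_dur)
    }
    fm <- cp$fine_motor
    resp$fine_motor <- stats::setNames(stats::runif(length(fm)) < fm, names(fm))
    resp$amplitude_signed <- if (resp$direction == "pull") -resp$amplitude
                             else resp$amplitude
    resp
  })
}

# lognormal truncated below at `lo` by redraw (falls back to lo after 50 tries)
rlnorm_min <- function(n, meanlog, sdlog, lo) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  for (i in seq_len(50)) {
    bad <- x < lo
    if (!any(bad)) break
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
  pmax(x, lo)
}

#' Minimum-jerk position profile
#'
#' Position along a minimum-jerk reach of amplitude `A` and duration `T`:
#' `x(t) = A (10 s^3 - 15 s^4 + 6 s^5)` with `s = t/T`. Its peak velocity is
#' `15 A / (8 T)` at the midpoint.
#'
#' @param t time from movement onset (s), vectorized.
#' @param A amplitude (signed, mm).
#' @param T_move movement duration (s).
#' @return positions (mm); `0` before onset, `A` after `T_move`.
#' @export
minimum_jerk <- function(t, A, T_move) {
  s <- pmin(pmax(t / T_move, 0), 1)
  A * (10 * s^3 - 15 * s^4 + 6 * s^5)
}

#' Synthesize a 5 kHz joystick trace for one trial
#'
#' Emits a smooth minimum-jerk excursion whose peak position equals the drawn
#' amplitude and whose peak velocity equals the drawn peak speed, plus
#' additive Gaussian sensor noise, and a small vibrotactile ripple at the
#' stimulus frequency confined to the stimulus window. Baseline mean is 0;
#' sign convention is push positive, pull negative.
#'
#' @param response an agent response from [sample_response()].
#' @param trial one-row trial record from [run_trial()] (needs
#'   `baseline_dur_s`, `delay_dur_s`, `stim_freq_hz`, `t_go_cue_s`).
#' @param config a [task_config()].
#' @param noise_sd sensor noise SD (mm).
#' @param ripple_mm amplitude of the vibrotactile ripple (mm).
#' @param stream an [rng_stream()], required when `noise_sd > 0`.
#' @param post_dur recording time after the answer window (s).
#' @return a `joystick_trace`: list with `sample_rate`, `t0` (s, = 0, trial
#'   start), and `positions` (mm).
#' @export
synthesize_trace <- function(response, trial, config = task_config(),
                             noise_sd = 0.05, ripple_mm = 0.2,
                             stream = NULL, post_dur = 0.5) {
  fs <- config$sample_rate
  dur <- trial$t_go_cue_s + config$answer_dur + post_dur
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  pos <- numeric(n)
  if (!is.na(response$move_time) && abs(response$amplitude) > 0) {
    A <- response$amplitude_signed
    if (is.null(A)) A <- response$amplitude
    T_move <- 15 * abs(A) / (8 * response$peak_speed)
    if (response$move_time >= trial$t_go_cue_s &&
        response$move_time + T_move > trial$t_go_cue_s + config$answer_dur)
      stop("amplitude/speed pair infeasible within the answer window")
    pos <- minimum_jerk(tt - response$move_time, A, T_move)
  }
  stim_on <- trial$baseline_dur_s
  stim_off <- stim_on + config$vibration_dur
  in_stim <- tt >= stim_on & tt < stim_off
  pos[in_stim] <- pos[in_stim] +
    ripple_mm * sin(2 * pi * trial$stim_freq_hz * (tt[in_stim] - stim_on))
  if (noise_sd > 0) {
    if (is.null(stream)) stop("stream required when noise_sd > 0")
    pos <- pos + with_stream(stream, stats::rnorm(n, 0, noise_sd))
  }
  structure(list(sample_rate = fs, t0 = 0, positions = pos),
            class = "joystick_trace")
}

#' @export
print.joystick_trace <- function(x, ...) {
  cat(sprintf("<joystick_trace: %d samples @ %g Hz (%.3f s), range [%.2f, %.2f] mm>\n",
              length(x$positions), x$sample_rate,
              length(x$positions) / x$sample_rate,
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' Laser epoch schedule for an inactivation trial
#'
#' Epochs exactly span the condition's trial period. A single site gets one
#' continuous epoch at `power_per_site`; two sites are illuminated on
#' alternating half-cycles of a 40 Hz alternation (the beam is blanked while
#' displaced between targets), so each site's total illumination is half the
#' period duration.
#'
#' @param condition an [inactivation_condition()] with `period != "none"`.
#' @param trial one-row trial record (needs `baseline_dur_s`, `delay_dur_s`,
#'   `t_go_cue_s`).
#' @param config a [task_config()].
#' @param alternation_hz dual-site site-switching frequency (Hz).
#' @return a data.frame of epochs: `site`, `t_on_s`, `t_off_s`, `power_mw`,
#'   `alternation_hz` (NA for single site). Zero rows for control trials.
#' @export
schedule_laser <- function(condition, trial, config = task_config(),
                           alternation_hz = 40) {
  empty <- data.frame(site = character(0), t_on_s = numeric(0),
                      t_off_s = numeric(0), power_mw = numeric(0),
                      alternation_hz = numeric(0), stringsAsFactors = FALSE)
  if (is_control(condition)) return(empty)
  stim_on <- trial$baseline_dur_s
  window <- switch(condition$period,
    vibration = c(stim_on, stim_on + config$vibration_dur),
    delay = c(stim_on + config$vibration_dur, trial$t_go_cue_s),
    answer = c(trial$t_go_cue_s, trial$t_go_cue_s + config$answer_dur),
    stop("unknown inactivation period: ", condition$period)
  )
  sites <- condition$sites
  if (length(sites) == 1L) {
    return(data.frame(site = sites, t_on_s = window[1], t_off_s = window[2],
                      power_mw = condition$power_per_site,
                      alternation_hz = NA_real_, stringsAsFactors = FALSE))
  }
  if (length(sites) != 2L) stop("dual-site scheduling supports two sites")
  half <- 1 / (2 * alternation_hz)
  t_on <- seq(window[1], window[2] - 1e-12, by = half)
  t_off <- pmin(t_on + half, window[2])
  site <- rep(sites, length.out = length(t_on))
  data.frame(site = site, t_on_s = t_on, t_off_s = t_off,
             power_mw = condition$power_per_site,
             alternation_hz = alternation_hz, stringsAsFactors = FALSE)
}
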