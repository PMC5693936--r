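# shared fixtures, built in code

# trial spec at final task parameters (go cue at 3 s)
make_spec <- function(trial_type = "pull", baseline = 1, delay = 1,
                      index = 1L, inactivation = NULL) {
  list(index = index, trial_type = trial_type,
       stim_freq = if (trial_type == "push") 10 else 40,
       baseline_dur = baseline, delay_dur = delay,
       inactivation = inactivation)
}

# deterministic agent response helper
make_response <- function(move_time = NA_real_, direction = "none",
                          amplitude = 0, peak_speed = 60,
                          lick_times = numeric(0), timeout_restarts = 0L) {
  list(move_time = move_time, direction = direction, amplitude = amplitude,
       amplitude_signed = if (direction == "pull") -amplitude else amplitude,
       peak_speed = peak_speed, lick_times = lick_times,
       timeout_restarts = timeout_restarts,
       fine_motor = c(paw_prevented = FALSE, slip = FALSE, drop = FALSE,
                      digit_extension = FALSE))
}

# history builder: types/outcomes as parallel vectors
make_history <- function(types, outcomes) {
  data.frame(trial_type = types, outcome = outcomes, stringsAsFactors = FALSE)
}

# noiseless minimum-jerk trace for kinematics oracles
make_mj_trace <- function(amplitude, T_move, onset_after_go = 0.2,
                          go_time = 3, fs = 5000, total = 4.5) {
  tt <- (seq_len(round(total * fs)) - 1) / fs
  pos <- minimum_jerk(tt - (go_time + onset_after_go), amplitude, T_move)
  structure(list(sample_rate = fs, t0 = 0, positions = pos),
            class = "joystick_trace")
}

# independent Kruskal-Wallis H from the textbook rank formula (no ties)
kw_h_oracle <- function(values, group) {
  r <- rank(values)
  N <- length(values)
  tapply_sum <- tapply(r, group, sum)
  n_i <- tapply(r, group, length)
  12 / (N * (N + 1)) * sum(tapply_sum^2 / n_i) - 3 * (N + 1)
}
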