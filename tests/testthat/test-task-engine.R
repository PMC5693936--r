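test_that("sequencer switches after a run of three identical types", {
  cfg <- task_config()
  s <- rng_stream(1, "seq")
  h <- make_history(rep("push", 3), rep("correct", 3))
  expect_identical(next_trial_type(h, cfg, s), "pull")
  h2 <- make_history(rep("pull", 3), rep("correct", 3))
  expect_identical(next_trial_type(h2, cfg, s), "push")
})

test_that("sequencer draws uniformly on an empty or short history", {
  cfg <- task_config()
  s <- rng_stream(7, "seq")
  draws <- replicate(200, next_trial_type(make_history(character(0),
                                                       character(0)), cfg, s))
  expect_true(all(draws %in% c("push", "pull")))
  expect_gt(mean(draws == "push"), 0.35)  # binomial(200, .5) 3 SE band
  expect_lt(mean(draws == "push"), 0.65)
})

test_that("failure-repeat rule repeats a poorly answered type", {
  cfg <- task_config(repeat_rule_threshold = 6)
  s <- rng_stream(1, "seq")
  # last 9 pull trials contain 7 incorrect; interleave pushes so the run
  # rule cannot mask the repeat rule
  types <- c(rbind(rep("pull", 9), rep("push", 9)))
  outcomes <- c(rbind(c(rep("incorrect", 7), "correct", "correct"),
                      rep("correct", 9)))
  h <- make_history(types, outcomes)
  expect_identical(next_trial_type(h, cfg, s), "pull")
  # at exactly the threshold (6 of 9) the rule must NOT fire
  outcomes2 <- c(rbind(c(rep("incorrect", 6), rep("correct", 3)),
                       rep("correct", 9)))
  h2 <- make_history(types, outcomes2)
  # last 3 trials end ...pull,push -> no run either; draw is free
  expect_true(next_trial_type(h2, cfg, s) %in% c("push", "pull"))
})

test_that("sequencer never emits four identical consecutive types", {
  cfg <- task_config()
  s <- rng_stream(11, "seq")
  n <- 2000
  ty <- character(n)
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1)
    ty[i] <- next_trial_type(list(trial_type = ty[prev],
                                  outcome = rep("correct", i - 1)), cfg, s)
  }
  expect_lte(max(rle(ty)$lengths), 3)
})

test_that("sequencer matches a brute-force rule evaluator on random histories", {
  cfg <- task_config()
  s <- rng_stream(5, "seq")
  gen <- rng_stream(6, "gen")
  brute_forced_type <- function(h) {
    # independent re-statement of the deterministic branches
    n <- length(h$trial_type)
    for (ty in c("push", "pull")) {
      idx <- utils::tail(which(h$trial_type == ty), 9)
      if (length(idx) && sum(h$outcome[idx] != "correct") > 5) return(ty)
    }
    if (n >= 3 && length(unique(h$trial_type[(n - 2):n])) == 1)
      return(setdiff(c("push", "pull"), h$trial_type[n]))
    NA_character_  # free draw
  }
  for (rep in 1:300) {
    len <- with_stream(gen, sample(0:12, 1))
    h <- make_history(
      with_stream(gen, sample(c("push", "pull"), len, replace = TRUE)),
      with_stream(gen, sample(outcome_levels(), len, replace = TRUE)))
    want <- brute_forced_type(h)
    got <- next_trial_type(h, cfg, s)
    if (!is.na(want)) expect_identical(got, want)
    else expect_true(got %in% c("push", "pull"))
  }
})

test_that("trial outcomes follow event precedence", {
  cfg <- task_config()
  spec <- make_spec("pull")  # go cue at 3 s
  # supra-threshold pull at go + 0.3 s on a pull trial -> correct + reward
  r <- run_trial(spec, make_response(3.3, "pull", 12), cfg)
  expect_identical(r$outcome, "correct")
  expect_true(r$reward)
  expect_true(is.na(r$timeout_s))
  # opposite direction -> incorrect, with a timeout
  r2 <- run_trial(spec, make_response(3.3, "push", 12), cfg)
  expect_identical(r2$outcome, "incorrect")
  expect_false(r2$reward)
  expect_false(is.na(r2$timeout_s))
  # lick at go + 0.1 before movement at go + 0.4 -> anticipated lick
  r3 <- run_trial(spec, make_response(3.4, "pull", 12, lick_times = 3.1), cfg)
  expect_identical(r3$outcome, "anticipated_lick")
  # peak excursion 9 mm under a 10 mm criterion -> ignored, no movement
  r4 <- run_trial(spec, make_response(3.3, "pull", 9), cfg)
  expect_identical(r4$outcome, "no_movement")
  # supra-threshold movement before the go cue -> premature
  r5 <- run_trial(spec, make_response(2.5, "pull", 12), cfg)
  expect_identical(r5$outcome, "premature_move")
  # premature movement earlier than a lick wins
  r6 <- run_trial(spec, make_response(2.5, "pull", 12, lick_times = 2.8), cfg)
  expect_identical(r6$outcome, "premature_move")
  # negative event times are rejected
  expect_error(run_trial(spec, make_response(-1, "pull", 12), cfg),
               "negative")
})

test_that("outcome classes are mutually exclusive and exhaustive", {
  cfg <- task_config()
  gen <- rng_stream(3, "gen")
  outs <- character(200)
  for (i in 1:200) {
    resp <- with_stream(gen, make_response(
      move_time = if (runif(1) < 0.8) runif(1, 0, 4.5) else NA_real_,
      direction = sample(c("push", "pull"), 1),
      amplitude = runif(1, 0, 15),
      lick_times = if (runif(1) < 0.5) sort(runif(2, 0, 4.5)) else numeric(0)))
    outs[i] <- run_trial(make_spec("push"), resp, cfg)$outcome
  }
  expect_true(all(outs %in% outcome_levels()))
  expect_identical(sum(table(factor(outs, outcome_levels()))), 200L)
})

test_that("timeout is drawn from the configured range and accumulates restarts", {
  cfg <- task_config()
  s <- rng_stream(2, "timeout")
  r <- run_trial(make_spec("pull"), make_response(3.3, "push", 12), cfg,
                 timeout_stream = s)
  expect_gte(r$timeout_s, 1)
  expect_lte(r$timeout_s, 3)
  r2 <- run_trial(make_spec("pull"),
                  make_response(3.3, "push", 12, timeout_restarts = 2L), cfg,
                  timeout_stream = s)
  expect_gte(r2$timeout_s, 3)   # three uniform(1,3) draws
  expect_lte(r2$timeout_s, 9)
})

test_that("run_trial is reproducible given seed and agent response", {
  cfg <- task_config()
  resp <- make_response(3.3, "push", 12)
  r1 <- run_trial(make_spec("pull"), resp, cfg,
                  timeout_stream = rng_stream(9, "t"))
  r2 <- run_trial(make_spec("pull"), resp, cfg,
                  timeout_stream = rng_stream(9, "t"))
  expect_identical(r1, r2)
})

test_that("staircase lengthens the delay by 50 ms per correct up to 1 s", {
  cfg <- task_config()
  st <- staircase_state(0.050, config = cfg)
  st <- update_staircase(st, "correct", cfg)
  expect_equal(st$current_delay, 0.100)
  st2 <- staircase_state(1.000, config = cfg)
  expect_equal(update_staircase(st2, "correct", cfg)$current_delay, 1.000)
  st3 <- staircase_state(0.500, config = cfg)
  for (o in c("incorrect", "no_movement", "anticipated_lick",
              "premature_move"))
    expect_equal(update_staircase(st3, o, cfg)$current_delay, 0.500)
})

test_that("staircase is monotone within a session and amplitude caps", {
  cfg <- task_config()
  st <- staircase_state(config = cfg)
  gen <- rng_stream(4, "gen")
  delays <- numeric(50)
  for (i in 1:50) {
    o <- with_stream(gen, sample(c("correct", "incorrect"), 1))
    st <- update_staircase(st, o, cfg)
    delays[i] <- st$current_delay
  }
  expect_true(all(diff(delays) >= 0))
  expect_true(all(delays <= cfg$staircase_cap))
  expect_lte(st$current_amplitude, cfg$amplitude_threshold)
})

test_that("delay carry-over is the clipped mean of the previous session", {
  expect_equal(carry_over_delay(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(carry_over_delay(rep(1.0, 20)), 1.0)
  expect_equal(carry_over_delay(c(1.2, 1.4)), 1.0)   # clipped to the cap
  expect_equal(carry_over_delay(numeric(0)), 0.050)  # first-session default
})

test_that("inactivation assignment matches the configured fraction and set", {
  cfg <- task_config(inactivation_fraction = 1 / 3)
  s <- rng_stream(13, "inact")
  conds <- list(inactivation_condition(c("CFA", "RFA"), "answer", 3))
  n <- 9000
  assigned <- vapply(seq_len(n), function(i) {
    cond <- assign_inactivation(conds, cfg, s)
    if (is_control(cond)) return(FALSE)
    expect_identical(sort(cond$sites), c("CFA", "RFA"))
    expect_equal(cond$power_per_site, 3)
    TRUE
  }, logical(1))
  ci <- qbinom(c(0.005, 0.995), n, 1 / 3)
  expect_gte(sum(assigned), ci[1])
  expect_lte(sum(assigned), ci[2])
  cfg0 <- task_config(inactivation_fraction = 0)
  expect_true(all(replicate(50, is_control(assign_inactivation(conds, cfg0, s)))))
})

test_that("task_config validates its invariants", {
  expect_error(task_config(repeat_rule_threshold = 7), "repeat_rule_threshold")
  expect_error(task_config(amplitude_start = 11), "amplitude_start")
  expect_error(task_config(inactivation_fraction = 1.2), "inactivation_fraction")
  expect_error(task_config(vibration_dur = -1), "durations")
  expect_error(inactivation_condition("CFA", "none"), "if and only if")
  expect_error(inactivation_condition(character(0), "delay"), "if and only if")
})

test_that("task_config round-trips through YAML", {
  cfg <- task_config(repeat_rule_threshold = 4, inactivation_fraction = 0.4)
  f <- tempfile(fileext = ".yaml")
  write_task_config(cfg, f)
  cfg2 <- read_task_config(f)
  expect_equal(cfg2, cfg)
})
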