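test_that("edge exclusion removes through the 5th and from the 5th-last correct", {
  # 20 trials, correct at known positions
  out <- rep("incorrect", 20)
  correct_at <- c(1, 2, 3, 4, 5, 8, 10, 12, 15, 16, 17, 18, 19, 20)
  out[correct_at] <- "correct"
  trials <- data.frame(index = 1:20, trial_type = "push", outcome = out,
                       stringsAsFactors = FALSE)
  kept <- exclude_trials(trials, mode = "learning")
  # 5th correct is trial 5; 5th-from-last correct is trial 16
  expect_identical(kept$index, 6:15)
  expect_identical(attr(kept, "n_excluded"), 10L)

  # when the first five correct trials are trials 1-5 they are all removed
  expect_false(any(kept$index <= 5))

  # inactivation mode additionally drops premature trials
  out2 <- out
  out2[9] <- "premature_move"
  trials2 <- data.frame(index = 1:20, trial_type = "push", outcome = out2,
                        stringsAsFactors = FALSE)
  kept2 <- exclude_trials(trials2, mode = "inactivation")
  expect_identical(kept2$index, setdiff(6:15, 9L))
  # with no premature trials both modes agree
  expect_identical(exclude_trials(trials, mode = "inactivation")$index,
                   kept$index)
})

test_that("sessions with fewer than 10 correct trials are emptied with a flag", {
  trials <- data.frame(index = 1:8, trial_type = "push",
                       outcome = rep(c("correct", "incorrect"), 4),
                       stringsAsFactors = FALSE)
  expect_warning(kept <- exclude_trials(trials), "correct")
  expect_identical(nrow(kept), 0L)
  expect_identical(attr(kept, "warning_flag"), "too_few_correct")
})

test_that("exclusion keeps a contiguous block and never relabels outcomes", {
  p <- realize_mouse(agent_params(), 2)
  s <- simulate_session("m", "s", p, n_trials = 200, seed = 8)
  kept <- exclude_trials(s$trials, mode = "learning")
  expect_identical(kept$index, seq(min(kept$index), max(kept$index)))
  expect_identical(kept$outcome,
                   s$trials$outcome[s$trials$index %in% kept$index])
})

test_that("clamped d-prime reproduces its printed extreme and analytic values", {
  expect_equal(round(dprime(1, 1), 2), 4.65)
  expect_equal(dprime(0, 0), -dprime(1, 1))
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(dprime(0, 1), 0)               # antisymmetric clamping
  expect_equal(dprime(0.8531, 0.8531), 2.10, tolerance = 0.01)
  # the alternative printed rounding is available by configuration
  expect_equal(dprime(1, 1, clamp = c(0.001, 0.999)), 2 * qnorm(0.999))
})

test_that("d-prime is monotone, antisymmetric and bounded", {
  ps <- seq(0.02, 0.98, by = 0.04)
  d <- vapply(ps, function(p) dprime(p, 0.5), 1)
  expect_true(all(diff(d) > 0))
  for (p in c(0.2, 0.5, 0.77)) for (q in c(0.3, 0.9))
    expect_equal(dprime(p, q), -dprime(1 - p, 1 - q))
  grid <- expand.grid(p = c(0, 0.01, 0.5, 1), q = c(0, 0.33, 1))
  dd <- mapply(dprime, grid$p, grid$q)
  expect_true(all(abs(dd) <= 2 * qnorm(0.99) + 1e-12))
})

test_that("proportion answered and bias follow their definitions", {
  trials <- data.frame(
    trial_type = rep(c("push", "pull"), each = 50),
    outcome = c(rep("correct", 25), rep("incorrect", 10), rep("no_movement", 10),
                rep("anticipated_lick", 5),
                rep("correct", 25), rep("incorrect", 10), rep("no_movement", 10),
                rep("anticipated_lick", 5)),
    stringsAsFactors = FALSE)
  ct <- outcome_counts(trials)
  expect_equal(proportion_answered(ct), 70 / 100)
  expect_equal(bias_score(ct), 0)
  all_corr <- data.frame(trial_type = c("push", "pull"),
                         outcome = "correct", stringsAsFactors = FALSE)
  expect_equal(proportion_answered(outcome_counts(all_corr)), 1.0)
  # push 80% vs pull 70% correct -> bias +10
  tr2 <- data.frame(
    trial_type = c(rep("push", 10), rep("pull", 10)),
    outcome = c(rep("correct", 8), rep("incorrect", 2),
                rep("correct", 7), rep("incorrect", 3)),
    stringsAsFactors = FALSE)
  expect_equal(bias_score(outcome_counts(tr2)), 10)
  # zero answered trials of a type -> absent values
  tr3 <- data.frame(trial_type = c("push", "pull"),
                    outcome = c("correct", "no_movement"),
                    stringsAsFactors = FALSE)
  expect_true(is.na(bias_score(outcome_counts(tr3))))
  expect_true(is.na(dprime_counts(outcome_counts(tr3))))
})

test_that("simulated answered fraction and bias match the generator", {
  p <- agent_params(p_premature = 0, mouse_z_sd = 0, mouse_pa_logit_sd = 0)
  s <- simulate_session("m", "s", p, n_trials = 5000, seed = 29)
  ct <- outcome_counts(s$trials)
  pa <- proportion_answered(ct)
  se <- sqrt(0.84 * 0.16 / sum(ct))
  expect_lt(abs(pa - 0.84), 3 * se)
  # symmetric generator: bias within 3 binomial SEs of zero (pp units)
  n_ans <- sum(ct[, c("correct", "incorrect")])
  se_bias <- 100 * sqrt(2 * 0.853 * 0.147 / (n_ans / 2))
  expect_lt(abs(bias_score(ct)), 3 * se_bias)
})

test_that("lick rate counts events in the window", {
  expect_equal(lick_rate(seq(0.1, 0.7, by = 0.1), c(0, 1))$rate_hz, 7)
  empty <- lick_rate(numeric(0), c(0, 1))
  expect_equal(empty$rate_hz, 0)
  expect_true(is.na(empty$latency_s))
  expect_equal(lick_rate(c(0.25, 0.5), c(0.2, 1.2))$latency_s, 0.05)
  # Poisson generator at 6 Hz: mean rate within 3 SE over 1000 windows
  s <- rng_stream(3, "licks")
  rates <- replicate(1000, {
    n <- with_stream(s, rpois(1, 6))
    lick_rate(with_stream(s, sort(runif(n))), c(0, 1))$rate_hz
  })
  expect_lt(abs(mean(rates) - 6), 3 * sqrt(6 / 1000))
})

test_that("fine-motor proportions are computed per condition with SEs", {
  trials <- data.frame(
    sites = rep(c("", "CFA"), each = 200),
    period = rep(c("none", "answer"), each = 200),
    fm_slip = c(rep(FALSE, 200), rep(c(TRUE, FALSE), c(50, 150))),
    fm_drop = FALSE,
    stringsAsFactors = FALSE)
  fp <- fine_motor_proportions(trials)
  cfa_slip <- fp[fp$condition == "CFA:answer" & fp$label == "slip", ]
  expect_equal(cfa_slip$proportion, 0.25)
  expect_equal(cfa_slip$se, sqrt(0.25 * 0.75 / 200))
  expect_equal(fp[fp$condition == ":none" & fp$label == "slip", ]$proportion, 0)
  expect_equal(fp[fp$label == "drop", ]$proportion, c(0, 0))
  # absent condition yields no row
  expect_false("RFA:answer" %in% fp$condition)
})

test_that("per-condition summaries conserve trial counts", {
  p <- realize_mouse(agent_params(), 4)
  conds <- list(inactivation_condition("CFA", "answer"),
                inactivation_condition("RFA", "answer"))
  s <- simulate_session("m", "s", p, n_trials = 400, seed = 31,
                        conditions = conds)
  summ <- summarize_performance(s, mode = "inactivation")
  kept <- exclude_trials(s$trials, mode = "inactivation")
  expect_equal(sum(summ$n_trials), nrow(kept))
  count_cols <- c("n_correct", "n_incorrect", "n_no_movement",
                  "n_anticipated_lick", "n_premature_move")
  expect_equal(sum(unlist(summ[, count_cols])), nrow(kept))
})
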