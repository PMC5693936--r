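#' Session exclusion rules
#'
#' Removes the unstable periods at the session edges: all trials up to and
#' including the 5th correct trial, and all trials from the 5th-from-last
#' correct trial onward. In `"inactivation"` mode, trials with premature
#' movements (supra-threshold crossing before the go cue) are additionally
#' removed. The surviving trials are a contiguous-in-time subset; outcome
#' labels are never altered.
#'
#' @param session a `session_log` (or a plain trial data.frame).
#' @param mode `"learning"` or `"inactivation"`.
#' @param n_edge number of edge correct trials defining the cut (5).
#' @return the session (or data.frame) with excluded trials dropped; if
#'   fewer than `2 * n_edge` correct trials exist, an empty result with
#'   attribute `warning_flag = "too_few_correct"` and a warning.
#' @export
exclude_trials <- function(session, mode = c("learning", "inactivation"),
                           n_edge = 5L) {
  mode <- match.arg(mode)
  is_log <- inherits(session, "session_log")
  trials <- if (is_log) session$trials else session
  corr <- which(trials$outcome == "correct")
  if (length(corr) < 2L * n_edge) {
    warning("fewer than ", 2L * n_edge,
            " correct trials; all trials excluded")
    keep <- logical(nrow(trials))
    flag <- "too_few_correct"
  } else {
    lo <- corr[n_edge]                      # 5th correct trial
    hi <- corr[length(corr) - n_edge + 1L]  # 5th-from-last correct trial
    keep <- seq_len(nrow(trials)) > lo & seq_len(nrow(trials)) < hi
    flag <- NULL
  }
  if (mode == "inactivation") keep <- keep & trials$outcome != "premature_move"
  kept <- trials[keep, , drop = FALSE]
  attr(kept, "n_excluded") <- nrow(trials) - nrow(kept)
  if (!is.null(flag)) attr(kept, "warning_flag") <- flag
  if (is_log) {
    session$trials <- kept
    idx <- as.character(kept$index)
    session$traces <- session$traces[names(session$traces) %in% idx]
    session$licks <- session$licks[names(session$licks) %in% idx]
    session$laser <- session$laser[names(session$laser) %in% idx]
    session
  } else kept
}

#' Outcome counts per trial type
#'
#' @param trials a trial data.frame (post-exclusion).
#' @return a 2 x 5 table (push/pull by outcome class).
#' @export
outcome_counts <- function(trials) {
  table(factor(trials$trial_type, levels = c("push", "pull")),
        factor(trials$outcome, levels = outcome_levels()))
}

#' Signal-detection sensitivity (d-prime) with rate clamping
#'
#' `d' = z(correct pull rate) + z(correct push rate)`, `z` the standard
#' normal inverse CDF. Rates are clamped to `clamp` before the transform so
#' rates of 0 or 1 cannot produce infinities; with the default clamp of
#' (0.01, 0.99) the attainable range is +/- 2 z(0.99) = +/- 4.65. The
#' narrower published rounding of extreme rates to (0.001, 0.999) is
#' available via `clamp = c(0.001, 0.999)`. Only correct and incorrect
#' trials enter the rates.
#'
#' @param correct_pull_rate,correct_push_rate per-type proportions of
#'   correct among answered (correct + incorrect) trials.
#' @param clamp numeric length 2, lower/upper rate clamp.
#' @return the d-prime value (unitless).
#' @export
#' @examples
#' dprime(1, 1)            # 4.65, the clamped maximum
#' dprime(0.5, 0.5)        # 0, chance level
dprime <- function(correct_pull_rate, correct_push_rate,
                   clamp = c(0.01, 0.99)) {
  stopifnot(all(c(correct_pull_rate, correct_push_rate) >= 0),
            all(c(correct_pull_rate, correct_push_rate) <= 1))
  cl <- function(p) pmin(pmax(p, clamp[1]), clamp[2])
  stats::qnorm(cl(correct_pull_rate)) + stats::qnorm(cl(correct_push_rate))
}

#' d-prime from outcome counts
#'
#' @param counts a table from [outcome_counts()].
#' @param clamp see [dprime()].
#' @return d-prime, or `NA` if either type has no answered trials.
#' @export
dprime_counts <- function(counts, clamp = c(0.01, 0.99)) {
  ans_push <- counts["push", "correct"] + counts["push", "incorrect"]
  ans_pull <- counts["pull", "correct"] + counts["pull", "incorrect"]
  if (ans_push == 0 || ans_pull == 0) return(NA_real_)
  dprime(counts["pull", "correct"] / ans_pull,
         counts["push", "correct"] / ans_push, clamp)
}

#' Proportion of answered trials
#'
#' (correct + incorrect) / (correct + incorrect + no_movement +
#' anticipated_lick). Premature trials are not part of the denominator:
#' they are aborted before the answer window opens.
#'
#' @param counts a table from [outcome_counts()].
#' @return a proportion in `[0, 1]`, or `NA` if the denominator is zero.
#' @export
proportion_answered <- function(counts) {
  num <- sum(counts[, c("correct", "incorrect")])
  den <- sum(counts[, c("correct", "incorrect", "no_movement",
                        "anticipated_lick")])
  if (den == 0) return(NA_real_)
  num / den
}

#' Directional response bias
#'
#' Percent correct in push trials minus percent correct in pull trials
#' (percentage points; rates over answered trials of each type).
#'
#' @param counts a table from [outcome_counts()].
#' @return bias in percentage points, or `NA` if a type has no answered
#'   trials.
#' @export
bias_score <- function(counts) {
  ans_push <- counts["push", "correct"] + counts["push", "incorrect"]
  ans_pull <- counts["pull", "correct"] + counts["pull", "incorrect"]
  if (ans_push == 0 || ans_pull == 0) return(NA_real_)
  100 * (counts["push", "correct"] / ans_push -
           counts["pull", "correct"] / ans_pull)
}

#' Lick rate and first-lick latency in a window
#'
#' @param licks numeric vector of lick times (s).
#' @param window numeric length 2, analysis window (s).
#' @return list with `rate_hz` (lick count / window duration) and
#'   `latency_s` (first lick after window start minus window start; `NA`
#'   when no lick falls in the window).
#' @export
lick_rate <- function(licks, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  in_win <- licks >= window[1] & licks < window[2]
  n <- sum(in_win)
  list(rate_hz = n / (window[2] - window[1]),
       latency_s = if (n > 0) min(licks[in_win]) - window[1] else NA_real_)
}

#' Fine-motor label proportions per condition
#'
#' Proportions (with binomial standard errors) of the video-scored labels
#' (paw prevented, slip, drop, digit extension) per inactivation condition.
#'
#' @param trials trial data.frame with `fm_*` label columns and `sites`,
#'   `period` columns (post-exclusion).
#' @param conditions character vector of condition labels to report, as
#'   `"<sites>:<period>"` with `":none"` for control; default: all present.
#' @return data.frame with `condition`, `label`, `proportion`, `se`, `n`.
#' @export
fine_motor_proportions <- function(trials, conditions = NULL) {
  lab_cols <- grep("^fm_", names(trials), value = TRUE)
  cond <- paste0(trials$sites, ":", trials$period)
  if (is.null(conditions)) conditions <- unique(cond)
  rows <- list()
  for (cc in conditions) {
    sel <- trials[cond == cc, , drop = FALSE]
    if (nrow(sel) == 0) next
    for (cl in lab_cols) {
      p <- mean(sel[[cl]])
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cc, label = sub("^fm_", "", cl), proportion = p,
        se = sqrt(p * (1 - p) / nrow(sel)), n = nrow(sel),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-condition performance summary of one or more sessions
#'
#' Applies the exclusion rules per session, pools trials per (mouse,
#' condition) and computes d-prime, proportion answered, bias and outcome
#' counts — the direct input of the comparison layer.
#'
#' @param sessions a `session_log` or list of them.
#' @param mode exclusion mode, see [exclude_trials()].
#' @param clamp d-prime clamp, see [dprime()].
#' @return data.frame with one row per (mouse, sites, period):
#'   `mouse`, `sites`, `period`, `dprime`, `pa`, `bias`, `n_trials`,
#'   `n_correct`, `n_incorrect`, `n_no_movement`, `n_anticipated_lick`,
#'   `n_premature_move`.
#' @export
summarize_performance <- function(sessions, mode = "inactivation",
                                  clamp = c(0.01, 0.99)) {
  if (inherits(sessions, "session_log")) sessions <- list(sessions)
  pooled <- do.call(rbind, lapply(sessions, function(s) {
    kept <- exclude_trials(s$trials, mode = mode)
    if (nrow(kept) == 0) return(NULL)
    kept$mouse <- s$meta$mouse_id
    kept
  }))
  if (is.null(pooled) || nrow(pooled) == 0)
    stop("no trials survive exclusion")
  key <- interaction(pooled$mouse, pooled$sites, pooled$period, drop = TRUE)
  rows <- lapply(split(pooled, key), function(d) {
    ct <- outcome_counts(d)
    cls <- colSums(ct)
    data.frame(mouse = d$mouse[1], sites = d$sites[1], period = d$period[1],
               dprime = dprime_counts(ct, clamp),
               pa = proportion_answered(ct),
               bias = bias_score(ct),
               n_trials = nrow(d),
               n_correct = cls[["correct"]],
               n_incorrect = cls[["incorrect"]],
               n_no_movement = cls[["no_movement"]],
               n_anticipated_lick = cls[["anticipated_lick"]],
               n_premature_move = cls[["premature_move"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$mouse, out$period, out$sites), ]
}
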