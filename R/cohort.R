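#' Cohort specification
#'
#' Sizes and seeds of a simulated cohort. Defaults mirror the published
#' cohort structure: 10 mice for learning, 9 for inactivation experiments,
#' with dual-site (combined CFA+RFA) conditions probed in a 5-mouse subset,
#' so that cohort-level SEMs are on a comparable scale.
#'
#' @param n_mice number of mice.
#' @param dual_site_mice how many of them (the first ones) also get the
#'   combined CFA+RFA condition (inactivation mode).
#' @param sessions sessions per mouse (per period set in inactivation mode).
#' @param trials_per_session trials per session.
#' @param mode `"inactivation"` or `"learning"`.
#' @param periods inactivation periods probed (each gets its own session
#'   set, conditions interleaved within session).
#' @param seed cohort master seed; per-(mouse, session) seeds are derived
#'   substreams and checked for collisions.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mice = 9, dual_site_mice = min(5, n_mice),
                        sessions = 2,
                        trials_per_session = 500,
                        mode = c("inactivation", "learning"),
                        periods = c("vibration", "delay", "answer"),
                        seed = 1) {
  mode <- match.arg(mode)
  if (mode == "learning" && n_mice == 9 && missing(n_mice)) n_mice <- 10
  stopifnot(dual_site_mice <= n_mice)
  structure(list(n_mice = n_mice, dual_site_mice = dual_site_mice,
                 sessions = sessions,
                 trials_per_session = trials_per_session, mode = mode,
                 periods = periods, seed = seed),
            class = "cohort_spec")
}

#' Simulate a cohort of sessions
#'
#' One seeded session per (mouse, session[, period]). Learning mode applies
#' the staircase with session-to-session delay carry-over and a monotone
#' improvement schedule of the agent (p_correct and p_answer interpolate
#' linearly from `learning_start` to the agent's final values across
#' sessions). Inactivation mode uses the final task parameters and, per
#' period, interleaves the conditions CFA, RFA and (for the dual-site mouse
#' subset) CFA+RFA with control trials at the configured inactivation
#' fraction.
#'
#' @param spec a [cohort_spec()].
#' @param config a [task_config()].
#' @param params population-level [agent_params()]; each mouse is realized
#'   from it with a seed derived from the cohort seed.
#' @param learning_start list of starting `p_correct`, `p_answer` for
#'   learning mode.
#' @param include_traces synthesize traces (heavy; off by default).
#' @return a list of `session_log` objects.
#' @export
simulate_cohort <- function(spec, config = task_config(),
                            params = agent_params(),
                            learning_start = list(p_correct = 0.52,
                                                  p_answer = 0.35),
                            include_traces = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  sessions <- list()
  seeds_used <- integer(0)
  for (m in seq_len(spec$n_mice)) {
    mouse_id <- sprintf("m%02d", m)
    mouse_seed <- substream_seed(spec$seed, paste0("mouse", m))
    mp <- realize_mouse(params, mouse_seed)
    if (spec$mode == "learning") {
      delay0 <- 0.050
      for (s in seq_len(spec$sessions)) {
        frac <- if (spec$sessions > 1) (s - 1) / (spec$sessions - 1) else 1
        mp_s <- mp
        mp_s$p_correct <- learning_start$p_correct +
          frac * (params$p_correct - learning_start$p_correct)
        mp_s$p_answer <- learning_start$p_answer +
          frac * (params$p_answer - learning_start$p_answer)
        sid <- sprintf("s%02d", s)
        seed_ms <- substream_seed(spec$seed, paste0(mouse_id, sid))
        if (seed_ms %in% seeds_used) stop("seed collision for ", mouse_id, sid)
        seeds_used <- c(seeds_used, seed_ms)
        log <- simulate_session(mouse_id, sid, mp_s, config,
                                n_trials = spec$trials_per_session,
                                mode = "learning", seed = seed_ms,
                                initial_delay = delay0,
                                include_traces = include_traces)
        delay0 <- carry_over_delay(log$trials$delay_req_s, config)
        sessions[[length(sessions) + 1L]] <- log
      }
    } else {
      for (per in spec$periods) {
        conds <- list(inactivation_condition("CFA", per, 9),
                      inactivation_condition("RFA", per, 9))
        if (m <= spec$dual_site_mice)
          conds <- c(conds,
                     list(inactivation_condition(c("CFA", "RFA"), per, 3)))
        for (s in seq_len(spec$sessions)) {
          sid <- sprintf("%s_s%02d", substr(per, 1, 3), s)
          seed_ms <- substream_seed(spec$seed, paste0(mouse_id, sid))
          if (seed_ms %in% seeds_used)
            stop("seed collision for ", mouse_id, sid)
          seeds_used <- c(seeds_used, seed_ms)
          sessions[[length(sessions) + 1L]] <-
            simulate_session(mouse_id, sid, mp, config,
                             n_trials = spec$trials_per_session,
                             mode = "inactivation", conditions = conds,
                             seed = seed_ms,
                             include_traces = include_traces)
        }
      }
    }
  }
  sessions
}

#' Per-session learning curves
#'
#' @param sessions list of `session_log` (learning mode).
#' @return data.frame `mouse`, `session`, `dprime`, `pa`.
#' @export
learning_curves <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    kept <- exclude_trials(s$trials, mode = "learning")
    if (nrow(kept) == 0) return(NULL)
    ct <- outcome_counts(kept)
    data.frame(mouse = s$meta$mouse_id, session = s$meta$session_id,
               dprime = dprime_counts(ct), pa = proportion_answered(ct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analyze an inactivation cohort
#'
#' Runs exclusion, per-mouse condition metrics, the omnibus + post-hoc
#' comparisons against control per period, and the difference-in-differences
#' contrasts of combined versus single-site silencing. Emits the summary
#' structures that mirror the study's reporting: a per-(mouse, condition)
#' performance table, a period x location matrix of post-hoc p values for
#' d-prime and proportion answered, and a DID table with
#' (measure, period, region1, region2, p) columns.
#'
#' @param sessions list of `session_log` (inactivation mode).
#' @param posthoc see [omnibus_compare()].
#' @param robust see [did_contrast()].
#' @return an object of class `cohort_analysis`: list with `summary`
#'   (per-mouse condition table), `matrix` (list of two 3 x 3 matrices of p
#'   values, rows CFA+RFA/CFA/RFA, columns vibration/delay/answer; `NA`
#'   where a condition has no data), and `did` (data.frame).
#' @export
analyze_cohort <- function(sessions, posthoc = "fisher_lsd",
                           robust = "auto") {
  if (length(sessions) == 0) stop("empty session set")
  summ <- summarize_performance(sessions, mode = "inactivation")
  site_rows <- c("CFA+RFA", "CFA", "RFA")
  periods <- c("vibration", "delay", "answer")
  measures <- c(dprime = "dprime", pa = "pa")
  ctl <- summ[summ$period == "none", ]
  # each contrast compares a silenced condition against the control values
  # of the same mice (conditions probed in a subset are compared within
  # that subset, as when a dual-site condition exists for 5 of 9 animals)
  mats <- lapply(measures, function(ms) {
    mat <- matrix(NA_real_, 3, 3, dimnames = list(site_rows, periods))
    for (per in periods) {
      for (rs in site_rows) {
        sil <- summ[summ$period == per & summ$sites == rs, ]
        if (nrow(sil) < 2) next
        ctl_m <- ctl[ctl$mouse %in% sil$mouse, ]
        values <- c(ctl_m[[ms]], sil[[ms]])
        group <- c(rep("control", nrow(ctl_m)), sil$sites)
        om <- omnibus_compare(values, group, control = "control",
                              posthoc = posthoc)
        mat[rs, per] <- om$contrasts$p[om$contrasts$condition == rs]
      }
    }
    mat
  })
  did <- list()
  for (ms in c("dprime", "pa", "percent_correct")) {
    for (per in periods) {
      tab <- did_input_table(summ, ms, per)
      if (is.null(tab)) next
      for (single in c("CFA", "RFA")) {
        if (!all(c(single, "CFA+RFA") %in% tab$condition)) next
        res <- tryCatch(
          suppressWarnings(did_contrast(tab, single, "CFA+RFA",
                                        robust = robust)),
          error = function(e) NULL)
        if (is.null(res)) next
        did[[length(did) + 1L]] <- data.frame(
          measure = ms, period = per, region1 = "CFA+RFA", region2 = single,
          estimate = res$interaction, p = res$p, robust = res$robust,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(summary = summ, matrix = mats,
                 did = if (length(did)) do.call(rbind, did) else NULL),
            class = "cohort_analysis")
}

# stack per-mouse values of one measure at one period into the DID layout
did_input_table <- function(summ, measure, period) {
  val <- function(d) {
    if (measure == "percent_correct")
      100 * d$n_correct / pmax(d$n_correct + d$n_incorrect, 1)
    else d[[measure]]
  }
  ctl <- summ[summ$period == "none", ]
  sil <- summ[summ$period == period & summ$sites != "", ]
  if (nrow(sil) == 0 || nrow(ctl) == 0) return(NULL)
  rbind(
    data.frame(mouse = ctl$mouse, condition = "control", value = val(ctl),
               stringsAsFactors = FALSE),
    data.frame(mouse = sil$mouse, condition = sil$sites, value = val(sil),
               stringsAsFactors = FALSE)
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Inactivation cohort analysis\n")
  cat(sprintf("  %d (mouse, condition) summary rows\n", nrow(x$summary)))
  for (ms in names(x$matrix)) {
    cat(sprintf("  post-hoc p values vs control (%s):\n", ms))
    print(round(x$matrix[[ms]], 4))
  }
  if (!is.null(x$did)) {
    cat("  difference-in-differences contrasts:\n")
    print(x$did, row.names = FALSE)
  }
  invisible(x)
}

#' Write cohort analysis tables as delimited text
#'
#' @param analysis a `cohort_analysis`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv17(analysis$summary, file.path(dir, "condition_summary.tsv"))
  for (ms in names(analysis$matrix)) {
    m <- analysis$matrix[[ms]]
    df <- data.frame(sites = rownames(m), as.data.frame(m))
    write_tsv17(df, file.path(dir, paste0("matrix_", ms, ".tsv")))
  }
  if (!is.null(analysis$did))
    write_tsv17(analysis$did, file.path(dir, "did_table.tsv"))
  invisible(dir)
}
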