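#' Session on-disk dialect
#'
#' A session is a directory of plain-text files:
#' \describe{
#'   \item{session.meta}{YAML metadata: mouse/session ids, seed, mode,
#'     schema version, and the task-config snapshot.}
#'   \item{trials.tsv}{one row per trial; fixed leading header
#'     `index, trial_type, stim_freq_hz, baseline_dur_s, delay_dur_s,
#'     t_go_cue_s, response_dir, t_first_move_s, t_first_lick_s, outcome,
#'     sites, period, power_mw, timeout_s` (further columns allowed and
#'     preserved).}
#'   \item{traces.tsv}{columns `index, sample, position_mm` (5 kHz samples).}
#'   \item{licks.tsv}{columns `index, lick_time_s`.}
#'   \item{laser.tsv}{columns `index, site, t_on_s, t_off_s, power_mw,
#'     alternation_hz`.}
#' }
#' Times are seconds from trial start (double precision), positions are
#' millimeters, push positive / pull negative. Floats are written with 17
#' significant digits so the round trip `read_session(write_session(x))` is
#' bit-for-bit exact.
#'
#' @param log a `session_log`.
#' @param path directory to create/write.
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   a validated `session_log`.
#' @export
write_session <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(log$meta, file.path(path, "session.meta"))
  write_tsv17(log$trials, file.path(path, "trials.tsv"))

  idx <- names(log$traces)
  traces <- if (length(idx)) do.call(rbind, lapply(idx, function(i) {
    p <- log$traces[[i]]$positions
    data.frame(index = as.integer(i), sample = seq_along(p), position_mm = p)
  })) else data.frame(index = integer(0), sample = integer(0),
                      position_mm = numeric(0))
  write_tsv17(traces, file.path(path, "traces.tsv"))

  lk <- names(log$licks)
  licks <- if (length(lk)) do.call(rbind, lapply(lk, function(i) {
    t <- log$licks[[i]]
    if (length(t) == 0) return(NULL)
    data.frame(index = as.integer(i), lick_time_s = t)
  })) else NULL
  if (is.null(licks)) licks <- data.frame(index = integer(0),
                                          lick_time_s = numeric(0))
  write_tsv17(licks, file.path(path, "licks.tsv"))

  lz <- names(log$laser)
  laser <- if (length(lz)) do.call(rbind, lapply(lz, function(i) {
    d <- log$laser[[i]]
    if (is.null(d) || nrow(d) == 0) return(NULL)
    cbind(data.frame(index = as.integer(i)), d)
  })) else NULL
  if (is.null(laser)) laser <- data.frame(index = integer(0),
                                          site = character(0),
                                          t_on_s = numeric(0),
                                          t_off_s = numeric(0),
                                          power_mw = numeric(0),
                                          alternation_hz = numeric(0))
  write_tsv17(laser, file.path(path, "laser.tsv"))
  invisible(path)
}

TRIAL_HEADER <- c("index", "trial_type", "stim_freq_hz", "baseline_dur_s",
                  "delay_dur_s", "t_go_cue_s", "response_dir",
                  "t_first_move_s", "t_first_lick_s", "outcome",
                  "sites", "period", "power_mw", "timeout_s")

# full-precision TSV so doubles survive the round trip exactly
write_tsv17 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.17g", out[[j]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "session.meta")
  if (!file.exists(meta_file)) stop("missing session.meta in ", path)
  meta <- yaml::read_yaml(meta_file)
  if (is.null(meta$schema_version) ||
      !identical(as.character(meta$schema_version), SESSION_SCHEMA_VERSION))
    stop("unknown session schema version: ",
         if (is.null(meta$schema_version)) "<absent>" else meta$schema_version)
  meta$config$baseline_range <- as.numeric(meta$config$baseline_range)

  trials <- utils::read.table(file.path(path, "trials.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_HEADER, names(trials))
  if (length(missing))
    stop("trials.tsv is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(trials$index))
    stop("duplicate trial index in trials.tsv: ",
         trials$index[duplicated(trials$index)][1])
  if (!all(sort(trials$index) == seq_len(nrow(trials))))
    stop("trial indices must be contiguous starting at 1")
  bad <- which(!trials$outcome %in% outcome_levels())
  if (length(bad))
    stop(sprintf("invalid outcome '%s' in trials.tsv row %d",
                 trials$outcome[bad[1]], bad[1]))
  if ("reward" %in% names(trials)) trials$reward <- as.logical(trials$reward)
  for (cl in grep("^fm_", names(trials), value = TRUE))
    trials[[cl]] <- as.logical(trials[[cl]])

  tr <- utils::read.table(file.path(path, "traces.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  dangling <- setdiff(unique(tr$index), trials$index)
  if (length(dangling))
    stop("traces.tsv refers to unknown trial index: ", dangling[1])
  fs <- meta$config$sample_rate
  traces <- lapply(split(tr$position_mm, tr$index), function(p) {
    structure(list(sample_rate = fs, t0 = 0, positions = unname(p)),
              class = "joystick_trace")
  })

  lk <- utils::read.table(file.path(path, "licks.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  if (length(setdiff(unique(lk$index), trials$index)))
    stop("licks.tsv refers to unknown trial index")
  licks <- lapply(split(lk$lick_time_s, lk$index), unname)
  # restore empty lick vectors for trials with no licks
  for (i in trials$index) {
    key <- as.character(i)
    if (is.null(licks[[key]])) licks[[key]] <- numeric(0)
  }
  licks <- licks[as.character(trials$index)]

  lz <- utils::read.table(file.path(path, "laser.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  if (length(setdiff(unique(lz$index), trials$index)))
    stop("laser.tsv refers to unknown trial index")
  laser <- lapply(split(lz[setdiff(names(lz), "index")], lz$index),
                  function(d) { rownames(d) <- NULL; d })

  structure(list(meta = meta, trials = trials, traces = traces,
                 licks = licks, laser = laser),
            class = "session_log")
}
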