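#' Distributional gates: normality and homoscedasticity
#'
#' Per-group normality by a Kolmogorov-Smirnov-type test and across-group
#' homoscedasticity by Bartlett's test; `parametric_ok` is `TRUE` only if
#' every test passes at `alpha`. By default normality uses the
#' Lilliefors-corrected KS test (parameters estimated from the sample);
#' `exact_ks = TRUE` uses the plain KS test against the fitted normal
#' instead.
#'
#' @param samples list of numeric vectors, one per group (each n >= 3).
#' @param alpha gate significance level.
#' @param exact_ks use the uncorrected KS test.
#' @return list with `parametric_ok`, `ks_p` (per group), `bartlett_p`, and
#'   `reason` (`NULL`, or why the gate failed, e.g. a degenerate
#'   zero-variance group).
#' @export
gate_distributions <- function(samples, alpha = 0.05, exact_ks = FALSE) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (any(vapply(samples, length, 1L) < 3))
    stop("each group needs at least 3 observations")
  if (any(vapply(samples, stats::sd, 1) == 0))
    return(list(parametric_ok = FALSE, ks_p = NULL, bartlett_p = NULL,
                reason = "degenerate zero-variance group"))
  ks_p <- vapply(samples, function(x) {
    if (exact_ks)
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value
    else nortest::lillie.test(x)$p.value
  }, 1)
  bartlett_p <- stats::bartlett.test(samples)$p.value
  ok <- all(ks_p > alpha) && bartlett_p > alpha
  list(parametric_ok = ok, ks_p = ks_p, bartlett_p = bartlett_p,
       reason = if (ok) NULL else "normality or homoscedasticity rejected")
}

#' Kruskal-Wallis omnibus with post-hoc contrasts against control
#'
#' Tie-corrected Kruskal-Wallis H across all groups, followed by a post-hoc
#' comparison of each non-control group against the control group on the
#' pooled ranks: Fisher's least-significant-difference t statistics
#' (Conover-style, pooled rank variance, df = N - k; the default) or
#' Tukey-Kramer studentized-range p values.
#'
#' @param values numeric vector of the measure (e.g. per-mouse d-prime).
#' @param group factor/character of condition labels, same length.
#' @param control label of the control group.
#' @param posthoc `"fisher_lsd"` or `"tukey_kramer"`.
#' @return list with `H`, `p` (omnibus), `df`, and `contrasts`: a data.frame
#'   (`condition`, `p`, `n`) of post-hoc p values versus control (conditions
#'   with fewer than 2 observations are reported as `NA`).
#' @export
omnibus_compare <- function(values, group, control = "control",
                            posthoc = c("fisher_lsd", "tukey_kramer")) {
  posthoc <- match.arg(posthoc)
  group <- as.character(group)
  stopifnot(length(values) == length(group), control %in% group)
  keep <- !is.na(values)
  values <- values[keep]; group <- group[keep]
  glev <- unique(group)
  k <- length(glev)
  if (k < 2) stop("need at least 2 conditions")
  N <- length(values)
  r <- rank(values)
  if (stats::var(r) == 0) {
    # every observation tied: no evidence of any difference
    H <- 0; p_omni <- 1
  } else {
    kt <- stats::kruskal.test(values, factor(group))
    H <- unname(kt$statistic); p_omni <- kt$p.value
  }
  n_i <- tapply(r, group, length)
  rbar <- tapply(r, group, mean)
  # pooled rank variance with tie correction (Conover)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  mse <- S2 * (N - 1 - H) / (N - k)
  others <- setdiff(glev, control)
  ps <- vapply(others, function(g) {
    if (n_i[[g]] < 2 || n_i[[control]] < 2) return(NA_real_)
    se2 <- mse * (1 / n_i[[g]] + 1 / n_i[[control]])
    if (se2 <= 0) return(1)
    d <- abs(rbar[[g]] - rbar[[control]])
    if (posthoc == "fisher_lsd") {
      2 * stats::pt(-d / sqrt(se2), df = N - k)
    } else {
      stats::ptukey(d / sqrt(se2 / 2), nmeans = k, df = N - k,
                    lower.tail = FALSE)
    }
  }, 1)
  list(H = H, p = p_omni, df = k - 1,
       contrasts = data.frame(condition = others, p = unname(ps),
                              n = as.integer(n_i[others]),
                              stringsAsFactors = FALSE))
}

#' Paired t test on animal averages
#'
#' Used for learning-curve summaries (early versus late session means per
#' mouse). Degenerate inputs (zero variance of the paired differences) are
#' flagged instead of producing spurious p values.
#'
#' @param early,late equal-length paired numeric vectors (per-mouse means).
#' @return list with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(early, late) {
  stopifnot(length(early) == length(late))
  if (length(early) < 2) stop("need at least 2 paired observations")
  d <- late - early
  if (stats::sd(d) == 0) {
    return(list(t = if (all(d == 0)) 0 else NA_real_,
                df = length(d) - 1,
                p = if (all(d == 0)) 1 else NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(late, early, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Difference-in-differences contrast of combined versus single silencing
#'
#' Tests whether combined two-site silencing changes a measure beyond the
#' single-site silencing effect. Per-mouse paired (control, silenced) values
#' of the two conditions are stacked and
#' `value ~ silenced + is_combined + silenced:is_combined` is fit by OLS;
#' the interaction coefficient is the DID estimate. Residual normality is
#' checked by Shapiro-Wilk; when rejected (or `robust = "always"`), a
#' Huber-weighted robust regression (`MASS::rlm`) is used and the
#' interaction p value comes from its t statistic on n - 4 df.
#'
#' @param table data.frame with columns `mouse`, `condition`, `value`;
#'   `condition` takes the `control`, `single` and `combined` labels. The
#'   control rows are shared between the two groups.
#' @param single,combined condition labels of the single-site and combined
#'   conditions.
#' @param control label of the control condition.
#' @param robust `"auto"` (Shapiro-Wilk decides), `"never"`, `"always"`.
#' @return an object of class `did_result`: list with `coefficients`
#'   (intercept, silenced, combined_group, interaction), `interaction`,
#'   `interaction_se`, `p`, `robust` (flag), `shapiro_p`, `n_mice`.
#' @export
did_contrast <- function(table, single, combined, control = "control",
                         robust = c("auto", "never", "always")) {
  robust <- match.arg(robust)
  stopifnot(all(c("mouse", "condition", "value") %in% names(table)))
  get_vals <- function(cond) {
    d <- table[table$condition == cond & !is.na(table$value), ]
    stats::setNames(d$value, d$mouse)
  }
  v_ctl <- get_vals(control); v_s <- get_vals(single); v_c <- get_vals(combined)
  mice <- intersect(names(v_ctl), intersect(names(v_s), names(v_c)))
  dropped <- setdiff(unique(table$mouse), mice)
  if (length(dropped))
    warning("dropping unpaired mice: ", paste(sort(dropped), collapse = ", "))
  if (length(mice) == 0) stop("no mouse has paired values in all conditions")
  df <- data.frame(
    value = c(v_ctl[mice], v_s[mice], v_ctl[mice], v_c[mice]),
    silenced = rep(c(0, 1, 0, 1), each = length(mice)),
    is_combined = rep(c(0, 0, 1, 1), each = length(mice))
  )
  fit <- stats::lm(value ~ silenced * is_combined, data = df)
  sw <- stats::shapiro.test(stats::residuals(fit))
  use_robust <- robust == "always" || (robust == "auto" && sw$p.value < 0.05)
  if (use_robust) {
    rfit <- MASS::rlm(value ~ silenced * is_combined, data = df, psi = MASS::psi.huber,
                      maxit = 100)
    cf <- summary(rfit)$coefficients
    est <- cf["silenced:is_combined", "Value"]
    se <- cf["silenced:is_combined", "Std. Error"]
    coefs <- stats::coef(rfit)
  } else {
    cf <- summary(fit)$coefficients
    est <- cf["silenced:is_combined", "Estimate"]
    se <- cf["silenced:is_combined", "Std. Error"]
    coefs <- stats::coef(fit)
  }
  dfree <- nrow(df) - 4L
  p <- 2 * stats::pt(-abs(est / se), df = dfree)
  structure(
    list(coefficients = stats::setNames(
           as.numeric(coefs),
           c("intercept", "silenced", "combined_group", "interaction")),
         interaction = unname(est), interaction_se = unname(se), p = unname(p),
         robust = use_robust, shapiro_p = sw$p.value, n_mice = length(mice)),
    class = "did_result")
}

#' @export
print.did_result <- function(x, ...) {
  cat(sprintf("<did_result: interaction %.4g +/- %.4g (p = %.4g, %s, %d mice)>\n",
              x$interaction, x$interaction_se, x$p,
              if (x$robust) "robust" else "OLS", x$n_mice))
  invisible(x)
}

#' Type-I error of the comparison pipeline on null condition tables
#'
#' Simulates null cohorts (all conditions identically distributed per-mouse
#' values), runs the distributional gates and the omnibus + post-hoc
#' comparison against control, and reports the per-contrast rejection rate
#' at nominal `alpha` — the empirical size of the pipeline.
#'
#' @param n_reps replicate cohorts.
#' @param n_mice mice (observations) per condition.
#' @param n_groups conditions including control.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @param posthoc see [omnibus_compare()].
#' @return list with `rate` (pooled over contrasts), `n_tests`,
#'   `gate_parametric_rate`.
#' @export
pipeline_type1_rate <- function(n_reps = 1000, n_mice = 9, n_groups = 4,
                                alpha = 0.05, seed = 1,
                                posthoc = "fisher_lsd") {
  s <- rng_stream(seed, "type1")
  labels <- c("control", paste0("g", seq_len(n_groups - 1L)))
  rej <- 0L; n_tests <- 0L; gate_ok <- 0L
  for (r in seq_len(n_reps)) {
    vals <- with_stream(s, stats::rnorm(n_mice * n_groups))
    grp <- rep(labels, each = n_mice)
    g <- gate_distributions(split(vals, grp))
    if (isTRUE(g$parametric_ok)) gate_ok <- gate_ok + 1L
    om <- omnibus_compare(vals, grp, posthoc = posthoc)
    pv <- om$contrasts$p
    rej <- rej + sum(pv < alpha, na.rm = TRUE)
    n_tests <- n_tests + sum(!is.na(pv))
  }
  list(rate = rej / n_tests, n_tests = n_tests,
       gate_parametric_rate = gate_ok / n_reps)
}
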