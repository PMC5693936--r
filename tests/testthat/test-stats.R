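test_that("distributional gates pass normal data and flag violations", {
  s <- rng_stream(1, "gates")
  a <- with_stream(s, rnorm(50))
  b <- with_stream(s, rnorm(50))
  g <- gate_distributions(list(a, b))
  expect_true(g$parametric_ok)
  # gross heteroscedasticity: Bartlett rejects
  g2 <- gate_distributions(list(a, 10 * b))
  expect_false(g2$parametric_ok)
  expect_lt(g2$bartlett_p, 0.05)
  # degenerate zero-variance group
  g3 <- gate_distributions(list(a, rep(1, 10)))
  expect_false(g3$parametric_ok)
  expect_match(g3$reason, "degenerate")
  expect_error(gate_distributions(list(a, c(1, 2))), "at least 3")
})

test_that("identical groups give H = 0 and p = 1 throughout", {
  om <- omnibus_compare(rep(2.5, 12), rep(c("control", "g1", "g2"), each = 4))
  expect_equal(om$H, 0)
  expect_equal(om$p, 1)
  expect_true(all(om$contrasts$p == 1))
})

test_that("the H statistic matches the rank-formula oracle", {
  vals <- c(2.1, 3.3, 1.2, 5.5, 4.4, 6.6, 9.9, 7.7, 8.8)
  grp <- rep(c("control", "g1", "g2"), each = 3)
  om <- omnibus_compare(vals, grp)
  expect_equal(om$H, kw_h_oracle(vals, grp), tolerance = 1e-12)
})

test_that("Kruskal-Wallis agrees with an exact permutation oracle for n <= 8", {
  # all relabelings of 8 observations into groups of sizes 3/3/2
  perm_p <- function(vals, sizes) {
    labs <- rep(seq_along(sizes), sizes)
    h_obs <- kw_h_oracle(vals, labs)
    combs <- combn(8, sizes[1])
    count <- 0; total <- 0
    for (i in seq_len(ncol(combs))) {
      rest <- setdiff(1:8, combs[, i])
      combs2 <- combn(rest, sizes[2])
      for (j in seq_len(ncol(combs2))) {
        lab <- integer(8)
        lab[combs[, i]] <- 1L
        lab[combs2[, j]] <- 2L
        lab[lab == 0] <- 3L
        total <- total + 1
        if (kw_h_oracle(vals, lab) >= h_obs - 1e-9) count <- count + 1
      }
    }
    count / total
  }
  s <- rng_stream(2, "perm")
  # a clearly separated and a null-ish arrangement: the chi-square p and the
  # exact permutation p must agree on the rejection decision, and H must
  # match the oracle exactly
  sep <- c(1, 2, 3, 11, 12, 13, 21, 22)
  nullish <- with_stream(s, rnorm(8))
  for (vals in list(sep, nullish)) {
    grp <- rep(c("a", "b", "control"), c(3, 3, 2))
    om <- omnibus_compare(vals, grp, control = "control")
    expect_equal(om$H, kw_h_oracle(vals, grp), tolerance = 1e-12)
    p_exact <- perm_p(vals, c(3, 3, 2))
    expect_identical(om$p < 0.05, p_exact < 0.05)
    # the chi-square approximation is coarse at n = 8; agreement is on the
    # decision and the rough scale
    expect_lt(abs(om$p - p_exact), 0.15)
  }
})

test_that("the omnibus pipeline detects a one-SD location shift", {
  s <- rng_stream(3, "power")
  hits <- replicate(400, {
    x <- with_stream(s, rnorm(9))
    y <- with_stream(s, rnorm(9, mean = 1))
    om <- omnibus_compare(c(x, y), rep(c("control", "g1"), each = 9))
    om$contrasts$p[1] < 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("paired t handles learning contrasts and degenerate inputs", {
  x <- c(1.2, 1.5, 0.9, 1.1)
  p0 <- paired_t(x, x)
  expect_equal(p0$t, 0)
  expect_equal(p0$p, 1)
  expect_true(p0$degenerate)
  pc <- paired_t(x, x + 2)     # constant difference, zero noise
  expect_true(pc$degenerate)
  expect_true(is.na(pc$p))
  s <- rng_stream(4, "pt")
  hits <- replicate(200, {
    early <- with_stream(s, rnorm(10, 0, 0.5))
    late <- with_stream(s, rnorm(10, 1, 0.5))
    paired_t(early, late)$p < 0.05
  })
  expect_gt(mean(hits), 0.95)
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("DID recovers a null and a known interaction within 3 SE", {
  s <- rng_stream(5, "did")
  make_table <- function(delta_combined) {
    mice <- sprintf("m%d", 1:9)
    base <- with_stream(s, rnorm(9, 2.1, 0.3))
    eff <- -0.6
    rbind(
      data.frame(mouse = mice, condition = "control", value = base +
                   with_stream(s, rnorm(9, 0, 0.2))),
      data.frame(mouse = mice, condition = "CFA", value = base + eff +
                   with_stream(s, rnorm(9, 0, 0.2))),
      data.frame(mouse = mice, condition = "CFA+RFA", value = base + eff +
                   delta_combined + with_stream(s, rnorm(9, 0, 0.2)))
    )
  }
  null_fit <- did_contrast(make_table(0), "CFA", "CFA+RFA", robust = "never")
  expect_lt(abs(null_fit$interaction), 3 * null_fit$interaction_se)
  rec <- did_contrast(make_table(-0.5), "CFA", "CFA+RFA", robust = "never")
  expect_lt(abs(rec$interaction - (-0.5)), 3 * rec$interaction_se)
  expect_named(rec$coefficients,
               c("intercept", "silenced", "combined_group", "interaction"))
})

test_that("DID is invariant to row order and drops unpaired mice", {
  tab <- data.frame(
    mouse = rep(sprintf("m%d", 1:5), 3),
    condition = rep(c("control", "CFA", "CFA+RFA"), each = 5),
    value = c(2.0, 2.2, 1.9, 2.1, 2.3, 1.4, 1.6, 1.3, 1.5, 1.8,
              0.9, 1.2, 0.8, 1.1, 1.4))
  f1 <- did_contrast(tab, "CFA", "CFA+RFA", robust = "never")
  f2 <- did_contrast(tab[sample.int(nrow(tab)), ], "CFA", "CFA+RFA",
                     robust = "never")
  expect_equal(f1, f2)
  tab2 <- rbind(tab, data.frame(mouse = "m6", condition = "control",
                                value = 2.5))
  expect_warning(f3 <- did_contrast(tab2, "CFA", "CFA+RFA", robust = "never"),
                 "unpaired")
  expect_equal(f3$interaction, f1$interaction)
  expect_error(suppressWarnings(
    did_contrast(tab[tab$condition != "control", ], "CFA", "CFA+RFA")),
    "no mouse")
})

test_that("heavy-tailed noise triggers the robust fit and reduces bias", {
  s <- rng_stream(6, "robust")
  errs <- replicate(40, {
    mice <- sprintf("m%d", 1:9)
    base <- with_stream(s, rnorm(9, 2, 0.3))
    contam <- function(n) with_stream(s, {
      e <- rnorm(n, 0, 0.15)
      big <- runif(n) < 0.15
      e[big] <- e[big] + rt(sum(big), df = 1)
      e
    })
    tab <- rbind(
      data.frame(mouse = mice, condition = "control", value = base + contam(9)),
      data.frame(mouse = mice, condition = "CFA", value = base - 0.5 + contam(9)),
      data.frame(mouse = mice, condition = "CFA+RFA",
                 value = base - 1.0 + contam(9)))
    ols <- did_contrast(tab, "CFA", "CFA+RFA", robust = "never")
    rob <- did_contrast(tab, "CFA", "CFA+RFA", robust = "always")
    c(ols = abs(ols$interaction - (-0.5)), rob = abs(rob$interaction - (-0.5)))
  })
  expect_lt(mean(errs["rob", ]), mean(errs["ols", ]))
  # and the auto rule switches on for contaminated residuals in most runs
  expect_true(any(errs["rob", ] != errs["ols", ]))
})

test_that("the comparison pipeline holds its nominal size on null cohorts", {
  out <- pipeline_type1_rate(n_reps = 200, n_mice = 9, n_groups = 4, seed = 12)
  expect_gt(out$rate, 0.01)
  expect_lt(out$rate, 0.12)
})
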