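test_that("log-NTCP ANOVA recovers effects and enforces the balanced design", {
  cohort <- trial_cohort()
  fit <- log_ntcp_anova(cohort)
  expect_s3_class(fit, "ntcp_anova")
  gl <- glance(fit)
  expect_lt(gl$p_patient, 1e-4)
  expect_lt(gl$p_scenario, 1e-4)
  expect_equal(fit$df_residual, (7 - 1) * (5 - 1))
  # identical NTCP across scenarios -> zero scenario effects
  flat <- cohort
  flat$ntcp_fraction <- rep(cohort$ntcp_fraction[cohort$scenario == 1],
                            each = 5)
  fit0 <- log_ntcp_anova(flat)
  expect_equal(max(abs(fit0$scenario_effects$effect)), 0, tolerance = 1e-12)
  # missing cell errors
  expect_error(log_ntcp_anova(cohort[-1, ]), "balanced")
  # zero NTCP errors
  zero <- cohort
  zero$ntcp_fraction[1] <- 0
  expect_error(log_ntcp_anova(zero), "> 0")
  # underflow is floored with a warning
  tiny <- cohort
  tiny$ntcp_fraction[1] <- 1e-15
  expect_warning(log_ntcp_anova(tiny), "floored")
})

test_that("tidy() exposes scenario and patient effects", {
  fit <- log_ntcp_anova(trial_cohort())
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("scenario", "patient"))
  expect_equal(nrow(td), 5 + 7)
  sc3 <- td$effect[td$term == "scenario" & td$level == "3"]
  sc1 <- td$effect[td$term == "scenario" & td$level == "1"]
  expect_equal(exp(sc3 - sc1), scenario_factor(fit, 3, 1)$factor)
})

test_that("scenario factors reproduce the published multiplicative effects", {
  fit <- log_ntcp_anova(trial_cohort())
  f31 <- scenario_factor(fit, 3, 1)
  f21 <- scenario_factor(fit, 2, 1)
  # fixed positioning: x5.50; varying positioning: x3.54 (printed-table
  # rounding moves the recomputed values by < 1%)
  expect_equal(f31$factor, 5.50, tolerance = 0.01)
  expect_equal(f21$factor, 3.54, tolerance = 0.01)
  expect_true(f31$conf_lo < f31$factor && f31$factor < f31$conf_hi)
  expect_lt(f31$p_value, 1e-4)
  expect_lt(f21$p_value, 1e-4)
  # degenerate self-contrast
  f11 <- scenario_factor(fit, 1, 1)
  expect_equal(f11$factor, 1)
  expect_equal(c(f11$conf_lo, f11$conf_hi), c(1, 1))
})

test_that("a balanced-design factor equals the geometric mean of patient ratios", {
  set.seed(15)
  for (i in 1:5) {
    tab <- expand.grid(patient = letters[1:6], scenario = 1:4)
    tab$ntcp_fraction <- exp(rnorm(nrow(tab), -7, 1.5))
    fit <- log_ntcp_anova(tab)
    a <- sample(1:4, 1); b <- sample(setdiff(1:4, a), 1)
    gm <- exp(mean(log(tab$ntcp_fraction[tab$scenario == a] /
                         tab$ntcp_fraction[tab$scenario == b])))
    expect_equal(scenario_factor(fit, a, b)$factor, gm, tolerance = 1e-12)
  }
})

test_that("factor confidence intervals achieve near-nominal coverage", {
  set.seed(2024)
  n_rep <- 500
  true_factor <- 3
  cover <- 0
  for (r in seq_len(n_rep)) {
    tab <- expand.grid(patient = letters[1:7], scenario = 1:3)
    eff <- c(0, log(2), log(true_factor))[tab$scenario]
    pat <- rnorm(7, -7, 1.5)[as.integer(tab$patient)]
    tab$ntcp_fraction <- exp(pat + eff + rnorm(nrow(tab), 0, 0.3))
    f <- scenario_factor(log_ntcp_anova(tab), 3, 1)
    if (f$conf_lo <= true_factor && true_factor <= f$conf_hi) {
      cover <- cover + 1
    }
  }
  expect_gte(cover / n_rep, 0.93)
  expect_lte(cover / n_rep, 0.97)
})

test_that("spearman_rank matches a rank-then-Pearson oracle and handles ties", {
  set.seed(8)
  for (i in 1:10) {
    x <- runif(20); y <- runif(20)
    oracle <- cor(rank(x), rank(y))
    expect_equal(spearman_rank(x, y), oracle, tolerance = 1e-12)
  }
  # ties via duplicated values, average ranks
  x <- c(1, 2, 2, 3, 4)
  y <- c(2, 1, 3, 3, 5)
  expect_equal(spearman_rank(x, y), cor(rank(x), rank(y)),
               tolerance = 1e-12)
  expect_equal(spearman_rank(1:10, 10:1), -1)
  expect_error(spearman_rank(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rank(1:4, 1:5), "lengths")
  expect_error(spearman_rank(1:2, 2:1), "at least 3")
})

test_that("rank correlation is invariant under strictly monotone transforms", {
  set.seed(14)
  x <- runif(25); y <- runif(25)
  r0 <- spearman_rank(x, y)
  expect_equal(spearman_rank(exp(3 * x), y), r0)
  expect_equal(spearman_rank(x, qnorm(y * 0.98 + 0.01)), r0)
  expect_equal(spearman_rank(rank(x), y), r0)
})

test_that("KS normality bands separate normal from NTCP-like skewed samples", {
  set.seed(101)
  normal <- rnorm(500)
  out_n <- ks_normality(normal)
  expect_equal(as.character(out_n$p_band), ">0.15")
  skewed <- exp(rnorm(200, -7, 2)) # lognormal, NTCP-like
  out_s <- ks_normality(skewed)
  expect_equal(as.character(out_s$p_band), "<0.01")
  # log restores normality for the same sample
  expect_equal(as.character(ks_normality(log(skewed))$p_band), ">0.15")
  expect_error(ks_normality(rnorm(4)), "at least 5")
})

test_that("cohort summary reports NTCP order statistics in percent", {
  cohort <- trial_cohort()
  s1 <- cohort_summary(cohort, 1)
  expect_equal(s1$median_pct, 0.1109)
  expect_equal(s1$max_pct, 1.4744)
  expect_equal(s1$min_pct, 0.0005)
  one <- cohort[cohort$patient == "A" & cohort$scenario == 1, ]
  s <- cohort_summary(one, 1)
  expect_equal(s$min_pct, s$median_pct)
  expect_equal(s$median_pct, s$max_pct)
  expect_error(cohort_summary(cohort, 9), "no rows")
})
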