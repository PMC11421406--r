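test_that("ICC(A,1) agrees with a two-way ANOVA oracle and penalizes offsets", {
  expect_equal(icc_absolute_agreement(c(1, 2, 3, 4), c(1, 2, 3, 4))$icc, 1)
  expect_lt(icc_absolute_agreement(c(1, 2, 3, 4), c(3, 4, 5, 6))$icc, 1)
  # frozen oracle value for a specific small table
  expect_equal(icc_absolute_agreement(c(1, 2, 3, 4), c(1, 2, 3, 5))$icc,
               0.94545455, tolerance = 1e-7)
  # closed form vs the lm/anova mean-squares route on many small tables
  set.seed(42)
  checked <- 0
  for (i in 1:400) {
    x <- sample(0:3, 4, replace = TRUE)
    y <- sample(0:3, 4, replace = TRUE)
    if (length(unique(c(x, y))) == 1) next
    expect_equal(icc_absolute_agreement(x, y)$icc,
                 suppressWarnings(icc_oracle_aov(x, y)),  # exact-fit tables
                 tolerance = 1e-10)
    checked <- checked + 1
  }
  expect_gt(checked, 300)
  expect_error(icc_absolute_agreement(1:4, 1:5), "equal length")
  expect_error(icc_absolute_agreement(rep(1, 4), rep(1, 4)), "variance")
})

test_that("Durbin-Watson has its closed-form values at the extremes", {
  n <- 50
  alt <- rep(c(1, -1), n / 2)
  expect_equal(durbin_watson(alt), 4 * (n - 1) / n)
  expect_equal(durbin_watson(rep(2, 10)), 0)
  white <- with_fixture_seed(3, stats::rnorm(5000))
  expect_equal(durbin_watson(white), 2, tolerance = 0.05)
  expect_error(durbin_watson(rep(0, 5)), "zero")
  expect_error(durbin_watson(1), "at least 2")
})

test_that("stepwise selection reduces to full OLS with entry_p = 1", {
  set.seed(7)
  d <- data.frame(x1 = rnorm(80), x2 = rnorm(80), x3 = rnorm(80))
  d$y <- 2 * d$x1 - 1.5 * d$x2 + 0.1 * d$x3 + rnorm(80)
  full <- fit_stepwise(d, "y", c("x1", "x2", "x3"), entry_p = 1,
                       removal_p = 1.01)
  ols <- lm(y ~ x1 + x2 + x3, data = d)
  expect_equal(setNames(full$coefficients$beta, full$coefficients$predictor),
               coef(ols)[c("x1", "x2", "x3")])
  expect_true(all(full$coefficients$entered))
  # standardized beta identity
  expect_equal(full$coefficients$std_beta,
               full$coefficients$beta *
                 sapply(d[c("x1", "x2", "x3")], sd) / sd(d$y),
               ignore_attr = TRUE)
  # CI brackets the estimate
  expect_true(all(full$coefficients$ci_lower <= full$coefficients$beta &
                    full$coefficients$beta <= full$coefficients$ci_upper))
  expect_lte(full$model$adj_r2, full$model$r2)
})

test_that("stepwise entry admits real predictors and reports rejected ones", {
  set.seed(11)
  d <- data.frame(x1 = rnorm(120), x2 = rnorm(120), x3 = rnorm(120))
  d$y <- 3 * d$x1 + rnorm(120)
  fit <- fit_stepwise(d, "y", c("x1", "x2", "x3"))
  expect_equal(fit$entry_order, "x1")
  tab <- fit$coefficients
  expect_equal(tab$predictor, c("x1", "x2", "x3"))  # all candidates reported
  expect_equal(tab$entered, c(TRUE, FALSE, FALSE))
  expect_equal(tab$beta[1], 3, tolerance = 0.15)
  # perfect collinearity rejected
  d$x4 <- d$x1
  expect_error(fit_stepwise(d, "y", c("x1", "x4"), entry_p = 1),
               "collinearity")
  expect_error(fit_stepwise(data.frame(y = c(1, NA), x = c(1, 2)), "y", "x"),
               "missing")
})

test_that("collinearity check flags strongly correlated predictor pairs", {
  set.seed(5)
  x <- rnorm(100)
  d <- data.frame(a = x, b = rnorm(100), dup = x + rnorm(100, sd = 1e-8))
  res <- collinearity_check(d)
  expect_equal(nrow(res$flagged), 1)
  expect_setequal(unlist(res$flagged[, 1:2]), c("a", "dup"))
  ortho <- data.frame(a = rep(c(-1, 1), 50), b = rep(c(-1, 1), each = 50))
  expect_equal(nrow(collinearity_check(ortho)$flagged), 0)
  expect_error(collinearity_check(data.frame(a = rep(1, 5), b = 1:5)),
               "constant")
  # the generator couples effort ratings to SNR strongly enough to flag
  cells <- simulate_latent_cells("rau_on_srle", seed = 3)
  cc <- collinearity_check(cells[, c("snr_re_srt", "srle_rank_individual")])
  expect_equal(nrow(cc$flagged), 1)
  expect_lt(cc$r["snr_re_srt", "srle_rank_individual"], -0.7)
})

test_that("per-participant correlations recover exact and null relations", {
  ids <- rep(letters[1:6], each = 10)
  x <- with_fixture_seed(2, stats::rnorm(60))
  res <- per_participant_pearson(x, -x, ids)
  expect_equal(res$per_participant$r, rep(-1, 6))
  expect_equal(res$summary$mean, -1)
  y <- with_fixture_seed(3, stats::rnorm(60))
  null_res <- per_participant_pearson(x, y, ids)
  expect_lt(abs(null_res$summary$mean), 0.35)
  # zero-variance participants are flagged and excluded from the summary
  x2 <- x; x2[ids == "a"] <- 1
  fl <- per_participant_pearson(x2, y, ids)
  expect_true(fl$per_participant$flagged[fl$per_participant$participant == "a"])
  expect_equal(fl$summary$n_flagged, 1)
})

test_that("basic test wrappers behave on degenerate and shifted inputs", {
  g <- rep(c("A", "B"), each = 20)
  v <- rep(1:20, 2)
  tt <- group_ttest(v, g)
  expect_equal(unname(tt$statistic), 0)
  expect_equal(tt$p.value, 1)
  v2 <- c(rnorm(200), rnorm(200) + 3)
  expect_lt(group_ttest(v2, rep(c("A", "B"), each = 200))$p.value, 1e-3)
  expect_equal(bonferroni(rep(0.01, 5)), rep(0.05, 5))
  # repeated-measures ANOVA detects a within-participant effect
  subj <- rep(1:10, each = 3)
  cond <- rep(c("c1", "c2", "c3"), 10)
  val <- with_fixture_seed(4, stats::rnorm(30, sd = 0.2) +
                                rep(stats::rnorm(10), each = 3)) +
    ifelse(cond == "c3", 2, 0)
  ra <- rm_anova(val, cond, subj)
  expect_lt(ra$p, 1e-4)
  expect_equal(ra$df1, 2)
})
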