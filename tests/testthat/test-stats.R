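test_that("Fisher's exact test reproduces the printed two-group p-values", {
  # counts: controls (n=5) vs AF (n=10); rows = factor yes/no
  cases <- list(
    hypertension = list(tab = matrix(c(1, 4, 2, 8), 2), p = 1.00),
    diabetes     = list(tab = matrix(c(1, 4, 0, 10), 2), p = 0.33),
    noac         = list(tab = matrix(c(0, 5, 5, 5), 2), p = 0.10),
    vka          = list(tab = matrix(c(0, 5, 2, 8), 2), p = 0.52)
  )
  for (nm in names(cases)) {
    res <- fisher_exact(cases[[nm]]$tab, variable = nm)
    expect_equal(round(res$p_value, 2), cases[[nm]]$p)
    expect_equal(res$test, "fisher")
  }
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)),
               class = "la_parameter_error")
})

test_that("continuous comparisons pick the right test and direction", {
  set.seed(31)
  a <- rnorm(10, 10, 1)
  # identical samples: no evidence of difference
  same_t <- compare_continuous(a, a, method = "t")
  expect_equal(same_t$statistic, 0)
  expect_equal(same_t$p_value, 1)
  same_w <- compare_continuous(a, a, method = "mann_whitney")
  expect_gt(same_w$p_value, 0.99)

  # clearly separated groups
  b <- rnorm(10, 0, 0.5)
  expect_lt(compare_continuous(a, b, method = "t")$p_value, 0.05)
  expect_lt(compare_continuous(a, b, method = "mann_whitney")$p_value, 0.05)

  # auto gates on Shapiro-Wilk normality
  skew <- c(rep(1, 12), 50, 80, 120)
  auto_skew <- compare_continuous(skew, skew + 1, method = "auto")
  expect_equal(auto_skew$test, "mann_whitney")
  auto_norm <- compare_continuous(a, b, method = "auto")
  expect_equal(auto_norm$test, "t")

  expect_error(compare_continuous(1, c(1, 2)), class = "la_sample_error")
})

test_that("simulated stasis comparison at study sample sizes has the power a Monte-Carlo oracle predicts", {
  # control 27.8 +/- 7.9 (n=5) vs AF 43.2 +/- 10.8 (n=9), Welch t
  set.seed(77)
  n_rep <- 2000
  rej <- 0L
  for (i in seq_len(n_rep)) {
    a <- rnorm(5, 27.8, 7.9)
    b <- rnorm(9, 43.2, 10.8)
    if (compare_continuous(a, b, method = "t")$p_value < 0.05) rej <- rej + 1L
  }
  power_impl <- rej / n_rep
  # independent oracle: direct Monte-Carlo of the Welch statistic
  set.seed(78)
  rej_o <- 0L
  for (i in seq_len(n_rep)) {
    a <- rnorm(5, 27.8, 7.9)
    b <- rnorm(9, 43.2, 10.8)
    se <- sqrt(var(a) / 5 + var(b) / 9)
    df <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 9)^2 / 8)
    tt <- (mean(a) - mean(b)) / se
    if (2 * pt(-abs(tt), df) < 0.05) rej_o <- rej_o + 1L
  }
  expect_lt(abs(power_impl - rej_o / n_rep), 0.03)
})

test_that("Spearman correlation handles perfect and inverse monotone relations", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_error(spearman_cor(1:4, 1:5), class = "la_parameter_error")
  expect_error(spearman_cor(1:2, 1:2), class = "la_sample_error")
})

test_that("paired t-test conventions and sign-flip oracle agree", {
  set.seed(41)
  x <- rnorm(10, 20, 3)
  same <- paired_t(x, x)
  expect_equal(same$p_value, 1)
  shifted <- paired_t(x, x + 3 + rnorm(10, 0, 0.5))
  expect_lt(shifted$p_value, 0.05)
  expect_gt(shifted$statistic, 0)

  # exact sign-flip permutation oracle on n = 8 pairs
  set.seed(42)
  before <- rnorm(8, 10, 2)
  after <- before + 1.2 + rnorm(8, 0, 1)
  d <- after - before
  tstat <- function(dd) mean(dd) / (sd(dd) / sqrt(length(dd)))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  perm_p <- mean(apply(signs, 1, function(s) abs(tstat(s * d))) >=
                   abs(tstat(d)) - 1e-12)
  res <- paired_t(before, after)
  expect_equal(res$p_value < 0.05, perm_p < 0.05)
  expect_equal(sign(res$statistic), sign(mean(d)))
})

test_that("ICC(A,1) recovers agreement structure", {
  # identical raters agree perfectly
  x <- c(1, 2, 3, 4, 5, 6, 7)
  perfect <- icc_absolute_agreement(cbind(x, x))
  expect_equal(perfect$icc, 1)

  # planted variance ratio 97:3 yields ICC near 0.97
  set.seed(51)
  iccs <- replicate(30, {
    truth <- rnorm(40, 0, sqrt(0.97))
    icc_absolute_agreement(cbind(truth + rnorm(40, 0, sqrt(0.03)),
                                 truth + rnorm(40, 0, sqrt(0.03))))$icc
  })
  expect_lt(abs(mean(iccs) - 0.97), 0.05)

  # independent ratings: ICC near zero, CI covers zero almost always
  set.seed(52)
  cover <- replicate(50, {
    r <- icc_absolute_agreement(cbind(rnorm(20), rnorm(20)))
    r$ci[1] <= 0 && r$ci[2] >= 0
  })
  expect_gte(mean(cover), 0.9)

  expect_error(icc_absolute_agreement(cbind(1:3, 1:3)),
               class = "la_sample_error")
  expect_error(icc_absolute_agreement(cbind(c(1, NA, 3, 4, 5), 1:5)),
               class = "la_parameter_error")
})

test_that("CHA2DS2-VASc sums the published point table", {
  expect_equal(cha2ds2_vasc(), 0)
  expect_equal(cha2ds2_vasc(female = TRUE, age_65_74 = TRUE), 2)
  # 66-year-old woman with hypertension
  expect_equal(cha2ds2_vasc(hypertension = TRUE, age_65_74 = TRUE,
                            female = TRUE), 3)
  expect_equal(cha2ds2_vasc(chf = TRUE, hypertension = TRUE, age_ge_75 = TRUE,
                            diabetes = TRUE, stroke_tia = TRUE,
                            vascular = TRUE, female = TRUE), 9)
  expect_error(cha2ds2_vasc(age_ge_75 = TRUE, age_65_74 = TRUE),
               class = "la_parameter_error")
})

test_that("group report tables summarise, test and respect label symmetry", {
  set.seed(61)
  df <- data.frame(group = rep(c("control", "af"), each = 8),
                   vel = c(rnorm(8, 16.7, 2), rnorm(8, 13.1, 2)),
                   stasis = c(rnorm(8, 28, 8), rnorm(8, 43, 10)))
  rep2 <- build_report(df)
  expect_setequal(rep2$variable, c("vel", "stasis"))
  expect_true(all(rep2$p_value >= 0 & rep2$p_value <= 1))

  # swapping labels leaves p-values unchanged
  df_swap <- df
  df_swap$group <- ifelse(df$group == "control", "af", "control")
  rep_swap <- build_report(df_swap)
  expect_equal(rep_swap$p_value, rep2$p_value, tolerance = 1e-12)

  # single group: summaries only
  rep1 <- build_report(df[df$group == "control", ])
  expect_true(all(is.na(rep1$p_value)))
  expect_error(build_report(df, group_col = "nope"),
               class = "la_parameter_error")
})
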