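aov_icc_oracle <- function(x) {
  # independent two-way ANOVA route via stats::aov
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(
    value = as.numeric(x),
    target = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(value ~ target + rater, data = df))[[1]]
  msr <- tab["target", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

test_that("ICC(2,1) matches a from-first-principles ANOVA oracle", {
  set.seed(42)
  for (i in 1:100) {
    subj <- rnorm(30, 0, runif(1, 0.5, 3))
    x <- cbind(subj + rnorm(30), subj + rnorm(1, 0, 0.5) + rnorm(30))
    fit <- icc_2_1(x)
    expect_equal(fit$icc, aov_icc_oracle(x), tolerance = 1e-10)
    expect_true(fit$p_value > 0 && fit$p_value <= 1)
  }
})

test_that("perfect agreement gives ICC of exactly 1", {
  x <- cbind(1:10, 1:10)
  fit <- icc_2_1(x)
  expect_equal(fit$icc, 1)
  expect_identical(fit$category, "excellent")
})

test_that("frozen reference values (two-way random effects, absolute agreement) are reproduced", {
  tabs <- utils::read.csv(test_path("fixtures", "icc_tables.csv"))
  expected <- utils::read.csv(test_path("fixtures", "icc_expected.csv"))
  for (t in unique(tabs$table)) {
    x <- as.matrix(tabs[tabs$table == t, c("r1", "r2")])
    fit <- icc_2_1(x)
    ex <- expected[expected$table == t, ]
    expect_equal(fit$icc, ex$icc, tolerance = 1e-6)
    expect_equal(fit$f_stat, ex$f, tolerance = 1e-6)
    expect_equal(fit$p_value, ex$pval, tolerance = 1e-6)
    # reference interval is reported to two decimals
    expect_equal(fit$ci95[1], ex$ci_lo, tolerance = 0.006)
    expect_equal(fit$ci95[2], ex$ci_hi, tolerance = 0.006)
  }
})

test_that("independent noise drives ICC to zero in expectation", {
  set.seed(8)
  vals <- replicate(200, {
    x <- cbind(rnorm(30, 0, 1), rnorm(30, 0, 1))
    icc_2_1(x)$icc
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("ICC is invariant to location/scale changes and rater order", {
  set.seed(3)
  subj <- rnorm(25, 5, 2)
  x <- cbind(subj + rnorm(25, 0, 0.7), subj + 0.3 + rnorm(25, 0, 0.7))
  base <- icc_2_1(x)$icc
  expect_equal(icc_2_1(x + 100)$icc, base, tolerance = 1e-12)
  expect_equal(icc_2_1(x * 7)$icc, base, tolerance = 1e-12)
  expect_equal(icc_2_1(x[, 2:1])$icc, base, tolerance = 1e-12)
})

test_that("the estimator recovers the theoretical ICC of a two-way random-effects model", {
  set.seed(19)
  s2s <- 4; s2r <- 0.25; s2e <- 1
  theo <- s2s / (s2s + s2r + s2e)
  est <- replicate(500, {
    subj <- rnorm(30, 0, sqrt(s2s))
    rat <- rnorm(2, 0, sqrt(s2r))
    x <- cbind(subj + rat[1] + rnorm(30, 0, sqrt(s2e)),
               subj + rat[2] + rnorm(30, 0, sqrt(s2e)))
    icc_2_1(x)$icc
  })
  expect_equal(mean(est), theo, tolerance = 0.03)
})

test_that("a constant table yields an explicit degenerate result, not NaN", {
  fit <- icc_2_1(matrix(5, 10, 2))
  expect_true(fit$degenerate)
  expect_true(is.na(fit$icc))
  expect_error(icc_2_1(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(icc_2_1(matrix(1:2, 1, 2)), "at least")
})

test_that("agreement categories follow the documented bins", {
  expect_identical(categorize_icc(0.80), "good")
  expect_identical(categorize_icc(0.49999), "poor")
  expect_identical(categorize_icc(0.95), "excellent")
  expect_identical(categorize_icc(c(0.5, 0.7499, 0.75, 0.9, 0.90001)),
                   c("moderate", "moderate", "good", "good", "excellent"))
  expect_error(categorize_icc(1.2), "exceed")
})

test_that("tidy and glance return one-row summaries", {
  x <- cbind(rnorm(20, 10), rnorm(20, 10))
  fit <- icc_2_1(x)
  td <- generics::tidy(fit)
  expect_identical(nrow(td), 1L)
  expect_true(all(c("icc", "conf.low", "conf.high", "p.value") %in% names(td)))
  gl <- generics::glance(fit)
  expect_identical(gl$n, 20L)
  expect_identical(gl$k, 2L)
})

test_that("per-family summaries validate the manifest and aggregate correctly", {
  man <- feature_manifest()
  icc_tbl <- man
  icc_tbl$icc <- 0.8
  icc_tbl$category <- "good"
  fam <- feature_group_summary(icc_tbl)
  expect_identical(fam$n_features,
                   c(18L, 14L, 24L, 16L, 16L, 5L, 14L))
  expect_true(all(fam$median_icc == 0.8))
  expect_true(all(fam$q1_icc == 0.8 & fam$q3_icc == 0.8))
  set.seed(4)
  icc_tbl$icc <- runif(107)
  fam2 <- feature_group_summary(icc_tbl)
  expect_true(all(fam2$q1_icc <= fam2$median_icc &
                    fam2$median_icc <= fam2$q3_icc))
  expect_error(feature_group_summary(icc_tbl[-5, ]),
               icc_tbl$feature[5])
})

test_that("pooled group means are count-weighted", {
  expect_equal(round(pool_group_means(data.frame(mean = c(73.5, 73.9),
                                                 n = c(140, 30))), 1),
               73.6)
  expect_equal(pool_group_means(data.frame(mean = c(4, 4, 4),
                                           n = c(1, 5, 9))), 4)
  expect_equal(pool_group_means(list(c(0, 10), c(10, 10))), 5)
  expect_error(pool_group_means(list()), "Empty")
  expect_error(pool_group_means(data.frame(mean = 1, n = 0)), ">= 1")
})
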