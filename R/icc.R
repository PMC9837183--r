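#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, where MSR, MSC and
#' MSE are the between-target, between-rater and residual mean squares of
#' the two-way ANOVA without replication. The significance test is
#' F = MSR/MSE with (n-1, (n-1)(k-1)) degrees of freedom; the 95%
#' confidence interval follows the F-based (Shrout-Fleiss / McGraw-Wong)
#' construction for absolute agreement.
#'
#' @param table Numeric matrix or data frame, rows = targets (n >= 2),
#'   columns = raters (k >= 2), no missing cells.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return An `icc_fit` object: list with `icc`, `ms_rows`, `ms_cols`,
#'   `ms_error`, `f_stat`, `df1`, `df2`, `p_value`, `ci95`, `category`,
#'   `n`, `k`, `degenerate`.
#' @export
icc_2_1 <- function(table, conf_level = 0.95) {
  x <- as.matrix(table)
  if (!is.numeric(x)) abort("Ratings must be numeric.")
  if (anyNA(x)) abort("Ratings table contains missing cells.")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) abort("Need at least 2 targets and 2 raters.")
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  degenerate <- ss_tot < .Machine$double.eps * max(1, abs(grand))^2
  if (degenerate) {
    res <- list(icc = NA_real_, ms_rows = msr, ms_cols = msc, ms_error = mse,
                f_stat = NA_real_, df1 = n - 1, df2 = (n - 1) * (k - 1),
                p_value = NA_real_, ci95 = c(NA_real_, NA_real_),
                category = NA_character_, n = n, k = k, degenerate = TRUE)
    return(structure(res, class = "icc_fit"))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  f_stat <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p_value <- pf(f_stat, df1, df2, lower.tail = FALSE)
  alpha <- 1 - conf_level
  ci <- c(NA_real_, NA_real_)
  if (mse > 0 && icc < 1) {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    # qf warns about limited accuracy for the huge synthetic df of
    # near-perfect agreement; far below the precision needed here
    f1 <- suppressWarnings(qf(1 - alpha / 2, n - 1, v))
    f2 <- suppressWarnings(qf(1 - alpha / 2, v, n - 1))
    lower <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    ci <- c(lower, upper)
  } else if (icc >= 1) {
    ci <- c(1, 1)
  }
  structure(
    list(icc = icc, ms_rows = msr, ms_cols = msc, ms_error = mse,
         f_stat = f_stat, df1 = df1, df2 = df2, p_value = p_value,
         ci95 = ci, category = categorize_icc(icc), n = n, k = k,
         degenerate = FALSE),
    class = "icc_fit"
  )
}

#' @export
print.icc_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<icc_fit> degenerate (constant ratings table)\n")
  } else {
    cat(sprintf(
      "<icc_fit> ICC(2,1) = %.3f [%.3f, %.3f] (%s); F(%d,%d) = %.2f, p = %.3g\n",
      x$icc, x$ci95[1], x$ci95[2], x$category, x$df1, x$df2, x$f_stat,
      x$p_value))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, conf.low = x$ci95[1], conf.high = x$ci95[2],
    category = x$category, statistic = x$f_stat, df1 = x$df1, df2 = x$df2,
    p.value = x$p_value
  )
}

#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, ms_rows = x$ms_rows, ms_cols = x$ms_cols,
                 ms_error = x$ms_error, degenerate = x$degenerate)
}

#' Agreement category of an ICC estimate
#'
#' Bins: poor (< 0.50), moderate (0.50 to < 0.75), good (0.75 to 0.90),
#' excellent (> 0.90). The published interval endpoints overlap; the
#' package fixes half-open assignment at 0.75 (favouring "good") and a
#' closed upper bound at 0.90 ("excellent" strictly above).
#'
#' @param value ICC estimate(s), each <= 1.
#' @return Character vector of categories.
#' @export
categorize_icc <- function(value) {
  if (any(value > 1 + 1e-12, na.rm = TRUE)) abort("ICC values cannot exceed 1.")
  out <- rep(NA_character_, length(value))
  out[value < 0.5] <- "poor"
  out[value >= 0.5 & value < 0.75] <- "moderate"
  out[value >= 0.75 & value <= 0.9] <- "good"
  out[value > 0.9] <- "excellent"
  out
}

#' Per-feature ICC(2,1) between two mask sources
#'
#' @param features Tidy feature table with columns `case_id`,
#'   `mask_source` (exactly two levels, e.g. manual/auto), `family`,
#'   `feature`, `value`.
#' @return Tibble with one row per feature: `family`, `feature`, `icc`,
#'   `conf.low`, `conf.high`, `statistic`, `p.value`, `category`,
#'   `degenerate`.
#' @export
feature_icc <- function(features) {
  req <- c("case_id", "mask_source", "family", "feature", "value")
  if (!all(req %in% names(features))) {
    abort(sprintf("`features` must have columns: %s.", paste(req, collapse = ", ")))
  }
  sources <- unique(features$mask_source)
  if (length(sources) != 2) abort("Exactly two mask sources are required.")
  features |>
    tidyr::pivot_wider(id_cols = c("family", "feature", "case_id"),
                       names_from = "mask_source", values_from = "value") |>
    dplyr::group_by(.data$family, .data$feature) |>
    dplyr::group_modify(function(df, key) {
      fit <- icc_2_1(as.matrix(df[, sources]))
      tibble::tibble(icc = fit$icc, conf.low = fit$ci95[1],
                     conf.high = fit$ci95[2], statistic = fit$f_stat,
                     p.value = fit$p_value, category = fit$category,
                     degenerate = fit$degenerate)
    }) |>
    dplyr::ungroup()
}

#' Per-family summary of feature ICCs (median and IQR)
#'
#' Validates that every family carries its full complement of features
#' (18/14/24/16/16/5/14) before summarizing.
#'
#' @param icc_table Output of [feature_icc()] (all 107 features present).
#' @return Tibble: `family`, `n_features`, `median_icc`, `q1_icc`,
#'   `q3_icc`.
#' @export
feature_group_summary <- function(icc_table) {
  man <- feature_manifest()
  have <- paste(icc_table$family, icc_table$feature)
  missing <- setdiff(paste(man$family, man$feature), have)
  if (length(missing) > 0) {
    abort(sprintf("Missing features: %s.", paste(missing, collapse = ", ")))
  }
  icc_table |>
    dplyr::group_by(family = factor(.data$family, levels = unique(man$family))) |>
    dplyr::summarise(
      n_features = dplyr::n(),
      median_icc = median(.data$icc),
      q1_icc = q13(.data$icc)[1],
      q3_icc = q13(.data$icc)[2],
      .groups = "drop"
    ) |>
    dplyr::mutate(family = as.character(.data$family))
}

#' Pooled mean of group means
#'
#' Count-weighted mean, e.g. pooling per-dataset cohort mean ages into the
#' overall cohort mean.
#'
#' @param groups Data frame with columns `mean` and `n`, or a list of
#'   `c(mean, n)` pairs.
#' @return Pooled mean.
#' @export
pool_group_means <- function(groups) {
  if (is.data.frame(groups)) {
    m <- groups$mean; n <- groups$n
  } else {
    if (length(groups) == 0) abort("Empty group list.")
    m <- vapply(groups, `[[`, numeric(1), 1)
    n <- vapply(groups, `[[`, numeric(1), 2)
  }
  if (length(m) == 0) abort("Empty group list.")
  if (any(n < 1)) abort("All group sizes must be >= 1.")
  sum(m * n) / sum(n)
}
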