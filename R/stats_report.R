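# Group-level statistical layer: two-group comparisons, categorical tests,
# correlation, paired contrasts, inter-observer agreement, stroke-risk
# scoring, and summary table generation.

summarise_sample <- function(x, style = c("mean_sd", "median_iqr")) {
  style <- match.arg(style)
  if (style == "mean_sd") {
    sprintf("%.3g ± %.3g", mean(x), sd(x))
  } else {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    sprintf("%.3g [%.3g-%.3g]", q[2], q[1], q[3])
  }
}

group_comparison <- function(variable, summaries, test, statistic, p_value) {
  structure(list(variable = variable, summaries = summaries, test = test,
                 statistic = statistic, p_value = p_value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s vs %s (%s, p = %.3g)\n", x$variable,
              x$summaries[1], x$summaries[2], x$test, x$p_value))
  invisible(x)
}

both_normal <- function(a, b, alpha = 0.05) {
  ok <- function(x) {
    if (length(x) < 3 || sd(x) == 0) return(TRUE)  # normality unverifiable
    shapiro.test(x)$p.value > alpha
  }
  ok(a) && ok(b)
}

#' Two-group comparison of a continuous variable
#'
#' `auto` uses an independent-samples t-test when both groups pass a
#' Shapiro-Wilk normality check at alpha = 0.05, otherwise a Mann-Whitney
#' U test. The t-test is Welch by default.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param method `"auto"`, `"t"` or `"mann_whitney"`.
#' @param welch use the Welch (unequal-variance) t statistic.
#' @param variable label carried into the result.
#' @return a `group_comparison` with two-sided p-value.
#' @export
compare_continuous <- function(a, b, method = c("auto", "t", "mann_whitney"),
                               welch = TRUE, variable = "value") {
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2) {
    stop_la("la_sample_error", "each group needs at least 2 observations")
  }
  if (method == "auto") {
    method <- if (both_normal(a, b)) "t" else "mann_whitney"
  }
  if (method == "t") {
    if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
      return(group_comparison(variable,
                              c(summarise_sample(a), summarise_sample(b)),
                              "t", 0, 1))
    }
    tt <- t.test(a, b, var.equal = !welch)
    group_comparison(variable, c(summarise_sample(a), summarise_sample(b)),
                     "t", unname(tt$statistic), tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    group_comparison(variable,
                     c(summarise_sample(a, "median_iqr"),
                       summarise_sample(b, "median_iqr")),
                     "mann_whitney", unname(wt$statistic), wt$p.value)
  }
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric probabilities no
#' larger than that of the observed table.
#'
#' @param table 2x2 matrix of nonnegative integer counts
#'   (rows = outcome yes/no, columns = groups).
#' @param variable label carried into the result.
#' @return a `group_comparison`.
#' @export
fisher_exact <- function(table, variable = "count") {
  if (!is.matrix(table) || any(dim(table) != 2) || any(table < 0) ||
      any(table != round(table))) {
    stop_la("la_parameter_error", "need a 2x2 matrix of nonnegative counts")
  }
  if (any(rowSums(table) + colSums(table) == 0)) {
    stop_la("la_parameter_error", "both margins must be positive")
  }
  ft <- fisher.test(table)
  n <- colSums(table)
  group_comparison(variable,
                   sprintf("%d/%d", table[1, ], n),
                   "fisher", unname(ft$estimate), ft$p.value)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; two-sided asymptotic
#' p-value.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) {
    stop_la("la_parameter_error", "x and y must have equal length")
  }
  if (length(x) < 3) stop_la("la_sample_error", "need at least 3 pairs")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Paired t-test
#'
#' Two-sided paired t on the differences `after - before`. Degenerate
#' zero-variance differences resolve by convention: all-zero differences
#' give p = 1; a constant nonzero shift gives p = 0.
#'
#' @param before,after paired numeric samples of equal length (n >= 2).
#' @param variable label carried into the result.
#' @return a `group_comparison`.
#' @export
paired_t <- function(before, after, variable = "value") {
  if (length(before) != length(after) || length(before) < 2) {
    stop_la("la_sample_error", "need paired samples of equal length >= 2")
  }
  d <- after - before
  if (sd(d) == 0) {
    p <- if (mean(d) == 0) 1 else 0
    stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(group_comparison(variable,
                            c(summarise_sample(before), summarise_sample(after)),
                            "paired_t", stat, p))
  }
  tt <- t.test(after, before, paired = TRUE)
  group_comparison(variable,
                   c(summarise_sample(before), summarise_sample(after)),
                   "paired_t", unname(tt$statistic), tt$p.value)
}

#' Intraclass correlation, two-way random effects, absolute agreement,
#' single measures
#'
#' ICC(A,1) from the two-way ANOVA mean squares, with the F-based 95%
#' confidence interval.
#'
#' @param ratings numeric matrix, subjects x 2 raters, no missing cells.
#' @param conf_level confidence level for the interval.
#' @return object of class `agreement_result`: `icc`, `ci` (length 2),
#'   `model`.
#' @export
icc_absolute_agreement <- function(ratings, conf_level = 0.95) {
  if (!is.matrix(ratings) || ncol(ratings) != 2 || anyNA(ratings)) {
    stop_la("la_parameter_error",
            "ratings must be a complete subjects x 2 matrix")
  }
  n <- nrow(ratings)
  if (n < 5) stop_la("la_sample_error", "need at least 5 subjects")
  k <- ncol(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  grand <- mean(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  if (icc >= 1 || (msc == 0 && mse == 0)) {
    ci <- c(1, 1)
    icc <- min(icc, 1)
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lower, upper)
  }
  structure(list(icc = icc, ci = ci,
                 model = "two-way random, absolute agreement, single measures"),
            class = "agreement_result")
}

#' CHA2DS2-VASc stroke-risk score
#'
#' Standard additive point table: congestive heart failure / LV
#' dysfunction (1), hypertension (1), age >= 75 (2), diabetes (1),
#' prior stroke/TIA (2), vascular disease (1), age 65-74 (1),
#' female sex (1); total 0-9.
#'
#' @param chf,hypertension,diabetes,stroke_tia,vascular,female logical
#'   component flags.
#' @param age_ge_75,age_65_74 mutually exclusive age-category flags.
#' @return integer total points.
#' @export
cha2ds2_vasc <- function(chf = FALSE, hypertension = FALSE,
                         age_ge_75 = FALSE, diabetes = FALSE,
                         stroke_tia = FALSE, vascular = FALSE,
                         age_65_74 = FALSE, female = FALSE) {
  if (age_ge_75 && age_65_74) {
    stop_la("la_parameter_error", "age categories are mutually exclusive")
  }
  sum(chf, hypertension, 2 * age_ge_75, diabetes, 2 * stroke_tia,
      vascular, age_65_74, female)
}

#' Two-group summary and comparison table
#'
#' For each metric column, emits per-group summaries (mean +/- sd when both
#' groups pass the normality check, otherwise median [IQR]), the test used
#' and its two-sided p-value. With a single group only summaries are
#' produced.
#'
#' @param df data frame with one row per subject.
#' @param group_col name of the group-label column.
#' @param value_cols metric columns to summarise; defaults to all numeric
#'   columns.
#' @return data frame with columns `variable`, one summary column per
#'   group, `test`, `p_value`.
#' @export
build_report <- function(df, group_col = "group", value_cols = NULL) {
  if (!group_col %in% names(df)) {
    stop_la("la_parameter_error", "missing group column '%s'", group_col)
  }
  groups <- unique(df[[group_col]])
  if (any(table(df[[group_col]]) == 0) || length(groups) < 1) {
    stop_la("la_parameter_error", "each group needs at least one subject")
  }
  if (is.null(value_cols)) {
    value_cols <- names(df)[vapply(df, is.numeric, logical(1))]
    value_cols <- setdiff(value_cols, group_col)
  }
  rows <- lapply(value_cols, function(v) {
    xs <- split(df[[v]], df[[group_col]])[as.character(groups)]
    if (length(groups) == 2) {
      cmp <- compare_continuous(xs[[1]], xs[[2]], method = "auto",
                                variable = v)
      out <- data.frame(variable = v, g1 = cmp$summaries[1],
                        g2 = cmp$summaries[2], test = cmp$test,
                        p_value = cmp$p_value)
    } else {
      style <- if (both_normal(xs[[1]], xs[[1]])) "mean_sd" else "median_iqr"
      out <- data.frame(variable = v, g1 = summarise_sample(xs[[1]], style),
                        test = NA_character_, p_value = NA_real_)
    }
    out
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "g1"] <- as.character(groups[1])
  if (length(groups) == 2) {
    names(out)[names(out) == "g2"] <- as.character(groups[2])
  }
  rownames(out) <- NULL
  out
}
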