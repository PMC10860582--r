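#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation with the Fisher z-transform 95% CI (standard
#' error `1/sqrt(n - 3)`) and a two-sided P from the t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of paired measurements (n >= 4).
#' @param level Confidence level; default 0.95.
#' @return A one-row tibble: `r`, `r_lo`, `r_hi`, `p`, `n`.
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_ci: zero variance; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, conf.level = level)
  tibble::tibble(r = unname(ct$estimate), r_lo = ct$conf.int[1],
                 r_hi = ct$conf.int[2], p = ct$p.value, n = length(x))
}

#' Intraclass correlation ICC(2,1) with F-based confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measures intraclass
#' correlation between two measurement methods, computed from the two-way
#' ANOVA mean squares (subjects x raters), with the standard F-based
#' confidence interval and the F test of `MSR / MSE`.
#'
#' @inheritParams pearson_ci
#' @return A one-row tibble: `icc`, `icc_lo`, `icc_hi`, `p`, `n`.
#' @export
icc_ci <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x); k <- 2
  dat <- cbind(x, y)
  if (stats::sd(dat) == 0)
    stop("icc_ci: all measurements identical; ICC undefined", call. = FALSE)
  grand <- mean(dat)
  row_m <- rowMeans(dat); col_m <- colMeans(dat)
  ssr <- k * sum((row_m - grand)^2)           # between subjects
  ssc <- n * sum((col_m - grand)^2)           # between raters
  sse <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)  # residual
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # F-based CI (Shrout & Fleiss / McGraw & Wong, ICC(A,1))
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  alpha <- 1 - level
  f_lo <- stats::qf(1 - alpha / 2, n - 1, v)
  f_hi <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_lo * mse) /
    (f_lo * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_hi * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_hi * msr)
  p <- stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  tibble::tibble(icc = icc, icc_lo = lo, icc_hi = hi, p = p, n = n)
}

#' Ordinary least-squares line
#'
#' @inheritParams pearson_ci
#' @return A one-row tibble: `slope`, `intercept`, `n`.
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0) stop("ols_fit: constant x", call. = FALSE)
  co <- stats::coef(stats::lm(y ~ x))
  tibble::tibble(slope = unname(co[2]), intercept = unname(co[1]),
                 n = length(x))
}

#' Bland-Altman agreement with percentile limits
#'
#' Differences are oriented `estimate - reference`, so positive means
#' overestimation. Limits are the empirical 2.5th and 97.5th percentiles of
#' the differences (linear interpolation between order statistics), not
#' normal-theory limits.
#'
#' @param estimate,reference Paired volumes (mL), n >= 3.
#' @return A one-row tibble of class rows: `mean_diff`, `lo`, `hi`, `n`.
#' @export
bland_altman <- function(estimate, reference) {
  stopifnot(length(estimate) == length(reference), length(estimate) >= 3)
  d <- estimate - reference
  q <- stats::quantile(d, c(0.025, 0.975), type = 7, names = FALSE)
  out <- tibble::tibble(mean_diff = mean(d), lo = q[1], hi = q[2],
                        n = length(d))
  attr(out, "differences") <- d
  attr(out, "means") <- (estimate + reference) / 2
  class(out) <- c("bland_altman", class(out))
  out
}

#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test and reports whether normality is retained at
#' `alpha`; a `FALSE` gate justifies medians/IQR and rank tests for the
#' volume data downstream.
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @param alpha Significance level; default 0.05.
#' @return A one-row tibble: `p`, `normal` (logical), `n`.
#' @export
shapiro_wilk_gate <- function(values, alpha = 0.05) {
  if (length(values) < 3 || length(values) > 5000)
    stop("shapiro_wilk_gate: n must be in [3, 5000]", call. = FALSE)
  p <- stats::shapiro.test(values)$p.value
  tibble::tibble(p = p, normal = p >= alpha, n = length(values))
}

#' Kruskal-Wallis comparison of group medians
#'
#' Rank-based H with tie correction and a chi-square P on k - 1 degrees of
#' freedom.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length.
#' @return A one-row tibble: `statistic` (H), `p`, `df`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  stopifnot(length(values) == length(groups), length(values) >= 3)
  if (length(unique(values)) < 2)
    stop("kruskal_wallis: all values identical", call. = FALSE)
  kt <- stats::kruskal.test(values, factor(groups))
  tibble::tibble(statistic = unname(kt$statistic), p = kt$p.value,
                 df = unname(kt$parameter), n = length(values))
}

#' Median and interquartile range
#'
#' Linear-interpolation percentile definition (order-statistic
#' interpolation), pinned for reproducibility.
#'
#' @param values Numeric vector, n >= 1.
#' @return A one-row tibble: `median`, `q25`, `q75`, `n`.
#' @export
median_iqr <- function(values) {
  if (length(values) < 1) stop("median_iqr: empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(median = q[2], q25 = q[1], q75 = q[3], n = length(values))
}

#' Agreement between two volume series
#'
#' Convenience wrapper combining Pearson, ICC(2,1) and the OLS line for a
#' pair of volume columns in a cohort table.
#'
#' @param data A data frame.
#' @param estimate,reference Column names (strings) of the paired volumes.
#' @return A one-row tibble with the Pearson, ICC and OLS fields.
#' @export
agreement <- function(data, estimate = "cnn_volume_mL", reference = "fiv_mL") {
  x <- data[[estimate]]; y <- data[[reference]]
  dplyr::bind_cols(
    pearson_ci(x, y),
    dplyr::rename_with(icc_ci(x, y), ~ paste0("icc_", .x), -dplyr::starts_with("icc")) |>
      dplyr::select(-icc_n),
    dplyr::select(ols_fit(x, y), slope, intercept)
  )
}
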