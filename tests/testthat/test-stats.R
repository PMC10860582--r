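test_that("Pearson matches the product-moment oracle and handles exact relations", {
  set.seed(101)
  for (i in 1:10) {
    x <- rnorm(20); y <- 0.6 * x + rnorm(20)
    res <- pearson_ci(x, y)
    expect_equal(res$r, oracle_pearson(x, y), tolerance = 1e-12)
    expect_true(res$r_lo <= res$r && res$r <= res$r_hi)
  }
  x <- 1:10
  perfect <- pearson_ci(x, 2 * x)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-10)
  expect_equal(pearson_ci(x, -x)$r, -1)
  expect_error(pearson_ci(x, rep(1, 10)), "variance")
})

test_that("ICC(2,1) matches ANOVA mean-squares oracles", {
  x <- c(55, 60, 42, 75, 68, 50)
  y <- c(58, 55, 48, 80, 62, 57)
  res <- icc_ci(x, y)
  # frozen from an independent mean-squares evaluation of this table
  expect_equal(res$icc, 0.884080370942813, tolerance = 1e-12)
  # independent route: two-way ANOVA via aov()
  long <- data.frame(score = c(x, y),
                     subj = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(score ~ subj + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 6)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-12)
  expect_true(res$icc_lo <= res$icc && res$icc <= res$icc_hi)
})

test_that("ICC penalises systematic offset while Pearson does not", {
  set.seed(5)
  x <- rnorm(30, 50, 20)
  y <- x + 40
  expect_equal(icc_ci(x, x)$icc, 1)
  expect_lt(icc_ci(x, y)$icc, pearson_ci(x, y)$r)
  expect_error(icc_ci(rep(3, 6), rep(3, 6)), "identical")
})

test_that("Pearson is affine-invariant, ICC(2,1) is not, both are order-invariant", {
  set.seed(8)
  x <- rnorm(25, 60, 15); y <- 0.7 * x + rnorm(25, 10, 8)
  expect_equal(pearson_ci(3 * x + 5, y)$r, pearson_ci(x, y)$r, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(icc_ci(3 * x + 5, y)$icc, icc_ci(x, y)$icc)))
  o <- sample(25)
  expect_equal(pearson_ci(x[o], y[o])$r, pearson_ci(x, y)$r, tolerance = 1e-12)
  expect_equal(icc_ci(x[o], y[o])$icc, icc_ci(x, y)$icc, tolerance = 1e-12)
})

test_that("OLS matches the normal-equation oracle", {
  res <- ols_fit(c(0, 1), c(1, 3))
  expect_equal(res$slope, 2); expect_equal(res$intercept, 1)
  expect_equal(ols_fit(1:10, 1:10)$slope, 1)
  expect_equal(ols_fit(1:10, 1:10)$intercept, 0)
  set.seed(13)
  x <- rnorm(40); y <- 2.5 * x + 1 + rnorm(40)
  res <- ols_fit(x, y)
  ref <- oracle_ols(x, y)
  expect_equal(res$slope, unname(ref["slope"]), tolerance = 1e-10)
  expect_equal(res$intercept, unname(ref["intercept"]), tolerance = 1e-10)
  expect_error(ols_fit(rep(2, 5), 1:5), "constant")
})

test_that("Bland-Altman uses percentile limits and is translation-equivariant", {
  x <- c(1, 2, 3); eq <- bland_altman(x, x)
  expect_equal(eq$mean_diff, 0); expect_equal(eq$lo, 0); expect_equal(eq$hi, 0)
  # d = (-1, 0, 1): frozen type-7 percentile evaluation
  ba <- bland_altman(c(0, 2, 4), c(1, 2, 3))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$lo, -0.95); expect_equal(ba$hi, 0.95)
  set.seed(17)
  a <- rnorm(50, 40, 20); b <- rnorm(50, 35, 18)
  b0 <- bland_altman(a, b); b1 <- bland_altman(a + 7, b)
  expect_equal(b1$mean_diff, b0$mean_diff + 7)
  expect_equal(b1$lo, b0$lo + 7); expect_equal(b1$hi, b0$hi + 7)
  d <- a - b
  expect_equal(b0$lo, oracle_quantile(d, 0.025), tolerance = 1e-12)
  expect_equal(b0$hi, oracle_quantile(d, 0.975), tolerance = 1e-12)
})

test_that("median/IQR match a sort-based oracle", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5))$median, 3)
  one <- median_iqr(7)
  expect_equal(one$q25, 7); expect_equal(one$q75, 7)
  set.seed(23)
  v <- rlnorm(37, 3, 1)
  res <- median_iqr(v)
  expect_equal(res$median, oracle_quantile(v, 0.5), tolerance = 1e-12)
  expect_equal(res$q25, oracle_quantile(v, 0.25), tolerance = 1e-12)
  expect_equal(res$q75, oracle_quantile(v, 0.75), tolerance = 1e-12)
  expect_error(median_iqr(numeric(0)))
})

test_that("Kruskal-Wallis H matches the rank-formula oracle and a permutation P", {
  set.seed(29)
  v <- c(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  g <- rep(1:3, each = 8)
  res <- kruskal_wallis(v, g)
  expect_equal(res$statistic, oracle_kw_h(v, g), tolerance = 1e-10)
  expect_equal(res$p, pchisq(res$statistic, 2, lower.tail = FALSE))
  # H invariant to within-group reordering
  o <- c(sample(1:8), sample(9:16), sample(17:24))
  expect_equal(kruskal_wallis(v[o], g[o])$statistic, res$statistic)
  # extreme separation: H at the maximum for two groups of 3
  sep <- kruskal_wallis(c(1, 2, 3, 101, 102, 103), rep(1:2, each = 3))
  hs <- apply(utils::combn(6, 3), 2, function(i) {
    grp <- rep(2L, 6); grp[i] <- 1L
    oracle_kw_h(c(1, 2, 3, 101, 102, 103), grp)
  })
  expect_equal(sep$statistic, max(hs), tolerance = 1e-10)
  expect_equal(oracle_kw_perm_p(c(1, 2, 3), c(101, 102, 103)), 2 / 20)
  expect_error(kruskal_wallis(rep(1, 6), rep(1:2, 3)), "identical")
})

test_that("Shapiro-Wilk gate separates normal from uniform data", {
  set.seed(37)
  gates <- replicate(50, shapiro_wilk_gate(runif(200))$normal)
  expect_lt(mean(gates), 0.2)
  set.seed(38)
  gates_n <- replicate(50, shapiro_wilk_gate(rnorm(200))$normal)
  expect_gt(mean(gates_n), 0.8)
  expect_error(shapiro_wilk_gate(c(1, 2)), "n must")
})
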