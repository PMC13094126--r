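# independent enumeration oracle for the exact signed-rank p-value
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  tot <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(0:1), n)))
  v_all <- as.numeric(signs %*% r)
  mean(abs(v_all - tot / 2) >= abs(v_obs - tot / 2) - 1e-12)
}

test_that("exact signed-rank p for differences (1,2,3) is 0.25", {
  res <- paired_signed_rank(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$statistic, 6)
  expect_equal(res$p_value, 0.25)
  expect_equal(res$p_value, enumerate_signed_rank_p(c(1, 2, 3)))
  # base-R exact test agrees
  wt <- suppressWarnings(wilcox.test(c(1, 2, 3), exact = TRUE))
  expect_equal(res$p_value, wt$p.value)
})

test_that("signed-rank matches the base exact test on random tie-free samples", {
  set.seed(1)
  for (i in 1:10) {
    d <- round(rnorm(10, 0.3, 1), 3)
    d <- d[d != 0]
    res <- paired_signed_rank(d, numeric(length(d)))
    wt <- wilcox.test(d, exact = TRUE)
    expect_equal(res$p_value, wt$p.value, tolerance = 1e-12)
  }
})

test_that("signed-rank degenerates on identical pairs and is antisymmetric", {
  x <- c(1, 2, 3)
  expect_error(paired_signed_rank(x, x), "zero")
  set.seed(2)
  a <- rnorm(30); b <- a + rnorm(30, 0.4, 1)
  r1 <- paired_signed_rank(a, b)
  r2 <- paired_signed_rank(b, a)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$effect_size, -r2$effect_size, tolerance = 1e-12)
})

test_that("exact and normal-approximation p agree for moderate n", {
  set.seed(3)
  for (i in 1:5) {
    d <- rnorm(26, 0.2, 1)
    p_norm <- paired_signed_rank(d, numeric(26))$p_value
    p_exact <- wilcox.test(d, exact = TRUE, correct = FALSE)$p.value
    expect_lt(abs(p_norm - p_exact), 0.02)
  }
})

test_that("ANCOVA partial eta-squared matches a brute-force SS decomposition", {
  set.seed(4)
  n <- 160
  g <- rep(0:1, each = n / 2)
  covs <- data.frame(age = rnorm(n), edu = rnorm(n))
  y <- 0.5 * g + 0.3 * covs$age + rnorm(n)
  res <- ancova_partial_eta(y, g, covs)

  # brute force via explicit projections
  X_red <- cbind(1, as.matrix(covs))
  X_full <- cbind(X_red, g)
  rss <- function(X) {
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }
  ss_g <- rss(X_red) - rss(X_full)
  eta <- ss_g / (ss_g + rss(X_full))
  expect_equal(res$effect_size, eta, tolerance = 1e-10)
  f_ref <- (ss_g / 1) / (rss(X_full) / (n - 4))
  expect_equal(res$statistic, f_ref, tolerance = 1e-10)

  # car's type-III SS for the group term agrees
  dat <- data.frame(y = y, g = factor(g), covs)
  a3 <- car::Anova(lm(y ~ age + edu + g, data = dat), type = 3)
  expect_equal(ss_g, a3["g", "Sum Sq"], tolerance = 1e-8)
})

test_that("ANCOVA endpoints behave: null group and saturated group", {
  set.seed(5)
  n <- 100
  g <- rep(0:1, each = n / 2)
  covs <- data.frame(age = rnorm(n))
  y_null <- 0.8 * covs$age + rnorm(n)
  res <- ancova_partial_eta(y_null, g, covs)
  expect_lt(res$effect_size, 0.05)

  res_sat <- ancova_partial_eta(as.numeric(g), g)
  expect_equal(res_sat$effect_size, 1, tolerance = 1e-12)
  expect_error(ancova_partial_eta(y_null, rep(1, n), covs), "two")
})

test_that("Benjamini-Hochberg adjustment is reproduced with monotonicity", {
  set.seed(6)
  n <- 60
  f <- data.frame(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  y <- data.frame(y1 = rnorm(n))
  res <- bivariate_fdr_scan(f, y)
  expect_equal(res$adjusted_p, p.adjust(res$p_value, "BH"))
  expect_true(all(res$adjusted_p >= res$p_value - 1e-15))
  expect_true(all(res$adjusted_p <= 1))

  # the textbook example, via the same adjustment rule
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))

  res1 <- bivariate_fdr_scan(f["f1"], y)
  expect_equal(res1$adjusted_p, res1$p_value)
})

test_that("the scan controls false discoveries under the null", {
  set.seed(7)
  n <- 150; m <- 20
  f <- as.data.frame(matrix(rnorm(n * m), n, m))
  hits <- replicate(40, {
    y <- data.frame(y = rnorm(n))
    mean(bivariate_fdr_scan(f, y)$adjusted_p < 0.05)
  })
  expect_lte(mean(hits), 0.06)
})

test_that("non-exerciser regressions recover a planted slope", {
  set.seed(8)
  n <- 50
  steps <- rnorm(n, 6000, 2500)
  y <- 0.4 * (steps - mean(steps)) / sd(steps) + rnorm(n, 0, 0.8)
  res <- nonexerciser_models(data.frame(daily_total_steps = steps),
                             data.frame(mtl = y))
  expect_lt(abs(res$beta - 0.4), 0.15)
  expect_equal(res$n, n)
  expect_error(nonexerciser_models(data.frame(x = rep(1, n)),
                                   data.frame(y = y)), "zero variance")
  expect_warning(nonexerciser_models(data.frame(x = rnorm(5)),
                                     data.frame(y = rnorm(5))), "only 5")
})

test_that("non-exerciser betas are invariant to double residualization", {
  set.seed(9)
  n <- 60
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  x <- rnorm(n)
  y <- 0.3 * x + 0.5 * covs$age + rnorm(n)
  y_res <- residualize_outcome(y, covs)
  y_res2 <- residualize_outcome(y_res, covs)
  b1 <- nonexerciser_models(data.frame(x = x), data.frame(y = y_res))$beta
  b2 <- nonexerciser_models(data.frame(x = x), data.frame(y = y_res2))$beta
  expect_equal(b1, b2, tolerance = 1e-12)
})

test_that("pooled t-tests report n-2 degrees of freedom", {
  set.seed(10)
  n1 <- 122; n2 <- 157
  panel <- data.frame(sex = rep(c(0, 1), c(n1, n2)),
                      age = rnorm(n1 + n2, 72, 10),
                      tiv = rnorm(n1 + n2, 1.45e6, 1e5),
                      mtl = rnorm(n1 + n2, 9664, 1000))
  res <- sex_comparison_tests(panel, vars = c("age", "mtl"),
                              adjust_tiv = "mtl")
  expect_equal(res$df[res$variable == "age"], 277)
  expect_equal(res$df[res$variable == "mtl"], 279 - 3)  # sex + tiv + intercept
})

test_that("pooled t matches the textbook formula on a toy sample", {
  x <- c(1.1, 2.3, 0.7); y <- c(2.0, 2.9, 3.4)
  panel <- data.frame(sex = rep(c(0, 1), each = 3), v = c(x, y))
  res <- sex_comparison_tests(panel, vars = "v")
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_ref <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_ref, tolerance = 1e-12)
  expect_equal(res$df, 4)

  same <- data.frame(sex = rep(c(0, 1), each = 50), v = rep(rnorm(50), 2))
  expect_lt(abs(sex_comparison_tests(same, "v")$statistic), 1e-12)
  expect_error(sex_comparison_tests(data.frame(sex = rep(1, 10),
                                               v = rnorm(10)), "v"),
               "both sexes")
})
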