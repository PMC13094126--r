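fake_features <- function(n, seed) {
  set.seed(seed)
  fn <- feature_names()[1:7]
  X <- as.data.frame(matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, fn)))
  X$age <- runif(n, 40, 91)
  X$sex <- rbinom(n, 1, 0.5)
  X
}

test_that("the full design has 42 columns partitioned 25/7/10, all unit variance", {
  d <- fake_features(80, seed = 1)
  X <- build_design_matrix(d[, 1:7], age = d$age, sex = d$sex)
  expect_equal(ncol(X), 42)
  info <- attr(X, "term_info")
  groups <- vapply(info, `[[`, character(1), "group")
  expect_equal(unname(table(groups)[c("in_session", "out_of_session",
                                      "cross")]),
               c(25L, 7L, 10L), ignore_attr = TRUE)
  expect_equal(colMeans(X), rep(0, 42), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(colMeans(X^2), rep(1, 42), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("design size follows k + k(k-1)/2 + 2k and mains_only keeps names", {
  d <- fake_features(50, seed = 2)
  X3 <- build_design_matrix(d[, 1:3], age = d$age, sex = d$sex)
  expect_equal(ncol(X3), 3 + 3 + 3 + 3)
  Xm <- build_design_matrix(d[, 1:7], mode = "mains_only")
  expect_equal(colnames(Xm), feature_names()[1:7])
})

test_that("zero-variance features are refused", {
  d <- fake_features(30, seed = 3)
  d$session_cadence <- 5
  expect_error(build_design_matrix(d[, 1:7], age = d$age, sex = d$sex),
               "session_cadence")
})

test_that("single-column ridge follows the 1/(1+lambda) closed form", {
  set.seed(4)
  x <- stepbouts:::zscore_pop(rnorm(100))
  X <- matrix(x, dimnames = list(NULL, "x"))
  for (lam in c(0, 0.5, 1, 4)) {
    fit <- stepbouts:::ridge_path(X, x, lam)
    expect_equal(unname(fit$beta[1, 1]), 1 / (1 + lam), tolerance = 1e-10)
  }
})

test_that("ridge at vanishing penalty matches ordinary least squares", {
  set.seed(5)
  n <- 200; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- X %*% rnorm(p) + rnorm(n)
  fit <- stepbouts:::ridge_path(X, as.numeric(y), 0)
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(fit$beta[, 1] - ols[-1])), 1e-8)
  expect_lt(abs(fit$intercept[1] - ols[1]), 1e-8)
})

test_that("coefficients shrink as beta_ols/(1+lambda) on an orthonormalized design", {
  set.seed(6)
  n <- 120; p <- 4
  # orthogonal polynomial columns are exactly centered and orthogonal
  X <- sqrt(n) * poly(seq_len(n), degree = p)   # X'X/n = I, colMeans = 0
  y <- as.numeric(X %*% c(2, -1, 0.5, 0.1) + rnorm(n, 0, 0.1))
  grid <- c(0, 0.1, 1, 10, 100)
  fit <- stepbouts:::ridge_path(X, y, grid)
  b0 <- fit$beta[, 1]
  for (j in seq_along(grid)) {
    expect_equal(unname(fit$beta[, j]), unname(b0 / (1 + grid[j])),
                 tolerance = 1e-10)
  }
  mags <- apply(abs(fit$beta), 1, diff)
  expect_true(all(mags <= 1e-12))
})

test_that("our ridge solution matches glmnet at a fixed penalty", {
  skip_if_not_installed("glmnet")
  set.seed(7)
  n <- 150; p <- 6
  X <- apply(matrix(rnorm(n * p), n, p), 2, stepbouts:::zscore_pop)
  colnames(X) <- paste0("v", 1:p)
  y <- as.numeric(X %*% rnorm(p) + rnorm(n))
  lam <- 0.7
  ours <- stepbouts:::ridge_path(X, y, lam)
  # glmnet internally rescales the gaussian response to unit (1/n) SD, so
  # its lambda lives on the standardized-y scale: multiply by sd(y)
  sy <- sqrt(mean((y - mean(y))^2))
  g <- glmnet::glmnet(X, y, alpha = 0, lambda = lam * sy,
                      standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(ours$beta[, 1]), unname(as.numeric(g$beta)),
               tolerance = 1e-5)
})

test_that("a pure-noise outcome yields near-zero cross-validated R-squared", {
  d <- fake_features(500, seed = 8)
  set.seed(9)
  y <- rnorm(500)
  fit <- ridge_importance(d[, 1:7], y, age = d$age, sex = d$sex, seed = 2)
  expect_lt(fit$r2, 0.05)
})

test_that("a planted single effect dominates the fitted coefficients", {
  d <- fake_features(300, seed = 10)
  set.seed(11)
  y <- 0.5 * scale(d$session_frequency)[, 1] + rnorm(300, 0, 0.5)
  fit <- ridge_importance(d[, 1:7], y, age = d$age, sex = d$sex, seed = 3)
  expect_equal(names(which.max(abs(coef(fit)))), "session_frequency")
  expect_equal(names(which.max(fit$importance)), "session_frequency")
})

test_that("importance proportions and group contributions sum to one", {
  d <- fake_features(120, seed = 12)
  set.seed(13)
  y <- rnorm(120)
  fit <- ridge_importance(d[, 1:7], y, age = d$age, sex = d$sex, seed = 4)
  expect_equal(sum(fit$importance), 1, tolerance = 1e-9)
  expect_equal(sum(fit$group_contrib), 1, tolerance = 1e-9)
  tab <- importance_table(fit)
  expect_setequal(unique(tab$group),
                  c("in_session", "out_of_session", "cross"))
})

test_that("hand-set coefficients give arithmetic importance proportions", {
  d <- fake_features(60, seed = 14)
  set.seed(15)
  fit <- ridge_importance(d[, 1:7], rnorm(60), age = d$age, sex = d$sex,
                          seed = 5)
  fit$coefficients[] <- 0
  fit$coefficients[c(1, 2, 3)] <- c(0.5, -0.3, 0.2)
  tab <- importance_table(fit)
  expect_equal(sort(tab$proportion, decreasing = TRUE)[1:3],
               c(0.5, 0.3, 0.2))
  # all mass on one in-by-out cross term
  fit$coefficients[] <- 0
  cross_term <- "session_cadence:daily_out_of_session_steps"
  fit$coefficients[cross_term] <- 1
  gc <- attr(importance_table(fit), "group_contrib")
  expect_equal(unname(gc["cross"]), 1)
  expect_equal(unname(gc["in_session"]), 0)
  # degenerate: everything zero
  fit$coefficients[] <- 0
  expect_error(importance_table(fit), "zero")
})

test_that("bootstrap CI collapses for a noiseless linear outcome and is seed-stable", {
  set.seed(16)
  X <- apply(matrix(rnorm(80 * 3), 80, 3), 2, stepbouts:::zscore_pop)
  colnames(X) <- paste0("v", 1:3)
  y <- as.numeric(X %*% c(1, -2, 0.5))
  suppressWarnings({
    ci <- bootstrap_r2_ci(X, y, n_boot = 60, lambda = 1e-4, seed = 1)
    ci2 <- bootstrap_r2_ci(X, y, n_boot = 60, lambda = 1e-4, seed = 1)
  })
  expect_gt(ci[1], 0.999)
  expect_identical(as.numeric(ci), as.numeric(ci2))
  expect_warning(bootstrap_r2_ci(X, y, n_boot = 50, lambda = 1, seed = 1),
                 "100")
  expect_error(bootstrap_r2_ci(X, y, n_boot = 1, lambda = 1, seed = 1),
               "at least 2")
})

test_that("prediction and residual methods are consistent", {
  d <- fake_features(100, seed = 17)
  set.seed(18)
  y <- 0.4 * scale(d$session_cadence)[, 1] + rnorm(100, 0, 0.7)
  fit <- ridge_importance(d[, 1:7], y, age = d$age, sex = d$sex, seed = 6)
  expect_equal(predict(fit, d[, 1:7], age = d$age, sex = d$sex),
               fitted(fit), tolerance = 1e-12)
  expect_equal(fitted(fit) + residuals(fit), y, tolerance = 1e-12)
})

test_that("a constant wear-days covariate reduces to the main model", {
  d <- fake_features(90, seed = 19)
  set.seed(20)
  y <- rnorm(90)
  suppressMessages({
    ss <- sensitivity_suite(d[, 1:7], y, d$age, d$sex,
                            wear_days = rep(28, 90), seed = 7)
  })
  expect_equal(coef(ss$wear_days), coef(ss$main), tolerance = 1e-12)
  expect_equal(nrow(ss$ranks), 7)
  expect_equal(ncol(ss$ranks), 3)
})

test_that("degenerate inputs are refused", {
  d <- fake_features(40, seed = 21)
  expect_error(ridge_importance(d[, 1:7], rep(1, 40), age = d$age,
                                sex = d$sex), "zero variance")
  expect_error(ridge_importance(d[, 1:7], c(rnorm(39), NA), age = d$age,
                                sex = d$sex), "non-finite")
  expect_error(ridge_importance(d[, 1:7], rnorm(40), age = d$age,
                                sex = d$sex, lambda_grid = numeric(0)),
               "empty")
})
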