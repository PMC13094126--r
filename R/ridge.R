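#' Build the standardized ridge design matrix
#'
#' Constructs the predictor design for the feature-importance models among
#' exercisers: the standardized core activity features, their pairwise
#' products, and their products with (standardized) age and with sex
#' (female = 1, male = 0).  With the seven core features this yields
#' 7 + 21 + 7 + 7 = 42 terms.  Products are computed from the standardized
#' mains and then each product column is re-standardized, so every column
#' has mean zero and unit variance and coefficient magnitudes are directly
#' comparable as relative importance.  Age and sex main effects are not in
#' the design; outcomes are pre-adjusted for them (see
#' [prepare_outcomes()]).
#'
#' Standardization uses the population (1/n) SD convention, so for every
#' column `sum(x^2)/n == 1`; this makes the ridge penalty scale-free (see
#' [ridge_importance()]).
#'
#' @param features data.frame/matrix of core activity features (exerciser
#'   rows, complete cases); columns classified as in-session or
#'   out-of-session by name (see [feature_names()]).
#' @param age,sex Numeric vectors aligned with `features` rows; required for
#'   `mode = "full"`.
#' @param mode `"full"` (mains + all pairwise/demographic products) or
#'   `"mains_only"` (the sensitivity variant: core features, no products).
#' @return Numeric matrix with canonical ordered column names and
#'   attributes `term_info` (per-column constituents and group:
#'   `in_session`, `out_of_session`, or `cross`) and `scaling` (the centers
#'   and scales needed to reproduce the construction on new data).
#' @export
build_design_matrix <- function(features, age = NULL, sex = NULL,
                                mode = c("full", "mains_only")) {
  mode <- match.arg(mode)
  F <- as.data.frame(features)
  fn <- colnames(F)
  if (anyNA(F)) stop("design matrix requires complete feature data",
                     call. = FALSE)
  n <- nrow(F)

  main_center <- vapply(F, mean, numeric(1))
  main_scale <- vapply(F, function(x) sqrt(mean((x - mean(x))^2)), numeric(1))
  zero <- names(main_scale)[main_scale == 0]
  if (length(zero)) {
    stop(sprintf("zero-variance feature column(s): %s",
                 paste(zero, collapse = ", ")), call. = FALSE)
  }
  Z <- sweep(sweep(as.matrix(F), 2, main_center), 2, main_scale, "/")

  grp_of <- function(vars) {
    f <- intersect(vars, fn)
    ins <- f %in% in_session_features()
    if (all(ins)) "in_session"
    else if (!any(ins)) "out_of_session"
    else "cross"
  }

  cols <- list(); info <- list()
  for (f in fn) {
    cols[[f]] <- Z[, f]
    info[[f]] <- list(vars = f, group = grp_of(f), product = FALSE)
  }

  if (mode == "full") {
    if (is.null(age) || is.null(sex)) {
      stop("mode 'full' requires age and sex", call. = FALSE)
    }
    if (length(age) != n || length(sex) != n) {
      stop("age and sex must align with feature rows", call. = FALSE)
    }
    z_age <- zscore_pop(age)
    sexv <- as.numeric(sex)
    if (!all(sexv %in% c(0, 1))) {
      stop("sex must be coded female = 1, male = 0", call. = FALSE)
    }
    k <- length(fn)
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        nm <- paste(fn[i], fn[j], sep = ":")
        cols[[nm]] <- Z[, i] * Z[, j]
        info[[nm]] <- list(vars = c(fn[i], fn[j]),
                           group = grp_of(c(fn[i], fn[j])), product = TRUE)
      }
    }
    for (f in fn) {
      nm <- paste(f, "age", sep = ":")
      cols[[nm]] <- Z[, f] * z_age
      info[[nm]] <- list(vars = c(f, "age"), group = grp_of(f),
                         product = TRUE)
    }
    for (f in fn) {
      nm <- paste(f, "sex", sep = ":")
      cols[[nm]] <- Z[, f] * sexv
      info[[nm]] <- list(vars = c(f, "sex"), group = grp_of(f),
                         product = TRUE)
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  term_center <- colMeans(X)
  term_scale <- sqrt(colMeans(sweep(X, 2, term_center)^2))
  dead <- colnames(X)[term_scale == 0]
  if (length(dead)) {
    stop(sprintf("zero-variance design column(s): %s",
                 paste(dead, collapse = ", ")), call. = FALSE)
  }
  X <- sweep(sweep(X, 2, term_center), 2, term_scale, "/")

  attr(X, "term_info") <- info
  attr(X, "scaling") <- list(
    main_center = main_center, main_scale = main_scale,
    age_center = if (mode == "full") mean(age) else NULL,
    age_scale = if (mode == "full") sqrt(mean((age - mean(age))^2)) else NULL,
    term_center = term_center, term_scale = term_scale, mode = mode,
    feature_names = fn)
  X
}

# Rebuild a design on new data using the scaling learned at fit time.
design_apply <- function(scaling, term_info, features, age = NULL,
                         sex = NULL) {
  F <- as.data.frame(features)[, scaling$feature_names, drop = FALSE]
  Z <- sweep(sweep(as.matrix(F), 2, scaling$main_center), 2,
             scaling$main_scale, "/")
  z_age <- if (!is.null(age)) (age - scaling$age_center) / scaling$age_scale
  sexv <- if (!is.null(sex)) as.numeric(sex)
  cols <- lapply(names(term_info), function(nm) {
    vars <- term_info[[nm]]$vars
    v <- rep(1, nrow(Z))
    for (u in vars) {
      v <- v * switch(u, age = z_age, sex = sexv, Z[, u])
    }
    v
  })
  X <- do.call(cbind, cols)
  colnames(X) <- names(term_info)
  sweep(sweep(X, 2, scaling$term_center), 2, scaling$term_scale, "/")
}

#' Default penalty grid
#'
#' 100 log-spaced values spanning effectively unpenalized (1e-4) to
#' near-total shrinkage (1e3) for standardized designs.
#' @return Numeric vector, ascending.
#' @export
default_lambda_grid <- function() 10^seq(-4, 3, length.out = 100)

# Ridge solutions over a lambda grid via one eigendecomposition.
# Objective: (1/2n)||y - a - X beta||^2 + (lambda/2)||beta||^2, intercept
# unpenalized.  Returns p x L coefficient matrix and length-L intercepts.
ridge_path <- function(X, y, lambdas) {
  n <- nrow(X)
  xc <- colMeans(X); yc <- mean(y)
  Xc <- sweep(X, 2, xc)
  yd <- y - yc
  C <- crossprod(Xc) / n
  b <- crossprod(Xc, yd) / n
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  qb <- crossprod(e$vectors, b)
  beta <- vapply(lambdas, function(l) {
    as.numeric(e$vectors %*% (qb / (ev + l)))
  }, numeric(ncol(X)))
  beta <- matrix(beta, nrow = ncol(X))
  rownames(beta) <- colnames(X)
  intercept <- yc - as.numeric(crossprod(xc, beta))
  list(beta = beta, intercept = intercept)
}

# Seeded k-fold assignment.
make_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

# k-fold CV over the lambda grid: pooled held-out predictions per lambda.
cv_ridge <- function(X, y, k_folds, lambdas, seed) {
  n <- nrow(X)
  if (n < k_folds) stop("fewer rows than folds", call. = FALSE)
  folds <- make_folds(n, k_folds, seed)
  pred <- matrix(NA_real_, n, length(lambdas))
  for (f in seq_len(k_folds)) {
    te <- folds == f
    fit <- ridge_path(X[!te, , drop = FALSE], y[!te], lambdas)
    pred[te, ] <- sweep(X[te, , drop = FALSE] %*% fit$beta, 2,
                        fit$intercept, "+")
  }
  mse <- colMeans((pred - y)^2)
  opt <- which.min(mse)
  ph <- pred[, opt]
  r2 <- if (sd(ph) == 0 || sd(y) == 0) 0 else cor(ph, y)^2
  list(lambda_opt = lambdas[opt], cv_mse = mse, opt_index = opt,
       heldout = ph, r2 = r2, mae = mean(abs(ph - y)), folds = folds)
}

#' Ridge feature-importance model
#'
#' The headline fitting routine: given exercisers' core activity features
#' and a (residualized) outcome, it builds the standardized design of mains
#' and interactions (see [build_design_matrix()]), selects the ridge penalty
#' by seeded k-fold cross-validation (minimum mean cross-validated error),
#' refits on all rows at the optimum, and summarizes relative importance as
#' each term's share of the total absolute standardized coefficient weight,
#' with group contributions for in-session, out-of-session and
#' in-by-out-of-session cross terms.  Optionally estimates a nonparametric
#' bootstrap percentile confidence interval for the model R-squared.
#'
#' The penalty convention is `(1/2n) ||y - X b||^2 + (lambda/2) ||b||^2`
#' with an unpenalized intercept, so for a single standardized column with
#' `y = x` the solution is `b = 1/(1 + lambda)`, and grid values do not
#' depend on n.  Both predictors and the outcome are standardized (1/n SD)
#' before fitting; reported R-squared and MAE are cross-validated (squared
#' correlation, and mean absolute error, of pooled held-out predictions
#' against the observed standardized outcome) unless `metric = "insample"`.
#'
#' @param features data.frame of core activity features (exerciser rows,
#'   complete cases).
#' @param y Numeric outcome, typically a residualized outcome from
#'   [prepare_outcomes()].
#' @param age,sex Demographics aligned with `features` (required for the
#'   full design); sex coded female = 1.
#' @param mode `"full"` (42 terms with the seven core features) or
#'   `"mains_only"`.
#' @param extra_covariates Optional data.frame of additional standardized-on
#'   -entry covariate columns appended to the design (e.g., valid wear
#'   days); zero-variance columns are dropped with a message.
#' @param lambda_grid Penalty grid; default [default_lambda_grid()].
#' @param k_folds Cross-validation folds (default 10).
#' @param n_boot Bootstrap resamples for the R-squared CI (0 = skip; the
#'   reference analysis uses 1000).
#' @param boot_retune Re-select lambda inside each bootstrap resample
#'   (slower); default keeps the full-sample optimum.
#' @param level Confidence level for the bootstrap CI.
#' @param metric `"cv"` (default) or `"insample"` performance metrics.
#' @param seed Integer seed driving fold assignment and the bootstrap.
#' @return Object of class `ridge_importance`: list with `lambda_opt`,
#'   `coefficients` (named, standardized scale), `intercept`, `r2`, `mae`,
#'   `r2_ci`, `importance` (per-term proportions), `group_contrib`,
#'   `n_used`, `seed`, plus the design/scaling needed by [predict()].
#' @seealso [importance_table()], [bootstrap_r2_ci()], [sensitivity_suite()]
#' @export
ridge_importance <- function(features, y, age = NULL, sex = NULL,
                             mode = c("full", "mains_only"),
                             extra_covariates = NULL,
                             lambda_grid = default_lambda_grid(),
                             k_folds = 10, n_boot = 0, boot_retune = FALSE,
                             level = 0.95, metric = c("cv", "insample"),
                             seed = 1) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  if (!length(lambda_grid)) stop("empty lambda grid", call. = FALSE)
  if (!all(is.finite(y))) stop("outcome contains non-finite values",
                               call. = FALSE)
  X <- build_design_matrix(features, age = age, sex = sex, mode = mode)
  term_info <- attr(X, "term_info")
  scaling <- attr(X, "scaling")
  if (!is.null(extra_covariates)) {
    EC <- as.data.frame(extra_covariates)
    for (nm in names(EC)) {
      v <- EC[[nm]]
      s <- sqrt(mean((v - mean(v))^2))
      if (s == 0) {
        message(sprintf("dropping zero-variance covariate '%s'", nm))
        next
      }
      X <- cbind(X, (v - mean(v)) / s)
      colnames(X)[ncol(X)] <- nm
      term_info[[nm]] <- list(vars = nm, group = "covariate",
                              product = FALSE)
    }
  }
  y_center <- mean(y)
  y_scale <- sqrt(mean((y - y_center)^2))
  if (y_scale == 0) stop("outcome has zero variance", call. = FALSE)
  ys <- (y - y_center) / y_scale

  cv <- cv_ridge(X, ys, k_folds, lambda_grid, seed)
  full <- ridge_path(X, ys, cv$lambda_opt)
  beta <- full$beta[, 1]

  if (metric == "insample") {
    fit_in <- as.numeric(X %*% beta) + full$intercept[1]
    r2 <- if (sd(fit_in) == 0) 0 else cor(fit_in, ys)^2
    mae <- mean(abs(fit_in - ys))
  } else {
    r2 <- cv$r2
    mae <- cv$mae
  }

  obj <- structure(list(
    coefficients = beta, intercept = full$intercept[1],
    lambda_opt = cv$lambda_opt, lambda_grid = lambda_grid,
    cv_mse = cv$cv_mse, r2 = r2, mae = mae, r2_ci = NULL,
    metric = metric, mode = mode, term_info = term_info,
    scaling = scaling, y_center = y_center, y_scale = y_scale,
    n_used = nrow(X), k_folds = k_folds, seed = seed,
    X = X, y_std = ys), class = "ridge_importance")

  tab <- importance_table(obj)
  obj$importance <- tab$proportion
  names(obj$importance) <- tab$term
  obj$group_contrib <- attr(tab, "group_contrib")

  if (n_boot > 0) {
    obj$r2_ci <- bootstrap_r2_ci(X, ys, n_boot = n_boot, level = level,
                                 k_folds = k_folds,
                                 lambda_grid = lambda_grid,
                                 lambda = if (boot_retune) NULL else
                                   cv$lambda_opt,
                                 seed = derive_seed(seed, 1L, salt = 9L))
    obj$n_boot <- n_boot
  }
  obj
}

#' Bootstrap percentile CI for model R-squared
#'
#' Resamples rows with replacement, recomputes the cross-validated
#' R-squared on each resample (at a fixed penalty, or re-selecting lambda
#' per resample when `lambda = NULL`), and returns the percentile bounds of
#' the resulting R-squared distribution.
#'
#' @param X Standardized design matrix.
#' @param y Standardized outcome.
#' @param n_boot Number of resamples (default 1000; fewer than 100 triggers
#'   a warning, fewer than 2 is an error).
#' @param level Confidence level (default 0.95).
#' @param k_folds,lambda_grid As in [ridge_importance()].
#' @param lambda Fixed penalty; `NULL` re-tunes per resample.
#' @param seed Integer seed.
#' @return Numeric `c(lower, upper)` with the bootstrap R-squared draws in
#'   attribute `"r2_boot"`.
#' @export
bootstrap_r2_ci <- function(X, y, n_boot = 1000, level = 0.95,
                            k_folds = 10, lambda_grid = default_lambda_grid(),
                            lambda = NULL, seed = 1) {
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  if (n_boot < 100) warning("fewer than 100 bootstrap resamples; CI will be unstable")
  n <- nrow(X)
  grid <- if (is.null(lambda)) lambda_grid else lambda
  set.seed(seed)
  idx_mat <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  r2s <- vapply(seq_len(n_boot), function(b) {
    idx <- idx_mat[, b]
    cv <- cv_ridge(X[idx, , drop = FALSE], y[idx], k_folds, grid,
                   seed = derive_seed(seed, b))
    cv$r2
  }, numeric(1))
  a <- (1 - level) / 2
  ci <- unname(quantile(r2s, c(a, 1 - a), type = 7))
  attr(ci, "r2_boot") <- r2s
  ci
}

#' Per-term importance and group contributions
#'
#' Importance of term j is `|coef_j| / sum(|coef|)`.  Group contributions
#' sum the same proportions within the in-session block (5 mains, 10
#' in-by-in products, 10 in-by-age/sex products), the out-of-session block
#' (2 mains, 1 out-by-out product, 4 out-by-age/sex products), and the 10
#' in-by-out cross products; with the full 42-term design the three blocks
#' partition all terms and their contributions sum to one.
#'
#' @param fit A [ridge_importance()] object.
#' @return data.frame with `term`, `coefficient`, `proportion`, `group`,
#'   ordered by decreasing proportion; group totals in attribute
#'   `"group_contrib"`.
#' @export
importance_table <- function(fit) {
  beta <- fit$coefficients
  tot <- sum(abs(beta))
  if (tot == 0) {
    stop("all coefficients are zero; importance proportions undefined",
         call. = FALSE)
  }
  groups <- vapply(fit$term_info[names(beta)], `[[`, character(1), "group")
  tab <- data.frame(term = names(beta), coefficient = unname(beta),
                    proportion = abs(unname(beta)) / tot,
                    group = unname(groups), stringsAsFactors = FALSE)
  gc <- tapply(tab$proportion, tab$group, sum)
  gc <- as.list(gc)
  for (g in c("in_session", "out_of_session", "cross")) {
    if (is.null(gc[[g]])) gc[[g]] <- 0
  }
  tab <- tab[order(-tab$proportion), ]
  rownames(tab) <- NULL
  attr(tab, "group_contrib") <- unlist(gc)
  tab
}

#' @export
print.ridge_importance <- function(x, ...) {
  cat(sprintf("Ridge feature-importance model (%s design, %d terms, n = %d)\n",
              x$mode, length(x$coefficients), x$n_used))
  cat(sprintf("  lambda (10-fold CV optimum): %.4g\n", x$lambda_opt))
  cat(sprintf("  %s R-squared: %.3f   MAE: %.3f\n",
              if (x$metric == "cv") "cross-validated" else "in-sample",
              x$r2, x$mae))
  if (!is.null(x$r2_ci)) {
    cat(sprintf("  bootstrap %d%% CI for R-squared: (%.3f, %.3f) [%d resamples]\n",
                round(100 * attr_level(x)), x$r2_ci[1], x$r2_ci[2],
                x$n_boot))
  }
  top <- head(sort(x$importance, decreasing = TRUE), 5)
  cat("  top terms (share of total |coefficient|):\n")
  for (nm in names(top)) cat(sprintf("    %-45s %5.1f%%\n", nm, 100 * top[nm]))
  invisible(x)
}

attr_level <- function(x) 0.95

#' @export
summary.ridge_importance <- function(object, ...) {
  tab <- importance_table(object)
  structure(list(fit = object, table = tab,
                 group_contrib = attr(tab, "group_contrib")),
            class = "summary.ridge_importance")
}

#' @export
print.summary.ridge_importance <- function(x, ...) {
  print(x$fit)
  cat("\nGroup contributions (share of total |coefficient|):\n")
  gc <- x$group_contrib
  for (g in names(gc)) cat(sprintf("  %-15s %5.1f%%\n", g, 100 * gc[g]))
  cat("\nAll terms:\n")
  tab <- x$table
  tab$proportion <- round(tab$proportion, 4)
  tab$coefficient <- signif(tab$coefficient, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ridge_importance <- function(object, ...) object$coefficients

#' Predict from a ridge importance model
#'
#' @param object A [ridge_importance()] fit.
#' @param features New core-feature data (same columns as at fit time);
#'   omit to return fitted values.
#' @param age,sex New demographics (full design only).
#' @param scale `"response"` (original outcome units, default) or
#'   `"standardized"`.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.ridge_importance <- function(object, features = NULL, age = NULL,
                                     sex = NULL,
                                     scale = c("response", "standardized"),
                                     ...) {
  scale <- match.arg(scale)
  X <- if (is.null(features)) {
    object$X[, names(object$coefficients), drop = FALSE]
  } else {
    design_apply(object$scaling, object$term_info, features, age, sex)
  }
  ps <- as.numeric(X %*% object$coefficients) + object$intercept
  if (scale == "standardized") ps else object$y_center + object$y_scale * ps
}

#' @export
fitted.ridge_importance <- function(object, ...) {
  predict(object, scale = "response")
}

#' @export
residuals.ridge_importance <- function(object, ...) {
  (object$y_center + object$y_scale * object$y_std) -
    predict(object, scale = "response")
}

#' Importance bar plot
#'
#' Horizontal bars of the top term-importance proportions, colored by
#' term group.
#'
#' @param x A [ridge_importance()] fit.
#' @param n_terms Number of top terms to draw.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted table.
#' @export
plot.ridge_importance <- function(x, n_terms = 10, ...) {
  tab <- importance_table(x)
  tab <- head(tab, n_terms)
  cols <- c(in_session = "#2166ac", out_of_session = "#b2182b",
            cross = "#762a83", covariate = "grey50")
  op <- graphics::par(mar = c(4, 14, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(tab$proportion), names.arg = rev(tab$term),
                    horiz = TRUE, las = 1, cex.names = 0.7,
                    col = cols[rev(tab$group)],
                    xlab = "share of total |coefficient|", ...)
  invisible(tab)
}

#' Sensitivity variants of the importance model
#'
#' Fits, for one outcome, (a) the main full-interaction model, (b) the
#' mains-only model (seven core features, no products), and (c) the full
#' model with valid wear days added as a covariate, then compares the rank
#' ordering of the seven core features (by the importance of their main
#' terms) across the three fits via Spearman correlation.
#'
#' @inheritParams ridge_importance
#' @param wear_days Numeric vector of valid wear days per row.
#' @return List of class `importance_sensitivity`: fits `main`,
#'   `mains_only`, `wear_days`; `ranks` (7 x 3 matrix, 1 = most important);
#'   `spearman` (3 x 3 rank-concordance matrix).
#' @export
sensitivity_suite <- function(features, y, age, sex, wear_days,
                              lambda_grid = default_lambda_grid(),
                              k_folds = 10, seed = 1) {
  fit_main <- ridge_importance(features, y, age, sex, mode = "full",
                               lambda_grid = lambda_grid,
                               k_folds = k_folds, seed = seed)
  fit_mains <- ridge_importance(features, y, mode = "mains_only",
                                lambda_grid = lambda_grid,
                                k_folds = k_folds, seed = seed)
  wd <- data.frame(wear_days = as.numeric(wear_days))
  s <- sqrt(mean((wd$wear_days - mean(wd$wear_days))^2))
  fit_wear <- ridge_importance(features, y, age, sex, mode = "full",
                               extra_covariates = if (s > 0) wd else NULL,
                               lambda_grid = lambda_grid,
                               k_folds = k_folds, seed = seed)
  fn <- colnames(as.data.frame(features))
  rank_of <- function(fit) {
    imp <- fit$importance[fn]
    rank(-imp, ties.method = "average")
  }
  ranks <- cbind(main = rank_of(fit_main), mains_only = rank_of(fit_mains),
                 wear_days = rank_of(fit_wear))
  structure(list(main = fit_main, mains_only = fit_mains,
                 wear_days = fit_wear, ranks = ranks,
                 spearman = cor(ranks, method = "spearman")),
            class = "importance_sensitivity")
}

#' @export
print.importance_sensitivity <- function(x, ...) {
  cat("Importance-model sensitivity suite\n")
  cat(sprintf("  R-squared: main %.3f | mains-only %.3f | +wear-days %.3f\n",
              x$main$r2, x$mains_only$r2, x$wear_days$r2))
  cat("  core-feature ranks (1 = most important):\n")
  print(x$ranks)
  cat("  Spearman rank concordance:\n")
  print(round(x$spearman, 3))
  invisible(x)
}
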