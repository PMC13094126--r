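stats_row <- function(test_name, statistic, df = NA_real_, p_value,
                      effect_size = NA_real_, adjusted_p = NA_real_, n) {
  data.frame(test_name = test_name, statistic = statistic, df = df,
             p_value = p_value, effect_size = effect_size,
             adjusted_p = adjusted_p, n = n, stringsAsFactors = FALSE)
}

#' Wilcoxon signed-rank test for paired skewed variables
#'
#' Compares paired measurements (e.g., in-session vs out-of-session daily
#' steps within participants) with the signed-rank test.  Zero differences
#' are dropped before ranking (their count is reported in the test name).
#' For n of at most 12 retained pairs the two-sided p-value is computed by
#' exhaustive enumeration of all 2^n sign assignments of the rank sum
#' (valid under ties); for larger n the normal approximation with a 0.5
#' continuity correction is used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default `TRUE`).
#' @param exact_max Largest n for which the exact enumeration is used.
#' @return One-row data.frame (`test_name`, `statistic` = V, the positive
#'   rank sum, `p_value`, `effect_size` = matched rank-biserial correlation,
#'   `n` = retained pairs).
#' @export
paired_signed_rank <- function(x, y, continuity = TRUE, exact_max = 12) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  d <- x - y
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("all paired differences are zero; signed-rank test degenerate",
         call. = FALSE)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  tot <- n * (n + 1) / 2
  effect <- (v - (tot - v)) / tot   # matched rank-biserial correlation

  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, v)
    method <- "exact enumeration"
  } else {
    mu <- tot / 2
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    cc <- if (continuity) sign(v - mu) * 0.5 else 0
    z <- (v - mu - cc) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- paste0("normal approximation",
                     if (continuity) " with continuity correction")
  }
  stats_row(
    test_name = sprintf("Wilcoxon signed rank (%s%s)", method,
                        if (n_zero) sprintf("; %d zero pairs dropped", n_zero)
                        else ""),
    statistic = v, p_value = p, effect_size = effect, n = n)
}

# Exact two-sided p by enumerating every sign assignment of the ranks.
signed_rank_exact_p <- function(ranks, v_obs) {
  n <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% ranks)
  tot <- sum(ranks)
  # two-sided: distance of V from its mean
  dev <- abs(v_all - tot / 2)
  min(1, mean(dev >= abs(v_obs - tot / 2) - 1e-12))
}

#' ANCOVA group comparison with partial eta-squared
#'
#' Compares a binary group (e.g., exercisers vs non-exercisers) on an
#' outcome adjusting for covariates, reporting the F test of the group term
#' and partial eta-squared = SS_group / (SS_group + SS_residual), where
#' SS_group is the reduction in residual sum of squares when the group term
#' is added to the covariate-only model (the group term's unique SS).
#'
#' @param outcome Numeric vector.
#' @param group Two-level vector (factor, logical, or 0/1).
#' @param covariates Optional data.frame/matrix of covariates.
#' @return One-row data.frame with `statistic` = F, `df` = residual df,
#'   `effect_size` = partial eta-squared.
#' @export
ancova_partial_eta <- function(outcome, group, covariates = NULL) {
  g <- as.factor(group)
  dat <- data.frame(.y = outcome, .g = g)
  covs <- character()
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    covs <- names(cv)
    dat <- cbind(dat, cv)
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nlevels(droplevels(dat$.g)) != 2) {
    stop("group must have exactly two observed levels", call. = FALSE)
  }
  rhs_red <- if (length(covs)) paste(covs, collapse = " + ") else "1"
  fit_red <- lm(stats::as.formula(paste(".y ~", rhs_red)), data = dat)
  fit_full <- lm(stats::as.formula(paste(".y ~", rhs_red, "+ .g")),
                 data = dat)
  rss_red <- sum(resid(fit_red)^2)
  rss_full <- sum(resid(fit_full)^2)
  ss_group <- rss_red - rss_full
  df_res <- fit_full$df.residual
  fstat <- (ss_group / 1) / (rss_full / df_res)
  p <- pf(fstat, 1, df_res, lower.tail = FALSE)
  stats_row(test_name = "ANCOVA (group term F)", statistic = fstat,
            df = df_res, p_value = p,
            effect_size = ss_group / (ss_group + rss_full),
            n = nrow(dat))
}

#' Covariate-adjusted bivariate scan with FDR correction
#'
#' Regresses each outcome on each feature (plus covariates), collects the
#' feature slope on the standardized scale and its p-value, and applies
#' Benjamini-Hochberg false-discovery-rate adjustment across the whole
#' scan.
#'
#' @param features data.frame of feature columns.
#' @param outcomes data.frame of outcome columns.
#' @param covariates Optional data.frame of covariates.
#' @param method Multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return data.frame, one row per feature-outcome pair: `feature`,
#'   `outcome`, `statistic` (t), `df`, `p_value`, `effect_size`
#'   (standardized slope), `adjusted_p`, `n`.
#' @export
bivariate_fdr_scan <- function(features, outcomes, covariates = NULL,
                               method = "BH") {
  features <- as.data.frame(features)
  outcomes <- as.data.frame(outcomes)
  if (!ncol(features) || !ncol(outcomes)) {
    stop("at least one feature-outcome pair is required", call. = FALSE)
  }
  rows <- list()
  for (o in names(outcomes)) {
    for (f in names(features)) {
      dat <- data.frame(.y = outcomes[[o]], .x = features[[f]])
      if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
      dat <- dat[complete.cases(dat), , drop = FALSE]
      sy <- sd(dat$.y); sx <- sd(dat$.x)
      if (sx == 0 || sy == 0) {
        stop(sprintf("zero variance in pair (%s, %s)", f, o), call. = FALSE)
      }
      dat$.y <- (dat$.y - mean(dat$.y)) / sy
      dat$.x <- (dat$.x - mean(dat$.x)) / sx
      rhs <- if (is.null(covariates)) ".x" else
        paste(c(".x", names(as.data.frame(covariates))), collapse = " + ")
      fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
      sm <- summary(fit)$coefficients
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(feature = f, outcome = o, stringsAsFactors = FALSE),
        stats_row(test_name = "adjusted linear regression",
                  statistic = sm[".x", "t value"],
                  df = fit$df.residual,
                  p_value = sm[".x", "Pr(>|t|)"],
                  effect_size = sm[".x", "Estimate"],
                  n = nrow(dat)))
    }
  }
  res <- do.call(rbind, rows)
  res$adjusted_p <- p.adjust(res$p_value, method = method)
  res
}

#' Activity-outcome regressions among non-exercisers
#'
#' For participants with no detected sessions, regresses each (residualized)
#' outcome on average daily total steps and on average daily
#' moderate-to-vigorous steps, reporting standardized slopes with standard
#' errors -- the companion analysis to the exerciser importance models.
#'
#' @param features data.frame with the non-exercisers' step features
#'   (columns used as predictors, e.g. `daily_out_of_session_steps` and
#'   `daily_mv_out_of_session_steps`).
#' @param outcomes data.frame of residualized outcomes (same rows).
#' @param min_n Below this row count a small-sample warning is raised.
#' @return data.frame: `outcome`, `feature`, `beta` (standardized), `se`,
#'   `statistic`, `p_value`, `n`.
#' @export
nonexerciser_models <- function(features, outcomes, min_n = 10) {
  features <- as.data.frame(features)
  outcomes <- as.data.frame(outcomes)
  rows <- list()
  for (o in names(outcomes)) {
    for (f in names(features)) {
      dat <- data.frame(.y = outcomes[[o]], .x = features[[f]])
      dat <- dat[complete.cases(dat), , drop = FALSE]
      if (nrow(dat) < min_n) {
        warning(sprintf("only %d non-exercisers for (%s, %s)", nrow(dat),
                        f, o))
      }
      sx <- sd(dat$.x)
      if (is.na(sx) || sx == 0) {
        stop(sprintf("feature '%s' has zero variance among non-exercisers",
                     f), call. = FALSE)
      }
      dat$.y <- (dat$.y - mean(dat$.y)) / sd(dat$.y)
      dat$.x <- (dat$.x - mean(dat$.x)) / sx
      fit <- lm(.y ~ .x, data = dat)
      sm <- summary(fit)$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = o, feature = f, beta = sm[".x", "Estimate"],
        se = sm[".x", "Std. Error"], statistic = sm[".x", "t value"],
        p_value = sm[".x", "Pr(>|t|)"], n = nrow(dat),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Sex comparisons of demographic, clinical and activity variables
#'
#' Two-sided pooled-variance (Student) t-tests compare the sexes on each
#' variable (df = n - 2); neuroimaging variables named in `adjust_tiv` are
#' instead compared via a linear model adjusting for total intracranial
#' volume (t test of the sex term).  Welch's test is available by flag.
#'
#' @param panel data.frame with a binary `sex` column (female = 1) and the
#'   variables to compare.
#' @param vars Character vector of variable names to compare.
#' @param adjust_tiv Subset of `vars` compared with TIV adjustment
#'   (requires a `tiv` column).
#' @param welch Use Welch's unequal-variance t instead of pooled.
#' @return data.frame, one row per variable.
#' @export
sex_comparison_tests <- function(panel, vars,
                                 adjust_tiv = character(), welch = FALSE) {
  if (length(unique(stats::na.omit(panel$sex))) != 2) {
    stop("both sexes must be present", call. = FALSE)
  }
  rows <- lapply(vars, function(v) {
    if (v %in% adjust_tiv) {
      dat <- data.frame(.y = panel[[v]], sex = panel$sex, tiv = panel$tiv)
      dat <- dat[complete.cases(dat), , drop = FALSE]
      fit <- lm(.y ~ sex + tiv, data = dat)
      sm <- summary(fit)$coefficients
      out <- stats_row(test_name = "t-test (TIV-adjusted)",
                       statistic = sm["sex", "t value"],
                       df = fit$df.residual,
                       p_value = sm["sex", "Pr(>|t|)"],
                       n = nrow(dat))
    } else {
      dat <- data.frame(.y = panel[[v]], sex = panel$sex)
      dat <- dat[complete.cases(dat), , drop = FALSE]
      tt <- stats::t.test(.y ~ sex, data = dat, var.equal = !welch)
      out <- stats_row(test_name = if (welch) "Welch t-test" else
                         "pooled t-test",
                       statistic = unname(tt$statistic),
                       df = unname(tt$parameter),
                       p_value = tt$p.value, n = nrow(dat))
    }
    cbind(data.frame(variable = v, stringsAsFactors = FALSE), out)
  })
  do.call(rbind, rows)
}
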