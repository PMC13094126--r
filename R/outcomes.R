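#' Build a cognitive composite from test scores
#'
#' Z-scores every test on the construction sample (sample mean/SD over
#' non-missing values), flips sign for tests where lower raw scores are
#' better (timed or error scores, orientation -1), and averages the
#' available tests per participant.  Participants missing every test get a
#' missing composite.
#'
#' @param test_scores Numeric matrix or data.frame, participants x tests.
#' @param orientations Numeric vector of +1/-1 per test (+1 = higher is
#'   better); default all +1.
#' @return Numeric vector of composite z-scores.
#' @export
make_composite <- function(test_scores,
                           orientations = rep(1, ncol(test_scores))) {
  m <- as.matrix(test_scores)
  if (length(orientations) != ncol(m)) {
    stop("one orientation (+1/-1) per test is required", call. = FALSE)
  }
  if (!all(orientations %in% c(-1, 1))) {
    stop("orientations must be +1 or -1", call. = FALSE)
  }
  for (j in seq_len(ncol(m))) {
    s <- sd(m[, j], na.rm = TRUE)
    if (is.na(s) || s == 0) {
      nm <- colnames(m)[j] %||% as.character(j)
      stop(sprintf("test '%s' has zero variance; z-score undefined", nm),
           call. = FALSE)
    }
    m[, j] <- orientations[j] * (m[, j] - mean(m[, j], na.rm = TRUE)) / s
  }
  rowMeans(m, na.rm = TRUE) -> comp
  comp[!is.finite(comp)] <- NA_real_
  comp
}

#' Log-transform a skewed outcome
#'
#' Applies `log(x + offset)` when the absolute sample skewness exceeds
#' `skew_cutoff` (default 1); otherwise returns the input unchanged.  The
#' default offset of 1 keeps zero-valued observations (e.g., zero
#' white-matter-hyperintensity volume) finite.  The transform is monotone,
#' so outcome ordering is preserved.  Outcomes taking values at or below
#' `-offset` (e.g., z-scale cognitive composites) are never transformed,
#' however skewed: the log is not defined for them.
#'
#' @param x Numeric outcome vector.
#' @param skew_cutoff Absolute skewness above which the transform applies.
#' @param offset Added inside the log.
#' @return Transformed (or untouched) vector, with attribute `"logged"`
#'   (logical) recording whether the transform was applied.
#' @export
log_if_skewed <- function(x, skew_cutoff = 1, offset = 1) {
  logged <- FALSE
  sk <- sample_skewness(x)
  if (is.finite(sk) && abs(sk) > skew_cutoff &&
      !any(x + offset <= 0, na.rm = TRUE)) {
    x <- log(x + offset)
    logged <- TRUE
  }
  attr(x, "logged") <- logged
  x
}

#' Residualize an outcome on covariates
#'
#' Least-squares regression of the outcome on the covariates plus an
#' intercept; the residuals carry forward as the adjusted outcome.
#' Residuals have zero mean and zero sample correlation with every
#' covariate, and the operation is idempotent.  Rows with a missing outcome
#' or covariate propagate `NA`.
#'
#' @param outcome Numeric vector.
#' @param covariates Numeric matrix or data.frame (same rows).
#' @return Numeric vector of residuals, `NA` where inputs were missing.
#' @export
residualize_outcome <- function(outcome, covariates) {
  X <- as.matrix(covariates)
  if (nrow(X) != length(outcome)) {
    stop("outcome and covariates must have the same number of rows",
         call. = FALSE)
  }
  cc <- complete.cases(outcome, X)
  Xc <- cbind(1, X[cc, , drop = FALSE])
  qr_x <- qr(Xc)
  if (qr_x$rank < ncol(Xc)) {
    dep <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1, ncol(Xc))] - 1]
    dep <- dep[!is.na(dep)]
    stop(sprintf("covariates are collinear (rank %d < %d): dependent column(s) %s",
                 qr_x$rank, ncol(Xc),
                 paste(dep, collapse = ", ")), call. = FALSE)
  }
  res <- rep(NA_real_, length(outcome))
  res[cc] <- qr.resid(qr_x, outcome[cc])
  res
}

#' Default covariate sets for outcome adjustment
#'
#' Cognitive outcomes are adjusted for age, sex and education; neuroimaging
#' outcomes for age, sex and total intracranial volume.  This mapping is
#' configuration, not code: pass your own named list to
#' [prepare_outcomes()] to change it.
#'
#' @return Named list: outcome name -> character vector of covariates.
#' @export
default_covariate_sets <- function() {
  cog <- c("age", "sex", "education")
  img <- c("age", "sex", "tiv")
  list(memory = cog, executive = cog, processing_speed = cog,
       mtl_volume = img, frontal_volume = img, wmh_burden = img,
       global_fa = img)
}

#' Prepare residualized outcomes for modeling
#'
#' For each outcome column: applies the skew-triggered log transform (see
#' [log_if_skewed()]), then residualizes on that outcome's covariate set.
#' Complete cases are handled per outcome, mirroring analyses where each
#' outcome has its own n.
#'
#' @param panel data.frame with outcome and covariate columns (see
#'   [simulate_cohort()]).
#' @param outcomes Character vector of outcome column names.
#' @param covariate_sets Named list mapping each outcome to its covariates;
#'   default [default_covariate_sets()].
#' @param skew_cutoff,offset Passed to [log_if_skewed()].
#' @return data.frame of residualized outcomes (same rows as `panel`,
#'   `NA` where unavailable), with attributes `"covariates"` (the mapping
#'   used) and `"logged"` (named logical).
#' @export
prepare_outcomes <- function(panel, outcomes = names(default_covariate_sets()),
                             covariate_sets = default_covariate_sets(),
                             skew_cutoff = 1, offset = 1) {
  outcomes <- intersect(outcomes, names(panel))
  res <- as.data.frame(matrix(NA_real_, nrow(panel), length(outcomes),
                              dimnames = list(NULL, outcomes)))
  logged <- logical(length(outcomes)); names(logged) <- outcomes
  for (o in outcomes) {
    covs <- covariate_sets[[o]]
    if (is.null(covs)) {
      stop(sprintf("no covariate set configured for outcome '%s'", o),
           call. = FALSE)
    }
    y <- log_if_skewed(panel[[o]], skew_cutoff = skew_cutoff, offset = offset)
    logged[o] <- attr(y, "logged")
    res[[o]] <- residualize_outcome(as.numeric(y),
                                    panel[, covs, drop = FALSE])
  }
  attr(res, "covariates") <- covariate_sets[outcomes]
  attr(res, "logged") <- logged
  res
}
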