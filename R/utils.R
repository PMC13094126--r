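#' @importFrom stats rnorm rbinom rpois runif sd var lm resid coef anova
#'   pf pt p.adjust complete.cases quantile cor predict median
#' @importFrom utils head tail
NULL

# Deterministic per-unit sub-seed so participant i's stream never depends on
# how many participants are requested.  Kept below 2^31 - 1.
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 7919 +
                as.numeric(salt) * 104729) %% 2147483647)
}

# Column standardization with the 1/n (population) SD convention used by the
# ridge solver, so that for a standardized column x'x/n = 1 exactly.
zscore_pop <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) stop("cannot standardize a zero-variance column", call. = FALSE)
  (x - mu) / s
}

# Conventional sample z-score (n - 1 SD), used for composites and features.
zscore <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    stop("cannot z-score a constant column", call. = FALSE)
  }
  (x - mean(x, na.rm = TRUE)) / s
}

# Moment-based sample skewness (m3 / m2^{3/2}) on non-missing values.
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

`%||%` <- function(a, b) if (is.null(a)) b else a
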