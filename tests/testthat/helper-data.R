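# Build a minute-level step table from a plain vector, starting at local
# midnight of `start` for participant `pid`.
make_steps <- function(x, pid = "P1", start = "2023-03-01") {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  data.table::data.table(
    participant_id = pid,
    timestamp = t0 + 60 * (seq_along(x) - 1),
    steps = as.integer(x))
}

# Stack several participants' vectors into one table.
make_cohort_steps <- function(vec_list, start = "2023-03-01") {
  data.table::rbindlist(lapply(names(vec_list), function(p) {
    make_steps(vec_list[[p]], pid = p, start = start)
  }))
}

# A mask that treats every observed day as valid (low thresholds).
permissive_mask <- function(steps) {
  compute_valid_days(steps, min_daily_steps = 0, min_valid_days = 1)
}

# Random 2-day minute series with cadences uniform on [0, 150].
random_series <- function(n_series, seed) {
  set.seed(seed)
  vecs <- lapply(seq_len(n_series), function(i) {
    as.integer(floor(runif(2880, 0, 151)))
  })
  names(vecs) <- sprintf("R%04d", seq_len(n_series))
  make_cohort_steps(vecs)
}

# Shared small synthetic cohort, built once per test run.
.acc_env <- new.env(parent = emptyenv())
acc_cohort <- function() {
  if (is.null(.acc_env$cohort)) {
    spec <- sim_spec(n_participants = 100)
    .acc_env$cohort <- simulate_cohort(spec, seed = 20240901)
  }
  .acc_env$cohort
}

expect_session_frames_equal <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a, b, tolerance = 1e-12)
}
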