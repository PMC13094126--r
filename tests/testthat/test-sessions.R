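cfg <- session_config()

detect_vec <- function(x, config = cfg) {
  detect_sessions(make_steps(x), mask = NULL, config = config)
}

test_that("no activity yields no sessions", {
  expect_equal(nrow(detect_vec(rep(0L, 60))), 0)
  expect_equal(nrow(detect_sessions(make_steps(integer(0)))), 0)
})

test_that("a minimal 10-minute qualifying run forms one session", {
  s <- detect_vec(c(rep(60L, 10), rep(0L, 50)))
  expect_equal(nrow(s), 1)
  expect_equal(s$start_minute, 1L)
  expect_equal(s$end_minute, 10L)
  expect_equal(s$duration_min, 10L)
  expect_equal(s$total_steps, 600L)
  expect_equal(s$mean_cadence, 60)
  expect_equal(s$n_breaks, 0L)
})

test_that("a tolerated break joins activity into one session, excluded from metrics", {
  x <- c(rep(100L, 12), rep(0L, 5), rep(50L, 8), rep(0L, 20))
  s <- detect_vec(x)
  expect_equal(nrow(s), 1)
  expect_equal(s$active_minutes, 20L)
  expect_equal(s$total_steps, 1600L)
  expect_equal(s$mean_cadence, 80)
  expect_equal(s$n_breaks, 1L)
  expect_equal(s$break_minutes, 5L)
  # break-minute steps are tracked separately (here zero)
  expect_equal(s$break_steps, 0L)
})

test_that("a gap of exactly 10 minutes splits sessions; 9 merges", {
  two <- detect_vec(c(rep(60L, 10), rep(0L, 10), rep(60L, 10)))
  expect_equal(nrow(two), 2)
  expect_equal(two$duration_min, c(10L, 10L))

  one <- detect_vec(c(rep(60L, 10), rep(0L, 9), rep(60L, 10)))
  expect_equal(nrow(one), 1)
  expect_equal(one$active_minutes, 20L)
  expect_equal(one$break_minutes, 9L)
})

test_that("nine-minute runs never open a session", {
  x <- rep(c(rep(50L, 9), rep(0L, 5)), 20)
  expect_equal(nrow(detect_vec(x)), 0)
})

test_that("a short orphan run before a qualifying run stays out-of-session", {
  x <- c(rep(50L, 5), rep(0L, 3), rep(60L, 12), rep(0L, 20))
  s <- detect_vec(x)
  expect_equal(nrow(s), 1)
  expect_equal(s$start_minute, 9L)   # session opens at the 10-min run
  expect_equal(s$active_minutes, 12L)
})

test_that("a single active minute resumes a session after a break", {
  x <- c(rep(60L, 10), rep(0L, 9), 80L, rep(0L, 30))
  s <- detect_vec(x)
  expect_equal(nrow(s), 1)
  expect_equal(s$end_minute, 20L)
  expect_equal(s$active_minutes, 11L)
})

test_that("recording end closes an open session at its last active minute", {
  s <- detect_vec(c(rep(0L, 5), rep(60L, 15)))
  expect_equal(nrow(s), 1)
  expect_equal(s$end_minute, 20L)
  # trailing sub-threshold minutes shorter than the terminal gap also close
  s2 <- detect_vec(c(rep(60L, 10), rep(0L, 4)))
  expect_equal(s2$end_minute, 10L)
  expect_equal(s2$n_breaks, 0L)
})

test_that("session invariants hold on random series", {
  steps <- random_series(60, seed = 42)
  sess <- detect_sessions(steps, mask = NULL, config = cfg)
  expect_true(all(sess$mean_cadence >= cfg$cadence_threshold))
  expect_true(all(sess$vigorous_steps <= sess$total_steps))
  for (p in unique(sess$participant_id)) {
    s <- sess[sess$participant_id == p][order(start_minute)]
    if (nrow(s) > 1) {
      gaps <- s$start_minute[-1] - s$end_minute[-nrow(s)] - 1
      expect_true(all(gaps >= cfg$min_terminal_gap))
    }
  }
})

test_that("reference detector agrees with the run-length detector on random series", {
  steps <- random_series(120, seed = 7)
  a <- detect_sessions(steps, mask = NULL, config = cfg)
  b <- detect_sessions_reference(steps, mask = NULL, config = cfg)
  expect_session_frames_equal(a, b)
})

test_that("sessions may span midnight and are dated by their start minute", {
  x <- integer(2880)
  x[1431:1450] <- 70L          # 23:50 day 1 through 00:10 day 2
  s <- detect_vec(x)
  expect_equal(nrow(s), 1)
  expect_equal(s$date, as.Date("2023-03-01"))
  expect_equal(s$active_minutes, 20L)
})

test_that("sessions touching an invalid day are discarded", {
  x <- integer(2880)
  x[1429:1442] <- 45L          # spans into day 2, which stays under 100 steps
  x[200:240] <- 30L            # keep day 1 valid (sub-threshold steps)
  steps <- make_steps(x)
  mask <- compute_valid_days(steps, min_daily_steps = 100,
                             min_valid_days = 1)
  expect_equal(mask$valid, c(TRUE, FALSE))  # day 2 total < 100
  s <- detect_sessions(steps, mask, cfg)
  expect_equal(nrow(s), 0)
})

test_that("excluded participants contribute no sessions", {
  x <- integer(1440 * 2)
  x[1:20] <- 80L
  steps <- make_steps(x)
  mask <- compute_valid_days(steps)  # 2 days < 7 minimum -> excluded
  expect_true(valid_day_summary(mask)$excluded)
  expect_equal(nrow(detect_sessions(steps, mask, cfg)), 0)
})

test_that("per-day step conservation: session active + break + out = total", {
  sim <- simulate_minute_series(sim_spec(n_participants = 8, n_days = 6),
                                seed = 21)
  mask <- compute_valid_days(sim$steps, min_valid_days = 1)
  sess <- detect_sessions(sim$steps, mask)
  dt <- sim$steps
  for (p in unique(dt$participant_id)) {
    sd <- dt[participant_id == p]
    ps <- sess[sess$participant_id == p]
    in_mask <- logical(nrow(sd))
    brk <- 0L
    if (nrow(ps)) {
      for (k in seq_len(nrow(ps))) {
        idx <- ps$start_minute[k]:ps$end_minute[k]
        in_mask[idx] <- sd$steps[idx] >= cfg$cadence_threshold
      }
      brk <- sum(ps$break_steps)
    }
    tot_in <- if (nrow(ps)) sum(ps$total_steps) else 0L
    expect_identical(sum(sd$steps[in_mask]), tot_in)
    out <- sum(sd$steps[!in_mask])
    expect_identical(tot_in + out, sum(sd$steps))
    expect_true(all(ps$break_minutes <= ps$n_breaks * cfg$max_break_len))
    expect_lte(brk, out)  # break steps are part of out-of-session steps
  }
})

test_that("threshold sweep: single point matches detection; exerciser sets nest", {
  sim <- simulate_minute_series(sim_spec(n_participants = 20, n_days = 5),
                                seed = 33)
  mask <- compute_valid_days(sim$steps, min_valid_days = 1)
  sw <- sweep_thresholds(sim$steps, mask, thresholds = 40)
  sess <- detect_sessions(sim$steps, mask, cfg)
  expect_equal(sw$n_sessions, nrow(sess))
  expect_equal(sw$n_exercisers, length(unique(sess$participant_id)))
  expect_equal(sw$mean_cadence, mean(sess$mean_cadence))

  sw3 <- sweep_thresholds(sim$steps, mask, thresholds = c(40, 60, 80))
  expect_true(all(diff(sw3$n_exercisers) <= 0))

  sets <- lapply(c(40, 60, 80), function(th) {
    unique(detect_sessions(sim$steps, mask,
                           session_config(cadence_threshold = th))$participant_id)
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))

  expect_error(sweep_thresholds(sim$steps, mask, thresholds = numeric(0)),
               "nonempty")
  expect_error(sweep_thresholds(sim$steps, mask, thresholds = c(60, 40)),
               "ascending")
})

test_that("config invariants are enforced", {
  expect_error(session_config(max_break_len = 10, min_terminal_gap = 10),
               "smaller")
  expect_error(session_config(cadence_threshold = 0), "positive")
})
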