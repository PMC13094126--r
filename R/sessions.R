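#' Session-detection configuration
#'
#' Rule set defining a physical-activity session from minute-level cadence
#' (at minute sampling, a minute's cadence equals its step count):
#' a session opens at the first minute of at least `min_start_run`
#' consecutive minutes at or above `cadence_threshold` steps/min; once open,
#' sub-threshold interruptions of at most `max_break_len` minutes ("session
#' breaks") are tolerated, and a single above-threshold minute after a break
#' resumes the session; the session ends at the last above-threshold minute
#' followed by at least `min_terminal_gap` sub-threshold minutes (or the end
#' of the recording).  `max_break_len = 9` with `min_terminal_gap = 10`
#' encodes "breaks of less than 10 minutes" in integer minutes.
#'
#' @param cadence_threshold Minimum cadence (steps/min) of an active minute.
#' @param min_start_run Consecutive active minutes required to open a
#'   session.
#' @param max_break_len Longest tolerated sub-threshold interruption
#'   (minutes) inside a session; must be smaller than `min_terminal_gap`.
#' @param min_terminal_gap Sub-threshold minutes that terminate a session.
#' @param vigorous_threshold Cadence (steps/min) counted as vigorous.
#' @param mv_threshold Cadence (steps/min) counted as moderate-to-vigorous.
#' @return Object of class `session_config`.
#' @export
session_config <- function(cadence_threshold = 40,
                           min_start_run = 10,
                           max_break_len = 9,
                           min_terminal_gap = 10,
                           vigorous_threshold = 120,
                           mv_threshold = 100) {
  cfg <- list(cadence_threshold = as.integer(cadence_threshold),
              min_start_run = as.integer(min_start_run),
              max_break_len = as.integer(max_break_len),
              min_terminal_gap = as.integer(min_terminal_gap),
              vigorous_threshold = as.integer(vigorous_threshold),
              mv_threshold = as.integer(mv_threshold))
  for (f in names(cfg)) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1) {
      stop(sprintf("session_config field '%s' must be a positive integer", f),
           call. = FALSE)
    }
  }
  if (cfg$max_break_len >= cfg$min_terminal_gap) {
    stop("max_break_len must be smaller than min_terminal_gap",
         call. = FALSE)
  }
  structure(cfg, class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf(
    "Session rules: >=%d min run at >=%d steps/min opens; breaks <=%d min allowed; gap >=%d min ends\n",
    x$min_start_run, x$cadence_threshold, x$max_break_len,
    x$min_terminal_gap))
  cat(sprintf("  vigorous >=%d, moderate-to-vigorous >=%d steps/min\n",
              x$vigorous_threshold, x$mv_threshold))
  invisible(x)
}

# Run-length state machine over one participant's continuous minute vector.
# Returns a data.frame of sessions with 1-based minute indices into x.
detect_core <- function(x, config) {
  n <- length(x)
  if (n == 0) return(empty_session_frame())
  active <- x >= config$cadence_threshold
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$lengths)

  out <- list()
  in_sess <- FALSE
  s_start <- NA_integer_; s_end <- NA_integer_
  brk_start <- integer(); brk_len <- integer()
  pend_start <- NA_integer_; pend_len <- NA_integer_

  close_session <- function() {
    out[[length(out) + 1L]] <<- list(start = s_start, end = s_end,
                                     brk_start = brk_start,
                                     brk_len = brk_len)
    in_sess <<- FALSE
    brk_start <<- integer(); brk_len <<- integer()
    pend_start <<- NA_integer_; pend_len <<- NA_integer_
  }

  for (j in seq_len(nr)) {
    if (r$values[j]) {                      # active run
      if (in_sess) {
        if (!is.na(pend_start)) {           # the gap was a tolerated break
          brk_start <- c(brk_start, pend_start)
          brk_len <- c(brk_len, pend_len)
          pend_start <- NA_integer_; pend_len <- NA_integer_
        }
        s_end <- ends[j]
      } else if (r$lengths[j] >= config$min_start_run) {
        in_sess <- TRUE
        s_start <- starts[j]
        s_end <- ends[j]
      }                                     # short orphan run: out-of-session
    } else if (in_sess) {                   # sub-threshold run
      if (r$lengths[j] <= config$max_break_len && j < nr) {
        pend_start <- starts[j]             # tentative break; confirmed if
        pend_len <- r$lengths[j]            # another active run follows
      } else {
        close_session()
      }
    }
  }
  if (in_sess) close_session()              # end-of-recording closes early

  session_metrics(x, out, config)
}

empty_session_frame <- function() {
  data.frame(start_minute = integer(), end_minute = integer(),
             active_minutes = integer(), duration_min = integer(),
             n_breaks = integer(), break_minutes = integer(),
             break_steps = integer(), total_steps = integer(),
             vigorous_steps = integer(), mean_cadence = numeric())
}

session_metrics <- function(x, sessions, config) {
  if (!length(sessions)) return(empty_session_frame())
  rows <- lapply(sessions, function(s) {
    idx <- s$start:s$end
    seg <- x[idx]
    act <- seg >= config$cadence_threshold
    total <- sum(seg[act])
    nact <- sum(act)
    brk_idx <- unlist(mapply(function(b0, bl) b0:(b0 + bl - 1L),
                             s$brk_start, s$brk_len, SIMPLIFY = FALSE),
                      use.names = FALSE)
    data.frame(
      start_minute = s$start, end_minute = s$end,
      active_minutes = nact, duration_min = nact,
      n_breaks = length(s$brk_len),
      break_minutes = sum(s$brk_len),
      break_steps = if (length(brk_idx)) sum(x[brk_idx]) else 0L,
      total_steps = total,
      vigorous_steps = sum(seg[act & seg >= config$vigorous_threshold]),
      mean_cadence = total / nact)
  })
  do.call(rbind, rows)
}

#' Detect physical-activity sessions
#'
#' Applies the session rule set (see [session_config()]) to each
#' participant's continuous minute timeline.  Detection runs across
#' midnight; a session is attributed to the calendar day containing its
#' start minute.  Sessions that touch any invalid (non-wear) day are
#' discarded, and excluded participants (insufficient valid days) yield no
#' sessions.
#'
#' @param steps Minute-level table (see [read_minute_steps()]).
#' @param mask Valid-day mask from [compute_valid_days()], or `NULL` to
#'   treat every day as valid.
#' @param config A [session_config()].
#' @return `data.table`, one row per session: `participant_id`, `start_ts`,
#'   `end_ts`, `date` (day of the start minute), `active_minutes`,
#'   `duration_min` (equal to `active_minutes`; break minutes are excluded
#'   from all session metrics), `n_breaks`, `break_minutes`, `break_steps`,
#'   `total_steps`, `vigorous_steps`, `mean_cadence`.
#' @export
detect_sessions <- function(steps, mask = NULL, config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  dt <- data.table::as.data.table(steps)
  if (nrow(dt) == 0) return(empty_session_table())
  data.table::setkey(dt, participant_id, timestamp)
  res <- dt[, detect_one(.SD, participant = .BY$participant_id,
                         mask = mask, config = config,
                         engine = detect_core),
            by = participant_id]
  if (nrow(res) == 0) return(empty_session_table())
  res[]
}

#' Reference session detector (exhaustive seed-and-merge)
#'
#' An independent implementation of the session definition used as a test
#' oracle: it marks active minutes, finds every maximal active run of at
#' least `min_start_run` minutes as a seed, greedily extends each seed
#' forward across sub-threshold gaps of at most `max_break_len` minutes, and
#' closes at longer gaps or at the end of the recording.  Intended for small
#' inputs; its output must match [detect_sessions()] on all inputs.
#'
#' @inheritParams detect_sessions
#' @return Same shape as [detect_sessions()].
#' @export
detect_sessions_reference <- function(steps, mask = NULL,
                                      config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  dt <- data.table::as.data.table(steps)
  if (nrow(dt) == 0) return(empty_session_table())
  data.table::setkey(dt, participant_id, timestamp)
  res <- dt[, detect_one(.SD, participant = .BY$participant_id,
                         mask = mask, config = config,
                         engine = reference_core),
            by = participant_id]
  if (nrow(res) == 0) return(empty_session_table())
  res[]
}

# Shared per-participant wrapper: run an engine on the minute vector, then
# stamp timestamps/dates and drop sessions touching invalid days.
detect_one <- function(sd, participant, mask, config, engine) {
  x <- sd$steps
  sess <- engine(x, config)
  if (nrow(sess) == 0) return(NULL)
  ts <- sd$timestamp
  sess$start_ts <- ts[sess$start_minute]
  sess$end_ts <- ts[sess$end_minute]
  sess$date <- as.Date(sess$start_ts, tz = "UTC")
  if (!is.null(mask)) {
    pm <- mask[mask$participant_id == participant]
    psum <- valid_day_summary(mask)
    if (nrow(psum[psum$participant_id == participant & psum$excluded])) {
      return(NULL)
    }
    invalid_dates <- pm$date[!pm$valid]
    if (length(invalid_dates)) {
      touch <- vapply(seq_len(nrow(sess)), function(k) {
        span <- seq(as.Date(sess$start_ts[k], tz = "UTC"),
                    as.Date(sess$end_ts[k], tz = "UTC"), by = "day")
        any(span %in% invalid_dates)
      }, logical(1))
      sess <- sess[!touch, , drop = FALSE]
    }
  }
  if (nrow(sess) == 0) return(NULL)
  sess[, c("start_ts", "end_ts", "date", "start_minute", "end_minute",
           "active_minutes", "duration_min", "n_breaks", "break_minutes",
           "break_steps", "total_steps", "vigorous_steps", "mean_cadence")]
}

empty_session_table <- function() {
  data.table::data.table(
    participant_id = character(), start_ts = as.POSIXct(character(), tz = "UTC"),
    end_ts = as.POSIXct(character(), tz = "UTC"),
    date = as.Date(character()), start_minute = integer(),
    end_minute = integer(), active_minutes = integer(),
    duration_min = integer(), n_breaks = integer(),
    break_minutes = integer(), break_steps = integer(),
    total_steps = integer(), vigorous_steps = integer(),
    mean_cadence = numeric())
}

# Independent engine: explicit seed-and-merge over the active-minute vector.
reference_core <- function(x, config) {
  n <- length(x)
  if (n == 0) return(empty_session_frame())
  active <- x >= config$cadence_threshold

  # maximal active runs by direct scan
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (active[i]) {
      j <- i
      while (j < n && active[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(empty_session_frame())
  run_mat <- do.call(rbind, runs)

  sessions <- list()
  covered_until <- 0L
  for (k in seq_len(nrow(run_mat))) {
    st <- run_mat[k, 1L]; en <- run_mat[k, 2L]
    if (st <= covered_until) next                      # inside prior session
    if (en - st + 1L < config$min_start_run) next      # too short to seed
    # greedy forward merge across tolerable gaps
    pos <- en
    brk_start <- integer(); brk_len <- integer()
    repeat {
      nxt <- which(run_mat[, 1L] > pos)
      if (!length(nxt)) break
      nk <- nxt[1L]
      gap <- run_mat[nk, 1L] - pos - 1L
      if (gap > config$max_break_len) break
      brk_start <- c(brk_start, pos + 1L)
      brk_len <- c(brk_len, gap)
      pos <- run_mat[nk, 2L]
    }
    sessions[[length(sessions) + 1L]] <-
      list(start = st, end = pos, brk_start = brk_start, brk_len = brk_len)
    covered_until <- pos
  }
  session_metrics(x, sessions, config)
}

#' Sweep the session cadence threshold
#'
#' Re-runs session detection over a grid of minimum-cadence thresholds with
#' every other rule held fixed, summarizing how the session count, exerciser
#' count and mean session metrics respond.  Because any qualifying run at a
#' higher threshold also qualifies at a lower one, exerciser sets are nested
#' and the exerciser count is non-increasing in the threshold.
#'
#' @param steps Minute-level table.
#' @param mask Valid-day mask, or `NULL`.
#' @param thresholds Ascending positive cadence thresholds (steps/min).
#' @param config Base [session_config()]; its `cadence_threshold` is
#'   replaced by each grid value in turn.
#' @return `data.table`: one row per threshold with `threshold`,
#'   `n_sessions`, `n_exercisers`, `mean_duration_min`, `mean_cadence`.
#' @export
sweep_thresholds <- function(steps, mask = NULL,
                             thresholds = c(30, 40, 50, 60),
                             config = session_config()) {
  if (!length(thresholds)) {
    stop("thresholds must be a nonempty ascending vector", call. = FALSE)
  }
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be positive and strictly ascending", call. = FALSE)
  }
  rows <- lapply(thresholds, function(th) {
    cfg <- session_config(cadence_threshold = th,
                          min_start_run = config$min_start_run,
                          max_break_len = config$max_break_len,
                          min_terminal_gap = config$min_terminal_gap,
                          vigorous_threshold = config$vigorous_threshold,
                          mv_threshold = config$mv_threshold)
    sess <- detect_sessions(steps, mask, cfg)
    data.table::data.table(
      threshold = th,
      n_sessions = nrow(sess),
      n_exercisers = data.table::uniqueN(sess$participant_id),
      mean_duration_min = if (nrow(sess)) mean(sess$duration_min) else NA_real_,
      mean_cadence = if (nrow(sess)) mean(sess$mean_cadence) else NA_real_)
  })
  data.table::rbindlist(rows)
}
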