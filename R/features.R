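#' Canonical aggregate-feature names
#'
#' The per-participant activity features summarizing the monitoring period:
#' mean session cadence and duration, sessions per week, and the four daily
#' step aggregates split by in-/out-of-session and by vigorous cadence,
#' plus the moderate-to-vigorous out-of-session aggregate reported for
#' non-exercisers.
#'
#' @return Character vector of feature column names.
#' @export
feature_names <- function() {
  c("session_cadence", "session_duration", "session_frequency",
    "daily_in_session_steps", "daily_vigorous_in_session_steps",
    "daily_out_of_session_steps", "daily_vigorous_out_of_session_steps",
    "daily_mv_out_of_session_steps")
}

#' @rdname feature_names
#' @details `core_feature_names()` returns the seven core modeling features
#'   (the moderate-to-vigorous out-of-session aggregate is descriptive only,
#'   reported for non-exercisers).
#' @export
core_feature_names <- function() feature_names()[1:7]

in_session_features <- function() {
  c("session_cadence", "session_duration", "session_frequency",
    "daily_in_session_steps", "daily_vigorous_in_session_steps")
}

out_session_features <- function() {
  c("daily_out_of_session_steps", "daily_vigorous_out_of_session_steps")
}

#' Aggregate per-participant activity features
#'
#' Computes, for every non-excluded participant, the aggregate feature
#' vector over valid days only: session cadence (mean of per-session mean
#' cadences), session duration (mean active minutes), session frequency
#' (`7 * n_sessions / n_valid_days`), and daily in-/out-of-session step
#' aggregates.  Out-of-session steps are all valid-day steps not taken in a
#' session's active minutes, so break minutes count as out-of-session and
#' step totals are conserved exactly: `daily_in + daily_out` equals total
#' valid-day steps per valid day.  Vigorous aggregates count minutes at or
#' above the vigorous cadence threshold (default 120 steps/min);
#' moderate-to-vigorous uses the MV threshold (default 100 steps/min).
#' Participants with no sessions get `NA` session cadence/duration (never
#' zero) and `is_exerciser = FALSE`.
#'
#' @param sessions Session table from [detect_sessions()] on the same
#'   `steps`/`mask`/`config`.
#' @param steps Minute-level table.
#' @param mask Valid-day mask from [compute_valid_days()].
#' @param config The [session_config()] used for detection.
#' @return `data.table`, one row per non-excluded participant: the columns
#'   of [feature_names()] plus `is_exerciser`, `n_sessions`, `n_valid_days`.
#' @export
aggregate_features <- function(sessions, steps, mask,
                               config = session_config()) {
  dt <- data.table::as.data.table(steps)
  data.table::setkey(dt, participant_id, timestamp)
  psum <- valid_day_summary(mask)
  keep <- psum$participant_id[!psum$excluded]

  if (!length(keep)) return(empty_feature_table())
  rows <- lapply(keep, function(pid) {
    pdays <- mask[mask$participant_id == pid]
    nv <- sum(pdays$valid)
    if (nv == 0) {
      stop(sprintf("participant %s has no valid days; features undefined",
                   pid), call. = FALSE)
    }
    sd <- dt[participant_id == pid]
    ps <- sessions[sessions$participant_id == pid, , drop = FALSE]
    ns <- nrow(ps)

    valid_dates <- pdays$date[pdays$valid]
    day_of <- as.Date(sd$timestamp, tz = "UTC")
    on_valid <- day_of %in% valid_dates

    in_mask <- logical(nrow(sd))
    if (ns) {
      for (k in seq_len(ns)) {
        idx <- ps$start_minute[k]:ps$end_minute[k]
        in_mask[idx] <- sd$steps[idx] >= config$cadence_threshold
      }
    }
    out_steps <- sd$steps[on_valid & !in_mask]
    tot_valid <- sum(sd$steps[on_valid])
    in_tot <- if (ns) sum(ps$total_steps) else 0L

    data.table::data.table(
      participant_id = pid,
      session_cadence = if (ns) mean(ps$mean_cadence) else NA_real_,
      session_duration = if (ns) mean(ps$duration_min) else NA_real_,
      session_frequency = 7 * ns / nv,
      daily_in_session_steps = in_tot / nv,
      daily_vigorous_in_session_steps =
        (if (ns) sum(ps$vigorous_steps) else 0L) / nv,
      daily_out_of_session_steps = (tot_valid - in_tot) / nv,
      daily_vigorous_out_of_session_steps =
        sum(out_steps[out_steps >= config$vigorous_threshold]) / nv,
      daily_mv_out_of_session_steps =
        sum(out_steps[out_steps >= config$mv_threshold]) / nv,
      is_exerciser = ns > 0L,
      n_sessions = ns,
      n_valid_days = nv)
  })
  data.table::rbindlist(rows)
}

empty_feature_table <- function() {
  out <- data.table::data.table(
    participant_id = character(), session_cadence = numeric(),
    session_duration = numeric(), session_frequency = numeric(),
    daily_in_session_steps = numeric(),
    daily_vigorous_in_session_steps = numeric(),
    daily_out_of_session_steps = numeric(),
    daily_vigorous_out_of_session_steps = numeric(),
    daily_mv_out_of_session_steps = numeric(),
    is_exerciser = logical(), n_sessions = integer(),
    n_valid_days = integer())
  out
}

#' Partition a cohort into exercisers and non-exercisers
#'
#' A participant is an exerciser when they completed at least one
#' physical-activity session during the monitoring period.
#'
#' @param features Result of [aggregate_features()].
#' @return List with `exercisers` and `non_exercisers` (character id
#'   vectors), counts `n_exercisers`/`n_non_exercisers`, and `fraction`
#'   (share of exercisers).
#' @export
classify_exercisers <- function(features) {
  ex <- features$participant_id[features$is_exerciser]
  nx <- features$participant_id[!features$is_exerciser]
  list(exercisers = ex, non_exercisers = nx,
       n_exercisers = length(ex), n_non_exercisers = length(nx),
       fraction = length(ex) / nrow(features))
}
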