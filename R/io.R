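#' Read minute-level step counts from a long-format CSV
#'
#' Reads a CSV with header columns `participant_id`, `timestamp`
#' (ISO-8601, minute resolution) and `steps`, and returns one tidy
#' minute-level table.  Every calendar day in each participant's monitoring
#' window (first observed day through last observed day) is materialized as
#' 1440 minutes; minutes absent from the file are zero-filled, matching the
#' convention of consumer-device exports where unrecorded minutes mean no
#' steps.  Timestamps are taken at face value as local clock time (no
#' timezone conversion); day boundaries are local midnight.
#'
#' @param path Path to the CSV file.
#' @return A `data.table` with columns `participant_id` (character),
#'   `timestamp` (POSIXct, UTC-encoded clock time), `steps` (integer),
#'   sorted by participant then time, strictly 1-minute spacing.
#' @section Errors:
#' Malformed timestamps and negative or non-integer step values abort with
#' the offending row number; duplicated (participant, minute) rows abort
#' with an integrity error.
#' @export
read_minute_steps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, colClasses = list(character = "timestamp"))
  need <- c("participant_id", "timestamp", "steps")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ts <- as.POSIXct(rep(NA_real_, nrow(raw)), origin = "1970-01-01",
                   tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(raw$timestamp[todo], fmt, tz = "UTC"))
  }
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("malformed timestamp '%s' at data row %d",
                 raw$timestamp[bad], bad), call. = FALSE)
  }
  st <- raw$steps
  if (is.character(st)) st <- suppressWarnings(as.numeric(st))
  bad <- which(is.na(st) | st < 0 | st != round(st))
  if (length(bad)) {
    stop(sprintf("invalid step value '%s' at data row %d (steps must be nonnegative integers)",
                 as.character(raw$steps[bad[1]]), bad[1]), call. = FALSE)
  }
  dt <- data.table::data.table(participant_id = as.character(raw$participant_id),
                               timestamp = ts, steps = as.integer(st))
  # minute resolution: truncate seconds
  dt[, timestamp := as.POSIXct(60 * (as.numeric(timestamp) %/% 60),
                               origin = "1970-01-01", tz = "UTC")]
  dup <- duplicated(dt, by = c("participant_id", "timestamp"))
  if (any(dup)) {
    d <- dt[which(dup)[1]]
    stop(sprintf("duplicate timestamp %s for participant %s",
                 format(d$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                 d$participant_id), call. = FALSE)
  }
  data.table::setkey(dt, participant_id, timestamp)

  # materialize full days over each participant's observed window
  filled <- dt[, {
    day0 <- as.Date(min(timestamp), tz = "UTC")
    day1 <- as.Date(max(timestamp), tz = "UTC")
    start <- as.POSIXct(paste(day0, "00:00:00"), tz = "UTC")
    end <- as.POSIXct(paste(day1, "23:59:00"), tz = "UTC")
    grid <- seq(start, end, by = 60)
    s <- integer(length(grid))
    s[match(as.numeric(timestamp), as.numeric(grid))] <- steps
    list(timestamp = grid, steps = s)
  }, by = participant_id]
  data.table::setkey(filled, participant_id, timestamp)
  filled[]
}

#' Write minute-level step counts to CSV
#'
#' Inverse of [read_minute_steps()]: writes `participant_id`, ISO-8601
#' `timestamp`, `steps`.  A written-then-read series reproduces the input
#' exactly (full days are already materialized).
#'
#' @param steps Minute-level table as returned by [read_minute_steps()] or
#'   [simulate_minute_series()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_minute_steps <- function(steps, path) {
  out <- data.table::as.data.table(steps)[, .(
    participant_id,
    timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    steps)]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Flag valid monitoring days and excluded participants
#'
#' A monitored day is valid when its total step count is at least
#' `min_daily_steps` (default 100); days below that are treated as non-wear
#' and excluded.  Participants with fewer than `min_valid_days` valid days
#' (default 7) are flagged as excluded from downstream analysis, but are
#' retained in the mask with their exclusion reason for auditability.
#'
#' @param steps Minute-level table (see [read_minute_steps()]).
#' @param min_daily_steps Minimum daily total for a valid day.
#' @param min_valid_days Minimum number of valid days to retain a
#'   participant.
#' @return A `data.table` of class `valid_day_mask` with one row per
#'   participant-day: `participant_id`, `date`, `total_steps`, `valid`; the
#'   participant-level summary (`n_valid_days`, `excluded`, `reason`) is in
#'   `attr(, "participants")`.
#' @export
compute_valid_days <- function(steps, min_daily_steps = 100,
                               min_valid_days = 7) {
  dt <- data.table::as.data.table(steps)
  if (nrow(dt) == 0) stop("empty step series", call. = FALSE)
  days <- dt[, .(total_steps = sum(steps)),
             by = .(participant_id, date = as.Date(timestamp, tz = "UTC"))]
  days[, valid := total_steps >= min_daily_steps]
  part <- days[, .(n_valid_days = sum(valid)), by = participant_id]
  part[, excluded := n_valid_days < min_valid_days]
  part[, reason := data.table::fifelse(
    excluded, sprintf("fewer than %d valid days (%d)", min_valid_days,
                      n_valid_days), "")]
  data.table::setkey(days, participant_id, date)
  data.table::setattr(days, "participants", part[])
  data.table::setattr(days, "class",
                      c("valid_day_mask", class(days)))
  days[]
}

#' @export
print.valid_day_mask <- function(x, ...) {
  part <- attr(x, "participants")
  cat(sprintf("Valid-day mask: %d participants, %d participant-days (%d valid)\n",
              nrow(part), nrow(x), sum(x$valid)))
  if (any(part$excluded)) {
    cat(sprintf("  excluded participants: %d (insufficient valid days)\n",
                sum(part$excluded)))
  }
  invisible(x)
}

#' Participant-level summary of a valid-day mask
#'
#' @param mask A [compute_valid_days()] result.
#' @return data.table with `participant_id`, `n_valid_days`, `excluded`,
#'   `reason`.
#' @export
valid_day_summary <- function(mask) {
  part <- attr(mask, "participants")
  if (is.null(part)) stop("not a valid_day_mask", call. = FALSE)
  part
}
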