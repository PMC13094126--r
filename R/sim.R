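#' Specify a synthetic actigraphy cohort
#'
#' Builds the parameter object driving the synthetic-cohort generator.  The
#' generator plants discrete physical-activity sessions (contiguous runs of
#' minutes at or above a cadence floor, optionally interrupted by one short
#' sub-threshold break) on top of fragmented background stepping, marks whole
#' days as non-wear, and simulates brain-health outcomes as linear functions
#' of the true (planted) activity features plus covariate effects and noise.
#'
#' Defaults are calibrated to the descriptive statistics of a community
#' cohort of older adults wearing a wrist device for 30 days: roughly 79%
#' of participants complete at least one session, sessions average about
#' 25 minutes at a mean cadence near 90 steps/min (SD 11), about 4 sessions
#' per week, and around 6000 background (out-of-session) steps per day.
#'
#' @param n_participants Number of participants to simulate.
#' @param n_days Monitoring days per participant (default 30).
#' @param session_rate_per_week Mean sessions/week across exercisers.  Each
#'   exerciser draws a personal weekly rate from a gamma distribution with
#'   this mean (see `session_rate_dispersion`), and session counts are
#'   Poisson at that rate, floored at one session (when the rate is
#'   positive) so the planted exerciser label is honest.
#' @param session_rate_dispersion Gamma shape of the per-participant rate
#'   mixing distribution; the default 1 (exponential) gives a
#'   between-participant SD equal to the mean rate.
#' @param session_duration_mean_min,session_duration_sd_min Mean and
#'   between-participant SD of each person's typical session duration,
#'   minutes; individual sessions jitter around the personal mean with SD
#'   `session_duration_within_sd` (durations truncated to `[10, 180]`).
#' @param session_duration_within_sd Within-participant session-duration SD.
#' @param session_cadence_mean,session_cadence_sd Mean and
#'   between-participant SD of each person's typical session cadence,
#'   steps/min; sessions jitter around the personal mean with SD
#'   `session_cadence_within_sd` (cadences truncated to `[45, 140]`).
#'   Persistent person-level differences dominate, as they do in observed
#'   cohorts, so the between-participant SD of the aggregated
#'   session-cadence feature tracks `session_cadence_sd`.
#' @param session_cadence_within_sd Within-participant session-cadence SD.
#' @param within_session_sd Minute-to-minute cadence SD inside a session.
#' @param break_prob Probability a session of at least 12 active minutes
#'   contains one sub-threshold break of 1--9 minutes.
#' @param background_active_prob Per-minute probability of nonzero background
#'   stepping on a wear day.
#' @param background_cadence_max Maximum background cadence, steps/min; kept
#'   below `min_cadence` so background alone can never form a session.
#' @param burst_per_day Mean number per wear day of short (1--6 min)
#'   above-threshold background bursts; too short to open a session and
#'   placed at least 10 min away from planted sessions so they never merge.
#' @param nonwear_day_prob Probability a day is non-wear (all-zero).
#' @param exerciser_fraction Target fraction of participants with at least
#'   one planted session.
#' @param min_cadence Cadence floor (steps/min) defining an active minute;
#'   must match the detector threshold for planted sessions to be recovered.
#' @param outcome_betas Named numeric vector of planted standardized effects
#'   of true features on the latent outcome; names must be aggregate-feature
#'   names (see [aggregate_features()]).
#' @param covariate_betas Named numeric vector of standardized covariate
#'   effects, names among `age`, `sex`, `education`, `tiv`.
#' @param noise_sd Residual SD of the latent outcome.
#'
#' @return An object of class `sim_spec` (a validated list).
#' @seealso [simulate_cohort()], [simulate_minute_series()]
#' @export
sim_spec <- function(n_participants = 100,
                     n_days = 30,
                     session_rate_per_week = 4,
                     session_rate_dispersion = 1,
                     session_duration_mean_min = 25,
                     session_duration_sd_min = 15,
                     session_duration_within_sd = 8,
                     session_cadence_mean = 90,
                     session_cadence_sd = 11,
                     session_cadence_within_sd = 3,
                     within_session_sd = 8,
                     break_prob = 0.5,
                     background_active_prob = 0.21,
                     background_cadence_max = 39,
                     burst_per_day = 1,
                     nonwear_day_prob = 0.067,
                     exerciser_fraction = 0.79,
                     min_cadence = 40,
                     outcome_betas = c(session_frequency = 0.5,
                                       session_cadence = 0.25),
                     covariate_betas = c(age = -0.3, sex = 0.1,
                                         education = 0.2, tiv = 0),
                     noise_sd = 0.5) {
  spec <- list(
    n_participants = n_participants, n_days = n_days,
    session_rate_per_week = session_rate_per_week,
    session_rate_dispersion = session_rate_dispersion,
    session_duration_mean_min = session_duration_mean_min,
    session_duration_sd_min = session_duration_sd_min,
    session_duration_within_sd = session_duration_within_sd,
    session_cadence_mean = session_cadence_mean,
    session_cadence_sd = session_cadence_sd,
    session_cadence_within_sd = session_cadence_within_sd,
    within_session_sd = within_session_sd,
    break_prob = break_prob,
    background_active_prob = background_active_prob,
    background_cadence_max = background_cadence_max,
    burst_per_day = burst_per_day,
    nonwear_day_prob = nonwear_day_prob,
    exerciser_fraction = exerciser_fraction,
    min_cadence = min_cadence,
    outcome_betas = outcome_betas,
    covariate_betas = covariate_betas,
    noise_sd = noise_sd
  )
  validate_sim_spec(spec)
  structure(spec, class = "sim_spec")
}

validate_sim_spec <- function(spec) {
  need_pos_int <- c("n_participants", "n_days")
  for (f in need_pos_int) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 1 ||
        v != round(v)) {
      stop(sprintf("sim_spec field '%s' must be a positive integer", f),
           call. = FALSE)
    }
  }
  probs <- c("break_prob", "background_active_prob", "nonwear_day_prob",
             "exerciser_fraction")
  for (f in probs) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("sim_spec field '%s' must be a probability in [0, 1]", f),
           call. = FALSE)
    }
  }
  pos <- c("session_duration_mean_min", "session_duration_sd_min",
           "session_duration_within_sd", "session_cadence_mean",
           "session_cadence_sd", "session_cadence_within_sd",
           "session_rate_dispersion", "within_session_sd",
           "noise_sd", "min_cadence", "background_cadence_max")
  for (f in pos) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop(sprintf("sim_spec field '%s' must be positive", f), call. = FALSE)
    }
  }
  nonneg <- c("session_rate_per_week", "burst_per_day")
  for (f in nonneg) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stop(sprintf("sim_spec field '%s' must be nonnegative", f),
           call. = FALSE)
    }
  }
  if (spec$background_cadence_max >= spec$min_cadence) {
    stop("sim_spec field 'background_cadence_max' must be below 'min_cadence'",
         call. = FALSE)
  }
  bad <- setdiff(names(spec$outcome_betas), feature_names())
  if (length(bad)) {
    stop(sprintf("sim_spec field 'outcome_betas' names unknown feature(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  badc <- setdiff(names(spec$covariate_betas),
                  c("age", "sex", "education", "tiv"))
  if (length(badc)) {
    stop(sprintf("sim_spec field 'covariate_betas' names unknown covariate(s): %s",
                 paste(badc, collapse = ", ")), call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Synthetic actigraphy cohort specification\n")
  cat(sprintf("  participants: %d, days: %d, exerciser fraction: %.2f\n",
              x$n_participants, x$n_days, x$exerciser_fraction))
  cat(sprintf("  sessions/week: %.1f, duration %g (%g) min, cadence %g (%g) steps/min\n",
              x$session_rate_per_week, x$session_duration_mean_min,
              x$session_duration_sd_min, x$session_cadence_mean,
              x$session_cadence_sd))
  cat(sprintf("  planted effects: %s\n",
              paste(sprintf("%s=%g", names(x$outcome_betas), x$outcome_betas),
                    collapse = ", ")))
  invisible(x)
}

# Origin for simulated timestamps (UTC); any fixed local-naive origin works.
sim_origin <- function() as.POSIXct("2023-03-01 00:00:00", tz = "UTC")

# Simulate one participant's minute vector plus planted-session records.
# Returns list(steps = integer vector n_days*1440, wear = logical n_days,
#              sessions = data.frame, exerciser = logical).
simulate_participant <- function(spec, pseed) {
  set.seed(pseed)
  n_min <- spec$n_days * 1440L
  steps <- integer(n_min)
  wear <- runif(spec$n_days) >= spec$nonwear_day_prob

  # fragmented background stepping, always below the cadence floor
  for (d in which(wear)) {
    act <- which(runif(1440L) < spec$background_active_prob)
    if (length(act)) {
      steps[(d - 1L) * 1440L + act] <-
        sample.int(spec$background_cadence_max, length(act), replace = TRUE)
    }
  }

  # persistent person-level activity style: personal session rate, typical
  # cadence and typical duration, with session-to-session jitter below
  exerciser <- runif(1) < spec$exerciser_fraction
  rate_i <- if (spec$session_rate_per_week > 0)
    rgamma(1, shape = spec$session_rate_dispersion,
           scale = spec$session_rate_per_week / spec$session_rate_dispersion)
  else 0
  cad_i <- max(50, min(135, rnorm(1, spec$session_cadence_mean,
                                  spec$session_cadence_sd)))
  dur_i <- max(12, min(120, rnorm(1, spec$session_duration_mean_min,
                                  spec$session_duration_sd_min)))
  n_s <- 0L
  lam <- rate_i * spec$n_days / 7
  if (exerciser && any(wear) && lam > 0) {
    n_s <- max(1L, rpois(1L, lam))
  }

  sess <- vector("list", n_s)
  # per-day occupied [start, end] spans, day-local minute coords (1-based)
  occupied <- vector("list", spec$n_days)
  kept <- 0L
  if (n_s > 0L) {
    day_pick <- sample(which(wear), n_s, replace = TRUE)
    for (k in seq_len(n_s)) {
      d <- day_pick[k]
      L <- max(10L, min(180L, as.integer(round(
        rnorm(1, dur_i, spec$session_duration_within_sd)))))
      cad <- max(45, min(140, rnorm(1, cad_i,
                                    spec$session_cadence_within_sd)))
      brk <- if (runif(1) < spec$break_prob && L >= 12L)
        sample.int(9L, 1L) else 0L
      span <- L + brk
      if (span > 1418L) { brk <- 0L; span <- L }
      if (span > 1418L) next
      start <- place_in_day(occupied[[d]], span)
      if (is.na(start)) next
      occupied[[d]] <- rbind(occupied[[d]], c(start, start + span - 1L))

      active_steps <- pmax(spec$min_cadence, pmin(220L, as.integer(round(
        rnorm(L, cad, spec$within_session_sd)))))
      prof <- active_steps
      brk_pos <- NA_integer_
      if (brk > 0L) {
        # break begins after the 10-min opening run, at least 1 active after
        brk_pos <- sample(10:(L - 1L), 1L)
        brk_steps <- sample(0:(spec$min_cadence - 1L), brk, replace = TRUE)
        prof <- c(active_steps[1:brk_pos], brk_steps,
                  active_steps[(brk_pos + 1L):L])
      }
      g0 <- (d - 1L) * 1440L + start - 1L  # 0-based global offset
      steps[g0 + seq_along(prof)] <- prof
      kept <- kept + 1L
      sess[[kept]] <- data.frame(
        day = d,
        start_minute = g0 + 1L,
        end_minute = g0 + span,
        active_minutes = L,
        n_breaks = as.integer(brk > 0L),
        break_minutes = brk,
        total_steps = sum(active_steps),
        vigorous_steps = sum(active_steps[active_steps >= 120L]),
        mean_cadence = sum(active_steps) / L
      )
    }
  }
  sessions <- if (kept > 0L) do.call(rbind, sess[seq_len(kept)]) else
    data.frame(day = integer(), start_minute = integer(),
               end_minute = integer(), active_minutes = integer(),
               n_breaks = integer(), break_minutes = integer(),
               total_steps = integer(), vigorous_steps = integer(),
               mean_cadence = numeric())

  # short above-threshold bursts: never long enough to open a session and
  # kept >= 10 min clear of planted sessions so they cannot extend one
  if (spec$burst_per_day > 0) {
    for (d in which(wear)) {
      nb <- rpois(1L, spec$burst_per_day)
      for (j in seq_len(nb)) {
        len <- sample.int(6L, 1L)
        start <- place_in_day(occupied[[d]], len)
        if (is.na(start)) next
        occupied[[d]] <- rbind(occupied[[d]], c(start, start + len - 1L))
        g0 <- (d - 1L) * 1440L + start - 1L
        steps[g0 + seq_len(len)] <-
          sample(spec$min_cadence:135L, len, replace = TRUE)
      }
    }
  }

  list(steps = steps, wear = wear, sessions = sessions,
       exerciser = kept > 0L)
}

# Pick a start minute (1-based, day-local) for a span so that it sits at
# least 11 minutes inside the day boundary and at least 11 minutes away from
# every occupied span (=> >= 10 sub-threshold minutes between spans, and
# cross-midnight spans never abut).  NA when no slot found.
place_in_day <- function(occ, span, tries = 60L) {
  lo <- 12L
  hi <- 1440L - span - 10L
  if (hi < lo) return(NA_integer_)
  for (t in seq_len(tries)) {
    s <- sample(lo:hi, 1L)
    e <- s + span - 1L
    if (is.null(occ) ||
        all(s > occ[, 2] + 10L | e < occ[, 1] - 10L)) {
      return(s)
    }
  }
  NA_integer_
}

#' Simulate minute-level step series with known ground truth
#'
#' Generates per-participant minute-level step counts over the monitoring
#' window together with a ground-truth record of every planted session.
#' A single integer seed drives the whole simulation; each participant gets
#' a deterministically derived sub-stream, so increasing `n_participants`
#' leaves earlier participants' data unchanged.
#'
#' @param spec A [sim_spec()] object.
#' @param seed Integer seed.
#' @return A list with elements
#' \describe{
#'   \item{steps}{`data.table` with columns `participant_id`, `timestamp`
#'     (POSIXct, minute resolution, UTC), `steps` (nonnegative integer);
#'     `n_days * 1440` rows per participant.}
#'   \item{truth}{list with `sessions` (one row per planted session),
#'     `participants` (planted exerciser flag, wear days), `features`
#'     (true aggregate features per participant), and the spec.}
#' }
#' @export
simulate_minute_series <- function(spec, seed) {
  sim <- simulate_internal(spec, seed)
  list(steps = sim$steps, truth = sim$truth)
}

simulate_internal <- function(spec, seed) {
  stopifnot(inherits(spec, "sim_spec"))
  validate_sim_spec(spec)
  n <- spec$n_participants
  ids <- sprintf("P%04d", seq_len(n))
  n_min <- spec$n_days * 1440L

  per <- vector("list", n)
  for (i in seq_len(n)) {
    per[[i]] <- simulate_participant(spec, derive_seed(seed, i))
  }

  steps_all <- unlist(lapply(per, `[[`, "steps"), use.names = FALSE)
  ts_one <- sim_origin() + 60 * (seq_len(n_min) - 1)
  steps_dt <- data.table::data.table(
    participant_id = rep(ids, each = n_min),
    timestamp = rep(ts_one, times = n),
    steps = as.integer(steps_all)
  )

  truth_sessions <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    s <- per[[i]]$sessions
    if (nrow(s)) cbind(participant_id = ids[i], s) else NULL
  }))

  feats <- do.call(rbind, lapply(seq_len(n), function(i) {
    true_features_one(per[[i]], spec)
  }))
  features <- data.frame(participant_id = ids, feats,
                         stringsAsFactors = FALSE)

  participants <- data.frame(
    participant_id = ids,
    exerciser = vapply(per, `[[`, logical(1), "exerciser"),
    n_wear_days = vapply(per, function(p) sum(p$wear), integer(1)),
    stringsAsFactors = FALSE
  )

  list(steps = steps_dt, per = per,
       truth = list(sessions = truth_sessions, participants = participants,
                    features = features, spec = spec, seed = seed))
}

# True aggregate features for one simulated participant, computed from the
# planted structure (not via the detector).
true_features_one <- function(p, spec) {
  day_tot <- vapply(seq_along(p$wear), function(d) {
    sum(p$steps[((d - 1L) * 1440L + 1L):(d * 1440L)])
  }, numeric(1))
  valid <- p$wear & day_tot >= 100
  nv <- sum(valid)
  s <- p$sessions
  ns <- nrow(s)
  if (nv == 0L) {
    return(data.frame(session_cadence = NA_real_, session_duration = NA_real_,
                      session_frequency = NA_real_,
                      daily_in_session_steps = NA_real_,
                      daily_vigorous_in_session_steps = NA_real_,
                      daily_out_of_session_steps = NA_real_,
                      daily_vigorous_out_of_session_steps = NA_real_,
                      daily_mv_out_of_session_steps = NA_real_,
                      is_exerciser = FALSE, n_sessions = 0L,
                      n_valid_days = 0L))
  }
  # in-session active-minute mask (break minutes excluded)
  in_mask <- logical(length(p$steps))
  if (ns) {
    for (k in seq_len(ns)) {
      idx <- s$start_minute[k]:s$end_minute[k]
      in_mask[idx] <- p$steps[idx] >= spec$min_cadence
    }
  }
  valid_mask <- rep(valid, each = 1440L)
  out_idx <- which(valid_mask & !in_mask)
  out_steps <- p$steps[out_idx]
  tot_valid <- sum(p$steps[valid_mask])
  in_steps <- if (ns) sum(s$total_steps) else 0
  data.frame(
    session_cadence = if (ns) mean(s$mean_cadence) else NA_real_,
    session_duration = if (ns) mean(s$active_minutes) else NA_real_,
    session_frequency = 7 * ns / nv,
    daily_in_session_steps = in_steps / nv,
    daily_vigorous_in_session_steps =
      (if (ns) sum(s$vigorous_steps) else 0) / nv,
    daily_out_of_session_steps = (tot_valid - in_steps) / nv,
    daily_vigorous_out_of_session_steps = sum(out_steps[out_steps >= 120]) / nv,
    daily_mv_out_of_session_steps = sum(out_steps[out_steps >= 100]) / nv,
    is_exerciser = ns > 0L,
    n_sessions = ns,
    n_valid_days = as.integer(nv)
  )
}

#' Simulate a full cohort: step series, demographics and outcomes
#'
#' Extends [simulate_minute_series()] with demographics (age 40--91 years,
#' binary sex with female = 1, education, total intracranial volume) and
#' seven brain-health outcomes.  Each outcome is built from a shared latent
#' linear predictor: the planted standardized effects (`outcome_betas`)
#' applied to z-scored true features, plus standardized covariate effects,
#' plus independent Gaussian noise per outcome.  Cognitive composites are on
#' the latent (z-like) scale; volumes, white-matter hyperintensity burden
#' (lognormal, hence right-skewed; higher latent health means lower burden)
#' and fractional anisotropy are mapped to realistic units.
#'
#' Session-only features (cadence, duration) are z-scored among exercisers;
#' non-exercisers contribute zero for those terms.
#'
#' @inheritParams simulate_minute_series
#' @return A list with `steps`, `truth` (as in [simulate_minute_series()],
#'   plus `lp`, the latent linear predictor), and `panel`: a data.frame of
#'   `participant_id`, demographics and outcome columns (`memory`,
#'   `executive`, `processing_speed`, `mtl_volume`, `frontal_volume`,
#'   `wmh_burden`, `global_fa`).
#' @export
simulate_cohort <- function(spec, seed) {
  sim <- simulate_internal(spec, seed)
  n <- spec$n_participants
  ids <- sim$truth$participants$participant_id

  demo <- do.call(rbind, lapply(seq_len(n), function(i) {
    set.seed(derive_seed(seed, i, salt = 1L))
    data.frame(
      age = max(40, min(91, rnorm(1, 72.4, 9.9))),
      sex = rbinom(1, 1, 0.56),
      education = max(10, min(22, rnorm(1, 17.5, 2.24))),
      tiv = rnorm(1, 1.45e6, 1.3e5)
    )
  }))

  lp <- latent_predictor(sim$truth$features, demo, spec)

  outs <- c("memory", "executive", "processing_speed", "mtl_volume",
            "frontal_volume", "wmh_burden", "global_fa")
  eps <- do.call(rbind, lapply(seq_len(n), function(i) {
    set.seed(derive_seed(seed, i, salt = 2L))
    rnorm(length(outs), 0, spec$noise_sd)
  }))
  colnames(eps) <- outs

  panel <- data.frame(
    participant_id = ids, demo,
    memory = lp + eps[, "memory"],
    executive = lp + eps[, "executive"],
    processing_speed = lp + eps[, "processing_speed"],
    mtl_volume = 9664 + 1028 * (lp + eps[, "mtl_volume"]),
    frontal_volume = 65118 + 7006 * (lp + eps[, "frontal_volume"]),
    wmh_burden = exp(7.5 - (lp + eps[, "wmh_burden"])),
    global_fa = 0.44 + 0.03 * (lp + eps[, "global_fa"]),
    stringsAsFactors = FALSE
  )

  sim$truth$lp <- lp
  list(steps = sim$steps, truth = sim$truth, panel = panel)
}

# Latent outcome predictor from true features and demographics.
latent_predictor <- function(features, demo, spec) {
  n <- nrow(features)
  lp <- numeric(n)
  ex <- features$is_exerciser %in% TRUE
  session_only <- c("session_cadence", "session_duration")
  for (f in names(spec$outcome_betas)) {
    b <- spec$outcome_betas[[f]]
    if (b == 0) next
    v <- features[[f]]
    if (f %in% session_only) {
      z <- numeric(n)
      z[ex] <- zscore(v[ex])
      lp <- lp + b * z
    } else {
      v[is.na(v)] <- 0
      lp <- lp + b * zscore(v)
    }
  }
  covs <- list(age = demo$age, sex = demo$sex, education = demo$education,
               tiv = demo$tiv)
  for (cn in names(spec$covariate_betas)) {
    g <- spec$covariate_betas[[cn]]
    if (g == 0) next
    lp <- lp + g * zscore(covs[[cn]])
  }
  lp
}

#' Write a simulated cohort to disk
#'
#' Writes the minute-level step CSV (the same long format
#' [read_minute_steps()] consumes), the participant panel CSV, and a
#' ground-truth JSON sidecar (planted sessions, true features, planted
#' effects, seed).
#'
#' @param sim Result of [simulate_cohort()] or [simulate_minute_series()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  steps_path <- file.path(dir, "steps.csv")
  out <- data.table::copy(sim$steps)
  out[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")]
  data.table::fwrite(out, steps_path)
  paths <- steps_path
  if (!is.null(sim$panel)) {
    panel_path <- file.path(dir, "panel.csv")
    data.table::fwrite(sim$panel, panel_path)
    paths <- c(paths, panel_path)
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- sim$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, truth_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, POSIXt = "ISO8601")
  invisible(c(paths, truth_path))
}
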