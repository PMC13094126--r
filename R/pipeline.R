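#' Run the full analysis pipeline on a synthetic cohort
#'
#' One call covering the whole workflow: simulate a cohort, (optionally)
#' round-trip the minute data through CSV, apply the valid-day rules,
#' detect sessions, aggregate features, classify exercisers, residualize
#' outcomes, and fit the ridge importance model per outcome among
#' exercisers.  When `out_dir` is given, all artifacts (steps, mask,
#' sessions, features, panel CSVs and a JSON report per outcome) are
#' written there.
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed for the whole run.
#' @param outcomes Outcome columns to model (default `"executive"`).
#' @param out_dir Optional output directory; enables the CSV round trip.
#' @param n_boot Bootstrap resamples for each model's R-squared CI.
#' @param config [session_config()] used for detection.
#' @param k_folds Cross-validation folds.
#' @return List with `steps`, `mask`, `sessions`, `features`,
#'   `classification`, `residualized` outcomes, and `fits` (one
#'   [ridge_importance()] object per outcome).
#' @export
run_pipeline <- function(spec = sim_spec(n_participants = 300), seed = 1,
                         outcomes = "executive", out_dir = NULL,
                         n_boot = 0, config = session_config(),
                         k_folds = 10) {
  sim <- simulate_cohort(spec, seed)
  steps <- sim$steps
  if (!is.null(out_dir)) {
    write_sim(sim, out_dir)
    steps <- read_minute_steps(file.path(out_dir, "steps.csv"))
  }
  mask <- compute_valid_days(steps)
  sessions <- detect_sessions(steps, mask, config)
  feats <- aggregate_features(sessions, steps, mask, config)
  cls <- classify_exercisers(feats)
  resid_out <- prepare_outcomes(sim$panel, outcomes)

  fits <- list()
  for (o in outcomes) {
    ex <- as.data.frame(merge(feats[feats$is_exerciser, ], sim$panel,
                              by = "participant_id"))
    ex$.y <- resid_out[[o]][match(ex$participant_id,
                                  sim$panel$participant_id)]
    ex <- ex[complete.cases(ex[, c(core_feature_names(), "age", "sex",
                                   ".y")]), ]
    fits[[o]] <- ridge_importance(
      ex[, core_feature_names()], ex$.y, age = ex$age, sex = ex$sex,
      n_boot = n_boot, k_folds = k_folds,
      seed = derive_seed(seed, match(o, outcomes), salt = 3L))
  }

  if (!is.null(out_dir)) {
    data.table::fwrite(as.data.frame(mask), file.path(out_dir, "mask.csv"))
    data.table::fwrite(sessions, file.path(out_dir, "sessions.csv"))
    data.table::fwrite(feats, file.path(out_dir, "features.csv"))
    for (o in names(fits)) {
      f <- fits[[o]]
      rep <- list(outcome = o, lambda_opt = f$lambda_opt,
                  coefficients = as.list(f$coefficients),
                  r2 = f$r2, mae = f$mae,
                  r2_ci = if (is.null(f$r2_ci)) NULL else
                    as.numeric(f$r2_ci),
                  importance = as.list(f$importance),
                  group_contrib = as.list(f$group_contrib),
                  n_used = f$n_used, seed = f$seed)
      jsonlite::write_json(rep,
                           file.path(out_dir, sprintf("report_%s.json", o)),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  list(steps = steps, mask = mask, sessions = sessions, features = feats,
       classification = cls, panel = sim$panel, truth = sim$truth,
       residualized = resid_out, fits = fits)
}
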