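# stepbouts

Wrist-worn consumer devices record step counts minute by minute, but most
analyses collapse them to totals, losing the distinction between sustained,
intentional bouts of activity and incidental everyday movement.
`stepbouts` is an R package for researchers in physical-activity
epidemiology and brain aging who want to recover that structure.  It

1. **detects discrete physical-activity sessions** from minute-level step
   counts: a session opens with ≥ 10 consecutive minutes at a cadence of
   ≥ 40 steps/min, tolerates sub-threshold breaks of < 10 min, and ends at
   the last active minute followed by ≥ 10 sub-threshold minutes;
2. **engineers per-participant features** over valid wear days (≥ 100
   steps/day, ≥ 7 valid days): mean session cadence and duration, sessions
   per week, and daily in-/out-of-session step aggregates split at
   vigorous (≥ 120 steps/min) and moderate-to-vigorous (≥ 100 steps/min)
   cadence — plus the exerciser label (≥ 1 session in the monitoring
   period);
3. **ranks feature importance for brain-health outcomes**: outcomes are
   residualized on covariates, then regressed among exercisers on the 42
   standardized terms (7 features, 21 pairwise products, 7 × age, 7 × sex)
   with ridge regression,

   minimize  (1/2n)‖y − α − Xβ‖² + (λ/2)‖β‖²,

   λ chosen by seeded 10-fold cross-validation; importance of term *j* is
   |β_j| / Σ|β_k|, with in-session / out-of-session / cross group shares
   and a nonparametric bootstrap percentile CI for the cross-validated R².

A seeded synthetic-cohort generator with planted sessions and known effect
sizes (`sim_spec()`, `simulate_cohort()`) makes the whole pipeline testable
without access to any cohort data, and the descriptive group statistics
used around such models (signed-rank tests with exact enumeration at small
n, ANCOVA with partial η², FDR-corrected bivariate scans, pooled-t sex
comparisons) are included.

## Worked example

```r
library(stepbouts)

spec <- sim_spec(n_participants = 120)        # 30 days, ~79% exercisers
sim  <- simulate_cohort(spec, seed = 42)

mask     <- compute_valid_days(sim$steps)     # >=100 steps/day, >=7 days
sessions <- detect_sessions(sim$steps, mask)
features <- aggregate_features(sessions, sim$steps, mask)
cls      <- classify_exercisers(features)

resid <- prepare_outcomes(sim$panel, "executive")  # residualize on age/sex/edu
ex  <- as.data.frame(features[features$is_exerciser, ])
pex <- sim$panel[match(ex$participant_id, sim$panel$participant_id), ]
y   <- resid$executive[match(ex$participant_id, sim$panel$participant_id)]

fit <- ridge_importance(ex[, core_feature_names()], y,
                        age = pex$age, sex = pex$sex,
                        n_boot = 1000, seed = 42)
print(fit)
```

```
Ridge feature-importance model (full design, 42 terms, n = 84)
  lambda (10-fold CV optimum): 0.6579
  cross-validated R-squared: 0.495   MAE: 0.578
  bootstrap 95% CI for R-squared: (0.373, 0.698) [1000 resamples]
  top terms (share of total |coefficient|):
    session_frequency                               9.7%
    daily_in_session_steps                          7.7%
    session_cadence                                 7.0%
    session_frequency:sex                           6.9%
    daily_in_session_steps:sex                      4.7%
```

The cohort was simulated with standardized effects of 0.5 on session
frequency and 0.25 on session cadence: among the 84 exercisers, session
frequency tops the ranking, the correlated in-session step volume and
session cadence follow, and physical-activity features explain about half
the residual outcome variance (R² = 0.495), consistent with the planted
signal-to-noise ratio.  `summary(fit)` lists all 42 terms with their group
(in-session / out-of-session / cross) contributions, `plot(fit)` draws the
importance bars, and `sensitivity_suite()` compares the feature ranking
against the mains-only and wear-days-adjusted variants.

`run_pipeline()` chains every step above; the same pipeline is scriptable
from a shell:

```sh
Rscript inst/cli/stepbouts.R pipeline --n 300 --days 30 --seed 17 \
    --outcome executive --out results/
```

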