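---
title: "Detecting physical-activity sessions and ranking their importance for brain health"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting physical-activity sessions and ranking their importance for brain health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Older adults' habitual physical activity is usually summarized by totals
(daily steps, minutes of moderate-to-vigorous activity).  Totals discard
the *structure* of activity: whether stepping is accumulated in sustained,
intentional bouts or in fragments of everyday movement.  `stepbouts`
implements a rule-based algorithm that isolates discrete activity
"sessions" from minute-level wrist-actigraphy step counts, derives
per-participant features that separate in-session from out-of-session
activity, and ranks those features' relative importance for cognitive and
neuroimaging outcomes with a residualize-then-ridge procedure.

The package is organized around one fitted object: `ridge_importance()`
returns an S3 model with the usual `print`, `summary`, `coef`, `predict`,
`fitted`, `residuals` and `plot` methods.  Everything upstream (reading and
validating minute data, session detection, feature aggregation, outcome
preparation) is a plain function; `run_pipeline()` chains them.

## Session definition

At minute-level sampling a minute's cadence equals its step count.  With
the defaults in `session_config()`:

* a minute is **active** when its cadence is at least 40 steps/min, a
  threshold associated with intentional, low-intensity stepping in older
  adults;
* a session **opens** at the first minute of at least 10 consecutive
  active minutes;
* once open, sub-threshold interruptions of **less than 10 minutes**
  ("session breaks": resting between sets, pausing a walk) are tolerated,
  and a single active minute after a break resumes the session — no second
  10-minute run is required;
* the session **ends** at the last active minute followed by at least 10
  sub-threshold minutes, or by the end of the recording (the terminal-gap
  rule exists to prevent premature closure, not to demand post-session
  data);
* session metrics (duration, total steps, steps at vigorous cadence,
  mean cadence) are computed over **active minutes only**, excluding
  breaks.  Mean cadence is therefore always at least the threshold.

`max_break_len = 9` with `min_terminal_gap = 10` encodes "breaks of less
than 10 minutes" in integer minutes.  Cadence cut-offs of 120 (vigorous)
and 100 (moderate-to-vigorous) steps/min follow the older-adult cadence
literature and are configurable.

Two deliberately open points were resolved as follows, and are
configuration rather than hard-coded behavior where possible:

* detection runs on the continuous timeline, so a session may span
  midnight; it is attributed to the calendar day containing its start
  minute;
* a session touching any invalid (non-wear) day is discarded entirely —
  its steps are untrusted.

A second, independently written detector (`detect_sessions_reference()`,
an exhaustive seed-and-merge scan) exists purely as a test oracle; the
randomized-equivalence tests require element-wise identical output from
both implementations.

## Day validity and features

A monitored day is valid when its total is at least 100 steps (a standard
non-wear proxy); participants with fewer than 7 valid days are excluded
but retained in the mask with their exclusion reason.  Sub-day non-wear
detection is out of scope; the day-total rule is applied verbatim.

`aggregate_features()` averages over valid days only, for consistency with
the exclusion rule.  Session frequency is `7 * n_sessions / n_valid_days`
rather than calendar-week bucketing, which is ill-defined for partial
weeks and biased under day subsampling.  Break minutes count toward
out-of-session steps — session metrics exclude breaks, and this convention
preserves exact step conservation, which the tests assert as an integer
identity: in-session active steps + break steps + out-of-session steps
equal the valid-day total.  Participants with no sessions get missing (not
zero) session cadence and duration, so models restricted to exercisers are
unaffected.

## Outcome preparation

Cognitive composites are sample-based z-scores averaged within domain,
with per-test orientations so that higher always means better.  Outcomes
with absolute sample skewness above 1 are log-transformed as
`log(x + 1)`; the offset keeps zero white-matter-hyperintensity volumes
finite, and the threshold/offset are arguments, since only the fact of the
transform — not its constants — is standard.  Outcomes containing values
at or below `-offset` (z-scale composites) are never logged: the transform
is undefined there and substantively wrong.  Each outcome is then
residualized on its covariate set (age, sex, education for cognition; age,
sex, total intracranial volume for neuroimaging — a configurable mapping),
and the residuals carry forward.  Residualization is exactly idempotent
and leaves residuals uncorrelated with each covariate to numerical
precision; complete cases are handled per outcome, so each outcome keeps
its own n.

## The importance model

Among exercisers, the design contains the 7 core features, their 21
pairwise products, and their products with age and with sex — 42 terms.
Age and sex main effects are excluded because outcomes are pre-residualized
on them.  Products are computed from standardized mains and then
re-standardized, so every column has unit variance and coefficient
magnitudes are comparable as relative importance.  Sex is coded female = 1,
so interaction coefficients read as female-vs-male moderation.

Standardization uses the population (1/n) SD convention.  The ridge
objective is

$$\frac{1}{2n}\lVert y - \alpha - X\beta \rVert^2 + \frac{\lambda}{2}\lVert\beta\rVert^2,$$

with an unpenalized intercept.  Under this convention grid values are
independent of n, and a single standardized column with $y = x$ has the
closed form $\hat\beta = 1/(1+\lambda)$, which the tests assert to 1e-10;
$\lambda \to 0$ reproduces OLS to 1e-8.  The solver uses one
eigendecomposition of $X^\top X / n$ per fit, so a whole 100-point grid
costs one decomposition.  The default grid is 100 log-spaced values in
$[10^{-4}, 10^{3}]$, spanning effectively-OLS to near-total shrinkage for
standardized data; ties in the cross-validated error resolve to the first
(smallest) grid value via `which.min`.

$\lambda$ is chosen by seeded 10-fold cross-validation on the minimum mean
held-out squared error.  Reported R² is the squared correlation of pooled
held-out predictions with the observed standardized outcome, and MAE their
mean absolute difference; an in-sample option exists behind the `metric`
flag because the reference workflow does not pin this down.  The
percentile bootstrap (default 1000 resamples) refits on row resamples and
recomputes the cross-validated R²; by default $\lambda$ stays fixed at the
full-sample optimum (fast and stable), with a retune mode available.

Importance of term $j$ is $|\beta_j| / \sum_k |\beta_k|$.  Terms partition
into three groups: in-session (5 mains, 10 in×in products, 10 in×age/sex
products = 25), out-of-session (2 mains, 1 out×out product, 4 out×age/sex
products = 7), and the 10 in×out cross products.  The cross products are
reported as their own group rather than folded into either side — the
natural resolution of an ambiguity in how "excluding interaction terms
with out-of-session features" applies to both groups at once.  Group
contributions use the same denominator, so the three shares sum to one.

Sensitivity variants: a mains-only model (7 features, no products) and the
full model with valid wear days appended as a standardized covariate
(dropped with a message if constant).  `sensitivity_suite()` reports the
rank order of the 7 core features under all three fits and their Spearman
concordance.

## Group statistics

* Paired in- vs out-of-session comparisons use the Wilcoxon signed-rank
  test: exact two-sided p by enumeration of all $2^n$ sign assignments for
  up to 12 retained pairs (valid under ties), otherwise the normal
  approximation with a 0.5 continuity correction and tie-corrected
  variance.  Zero differences are dropped before ranking and counted.
* Exerciser/non-exerciser contrasts use ANCOVA; partial $\eta^2$ is
  SS(group) / (SS(group) + SS(residual)), with SS(group) the unique
  reduction in residual SS when the group term enters last.  A test
  cross-checks this against an explicit projection-matrix decomposition
  and against type-III SS from `car::Anova`.
* Feature-outcome scans report covariate-adjusted standardized slopes with
  Benjamini–Hochberg adjustment across the scan (the FDR procedure is an
  argument; the method choice is a default, not a claim).
* Sex comparisons default to the pooled (Student) t-test — integer
  n − 2 degrees of freedom, matching printed values like t(277) for groups
  of 122 and 157 — with Welch behind a flag; neuroimaging variables are
  compared with TIV adjustment via a linear model.

## The synthetic cohort generator

No public minute-level cohort with these outcomes exists, so the package
carries a seeded generator whose defaults *are* the study conditions the
pipeline targets: 30 days of monitoring, about 79% exercisers, roughly 4
sessions/week, session cadence centered near 90 steps/min with a
between-person SD near 11, typical durations near 25 minutes, about 28
valid days, and several thousand background steps/day.

Design choices:

* **Person-level styles.** Each participant draws a personal mean cadence,
  a personal typical duration, and a personal weekly session rate (gamma
  mixed; the default shape of 1 gives rate SD equal to the mean).
  Individual sessions jitter around the personal means.  Persistent
  between-person differences dominate the aggregate features, as in
  observed cohorts — without this layer the between-participant SD of mean
  session cadence would shrink by $\sqrt{n_\text{sessions}}$ and be
  unrealistically small.
* **Background activity** is a two-state per-minute process with cadence
  uniform on 1–39 steps/min, so background alone can never reach the
  40-steps/min threshold.  Short (1–6 min) above-threshold bursts are
  planted at least 10 minutes clear of sessions: long enough gaps that
  they can neither open nor extend a session.  Planted sessions are
  separated by at least 10 sub-threshold minutes, so the detector's
  definition can recover them exactly; the tests require at least 95%
  exact boundary recovery and observe 100%.
* **Non-wear** is whole days of zeros (the validity rule is day-level;
  partial-day non-wear is out of scope).
* **Demographics** cover ages 40–91 (mean near 72, SD near 10), binary sex
  with female = 1, education and total intracranial volume in realistic
  ranges.
* **Outcomes** share one latent linear predictor: planted standardized
  effects (`outcome_betas`, default 0.5 on session frequency and 0.25 on
  session cadence) applied to z-scored *true* features, plus standardized
  covariate effects, plus independent Gaussian noise per outcome
  (`noise_sd`, default 0.5).  Cognitive outcomes live on the latent
  z-like scale; volumes and fractional anisotropy are affine maps of it;
  WMH burden is lognormal in the negated latent, so it is right-skewed,
  triggers the log transform, and "more activity, less burden" holds by
  construction.  Session-only features are z-scored among exercisers and
  contribute zero for non-exercisers.
* **Sub-streams.** One integer seed drives everything; each participant's
  stream is derived deterministically from (seed, index), so enlarging the
  cohort never reshuffles earlier participants.

What the generator does **not** emulate: device-specific noise, heart
rate or sleep, triaxial acceleration, circadian placement of activity
(sessions land uniformly in free slots), within-day autocorrelation of
background stepping, and partial-day non-wear.  Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under the
stated generative assumptions, not validity on any particular device's
exports.

## What the checks do and do not show

The equivalence, conservation, nesting, closed-form and design-audit
properties are exact and hold on every input tested, including 1000
randomized two-day series.  The statistical properties are Monte-Carlo
claims at specific problem sizes, chosen as the package's own test
conditions: planted-effect recovery and bootstrap coverage use n = 300
participants (7 simulated days for the generator-based variant, direct
feature draws otherwise), 20 seeds/replications, and 200 bootstrap
resamples for the coverage study; the acceptance pipeline itself runs 300
participants over 30 days with 1000 resamples.

One caveat deserves emphasis because it is scientific, not numerical: the
generator's true features are correlated — participants with more sessions
also accumulate more in-session steps (r ≈ 0.84 between session frequency
and daily in-session steps).  Ridge regression deliberately *shares*
weight across correlated predictors instead of picking one, so when a 0.5
and a 0.25 effect are planted on two features, the 0.25 effect's rank
among correlated competitors is unstable even though the 0.5 effect ranks
first reliably.  The planted-ordering recovery property is therefore
tested on independently drawn features, and the end-to-end generator test
plants a single effect against six nulls.  The same caution applies to
interpreting coefficient-weight proportions on real cohorts: importance is
shared within blocks of correlated features.

## Known limitations

* The detector trusts minute timestamps and assumes a regular 1-minute
  grid (the reader materializes and zero-fills whole days).
* Importance proportions depend on the 1/n standardization and on the
  penalty; they are relative association strengths within one model, not
  effect sizes.
* The bootstrap CI for the cross-validated R² inherits the optimism of
  resampled cross-validation (duplicated rows appear on both sides of a
  fold split); the retune mode does not remove this.
* The generator's distributional choices are calibration conveniences
  targeting published descriptives, not a claim about any cohort's data-
  generating process.
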