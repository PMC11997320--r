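---
title: "From 1 Hz RFID presence logs to feeding-behaviour models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From 1 Hz RFID presence logs to feeding-behaviour models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Group-housed broilers are individually indistinguishable to the eye, so
individual feeding behaviour is observed indirectly: birds carry passive HF
RFID wing tags, feeders carry antennas, and the reader writes one record per
second per bird detected within antenna range. `flockfeedr` turns those raw
presence logs into three daily descriptors per bird —

* **NFV** — number of feeder visits (bouts) in a day,
* **MFBD** — mean feeding bout duration per visit, in seconds,
* **NDF** — number of different feeders visited in a day,

— and models them with random-intercept linear mixed models against age,
sex, gait class, start body weight and body-weight gain.

## Bout segmentation and the meal criterion

A *feeding bout* is a maximal run of same-bird, same-feeder records whose
internal record gaps never exceed the gap threshold (default 24 s).  Two
conventions matter and are explicit in the code:

* **The reader auto-extension is a property of the log, not of the
  segmenter.**  The acquisition system keeps reporting a tag at its last
  antenna for 6 s after the last true detection.  The segmenter therefore
  applies the 24 s rule to record timestamps as they are; the *effective*
  threshold on true feeding interruptions is 24 + 6 = 30 s, and
  `segmentation_params()` reports exactly that decomposition.  The
  simulator reproduces the extension so round-trip tests see realistic
  logs.
* **A feeder switch always closes a bout**, whatever the gap, because the
  meal criterion is defined for visits *at the same feeder*.  The bout
  table records the close reason (`gap`, `switch`, `end_of_log`) for audit.

Duration is `last − first + 1` s: each 1 Hz record stands for one second of
presence, so an isolated record is a 1 s bout and no bout has length zero.
Bouts are never cut at midnight during segmentation; day assignment (to the
day the bout *starts*) belongs to the descriptor stage.

A deliberately naive O(n²) reference (`merge_oracle()`: pairwise linkage +
transitive closure over the same-feeder, within-threshold, no-intervening-
switch relation, components via `igraph`) exists purely so tests can check
the single-pass segmenter against an independent derivation.

## Descriptors and the outlier rule

`compute_daily_descriptors()` emits one row per bird × day of the analysis
window (default ages 20–30 d), including explicit zero rows (`nfv = 0`,
`ndf = 0`, `mfbd_s = NA`) for birds not seen that day.

Extreme observations are removed by a four-standard-deviation rule that is
**single-pass and pooled**: mean and SD of each descriptor are computed once
over *all* bird-day observations, outliers are `|x − mean| > k·SD`
(two-sided, `k = 4`), and an outlier is excluded only from the analysis set
of the descriptor in which it is extreme.  We chose the pooled scope (not
per-bird, not per-day) because the exclusion counts reported for this kind
of data are single small numbers per descriptor, which is consistent with a
pooled rule; the rule is a parameter, not a constant, so other scopes can
be studied.  Zero-SD descriptors flag nothing rather than dividing by zero.

## Covariates

* start BW = body weight at 14 d (grams);
* BW gain = (BW at 35 d − BW at 14 d)/21 (g/day; denominator exposed as a
  parameter for other weighing schedules); negative gain is allowed with a
  warning, since real birds occasionally lose weight;
* hock-burn and footpad-dermatitis scores (0–5 per leg) are summed over
  left and right legs to 0–10 — carried and summarised but *not* entered in
  the models;
* gait score 0–5 at 27 d is dichotomised: **GG** (good gait) ≤ 2,
  **SG** (suboptimal) ≥ 3.  The 27 d score is used because it overlaps the
  tracking window best.

The descriptive correlation matrix (per-bird descriptor means × bird
characteristics) uses Pearson coefficients with two-sided t-based p-values
and no multiplicity correction; binary variables are coded 0/1, making
those entries point-biserial correlations.  Spearman is available as an
option since descriptive matrices of this kind do not always state their
method.

## The mixed models

For descriptor $y_{ij}$ of bird $j$ on day $i$:

$$y_{ij} = \mu + \beta_1 \mathrm{Age}_{ij} + \beta_2 \mathrm{SW}_j +
\beta_3 \mathrm{WG}_j + \dots + u_j + e_{ij},\qquad
u_j \sim N(0, \sigma^2_{id}),\; e_{ij} \sim N(0, \sigma^2_e)$$

* Estimation is REML throughout (including during selection), via `lme4`.
* Categorical terms use sum-to-zero contrasts, so the intercept is a grand
  mean and two-level factors contribute a single ±1 column.
* No random slopes, by construction.
* Covariates are *not* centred by default; users who want centring can
  transform columns.  The `lme4` X-scale warning is disabled for this
  reason — the magnitudes involved (grams, days) are far from harming the
  double-precision solve.
* Counts (NFV, NDF) are modelled as Gaussian responses.  That is a known
  misspecification, retained deliberately: the pipeline's purpose is the
  linear age/BW trends, and the simulator (below) generates counts as
  counts so that the robustness of the Gaussian analysis to this choice is
  part of what the end-to-end tests demonstrate.

### Degrees of freedom and p-values

Satterthwaite-approximate denominator degrees of freedom are computed
in-package.  For the single-random-intercept model the marginal covariance
$V = \sigma^2_e I + \sigma^2_{id} ZZ'$ is block diagonal per bird with the
analytic inverse
$V_i^{-1} = \sigma^{-2}_e (I - \gamma_i J)$, $\gamma_i = \sigma^2_{id} /
(\sigma^2_e + n_i \sigma^2_{id})$, which makes three ingredients cheap and
exact up to numerical differentiation:

1. $f(\theta) = \mathrm{Var}(c'\hat\beta) = c'(X'V^{-1}X)^{-1}c$,
2. its gradient in $(\sigma^2_{id}, \sigma^2_e)$ (central differences;
   forward at the $\sigma^2_{id} = 0$ boundary),
3. the REML Fisher information
   $\mathcal I_{jk} = \tfrac12 \mathrm{tr}(P V_j P V_k)$ evaluated through
   a low-rank expansion of $P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}$
   (only per-bird $p \times p$ blocks are ever formed).

Then $\mathrm{df} = 2 f^2 / (g' \mathcal I^{-1} g)$.  The implementation is
validated against a dense-matrix reference in the test suite.  When the
information matrix is numerically singular (e.g. a variance estimate on the
boundary), the fit falls back to between-within degrees of freedom
(within-bird columns get residual-within df, bird-level columns bird-level
df) and records the method used.  Term F-tests are Type-III Wald tests;
with sum-to-zero two-level factors every candidate term is 1 df, so
F = t².

### Backward elimination

From the full candidate set (five main effects and all ten two-way
interactions), the single least-significant *eligible* term with
p > α (= 0.05) is removed, the model refit, and the process repeated until
every retained term is significant or protected.  Marginality is enforced:
a main effect is eligible for removal only when no retained interaction
contains it.  Ties are broken by removing the higher-order term first, then
alphabetically.  Every removal (term, p, remaining model) is logged so the
selection path is auditable.

Two statistical facts about this procedure, which the acceptance tests
measure explicitly, deserve honesty:

* With $k$ truly null candidates, the probability that the final model is
  *exactly* the true one is roughly $(1-\alpha)^k$ — about 0.55 for
  $k \approx 12$–14 — because elimination stops precisely when every
  remaining term has $p \le \alpha$, so each null term survives with
  probability about α.  A target of "exact structure recovery in ≥ 95% of
  replicates" at α = 0.05 is therefore unattainable by construction, and
  the corresponding acceptance assertion is expected to stay red; the true
  terms themselves are recovered in essentially 100% of replicates at 3×
  effect sizes.
* Under the marginality rule, a null main effect contained in a retained
  (type-I) interaction is kept *by design*; its unconditional retention
  rate is therefore structurally ≈ 0.20 (one minus the probability that
  none of its four interactions survives), not α.  Selection noise proper
  is measured by interaction retention and by main-effect retention
  conditional on being unprotected, both ≈ α.

### R²

The marginal/conditional R² pair is the standard variance decomposition for
Gaussian mixed models:
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_{id} + \sigma^2_e)$ and
$R^2_c = (\sigma^2_f + \sigma^2_{id}) / (\sigma^2_f + \sigma^2_{id} +
\sigma^2_e)$, with $\sigma^2_f$ the sample variance of the fixed-effect
linear predictor over the data.  `r2_components()` exposes the closed form;
`r2_nakagawa()` applies it to a fit.

## The synthetic flock

`simulate_flock()` is a first-class module, not a fixture: it generates the
*stated world* under which every downstream stage is validated.

Defaults describe a 58-bird tagged subset observed over ages 20–30 d in a
16-feeder pen with 15 antennas (the antenna-less feeder is feeder 1), under
an 18 h lights-on window (03:00–21:00, a commercial-style 18L:6D schedule —
the window value is our choice; only its existence, not its phase, matters
to the tests):

* **Bird traits.** Start BW ~ N(596, 52²) g; gain ~ N(91.38, 18²) g/d with
  corr(start BW, gain) = 0.30; sex Bernoulli(½); gait scores discretised
  normals matching the scoring-day means/SDs, with the 27 d score driving
  the GG/SG class.  The gain SD (18 g/d) is derived from the 35 d weight
  dispersion of the same population; means, SDs and the correlation are the
  published flock summaries.
* **Daily descriptors.** Per response, linear predictors use the published
  model estimates (e.g. NFV: intercept 111.41, age slope −2.212; variance
  components 232.4 / 368.3) with per-bird random intercepts and Gaussian
  residuals at those components.  NFV is then *realized* as a Poisson draw
  around the positive-truncated predictor — deliberately re-creating the
  count-vs-Gaussian misspecification the analysis tolerates.  Bout
  durations are log-normal (shape `mfbd_sdlog = 0.5`, a choice; no duration
  distribution is published) with mean tied to the MFBD predictor.
* **Feeder choice and site fidelity.** Each bird has a Dirichlet preference
  vector over the 15 instrumented feeders (concentration κ per feeder,
  default 1; sampled in log space so κ → 0 produces genuinely one-hot,
  site-faithful birds without underflow).  Each day the target NDF from its
  linear predictor picks how many distinct feeders are used; *which*
  feeders, and how extra bouts distribute over them, follows the preference
  vector.  So NDF tracks its model while κ controls the spatial style
  (one-corner birds vs pen-wide users).
* **Bout placement.** Starts are uniform in the lights-on window (a
  `start_profile` hook accepts any spacing-weight function; no canonical
  diurnal profile is assumed), with a minimum true inter-bout gap of 31 s =
  effective threshold + 1.  That floor is what makes true bouts
  *identifiable*: gaps above it can never be bridged by the record rule
  after the 6 s extension.  A day whose requested bout time exceeds the
  window is a hard error, not a silent truncation.
* **Log rendering.** `emit_detections()` writes one record per second per
  bout, drops interior seconds with probability 0.10 in runs capped at
  12 s (< 24 s, so segmentation must re-merge every drop-out), always keeps
  a bout's first and last second, then appends the 6 s extension, truncated
  if the bird's next bout starts sooner (configurable, default truncate).

What the generator does **not** emulate — and hence what a green round-trip
does not establish — includes: social interaction at feeders (competition,
displacement), diurnal feeding rhythms, tag-read failure correlated with
posture or bird size, clock drift between readers, and visits to the
antenna-less feeder (feeder choice is restricted to instrumented feeders by
default so that ground truth is fully observable; setting
`include_blind_feeder = TRUE` lets birds visit the blind feeder, whose
bouts leave no records — a realistic undercount that the round-trip tests
then cannot, and do not, check).

## Numerical and degenerate-input choices

* Timestamps are timezone-naive local clock time stored as UTC `POSIXct`;
  days are calendar days of that clock.
* A bird detected at two antennas in the same second is resolved by
  previous-second continuity, then the lower antenna number, with a
  warning; the case is physically possible at range boundaries but not
  described by the acquisition system's documentation.
* Unsorted input to the segmenter is an error, never silently sorted.
* Rank-deficient fixed-effect designs are an error naming the collinear
  columns; the CLI additionally prunes inestimable candidate terms (e.g. a
  small flock that is all good-gait) before selection, logging what it
  dropped.
* Exact p-value ties during elimination are broken deterministically
  (higher interaction order first, then term name), so runs are
  reproducible to the byte.

## Known limitations

* The per-bird random intercept is the only random term; day-level shocks
  shared across birds (weather, disturbances) are not modelled, in the
  generator or the analysis.
* MFBD inherits a constant +6 s from the auto-extension; the pipeline
  reports it as measured (intercept-level bias only), mirroring the source
  convention of thresholding on records.
* The Satterthwaite machinery is specific to the single-random-intercept
  structure; multi-factor random designs would need the general gradient
  machinery.
* Acceptance criteria involving replicated simulation use fixed seeds; the
  reported rates are Monte-Carlo estimates with the replicate counts stated
  in the tests.
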