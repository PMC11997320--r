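# flockfeedr

Individual feeding behaviour of group-housed broilers, from raw RFID
presence logs to mixed-model inference.

## The problem

Broilers are kept in groups of hundreds to thousands of visually identical
birds, so individual feeding behaviour cannot be observed directly. A
practical instrument is passive HF RFID: birds carry wing tags, feeders
carry antennas, and a reader logs one record per second per bird detected
at a feeder. `flockfeedr` is the analysis layer for such logs. It is aimed
at precision-livestock and animal-breeding researchers who want per-bird,
per-day feeding descriptors and defensible repeated-measures models, plus a
fully synthetic flock generator so every stage can be validated without any
farm data.

## What it computes

**Bout segmentation (meal criterion).** Within one bird at one feeder,
record gaps over 24 s split feeding bouts; shorter gaps are bridged.
Because the reader keeps reporting a tag at its last antenna for 6 s after
the last true detection (auto-extension), the effective criterion on true
feeding interruptions is 24 + 6 = 30 s. A feeder switch always closes a
bout. Duration is `last − first + 1` s.

**Daily descriptors.** Per bird × day: NFV (number of feeder visits), MFBD
(mean feeding bout duration, s), NDF (number of different feeders visited,
max 15 instrumented feeders). Extreme observations are filtered by a
single-pass, pooled 4-SD rule, per descriptor and per observation.

**Mixed models.** For descriptor $y_{ij}$ of bird $j$ at age $i$ (days):

$$y_{ij} = \mu + \beta_1\,\mathrm{Age}_{ij} + \beta_2\,\mathrm{SW}_j +
\beta_3\,\mathrm{WG}_j + \dots + u_j + e_{ij}, \quad u_j \sim N(0,\sigma^2_{id}),\;
e_{ij} \sim N(0,\sigma^2_e)$$

REML via `lme4`, sum-to-zero contrasts, random intercept per bird,
Satterthwaite degrees of freedom (implemented in-package), backward
elimination of the five candidate main effects (age, sex, gait class, start
body weight SW, body-weight gain WG) and their ten two-way interactions
under marginality constraints, and marginal/conditional R²
($R^2_m = \sigma^2_f/(\sigma^2_f+\sigma^2_{id}+\sigma^2_e)$,
$R^2_c = (\sigma^2_f+\sigma^2_{id})/(\sigma^2_f+\sigma^2_{id}+\sigma^2_e)$).

**Synthetic flock.** An agent-based generator draws bird traits (start BW
~ N(596, 52²) g, gain correlated 0.30 with it, sex, gait), realizes daily
bout counts, durations and feeder choices from the descriptor models with
per-bird random intercepts and Dirichlet feeder preferences (site
fidelity), and renders ground-truth bouts as a raw 1 Hz log with detection
drop-outs and the 6 s auto-extension. See the methods vignette
(`vignettes/feeding-behaviour-pipeline.Rmd`) for every default and its
rationale.

## Worked example

```r
library(flockfeedr)

cfg  <- flock_config(seed = 11)          # 58 birds, ages 20-30 d
sim  <- simulate_flock(cfg)              # ground truth bouts + covariates
set.seed(11)
det  <- emit_detections(sim)             # raw 1 Hz log (drop-outs + 6 s extension)
bouts <- segment_bouts(det, segmentation_params())   # 24 s rule
des  <- compute_daily_descriptors(bouts,
          feed_calendar(cfg$hatch_date, cfg$ages),
          birds = sim$covariates$bird_id)
fo   <- flag_outliers(des, k = 4)
cov  <- build_covariates(sim$covariates_raw)
d    <- merge(fo$filtered$nfv, cov, by = "bird_id")
sel  <- backward_select(d, "nfv", alpha = 0.05)
print(sel$fit)
```

Output (as printed by the code above):

```
records: 3449518  true bouts: 36786
segmented bouts: 36786
   bird_id age_days   nfv    mfbd_s   ndf total_feeding_s
1:    B001       20    72  90.25000    15            6498
2:    B001       21    90 187.77778    15           16900
3:    B001       22    56  65.33929    10            3659
4:    B001       23    46  80.21739    11            3690

Linear mixed model (REML), response: nfv
   637 observations, 58 birds; df: satterthwaite
Fixed effects:
        coef estimate     se    df     t         p
 (Intercept)   98.830 6.4940 633.1 15.22 8.444e-45
    age_days   -1.652 0.2499 578.1 -6.61 8.751e-11
Random effects:
  bird intercept variance 144.8 (sd 12.03)
  residual variance       396.7 (sd 19.92)
R2 marginal 0.0479, conditional 0.3025
```

Reading it: segmentation recovered exactly the 36,786 true bouts from 3.4 M
raw records; one outlying bird-day was removed by the 4-SD rule (637 of 638
observations remain); backward selection kept only age — birds visit
feeders less often as they grow (here −1.65 visits/day per day of age) —
and the bird identity intercept explains the difference between the 4.8%
(fixed effects only) and 30.3% (fixed + bird) of variance accounted for.

## Command line

```sh
Rscript inst/cli/flockfeedr all --out run1 --seed 7          # full pipeline
Rscript inst/cli/flockfeedr segment --log det.csv --out run2 \
        --gap-threshold 24 --extension 6
```

Subcommands: `simulate`, `segment`, `describe`, `model`, `report`, `all`.
Each run writes `run_summary.json` echoing the full configuration (the
summary alone suffices to reproduce the run), model reports as JSON + text,
and diagnostic figures (per-bird spatio-temporal visit maps with the
half-pen boundary; daily descriptor trend panels). Exit codes: 0 success,
2 missing input, 3 validation failure.

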