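# Agent-based synthetic flock.
#
# Generates ground-truth feeding bouts plus matching covariate tables with
# the statistical structure the downstream models assume (linear age /
# start-BW / BW-gain effects on NFV, MFBD, NDF with a per-bird random
# intercept), then renders the bouts as a raw 1 Hz detection log including
# the reader artifacts: within-bout detection drop-outs and the 6 s
# auto-extension after the last true detection.  Every stage of the pipeline
# can be validated against this ground truth without any external data.

#' Synthetic flock configuration
#'
#' Defaults describe a 58-bird tagged subset observed over ages 20-30 d in a
#' 16-feeder pen with 15 antennas, with effect sizes and variance components
#' of the default descriptor models; see the methods vignette for the
#' rationale of each value.
#'
#' @param n_birds Number of tagged birds (58).
#' @param ages Age window in days (20:30).
#' @param hatch_date `Date` of age 0.
#' @param layout A [pen_layout()].
#' @param active_window_s Lights-on window, seconds since midnight
#'   (default 03:00-21:00, an 18L:6D commercial-style schedule).
#' @param bw_mean,bw_sd Start body weight (14 d) distribution, grams.
#' @param gain_mean,gain_sd Body-weight-gain distribution, g/day.
#' @param rho Correlation between start BW and gain (0.30).
#' @param p_female Probability a bird is female.
#' @param coefficients Named list per response (`nfv`, `mfbd`, `ndf`) of
#'   named vectors `intercept`, `age`, and optionally `sw` (start BW) and
#'   `wg` (gain): the true linear predictors of the daily descriptors.
#' @param varcomp Named list per response of `c(var_id, var_resid)`.
#' @param effect_scale Multiplier applied to all non-intercept coefficients;
#'   intercepts are re-centred so the mean response at the reference point
#'   (age 25, BW 596 g, gain 91.38 g/d) is unchanged.
#' @param kappa Dirichlet concentration per feeder for the per-bird feeder
#'   preference vector: small values give site-faithful birds, large values
#'   pen-wide users.
#' @param include_blind_feeder If `TRUE`, birds may also visit the
#'   antenna-less feeder(s) of the layout; those true bouts generate NO
#'   detection records (a realistic undercount) and do not count towards
#'   NDF, which is defined over instrumented feeders.  Default `FALSE`, so
#'   ground truth stays fully observable for round-trip testing.
#' @param dropout_prob Per interior second probability that a detection is
#'   missed inside a bout.
#' @param max_dropout_gap_s Longest permitted drop-out run, seconds; must be
#'   at most the record gap threshold so segmentation re-merges drop-outs.
#' @param auto_extension_s Reader auto-extension appended after each bout's
#'   last true detection (6 s).
#' @param truncate_extension Cut the extension short when the bird's next
#'   bout starts sooner (default `TRUE`).
#' @param min_interbout_gap_s Minimum true gap between consecutive bouts of
#'   one bird; the default 31 s (= effective threshold + 1) guarantees true
#'   bouts remain identifiable after the auto-extension.
#' @param mfbd_sdlog Log-scale SD of the log-normal bout-duration draw.
#' @param min_bout_s Floor for the per-day mean bout duration target.
#' @param start_profile `NULL` for uniform within-day bout starts, or a
#'   function `f(n)` returning `n + 1` non-negative spacing weights used to
#'   distribute the free time of the day.
#' @param seed Integer seed used by [simulate_flock()].
#' @return A `flock_config` list.
#' @export
flock_config <- function(n_birds = 58,
                         ages = 20:30,
                         hatch_date = as.Date("2024-01-01"),
                         layout = pen_layout(),
                         active_window_s = c(3, 21) * 3600,
                         bw_mean = 596, bw_sd = 52,
                         gain_mean = 91.38, gain_sd = 18,
                         rho = 0.30,
                         p_female = 0.5,
                         coefficients = list(
                           nfv  = c(intercept = 111.41, age = -2.212),
                           mfbd = c(intercept = 6.198, age = 2.192,
                                    sw = 0.130, wg = -0.390),
                           ndf  = c(intercept = 23.70, age = -0.396,
                                    sw = -0.011, wg = 0.028)),
                         varcomp = list(
                           nfv  = c(var_id = 232.4, var_resid = 368.3),
                           mfbd = c(var_id = 223.5, var_resid = 900.0),
                           ndf  = c(var_id = 1.155, var_resid = 4.586)),
                         effect_scale = 1,
                         kappa = 1,
                         include_blind_feeder = FALSE,
                         dropout_prob = 0.10,
                         max_dropout_gap_s = 12,
                         auto_extension_s = 6,
                         truncate_extension = TRUE,
                         min_interbout_gap_s = 31,
                         mfbd_sdlog = 0.5,
                         min_bout_s = 2,
                         start_profile = NULL,
                         seed = 1L) {
  stopifnot(n_birds >= 1, length(ages) >= 1,
            active_window_s[1] >= 0, active_window_s[2] <= 86400,
            active_window_s[1] < active_window_s[2],
            dropout_prob >= 0, dropout_prob < 1,
            max_dropout_gap_s >= 0, auto_extension_s >= 0,
            min_interbout_gap_s >= 1, kappa > 0,
            all(vapply(varcomp, function(v) all(v >= 0), logical(1))))
  cfg <- as.list(environment())
  class(cfg) <- "flock_config"
  cfg
}

# reference point used when re-centring intercepts under effect_scale
.REF <- c(age = 25, sw = 596, wg = 91.38)

.scaled_coef <- function(co, scale) {
  if (scale == 1) return(co)
  ref_mean <- co[["intercept"]] +
    sum(vapply(intersect(names(co), names(.REF)),
               function(k) co[[k]] * .REF[[k]], numeric(1)))
  out <- co
  for (k in setdiff(names(co), "intercept")) out[[k]] <- co[[k]] * scale
  out[["intercept"]] <- ref_mean -
    sum(vapply(intersect(names(out), names(.REF)),
               function(k) out[[k]] * .REF[[k]], numeric(1)))
  out
}

.linear_predictor <- function(co, age, sw, wg) {
  lp <- rep(co[["intercept"]], length(age))
  if ("age" %in% names(co)) lp <- lp + co[["age"]] * age
  if ("sw" %in% names(co)) lp <- lp + co[["sw"]] * sw
  if ("wg" %in% names(co)) lp <- lp + co[["wg"]] * wg
  lp
}

.discretized_score <- function(n, mean, sd) {
  p <- diff(stats::pnorm(c(-Inf, 0.5, 1.5, 2.5, 3.5, 4.5, Inf), mean, sd))
  sample(0:5, n, replace = TRUE, prob = p)
}

# raw covariate table consistent with the latent draws
.raw_covariates <- function(cv) {
  n <- nrow(cv)
  bw14 <- round(cv$start_bw_g)
  bw35 <- round(cv$start_bw_g + 21 * cv$bw_gain_g_d)
  gain_tot <- bw35 - bw14
  bw21 <- round(bw14 + 0.282 * gain_tot + stats::rnorm(n, 0, 25))
  bw27 <- round(bw14 + 0.576 * gain_tot + stats::rnorm(n, 0, 30))
  leg <- function(mean_sum) stats::rbinom(n, 5, min(mean_sum / 10, 1))
  out <- data.table::data.table(
    bird_id = cv$bird_id, sex = as.character(cv$sex),
    bw_14 = bw14, bw_21 = bw21, bw_27 = bw27, bw_35 = bw35,
    hb_left_21 = leg(1.4), hb_right_21 = leg(1.4),
    hb_left_27 = leg(2.2), hb_right_27 = leg(2.2),
    hb_left_35 = leg(3.6), hb_right_35 = leg(3.6),
    fpd_left_21 = leg(1.0), fpd_right_21 = leg(1.0),
    fpd_left_27 = leg(1.3), fpd_right_27 = leg(1.3),
    fpd_left_35 = leg(2.0), fpd_right_35 = leg(2.0),
    gait_21 = .discretized_score(n, 1.6, 0.6),
    gait_35 = .discretized_score(n, 2.6, 0.8))
  # gait at 27 d must match the latent gait class used in the generator
  out[, gait_27 := ifelse(cv$gait_class == "SG",
                          pmin(.discretized_score(n, 3.3, 0.5), 5L),
                          pmax(pmin(.discretized_score(n, 1.9, 0.6), 2L), 0L))]
  out[, gait_27 := pmax(gait_27, ifelse(cv$gait_class == "SG", 3L, 0L))]
  data.table::setcolorder(out, .wide_cov_cols()[.wide_cov_cols() %in% names(out)])
  out[]
}

#' Simulate a flock: ground-truth bouts, daily truth, covariates
#'
#' Draws per-bird latent traits (start BW, gain, sex, gait, feeder
#' preferences, per-response random intercepts), then realizes each
#' bird-day: the number of feeder visits as a Poisson draw around the
#' (positive-truncated) NFV linear predictor, bout durations log-normal
#' around the MFBD linear predictor, and feeder identities drawn from the
#' bird's Dirichlet preference vector tempered so the number of distinct
#' feeders tracks the NDF linear predictor.  Bouts are placed without
#' overlap inside the lights-on window with true inter-bout gaps of at
#' least `min_interbout_gap_s`.
#'
#' @param config A [flock_config()].
#' @return List of class `flock_sim`: `bouts` (true bouts: `bird_id`,
#'   `age_days`, `feeder_id`, `start`, `duration_s`), `daily` (per bird-day
#'   realized and intended descriptor values), `covariates` (latent
#'   per-bird table), `covariates_raw` (weighing/scoring table as
#'   [read_covariates()] would return), `preferences`, `config`.
#' @export
simulate_flock <- function(config = flock_config()) {
  stopifnot(inherits(config, "flock_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_birds
  cv <- .draw_bird_covariates(n, config$bw_mean, config$bw_sd,
                              config$gain_mean, config$gain_sd, config$rho)
  cv[, sex := factor(sample(c("female", "male"), n, TRUE,
                            prob = c(config$p_female, 1 - config$p_female)),
                     levels = c("female", "male"))]
  raw <- .raw_covariates(cv)
  cv[, gait_class := factor(classify_gait(raw$gait_27), levels = c("GG", "SG"))]

  equipped <- config$layout$antenna_equipped
  choice_ids <- if (isTRUE(config$include_blind_feeder))
    config$layout$feeder_ids else equipped
  nf <- length(choice_ids)
  # per-bird Dirichlet feeder preferences, sampled in log space so tiny
  # concentrations (extreme site fidelity) do not underflow: for any a > 0,
  # Gamma(a) = U^(1/a) * Gamma(a + 1) exactly, hence
  # log Gamma(a) = log(U)/a + log Gamma(a + 1)
  lg <- matrix(log(stats::runif(n * nf)) / config$kappa +
                 log(stats::rgamma(n * nf, shape = config$kappa + 1)),
               n, nf)
  lg <- lg - apply(lg, 1L, max)
  pref <- exp(lg)
  pref <- pref / rowSums(pref)
  colnames(pref) <- as.character(choice_ids)

  co <- lapply(config$coefficients, .scaled_coef, scale = config$effect_scale)
  u <- lapply(config$varcomp, function(v)
    stats::rnorm(n, 0, sqrt(v[["var_id"]])))

  W <- diff(config$active_window_s)
  day0 <- config$active_window_s[1]
  ages <- config$ages
  na <- length(ages)
  nd <- n * na
  # bird-day grid in (bird, age) order; all scalar draws vectorized
  jj <- rep(seq_len(n), each = na)
  age_v <- rep(ages, n)
  day_origin <- as.numeric(as.POSIXct(config$hatch_date, tz = "UTC")) +
    86400 * age_v + day0
  lp <- sapply(names(co), function(r)
    .linear_predictor(co[[r]], age_v, cv$start_bw_g[jj], cv$bw_gain_g_d[jj]) +
      u[[r]][jj] +
      stats::rnorm(nd, 0, sqrt(config$varcomp[[r]][["var_resid"]])))
  nfv_v <- stats::rpois(nd, pmax(lp[, "nfv"], 0))
  m_target <- pmax(lp[, "mfbd"], config$min_bout_s)
  ndf_target <- pmax(1L, pmin(round(lp[, "ndf"]), nf))
  support_l <- apply(pref, 1L, function(p) which(p > 1e-6), simplify = FALSE)

  gapmin <- config$min_interbout_gap_s
  sdl <- config$mfbd_sdlog
  dur_l <- start_l <- feeder_l <- vector("list", nd)
  mfbd_real <- rep(NA_real_, nd)
  ndf_real <- integer(nd)
  for (k in seq_len(nd)) {
    nfv <- nfv_v[k]
    if (nfv == 0L) next
    j <- jj[k]
    dur <- pmax(round(stats::rlnorm(nfv, log(m_target[k]) - sdl^2 / 2, sdl)), 1)
    busy <- sum(dur) + gapmin * (nfv - 1)
    if (busy > W)
      stop("infeasible day: total bout time ", busy,
           " s exceeds the active window (", W, " s) for bird ",
           cv$bird_id[j], " at age ", age_v[k])
    wts <- if (is.null(config$start_profile)) stats::runif(nfv + 1) else
      config$start_profile(nfv)
    extra <- floor((W - busy) * wts / sum(wts))[seq_len(nfv)]
    starts <- cumsum(extra + c(0, dur[-nfv] + gapmin))
    # feeder identities: pick the target number of distinct feeders from
    # the preference vector, then fill remaining bouts among them
    pj <- pref[j, ]
    support <- support_l[[j]]
    m_s <- min(ndf_target[k], nfv, length(support))
    S <- if (length(support) == 1L) support else
      sample(support, m_s, prob = pj[support])
    fill <- if (nfv > m_s) {
      if (length(S) == 1L) rep(S, nfv - m_s) else
        sample(S, nfv - m_s, replace = TRUE, prob = pj[S])
    } else integer(0)
    sel <- c(S, fill)
    dur_l[[k]] <- dur
    start_l[[k]] <- day_origin[k] + starts
    feeder_l[[k]] <- choice_ids[sel[sample.int(length(sel))]]
    mfbd_real[k] <- mean(dur)
    # NDF is defined over instrumented feeders only
    ndf_real[k] <- length(unique(sel[choice_ids[sel] %in% equipped]))
  }
  nb <- nfv_v
  bouts <- data.table::data.table(
    bird_id = rep(cv$bird_id[jj], nb),
    age_days = rep(age_v, nb),
    feeder_id = unlist(feeder_l),
    start = as.POSIXct(unlist(start_l), tz = "UTC", origin = "1970-01-01"),
    duration_s = as.numeric(unlist(dur_l)))
  data.table::setorder(bouts, bird_id, start)
  daily <- data.table::data.table(
    bird_id = cv$bird_id[jj], age_days = age_v,
    nfv = as.integer(nfv_v), mfbd_s = mfbd_real, ndf = ndf_real,
    lp_nfv = lp[, "nfv"], lp_mfbd = lp[, "mfbd"], lp_ndf = lp[, "ndf"])
  data.table::setorder(daily, bird_id, age_days)
  structure(list(bouts = bouts, daily = daily,
                 covariates = cv, covariates_raw = raw,
                 preferences = pref, config = config),
            class = "flock_sim")
}

#' @export
print.flock_sim <- function(x, ...) {
  cat("<flock_sim> ", x$config$n_birds, " birds, ages ",
      min(x$config$ages), "-", max(x$config$ages), " d, ",
      nrow(x$bouts), " true bouts\n", sep = "")
  invisible(x)
}

#' Render ground-truth bouts as a raw 1 Hz detection log
#'
#' Each true bout becomes a run of one record per second at its feeder.
#' Interior seconds are dropped independently with `dropout_prob`, with
#' drop-out runs capped at `max_dropout_gap_s` (so the segmenter's gap rule
#' re-merges them); a bout's first and last second are always detected.
#' After the last true detection `auto_extension_s` extension records are
#' appended, truncated when the bird's next bout starts sooner (if
#' `truncate_extension`).
#'
#' @param sim A `flock_sim` from [simulate_flock()], or a true-bout table
#'   with columns `bird_id`, `feeder_id`, `start`, `duration_s`.
#' @param config A [flock_config()]; defaults to `sim$config`.
#' @return Detection `data.table` (`timestamp`, `bird_id`, `antenna_id`)
#'   sorted by `(bird_id, timestamp)`, ready for [segment_bouts()].
#' @export
emit_detections <- function(sim, config = NULL) {
  bouts <- if (inherits(sim, "flock_sim")) sim$bouts else
    data.table::as.data.table(sim)
  if (is.null(config)) {
    stopifnot(inherits(sim, "flock_sim"))
    config <- sim$config
  }
  if (nrow(bouts) == 0L)
    return(data.table::data.table(timestamp = .parse_ts(character()),
                                  bird_id = character(),
                                  antenna_id = integer()))
  b <- data.table::as.data.table(bouts)
  # bouts at a feeder without an antenna leave no trace in the log; they are
  # removed before extension truncation is computed, because an undetected
  # move cannot cut the reader's extension either
  b <- b[b$feeder_id %in% config$layout$antenna_equipped]
  if (nrow(b) == 0L)
    return(data.table::data.table(timestamp = .parse_ts(character()),
                                  bird_id = character(),
                                  antenna_id = integer()))
  data.table::setorder(b, bird_id, start)
  d <- as.integer(b$duration_s)
  nb <- nrow(b)
  # integer bird codes keep the hot path numeric; ids restored at the end
  bird_levels <- unique(b$bird_id)
  bcode <- match(b$bird_id, bird_levels)
  idx <- rep(seq_len(nb), d)
  off <- sequence(d) - 1L
  interior <- off > 0L & off < (d[idx] - 1L)
  drop <- interior & stats::runif(length(off)) < config$dropout_prob
  if (any(drop) && config$max_dropout_gap_s >= 1) {
    # cap drop-out runs: within a run of dropped seconds, re-keep every
    # (max_gap + 1)-th second
    run_start <- drop & !c(FALSE, drop[-length(drop)])
    idr <- cumsum(run_start)
    start_pos <- which(run_start)
    pos <- integer(length(drop))
    w <- which(drop)
    pos[w] <- w - start_pos[idr[w]] + 1L
    undrop <- drop & (pos %% (config$max_dropout_gap_s + 1L) == 0L)
    drop[undrop] <- FALSE
  } else if (any(drop) && config$max_dropout_gap_s < 1) {
    drop[] <- FALSE
  }
  ts0 <- as.numeric(b$start)
  keep <- which(!drop)
  t_v <- (ts0[idx] + off)[keep]
  bi_v <- bcode[idx][keep]
  ant_v <- b$feeder_id[idx][keep]

  ext_n <- as.integer(config$auto_extension_s)
  if (ext_n > 0L) {
    endt <- ts0 + d - 1
    nxt <- c(ts0[-1L], Inf)
    nxt[bcode != c(bcode[-1L], 0L)] <- Inf
    avail <- if (config$truncate_extension)
      pmin(ext_n, pmax(nxt - endt - 1, 0)) else rep(ext_n, nb)
    avail <- as.integer(avail)
    eidx <- rep(seq_len(nb), avail)
    eoff <- sequence(avail)
    t_v <- c(t_v, endt[eidx] + eoff)
    bi_v <- c(bi_v, bcode[eidx])
    ant_v <- c(ant_v, b$feeder_id[eidx])
  }
  o <- order(bi_v, t_v, method = "radix")
  ts <- t_v[o]
  attributes(ts) <- list(class = c("POSIXct", "POSIXt"), tzone = "UTC")
  out <- list(timestamp = ts,
              bird_id = bird_levels[bi_v[o]],
              antenna_id = as.integer(ant_v[o]))
  data.table::setDT(out)
  out[]
}

#' Write all simulator outputs to a directory
#'
#' Writes `detections.csv`, `covariates.csv`, `truth_bouts.csv`,
#' `truth_daily.csv` and `layout.json`.
#'
#' @param sim A `flock_sim`.
#' @param dir Output directory (created if needed).
#' @param detections Optional pre-computed detection table (else emitted
#'   here, consuming random numbers).
#' @return `dir`, invisibly.
#' @export
write_flock <- function(sim, dir, detections = NULL) {
  stopifnot(inherits(sim, "flock_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(detections)) detections <- emit_detections(sim)
  write_detection_log(detections, file.path(dir, "detections.csv"))
  write_covariates(sim$covariates_raw, file.path(dir, "covariates.csv"))
  tb <- data.table::copy(sim$bouts)
  tb[, start := .format_ts(start)]
  data.table::fwrite(tb, file.path(dir, "truth_bouts.csv"))
  data.table::fwrite(sim$daily, file.path(dir, "truth_daily.csv"))
  write_layout(sim$config$layout, file.path(dir, "layout.json"))
  invisible(dir)
}
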