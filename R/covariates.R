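# Per-bird modelling covariates.
#
# From the raw weighing/scoring table we derive the quantities entering the
# mixed models: start body weight (14 d), body-weight gain per day between
# 14 and 35 d, summed left+right hock-burn and footpad-dermatitis scores,
# and the dichotomised gait class at 27 d (GG: score <= 2, SG: score >= 3).

#' Body-weight gain per day
#'
#' @param bw14 Body weight at the start of the interval, grams (> 0).
#' @param bw35 Body weight at the end of the interval, grams (> 0).
#' @param days Length of the interval in days, default 21 (= 35 - 14).
#' @return Gain in grams/day, `(bw35 - bw14) / days`.  Negative gain
#'   (weight loss) is allowed with a warning.
#' @examples
#' compute_bw_gain(596, 2515)  # 91.38 g/day
#' @export
compute_bw_gain <- function(bw14, bw35, days = 21) {
  if (any(days <= 0)) stop("days must be > 0")
  if (any(bw14 <= 0, na.rm = TRUE) || any(bw35 <= 0, na.rm = TRUE))
    stop("body weights must be positive")
  g <- (bw35 - bw14) / days
  if (any(g < 0, na.rm = TRUE))
    warning("negative body-weight gain (weight loss) for ",
            sum(g < 0, na.rm = TRUE), " bird(s)")
  g
}

#' Dichotomise a gait score into good / suboptimal gait
#'
#' Good gait (`"GG"`) is a score of 2 or lower; suboptimal gait (`"SG"`) a
#' score of 3 or higher.
#'
#' @param score Integer gait score(s) in 0-5.
#' @return Character vector of `"GG"` / `"SG"`.
#' @export
classify_gait <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 5))
    stop("gait score must be in 0-5")
  ifelse(score <= 2, "GG", "SG")
}

#' Sum left and right leg-health scores
#'
#' @param left,right Per-leg scores in 0-5.
#' @return Summed score in 0-10.
#' @export
sum_leg_scores <- function(left, right) {
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 5))
  if (!ok(left) || !ok(right)) stop("leg scores must be in 0-5")
  left + right
}

#' Build per-bird modelling covariates from a raw covariate table
#'
#' @param raw Wide covariate table from [read_covariates()] (or equivalent).
#' @param complete_only Drop birds flagged incomplete (default `TRUE`).
#' @return `data.table`, one row per bird: `bird_id`, `sex`, `start_bw_g`,
#'   `bw_gain_g_d`, `hb_sum_21/27/35`, `fpd_sum_21/27/35`, `gait_score_27`,
#'   `gait_class`.
#' @export
build_covariates <- function(raw, complete_only = TRUE) {
  dt <- data.table::as.data.table(raw)
  if (complete_only && "complete" %in% names(dt)) dt <- dt[complete == TRUE]
  out <- dt[, .(bird_id,
                sex = factor(sex, levels = c("female", "male")),
                start_bw_g = bw_14,
                bw_gain_g_d = compute_bw_gain(bw_14, bw_35))]
  for (a in c(21L, 27L, 35L)) {
    out[, paste0("hb_sum_", a) :=
            sum_leg_scores(dt[[paste0("hb_left_", a)]],
                           dt[[paste0("hb_right_", a)]])]
    out[, paste0("fpd_sum_", a) :=
            sum_leg_scores(dt[[paste0("fpd_left_", a)]],
                           dt[[paste0("fpd_right_", a)]])]
  }
  out[, gait_score_27 := dt$gait_27]
  out[, gait_class := factor(classify_gait(gait_score_27),
                             levels = c("GG", "SG"))]
  out[]
}

#' Correlation matrix of bird characteristics and feeding descriptors
#'
#' Aggregates the daily descriptors to one mean value per bird, joins the
#' covariates, and computes pairwise correlations with two-sided t-based
#' p-values.  Binary variables (sex, gait class) are coded 0/1 so their
#' correlations with continuous variables are point-biserial.  Zero-variance
#' columns yield `NA` coefficients rather than errors.
#'
#' @param descriptors Daily descriptor table.
#' @param covariates Per-bird covariates from [build_covariates()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with matrices `r` (coefficients), `p` (p-values) and `n`
#'   (pairwise sample sizes).
#' @export
correlation_matrix <- function(descriptors, covariates,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  des <- data.table::as.data.table(descriptors)
  cov <- data.table::as.data.table(covariates)
  per_bird <- des[, .(nfv = mean(nfv, na.rm = TRUE),
                      mfbd_s = mean(mfbd_s, na.rm = TRUE),
                      ndf = mean(ndf, na.rm = TRUE)), by = bird_id]
  m <- cov[per_bird, on = "bird_id"]
  if (nrow(m) < 3L) stop("need at least 3 birds for a correlation matrix")
  num <- data.frame(
    sex = as.numeric(m$sex == "male"),
    gait_class = as.numeric(m$gait_class == "SG"),
    start_bw_g = m$start_bw_g,
    bw_gain_g_d = m$bw_gain_g_d,
    nfv = m$nfv, mfbd_s = m$mfbd_s, ndf = m$ndf)
  vars <- names(num)
  k <- length(vars)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    x <- num[[i]]; y <- num[[j]]
    ok <- stats::complete.cases(x, y)
    n[i, j] <- sum(ok)
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method))
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p, n = n)
}
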