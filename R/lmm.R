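# Random-intercept linear mixed models for the daily feeding descriptors.
#
# Model: y_ij = x_ij' beta + u_j + e_ij, u_j ~ N(0, tau2) per bird,
# e_ij ~ N(0, sigma2), REML estimation via lme4.  Categorical terms use
# sum-to-zero contrasts so the intercept is a grand mean.  Fixed-effect
# tests are t/F tests with Satterthwaite degrees of freedom computed
# in-package: for the single-random-intercept case V = sigma2*I + tau2*ZZ'
# is block diagonal per bird with an analytic inverse, which makes the REML
# Fisher information of (tau2, sigma2) and the delta-method variance of
# Var(c'beta_hat) cheap and exact up to numerical differentiation.

.MAIN_TERMS <- c("age_days", "sex", "gait_class", "start_bw_g", "bw_gain_g_d")

#' Candidate fixed-effect terms for descriptor models
#'
#' The five main effects (age in days, sex, gait class, start body weight,
#' body-weight gain) and all ten two-way interactions.
#'
#' @return Character vector of 15 term labels.
#' @export
candidate_terms <- function() {
  inter <- utils::combn(.MAIN_TERMS, 2, FUN = paste, collapse = ":")
  c(.MAIN_TERMS, inter)
}

.term_components <- function(term) strsplit(term, ":", fixed = TRUE)[[1L]]
.term_order <- function(term) length(.term_components(term))

.contrast_list <- function(data, vars) {
  fac <- vars[vapply(vars, function(v) is.factor(data[[v]]), logical(1))]
  if (!length(fac)) return(NULL)
  stats::setNames(rep(list("contr.sum"), length(fac)), fac)
}

# ---------------------------------------------------------------------------
# Satterthwaite machinery (single random intercept).
#
# Per-bird sufficient statistics: n_i, X_i'X_i, X_i'1.  With
# gamma_i = tau2 / (sigma2 + n_i tau2) and a_i = 1 / (sigma2 + n_i tau2):
#   X'V^-1 X = sum_i (X_i'X_i - gamma_i (X_i'1)(X_i'1)') / sigma2

.per_bird_stats <- function(X, group) {
  idx <- split(seq_len(nrow(X)), group)
  lapply(idx, function(ii) {
    Xi <- X[ii, , drop = FALSE]
    list(n = length(ii), XtX = crossprod(Xi), Xt1 = colSums(Xi))
  })
}

.xtvinvx <- function(stats_, tau2, sigma2) {
  p <- nrow(stats_[[1L]]$XtX)
  M <- matrix(0, p, p)
  for (s in stats_) {
    g <- tau2 / (sigma2 + s$n * tau2)
    M <- M + (s$XtX - g * tcrossprod(s$Xt1))
  }
  M / sigma2
}

.reml_fisher_info <- function(stats_, tau2, sigma2) {
  p <- nrow(stats_[[1L]]$XtX)
  C <- solve(.xtvinvx(stats_, tau2, sigma2))
  T1 <- matrix(0, 2, 2)
  Gt <- Gs <- Htt <- Hts <- Hss <- matrix(0, p, p)
  for (s in stats_) {
    n <- s$n
    a <- 1 / (sigma2 + n * tau2)
    g <- tau2 * a
    si <- n * a
    o <- tcrossprod(s$Xt1)
    T1[1, 1] <- T1[1, 1] + si^2
    T1[1, 2] <- T1[1, 2] + n * a^2
    T1[2, 2] <- T1[2, 2] + (n - 2 * g * n + g^2 * n^2) / sigma2^2
    Gt <- Gt + a^2 * o
    Gs <- Gs + (s$XtX - g * (2 - g * n) * o) / sigma2^2
    Htt <- Htt + si * a^2 * o
    Hts <- Hts + a^3 * o
    Hss <- Hss + (s$XtX - g * (3 - 3 * g * n + g^2 * n^2) * o) / sigma2^3
  }
  T1[2, 1] <- T1[1, 2]
  tr <- function(A) sum(diag(A))
  trace_pp <- function(T1jk, Hjk, Hkj, Gj, Gk)
    T1jk - tr(C %*% Hkj) - tr(C %*% Hjk) + tr(C %*% Gj %*% C %*% Gk)
  I <- matrix(0, 2, 2)
  I[1, 1] <- trace_pp(T1[1, 1], Htt, Htt, Gt, Gt)
  I[1, 2] <- I[2, 1] <- trace_pp(T1[1, 2], Hts, Hts, Gt, Gs)
  I[2, 2] <- trace_pp(T1[2, 2], Hss, Hss, Gs, Gs)
  I / 2
}

# Satterthwaite df for each coefficient (contrast e_j).
.satterthwaite_df <- function(stats_, tau2, sigma2, n, p) {
  info <- .reml_fisher_info(stats_, tau2, sigma2)
  A <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(A)) return(NULL)
  fC <- function(t2, s2) diag(solve(.xtvinvx(stats_, t2, s2)))
  h1 <- max(tau2, sigma2 * 1e-3) * 1e-4
  h2 <- sigma2 * 1e-4
  # central differences; forward for tau2 at the boundary
  if (tau2 - h1 > 0) {
    d_tau <- (fC(tau2 + h1, sigma2) - fC(tau2 - h1, sigma2)) / (2 * h1)
  } else {
    d_tau <- (fC(tau2 + h1, sigma2) - fC(tau2, sigma2)) / h1
  }
  d_sig <- (fC(tau2, sigma2 + h2) - fC(tau2, sigma2 - h2)) / (2 * h2)
  f0 <- fC(tau2, sigma2)
  df <- vapply(seq_len(p), function(j) {
    g <- c(d_tau[j], d_sig[j])
    den <- drop(t(g) %*% A %*% g)
    if (den <= 0) return(NA_real_)
    2 * f0[j]^2 / den
  }, numeric(1))
  # clamp to a sane range
  pmin(pmax(df, 1), n - p)
}

# Between-within fallback: coefficients whose design column varies within
# birds get residual-within df, bird-level coefficients get bird-level df.
.between_within_df <- function(X, group, n, p) {
  inner <- vapply(seq_len(ncol(X)), function(j) {
    dev <- stats::ave(X[, j], group) - X[, j]
    any(abs(dev) > 1e-10)
  }, logical(1))
  n_birds <- length(unique(group))
  p_inner <- sum(inner)
  p_outer <- p - p_inner - 1L  # excluding intercept
  df <- numeric(p)
  df[inner] <- max(n - n_birds - p_inner, 1L)
  df[!inner] <- max(n_birds - p_outer - 1L, 1L)
  df
}

# ---------------------------------------------------------------------------

#' Fit a random-intercept linear mixed model for one feeding descriptor
#'
#' REML fit of `response ~ fixed terms + (1 | bird_id)` with sum-to-zero
#' contrasts for categorical terms.  Reports per-coefficient estimates, SEs,
#' Satterthwaite (default) or between-within degrees of freedom, t- and
#' F-tests, the two variance components, and the marginal / conditional
#' R-squared pair.
#'
#' @param data Model-ready data frame/table: `bird_id` plus the response and
#'   covariate columns (`age_days`, `sex`, `gait_class`, `start_bw_g`,
#'   `bw_gain_g_d`).  Rows with missing values in used columns are dropped
#'   with a count recorded in the fit.
#' @param response Response column name (`"nfv"`, `"mfbd_s"` or `"ndf"`, or
#'   any numeric column).
#' @param terms Character vector of fixed-effect term labels (interactions
#'   as `"a:b"`); empty vector fits an intercept-only model.
#' @param df_method `"satterthwaite"` (default) or `"between-within"`.
#' @return An object of class `lmm_fit`; see Details.  Key elements:
#'   `coefficients` (per-coefficient table), `term_table` (per-term F tests,
#'   the shape of a journal-style fixed-effects table), `varcomp`, `r2_marginal`,
#'   `r2_conditional`, `n_obs`, `n_birds`.
#' @details The fit fails loudly on a rank-deficient fixed-effect design
#'   (naming the collinear columns) and on non-convergence.  With
#'   sum-to-zero contrasts every two-level factor contributes one column,
#'   so term F-tests are squared t-tests; multi-column terms get Wald F
#'   statistics with the smallest member df.
#' @export
fit_lmm <- function(data, response, terms = candidate_terms(),
                    df_method = c("satterthwaite", "between-within")) {
  df_method <- match.arg(df_method)
  dt <- data.table::as.data.table(data)
  stopifnot("bird_id" %in% names(dt), response %in% names(dt))
  used_vars <- unique(unlist(lapply(terms, .term_components)))
  miss_cols <- setdiff(used_vars, names(dt))
  if (length(miss_cols)) stop("missing covariate column(s): ",
                              paste(miss_cols, collapse = ", "))
  keep <- stats::complete.cases(dt[, c("bird_id", response, used_vars),
                                   with = FALSE])
  n_dropped <- sum(!keep)
  dt <- dt[keep]
  if (data.table::uniqueN(dt$bird_id) < 2L)
    stop("need at least 2 birds")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fixed_fml <- stats::as.formula(paste(response, "~", rhs))
  full_fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 | bird_id)"))
  ctr <- .contrast_list(dt, used_vars)
  X <- stats::model.matrix(fixed_fml, data = dt, contrasts.arg = ctr)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  # covariates are deliberately left uncentered (grand-mean intercepts under
  # sum-to-zero coding stay interpretable), so the scale check is off
  fit <- lme4::lmer(full_fml, data = dt, REML = TRUE,
                    contrasts = ctr,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.scaleX = "ignore"))
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_id <- vc$vcov[vc$grp == "bird_id"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  n <- nrow(dt)
  p <- length(beta)
  group <- as.character(dt$bird_id)

  df <- NULL
  method_used <- df_method
  if (df_method == "satterthwaite") {
    stats_ <- .per_bird_stats(X, group)
    df <- tryCatch(.satterthwaite_df(stats_, var_id, var_resid, n, p),
                   error = function(e) NULL)
    if (is.null(df) || anyNA(df)) {
      df <- .between_within_df(X, group, n, p)
      method_used <- "between-within (satterthwaite fallback)"
    }
  } else {
    df <- .between_within_df(X, group, n, p)
  }
  se <- sqrt(diag(V))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  coefs <- data.table::data.table(
    coef = names(beta), estimate = unname(beta), se = se,
    df = df, t = tval, p = pval)

  # term-level (type III) Wald F tests via the assign map
  asg <- attr(X, "assign")
  labels <- attr(stats::terms(fixed_fml), "term.labels")
  tt <- lapply(seq_along(labels), function(k) {
    jj <- which(asg == k)
    q <- length(jj)
    if (q == 1L) {
      data.table::data.table(term = labels[k], df1 = 1,
                             df2 = df[jj], F = tval[jj]^2, p = pval[jj],
                             estimate = beta[jj], se = se[jj])
    } else {
      b <- beta[jj]
      Fv <- drop(t(b) %*% solve(V[jj, jj, drop = FALSE]) %*% b) / q
      d2 <- min(df[jj])
      data.table::data.table(term = labels[k], df1 = q, df2 = d2, F = Fv,
                             p = stats::pf(Fv, q, d2, lower.tail = FALSE),
                             estimate = NA_real_, se = NA_real_)
    }
  })
  term_table <- if (length(tt)) data.table::rbindlist(tt) else
    data.table::data.table(term = character(), df1 = numeric(),
                           df2 = numeric(), F = numeric(), p = numeric(),
                           estimate = numeric(), se = numeric())
  var_fixed <- stats::var(as.vector(X %*% beta))
  r2 <- r2_components(var_fixed, var_id, var_resid)
  structure(list(model = fit, response = response, terms = terms,
                 formula = full_fml, coefficients = coefs,
                 term_table = term_table,
                 varcomp = c(var_id = var_id, var_resid = var_resid),
                 var_fixed = var_fixed,
                 r2_marginal = r2[["r2_marginal"]],
                 r2_conditional = r2[["r2_conditional"]],
                 n_obs = n, n_birds = data.table::uniqueN(dt$bird_id),
                 n_dropped = n_dropped, df_method = method_used,
                 estimation = "REML"),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  cat("Linear mixed model (REML), response:", x$response, "\n")
  cat("  ", x$n_obs, "observations,", x$n_birds, "birds; df:",
      x$df_method, "\n")
  cat("Fixed effects:\n")
  ct <- as.data.frame(x$coefficients)
  ct[, -1] <- lapply(ct[, -1], function(v) signif(v, digits))
  print(ct, row.names = FALSE)
  cat("Random effects:\n")
  cat(sprintf("  bird intercept variance %.4g (sd %.4g)\n",
              x$varcomp[["var_id"]], sqrt(x$varcomp[["var_id"]])))
  cat(sprintf("  residual variance       %.4g (sd %.4g)\n",
              x$varcomp[["var_resid"]], sqrt(x$varcomp[["var_resid"]])))
  cat(sprintf("R2 marginal %.4f, conditional %.4f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Marginal and conditional R-squared from variance components
#'
#' Variance-decomposition R-squared for a Gaussian random-intercept model:
#' `r2_marginal = var_fixed / (var_fixed + var_id + var_resid)` and
#' `r2_conditional = (var_fixed + var_id) / (var_fixed + var_id + var_resid)`,
#' where `var_fixed` is the variance of the fixed-effect linear predictor
#' over the data.
#'
#' @param var_fixed,var_id,var_resid Non-negative variance components.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @examples
#' r2_components(1, 1, 2)  # 0.25, 0.50
#' @export
r2_components <- function(var_fixed, var_id, var_resid) {
  tot <- var_fixed + var_id + var_resid
  if (!is.finite(tot) || tot <= 0)
    return(c(r2_marginal = 0, r2_conditional = 0))
  c(r2_marginal = var_fixed / tot,
    r2_conditional = (var_fixed + var_id) / tot)
}

#' @rdname r2_components
#' @param fit An `lmm_fit`.
#' @return `r2_nakagawa()`: the same pair computed from a fitted model.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  r2_components(fit$var_fixed, fit$varcomp[["var_id"]],
                fit$varcomp[["var_resid"]])
}

# Drop candidate terms that cannot be estimated on this data set: terms
# involving zero-variance covariates (e.g. a flock that happens to be all
# good-gait), then any terms whose design columns are collinear (interactions
# dropped before main effects).  Used by the pipeline driver; fit_lmm itself
# stays strict.
.prune_model_terms <- function(data, response, terms) {
  dt <- data.table::as.data.table(data)
  vars <- unique(unlist(lapply(terms, .term_components)))
  const <- vars[vapply(vars, function(v)
    data.table::uniqueN(dt[[v]][!is.na(dt[[v]])]) < 2L, logical(1))]
  terms <- terms[!vapply(terms, function(tm)
    any(.term_components(tm) %in% const), logical(1))]
  repeat {
    if (!length(terms)) break
    fml <- stats::as.formula(paste(response, "~",
                                   paste(terms, collapse = " + ")))
    used <- unique(unlist(lapply(terms, .term_components)))
    X <- stats::model.matrix(fml, data = dt,
                             contrasts.arg = .contrast_list(dt, used))
    qrX <- qr(X)
    if (qrX$rank == ncol(X)) break
    bad_cols <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    bad_terms <- unique(attr(stats::terms(fml), "term.labels")[
      attr(X, "assign")[bad_cols]])
    ord <- order(-vapply(bad_terms, .term_order, 1L), bad_terms)
    terms <- setdiff(terms, bad_terms[ord[1L]])
  }
  terms
}

# ---------------------------------------------------------------------------

#' Backward elimination of fixed effects
#'
#' Iteratively refits the model, removing at each step the single least
#' significant eligible term with `p > alpha`.  Marginality is respected:
#' interactions are always eligible, a main effect only once no retained
#' interaction contains it.  Ties in p-value are broken by removing the
#' higher-order term first, then alphabetically.  Every removal is recorded.
#'
#' @inheritParams fit_lmm
#' @param alpha Retention threshold, default 0.05; `alpha = 1` returns the
#'   full model untouched.
#' @return List: `fit` (final `lmm_fit`), `terms` (retained term labels),
#'   `log` (`data.table` of elimination steps: step, term removed, its p,
#'   terms remaining after removal).
#' @export
backward_select <- function(data, response, terms = candidate_terms(),
                            alpha = 0.05,
                            df_method = c("satterthwaite", "between-within")) {
  df_method <- match.arg(df_method)
  stopifnot(alpha > 0, alpha <= 1)
  current <- terms
  steps <- list()
  step <- 0L
  fit <- fit_lmm(data, response, current, df_method = df_method)
  repeat {
    tt <- fit$term_table
    if (!nrow(tt)) break
    retained_inter <- current[vapply(current, .term_order, 1L) > 1L]
    protected <- unique(unlist(lapply(retained_inter, .term_components)))
    eligible <- vapply(tt$term, function(tm) {
      .term_order(tm) > 1L || !(tm %in% protected)
    }, logical(1))
    cand <- tt[eligible & tt$p > alpha]
    if (!nrow(cand)) break
    ord <- order(-cand$p,
                 -vapply(cand$term, .term_order, 1L),
                 cand$term)
    drop_term <- cand$term[ord[1L]]
    drop_p <- cand$p[ord[1L]]
    current <- setdiff(current, drop_term)
    step <- step + 1L
    steps[[step]] <- data.table::data.table(
      step = step, removed = drop_term, p = drop_p,
      remaining = paste(current, collapse = " + "))
    fit <- fit_lmm(data, response, current, df_method = df_method)
  }
  log <- if (length(steps)) data.table::rbindlist(steps) else
    data.table::data.table(step = integer(), removed = character(),
                           p = numeric(), remaining = character())
  list(fit = fit, terms = current, log = log)
}

# ---------------------------------------------------------------------------

#' Simulate descriptor data directly from a random-intercept model
#'
#' Gaussian generator used for parameter-recovery and selection tests:
#' `y_ij = intercept + sum_k beta_k x_k + u_j + e_ij` over a balanced
#' bird x age grid, with `u_j ~ N(0, var_id)` and `e_ij ~ N(0, var_resid)`.
#' Bird-level covariates (start BW, gain, sex, gait class) are drawn as in
#' the default synthetic flock unless supplied.
#'
#' @param n_birds Number of birds (default 58).
#' @param ages Integer ages in days (default 20:30).
#' @param beta Named numeric vector of true coefficients; names among
#'   `"(Intercept)"`, `"age_days"`, `"start_bw_g"`, `"bw_gain_g_d"`,
#'   `"sex"` (sum-to-zero effect of female), `"gait_class"` (effect of GG).
#' @param var_id,var_resid True variance components.
#' @param covariates Optional per-bird covariate table (`bird_id`, `sex`,
#'   `gait_class`, `start_bw_g`, `bw_gain_g_d`); drawn if `NULL`.
#' @return `data.table` with `bird_id`, `age_days`, the covariates, the
#'   response `y`, and attribute `truth` (the inputs).
#' @export
simulate_lmm_data <- function(n_birds = 58, ages = 20:30,
                              beta = c(`(Intercept)` = 111.41,
                                       age_days = -2.212),
                              var_id = 232.4, var_resid = 368.3,
                              covariates = NULL) {
  if (is.null(covariates)) covariates <- .draw_bird_covariates(n_birds)
  cv <- data.table::as.data.table(covariates)
  grid <- data.table::CJ(bird_id = cv$bird_id, age_days = as.integer(ages))
  d <- cv[grid, on = "bird_id"]
  lp <- rep(beta[["(Intercept)"]], nrow(d))
  if ("age_days" %in% names(beta)) lp <- lp + beta[["age_days"]] * d$age_days
  if ("start_bw_g" %in% names(beta)) lp <- lp + beta[["start_bw_g"]] * d$start_bw_g
  if ("bw_gain_g_d" %in% names(beta)) lp <- lp + beta[["bw_gain_g_d"]] * d$bw_gain_g_d
  if ("sex" %in% names(beta))
    lp <- lp + beta[["sex"]] * ifelse(d$sex == "female", 1, -1)
  if ("gait_class" %in% names(beta))
    lp <- lp + beta[["gait_class"]] * ifelse(d$gait_class == "GG", 1, -1)
  u <- stats::rnorm(nrow(cv), 0, sqrt(var_id))
  names(u) <- cv$bird_id
  d[, y := lp + u[bird_id] + stats::rnorm(.N, 0, sqrt(var_resid))]
  data.table::setattr(d, "truth",
                      list(beta = beta, var_id = var_id, var_resid = var_resid))
  d[]
}

# default bird-level covariate draws shared with the flock simulator
.draw_bird_covariates <- function(n_birds,
                                  bw_mean = 596, bw_sd = 52,
                                  gain_mean = 91.38, gain_sd = 18,
                                  rho = 0.30, p_sg = 17 / 58) {
  z1 <- stats::rnorm(n_birds)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_birds)
  data.table::data.table(
    bird_id = sprintf("B%03d", seq_len(n_birds)),
    sex = factor(sample(c("female", "male"), n_birds, TRUE),
                 levels = c("female", "male")),
    gait_class = factor(ifelse(stats::runif(n_birds) < p_sg, "SG", "GG"),
                        levels = c("GG", "SG")),
    start_bw_g = bw_mean + bw_sd * z1,
    bw_gain_g_d = gain_mean + gain_sd * z2)
}
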