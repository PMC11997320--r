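sim_small <- function(seed = 101, n_birds = 20, ages = 20:25, ...) {
  set.seed(seed)
  simulate_lmm_data(n_birds = n_birds, ages = ages, ...)
}

test_that("R2 from variance components: closed form and limits", {
  r2 <- r2_components(1, 1, 2)
  expect_equal(unname(r2), c(0.25, 0.50), tolerance = 1e-10)
  expect_equal(unname(r2_components(0, 1, 2)[1]), 0)
  expect_equal(unname(r2_components(0, 0, 0)), c(0, 0))
  # all-null fixed effects: marginal R2 ~ 0
  d <- sim_small(103, beta = c(`(Intercept)` = 5), var_id = 4, var_resid = 9)
  f <- fit_lmm(d, "y", character(0))
  expect_lt(f$r2_marginal, 1e-6)
  expect_lte(f$r2_marginal, f$r2_conditional)
  expect_lte(f$r2_conditional, 1)
})

test_that("balanced two-level factor with sum-to-zero coding: intercept is the mean of group means", {
  d <- data.table::data.table(
    bird_id = rep(c("a", "b", "c", "d"), each = 2),
    sex = factor(rep(c("female", "female", "male", "male"), each = 2),
                 levels = c("female", "male")),
    age_days = rep(c(20L, 21L), 4),
    y = c(10, 12, 14, 16, 20, 22, 30, 32))
  f <- fit_lmm(d, "y", "sex")
  gm <- mean(c(mean(c(10, 12, 14, 16)), mean(c(20, 22, 30, 32))))
  expect_equal(f$coefficients$estimate[1], gm, tolerance = 1e-8)
  # contrast columns sum to zero
  X <- stats::model.matrix(~sex, d, contrasts.arg = list(sex = "contr.sum"))
  expect_equal(sum(X[, 2]), 0)
})

test_that("fast Satterthwaite machinery matches the dense reference", {
  d <- sim_small(111, n_birds = 8, ages = 20:24,
                 beta = c(`(Intercept)` = 10, age_days = 1,
                          start_bw_g = 0.01),
                 var_id = 4, var_resid = 9)
  f <- fit_lmm(d, "y", c("age_days", "start_bw_g"))
  X <- stats::model.matrix(~age_days + start_bw_g, d)
  tau2 <- f$varcomp[["var_id"]]; sig2 <- f$varcomp[["var_resid"]]
  ref <- dense_satterthwaite(X, d$bird_id, tau2, sig2)
  st <- flockfeedr:::.per_bird_stats(X, as.character(d$bird_id))
  info_fast <- flockfeedr:::.reml_fisher_info(st, tau2, sig2)
  expect_equal(info_fast, ref$info, tolerance = 1e-8)
  df_fast <- flockfeedr:::.satterthwaite_df(st, tau2, sig2, nrow(X), ncol(X))
  expect_equal(df_fast, ref$df, tolerance = 1e-6)
  expect_equal(f$coefficients$df, unname(df_fast), tolerance = 1e-6)
  # within-bird covariate gets large df, bird-level covariate small df
  expect_gt(f$coefficients$df[2], f$coefficients$df[3])
})

test_that("flipping factor level labels flips the coefficient sign only", {
  d <- sim_small(121, beta = c(`(Intercept)` = 10, sex = 2),
                 var_id = 1, var_resid = 4)
  f1 <- fit_lmm(d, "y", c("age_days", "sex"))
  d2 <- data.table::copy(d)
  d2[, sex := factor(sex, levels = c("male", "female"))]
  f2 <- fit_lmm(d2, "y", c("age_days", "sex"))
  i <- match("sex1", f1$coefficients$coef)
  expect_equal(f1$coefficients$estimate[i], -f2$coefficients$estimate[i],
               tolerance = 1e-8)
  j <- match("age_days", f1$coefficients$coef)
  expect_equal(f1$coefficients$estimate[j], f2$coefficients$estimate[j],
               tolerance = 1e-8)
  expect_equal(f1$coefficients$p[i], f2$coefficients$p[i], tolerance = 1e-8)
})

test_that("R2 pair is invariant to affine rescaling of a covariate", {
  d <- sim_small(131, beta = c(`(Intercept)` = 10, age_days = -1,
                               start_bw_g = 0.05),
                 var_id = 2, var_resid = 5)
  f1 <- fit_lmm(d, "y", c("age_days", "start_bw_g"))
  d2 <- data.table::copy(d)
  d2[, start_bw_g := (start_bw_g - 600) / 50]
  f2 <- fit_lmm(d2, "y", c("age_days", "start_bw_g"))
  expect_equal(f1$r2_marginal, f2$r2_marginal, tolerance = 1e-6)
  expect_equal(f1$r2_conditional, f2$r2_conditional, tolerance = 1e-6)
})

test_that("degenerate random effect: var_id ~ 0 gives r2_marginal ~ r2_conditional", {
  d <- sim_small(141, beta = c(`(Intercept)` = 10, age_days = 2),
                 var_id = 0, var_resid = 4)
  f <- fit_lmm(d, "y", "age_days")
  # truth var_id = 0: estimate sits at/near the boundary, a small fraction
  # of the residual variance (4)
  expect_lt(f$varcomp[["var_id"]], 0.1 * f$varcomp[["var_resid"]])
  expect_equal(f$r2_marginal, f$r2_conditional, tolerance = 0.05)
})

test_that("singular designs fail loudly naming the collinear column", {
  d <- sim_small(151)
  d[, dup := start_bw_g]
  expect_error(fit_lmm(d, "y", c("start_bw_g", "dup")),
               "singular.*dup")
})

test_that("parameter recovery at the default effect sizes (quick check)", {
  set.seed(161)
  est <- replicate(10, {
    d <- simulate_lmm_data()   # defaults: 58 birds x 11 d, age slope -2.212
    fit_lmm(d, "y", "age_days")$coefficients$estimate[2]
  })
  expect_equal(mean(est), -2.212, tolerance = 0.15)
})

test_that("backward selection: alpha = 1 keeps the full model; strong age effect is found", {
  d <- sim_small(171, n_birds = 30, ages = 20:27,
                 beta = c(`(Intercept)` = 100, age_days = -5),
                 var_id = 10, var_resid = 20)
  full <- backward_select(d, "y", terms = c("age_days", "sex", "start_bw_g"),
                          alpha = 1)
  expect_equal(sort(full$terms), sort(c("age_days", "sex", "start_bw_g")))
  expect_equal(nrow(full$log), 0L)
  sel <- backward_select(d, "y", terms = c("age_days", "sex", "start_bw_g"))
  expect_true("age_days" %in% sel$terms)
})

test_that("backward selection respects marginality and logs a valid derivation", {
  d <- sim_small(181, n_birds = 24, ages = 20:25,
                 beta = c(`(Intercept)` = 50, age_days = -3),
                 var_id = 4, var_resid = 9)
  sel <- backward_select(d, "y")
  # final model: every retained interaction has its mains retained
  inter <- sel$terms[grepl(":", sel$terms)]
  for (tm in inter) {
    comps <- strsplit(tm, ":")[[1]]
    expect_true(all(comps %in% sel$terms))
  }
  # each logged removal had p > alpha at its step
  expect_true(all(sel$log$p > 0.05))
  # no main effect was removed while one of its interactions was retained
  if (nrow(sel$log)) {
    for (s in seq_len(nrow(sel$log))) {
      rm_term <- sel$log$removed[s]
      if (!grepl(":", rm_term)) {
        remaining <- strsplit(sel$log$remaining[s], " \\+ ")[[1]]
        inter_left <- remaining[grepl(":", remaining)]
        comps <- unlist(strsplit(inter_left, ":"))
        expect_false(rm_term %in% comps)
      }
    }
  }
})
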