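# shared test machinery: single-threaded BLAS (multi-core hosts only; the
# numbers are identical either way), random-log generators, a small flock
# config, and a dense-matrix Satterthwaite reference implementation.

Sys.setenv(OMP_NUM_THREADS = "1", OPENBLAS_NUM_THREADS = "1")

.ts0 <- as.POSIXct("2024-01-21 06:00:00", tz = "UTC")

# detection table straight from vectors (already canonical form)
det_table <- function(t_offsets, bird, antenna, origin = .ts0) {
  dt <- data.table::data.table(timestamp = origin + t_offsets,
                               bird_id = as.character(bird),
                               antenna_id = as.integer(antenna))
  data.table::setorder(dt, bird_id, timestamp)
  dt[]
}

# random log with gaps concentrated around the 24 s boundary and frequent
# feeder switches; unique (bird, second) pairs by construction
rand_log <- function(n_records, n_birds = 3, antennas = c(2L, 3L, 7L, 16L)) {
  per <- table(sample(seq_len(n_birds), n_records, replace = TRUE))
  rows <- lapply(names(per), function(b) {
    n <- per[[b]]
    gaps <- sample(c(1:5, 23L, 24L, 25L, 26L, 40L), n, replace = TRUE,
                   prob = c(rep(0.12, 5), 0.1, 0.1, 0.1, 0.05, 0.05))
    t <- cumsum(gaps)
    ant <- antennas[1 + cumsum(stats::runif(n) < 0.15) %% length(antennas)]
    data.table::data.table(off = t, bird = sprintf("b%s", b), ant = ant)
  })
  d <- data.table::rbindlist(rows)
  det_table(d$off, d$bird, d$ant)
}

# small, fast flock: 6 birds x 4 days, modest visit counts
tiny_config <- function(seed = 1L, ...) {
  flock_config(
    n_birds = 6, ages = 20:23,
    coefficients = list(
      nfv  = c(intercept = 20.3, age = -0.30),
      mfbd = c(intercept = 10, age = 0.8, sw = 0.02, wg = -0.06),
      ndf  = c(intercept = 14, age = -0.15, sw = -0.004, wg = 0.01)),
    varcomp = list(nfv = c(var_id = 4, var_resid = 9),
                   mfbd = c(var_id = 16, var_resid = 64),
                   ndf = c(var_id = 0.4, var_resid = 1.2)),
    seed = seed, ...)
}

# model-ready table: descriptors from a flock sim joined to covariates
model_data <- function(sim, descriptors) {
  cov <- build_covariates(sim$covariates_raw)
  merge(descriptors, cov, by = "bird_id")
}

# ---------------------------------------------------------------------------
# dense reference for the Satterthwaite machinery: builds V explicitly

dense_satterthwaite <- function(X, group, tau2, sigma2) {
  n <- nrow(X); p <- ncol(X)
  Z <- stats::model.matrix(~ 0 + factor(group))
  Vfun <- function(t2, s2) s2 * diag(n) + t2 * tcrossprod(Z)
  Cfun <- function(t2, s2) solve(t(X) %*% solve(Vfun(t2, s2)) %*% X)
  V <- Vfun(tau2, sigma2)
  Vi <- solve(V)
  C <- Cfun(tau2, sigma2)
  P <- Vi - Vi %*% X %*% C %*% t(X) %*% Vi
  Vt <- tcrossprod(Z); Vs <- diag(n)
  tr <- function(A) sum(diag(A))
  info <- matrix(0, 2, 2)
  info[1, 1] <- tr(P %*% Vt %*% P %*% Vt) / 2
  info[1, 2] <- info[2, 1] <- tr(P %*% Vt %*% P %*% Vs) / 2
  info[2, 2] <- tr(P %*% Vs %*% P %*% Vs) / 2
  A <- solve(info)
  f0 <- diag(C)
  h1 <- max(tau2, sigma2 * 1e-3) * 1e-4
  h2 <- sigma2 * 1e-4
  d_tau <- if (tau2 - h1 > 0)
    (diag(Cfun(tau2 + h1, sigma2)) - diag(Cfun(tau2 - h1, sigma2))) / (2 * h1)
  else (diag(Cfun(tau2 + h1, sigma2)) - f0) / h1
  d_sig <- (diag(Cfun(tau2, sigma2 + h2)) - diag(Cfun(tau2, sigma2 - h2))) / (2 * h2)
  df <- vapply(seq_len(p), function(j) {
    g <- c(d_tau[j], d_sig[j])
    2 * f0[j]^2 / drop(t(g) %*% A %*% g)
  }, numeric(1))
  list(info = info, df = pmin(pmax(df, 1), n - p))
}
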