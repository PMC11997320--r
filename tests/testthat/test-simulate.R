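test_that("same seed reproduces the flock bit for bit", {
  s1 <- simulate_flock(tiny_config(seed = 42))
  s2 <- simulate_flock(tiny_config(seed = 42))
  expect_identical(s1$bouts, s2$bouts)
  expect_identical(s1$daily, s2$daily)
  expect_identical(s1$covariates_raw, s2$covariates_raw)
  set.seed(42)
  d1 <- emit_detections(s1)
  set.seed(42)
  d2 <- emit_detections(s2)
  expect_identical(d1, d2)
  s3 <- simulate_flock(tiny_config(seed = 43))
  expect_false(identical(s1$bouts, s3$bouts))
})

test_that("start-BW draws match the configured distribution (3 SE at n = 58)", {
  set.seed(7)
  ok_mean <- ok_sd <- logical(20)
  for (i in 1:20) {
    sim <- simulate_flock(flock_config(ages = 20L, seed = 1000 + i))
    bw <- sim$covariates$start_bw_g
    ok_mean[i] <- abs(mean(bw) - 596) < 3 * 52 / sqrt(58)
    ok_sd[i] <- abs(sd(bw) - 52) < 3 * 52 / sqrt(2 * 58)
  }
  expect_gte(mean(ok_mean), 0.9)
  expect_gte(mean(ok_sd), 0.9)
})

test_that("realized NFV tracks the generator's own closed-form mean", {
  sim <- simulate_flock(flock_config(n_birds = 50, ages = 20:29, seed = 3))
  daily <- sim$daily
  # E[NFV | lp] = max(lp, 0); compare Monte-Carlo mean against it
  expected <- mean(pmax(daily$lp_nfv, 0))
  se <- sd(daily$nfv) / sqrt(nrow(daily))
  expect_lt(abs(mean(daily$nfv) - expected), 3 * se + 0.5)
})

test_that("site fidelity: near-degenerate preferences give NDF ~ 1", {
  cfg <- tiny_config(seed = 13, kappa = 1e-4)
  sim <- simulate_flock(cfg)
  active <- sim$daily[sim$daily$nfv > 0, ]
  expect_lt(mean(active$ndf), 2.1)
  expect_gte(mean(active$ndf == 1), 0.5)
})

test_that("bouts of one bird never overlap and respect the minimum gap", {
  sim <- simulate_flock(tiny_config(seed = 17))
  b <- data.table::copy(sim$bouts)
  data.table::setorder(b, bird_id, start)
  gap <- as.numeric(b$start[-1]) -
    (as.numeric(b$start[-nrow(b)]) + b$duration_s[-nrow(b)])
  same <- b$bird_id[-1] == b$bird_id[-nrow(b)]
  expect_true(all(gap[same] >= sim$config$min_interbout_gap_s))
})

test_that("emission conservation: no drop-out, no extension", {
  cfg <- tiny_config(seed = 19, dropout_prob = 0, auto_extension_s = 0)
  sim <- simulate_flock(cfg)
  det <- emit_detections(sim)
  expect_equal(nrow(det), sum(sim$bouts$duration_s))
})

test_that("emitted logs pass rfid_io validation and round-trip", {
  sim <- simulate_flock(tiny_config(seed = 23))
  set.seed(23)
  det <- emit_detections(sim)
  expect_true(all(det$antenna_id %in% sim$config$layout$antenna_equipped))
  f <- withr::local_tempfile(fileext = ".csv")
  write_detection_log(det, f)
  rec <- read_detection_log(f, sim$config$layout)
  expect_equal(as.data.frame(rec), as.data.frame(det), ignore_attr = TRUE)
  expect_identical(attr(rec, "n_collapsed"), 0L)
})

test_that("default config: segmentation recovers the true bouts exactly", {
  sim <- simulate_flock(tiny_config(seed = 29))
  set.seed(29)
  det <- emit_detections(sim)
  seg <- segment_bouts(det)
  truth <- data.table::copy(sim$bouts)
  data.table::setorder(truth, bird_id, start)
  expect_equal(nrow(seg), nrow(truth))
  expect_equal(seg$feeder_id, truth$feeder_id)
  expect_equal(as.numeric(seg$start), as.numeric(truth$start))
  expect_equal(seg$duration_s, truth$duration_s + 6)
})

test_that("a forced 25 s in-bout drop-out splits the bout (negative control)", {
  # one true bout of 60 s with seconds 11..35 removed: record gap 26 s > 24
  bout <- data.table::data.table(bird_id = "b1", feeder_id = 3L,
                                 start = .ts0, duration_s = 60)
  cfg <- tiny_config(seed = 1, dropout_prob = 0, auto_extension_s = 0)
  det <- emit_detections(bout, cfg)
  det <- det[!(as.numeric(timestamp) - as.numeric(.ts0)) %in% 10:35]
  seg <- segment_bouts(det)
  expect_equal(nrow(seg), 2L)
  # while a capped drop-out (<= max gap) is re-merged
  det2 <- emit_detections(bout, cfg)
  det2 <- det2[!(as.numeric(timestamp) - as.numeric(.ts0)) %in% 10:20]
  expect_equal(nrow(segment_bouts(det2)), 1L)
})

test_that("extension truncation: next bout at another feeder cuts the tail", {
  bouts <- data.table::data.table(
    bird_id = "b1", feeder_id = c(3L, 7L),
    start = .ts0 + c(0, 13), duration_s = c(10, 5))
  cfg <- tiny_config(seed = 1, dropout_prob = 0, truncate_extension = TRUE)
  det <- emit_detections(bouts, cfg)
  # bout 1 spans 0..9; extension would cover 10..15 but bout 2 starts at 13
  ext <- det[det$antenna_id == 3L]
  expect_equal(max(as.numeric(ext$timestamp) - as.numeric(.ts0)), 12)
  cfg2 <- tiny_config(seed = 1, dropout_prob = 0, truncate_extension = FALSE)
  det2 <- emit_detections(bouts, cfg2)
  ext2 <- det2[det2$antenna_id == 3L]
  expect_equal(max(as.numeric(ext2$timestamp) - as.numeric(.ts0)), 15)
})

test_that("infeasible day errors; effect_scale preserves the reference mean", {
  cfg <- tiny_config(seed = 31, active_window_s = c(0, 1200))
  expect_error(simulate_flock(cfg), "infeasible")
  co <- flock_config()$coefficients$nfv
  sc <- flockfeedr:::.scaled_coef(co, 3)
  ref <- flockfeedr:::.REF
  m1 <- co[["intercept"]] + co[["age"]] * ref[["age"]]
  m3 <- sc[["intercept"]] + sc[["age"]] * ref[["age"]]
  expect_equal(m1, m3, tolerance = 1e-10)
  expect_equal(sc[["age"]], 3 * co[["age"]])
})

test_that("blind feeder: true visits there leave no records and an undercount", {
  cfg <- tiny_config(seed = 53, include_blind_feeder = TRUE, kappa = 5)
  sim <- simulate_flock(cfg)
  blind <- setdiff(cfg$layout$feeder_ids, cfg$layout$antenna_equipped)
  n_blind <- sum(sim$bouts$feeder_id %in% blind)
  expect_gt(n_blind, 0)         # with kappa = 5 all 16 feeders get traffic
  set.seed(53)
  det <- emit_detections(sim)
  expect_false(any(det$antenna_id %in% blind))
  seg <- segment_bouts(det)
  # observed bout count = truth minus the unobservable blind-feeder bouts
  expect_equal(nrow(seg), nrow(sim$bouts) - n_blind)
  # truth NDF never counts the blind feeder
  expect_true(all(sim$daily$ndf <= length(cfg$layout$antenna_equipped)))
})

test_that("write_flock writes a complete, readable artifact bundle", {
  dir <- withr::local_tempdir()
  sim <- simulate_flock(tiny_config(seed = 37))
  set.seed(37)
  write_flock(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("detections.csv", "covariates.csv", "truth_bouts.csv",
      "truth_daily.csv", "layout.json")))))
  cv <- read_covariates(file.path(dir, "covariates.csv"))
  expect_true(all(cv$complete))
  rec <- read_detection_log(file.path(dir, "detections.csv"))
  expect_gt(nrow(rec), 0)
})
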