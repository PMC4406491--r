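test_that("protocol geometry gives ~375-ms contractions", {
  expect_equal(protocol_duration(90, 240), 0.375)
  expect_error(protocol_duration(0, 240), "invalid-config")
})

test_that("torque generator honours its construction constraints", {
  tr <- gen_contraction_torque(1000, 100)
  expect_equal(length(tr$values), round(0.375 * 100))
  expect_equal(tr$values[1], 0)
  expect_equal(compute_rtd(tr, 0), 1000, tolerance = 1e-9)
  tr2 <- gen_contraction_torque(1069, 172.8)
  expect_equal(max(tr2$values), 172.8)
  # programmed mean torque
  tr3 <- gen_contraction_torque(1069, 172.8, tmean_true = 94.0)
  expect_equal(mean(tr3$values), 94.0, tolerance = 1e-9)
  # peak occurs ~160 ms after onset
  expect_equal(trace_time(tr2)[which.max(tr2$values)], 0.16)
  expect_error(gen_contraction_torque(-5, 100), "invalid-config")
  expect_error(gen_contraction_torque(1000, 100, duration = 0.2),
               "invalid-config")
  expect_error(gen_contraction_torque(1000, 100, rate = -1), "invalid-config")
})

test_that("noisy torque traces give an unbiased RTD on average", {
  set.seed(6)
  slopes <- replicate(400, {
    tr <- gen_contraction_torque(1069, 172.8, noise = 0.05,
                                 tmean_true = 94.0)
    compute_rtd(tr, 0)
  })
  sem <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 1069), 2 * sem + 1e-9)
})

test_that("EMG generator produces the programmed spectral content", {
  set.seed(31)
  # constant 80 Hz center: periodogram centroid within 5%
  x <- gen_contraction_emg(0.5, 80, duration = 2)
  expect_lt(abs(mean(x$values)), 1e-9)  # zero mean
  cen <- periodogram_centroid(x$values[x$values != 0], 2048)
  expect_lt(abs(cen / 80 - 1), 0.05)
  # zero envelope scale: silent trace
  expect_equal(max(abs(gen_contraction_emg(0, 80, duration = 0.5)$values)), 0)
  # step 100 -> 80 Hz at mid-signal: per-half centroids decrease
  set.seed(32)
  fstep <- function(t) ifelse(t < 1, 100, 80)
  xs <- gen_contraction_emg(0.5, fstep, duration = 2)
  n <- length(xs$values)
  c1 <- periodogram_centroid(xs$values[200:(n / 2 - 200)], 2048)
  c2 <- periodogram_centroid(xs$values[(n / 2 + 200):(n - 200)], 2048)
  expect_gt(c1 - c2, 10)
  expect_error(gen_contraction_emg(0.5, 600, duration = 0.5),
               "invalid-config")
  expect_error(gen_contraction_emg(0.5, 5, duration = 0.5), "invalid-config")
})

test_that("protocol generator has the study geometry and exact noise-free truth", {
  cfg <- quiet_config(n_subjects = 1, n_sets = 3, reps_per_set = 4)
  proto <- generate_protocol(cfg, include_emg = FALSE)
  expect_equal(length(proto$contractions), 12L)
  expect_equal(nrow(proto$truth$contractions), 12L)
  # single-contraction protocol: truth equals baseline
  cfg1 <- quiet_config(n_subjects = 1, n_sets = 1, reps_per_set = 1)
  p1 <- generate_protocol(cfg1, include_emg = FALSE)
  expect_equal(p1$truth$contractions$t_peak, p1$subjects$t_peak)
  expect_equal(p1$truth$contractions$rtd, p1$subjects$rtd)
  # noise-free extraction returns programmed truth to numerical precision
  tq <- torque_metrics_table(proto)
  tru <- proto$truth$contractions
  expect_true(all(abs(tq$rtd / tru$rtd - 1) < 1e-3))
  expect_true(all(abs(tq$t_peak / tru$t_peak - 1) < 1e-3))
  expect_true(all(abs(tq$t_mean / tru$t_mean - 1) < 1e-3))
  expect_true(all(tq$onset_s == cfg$timing$pre_baseline))
})

test_that("per-set declines follow the programmed schedule exactly", {
  cfg <- quiet_config(n_subjects = 1, n_sets = 5, reps_per_set = 2)
  proto <- generate_protocol(cfg, include_emg = FALSE)
  tru <- proto$truth$contractions
  sched <- 1 - (1 - cfg$decline$rtd) * (1:5 - 1) / 4
  set_means <- as.numeric(tapply(tru$rtd, tru$set, mean))
  expect_equal(set_means / set_means[1], sched)
  # extraction reproduces it on noise-free signals
  tq <- torque_metrics_table(proto)
  meas <- as.numeric(tapply(tq$rtd, tq$set, mean))
  expect_equal(meas / meas[1], sched, tolerance = 1e-6)
})

test_that("identical configurations give identical datasets, EMG subsetting changes nothing else", {
  cfg <- small_config(n_subjects = 1, n_sets = 2, reps_per_set = 2, seed = 9)
  p1 <- generate_protocol(cfg)
  p2 <- generate_protocol(cfg)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$contractions[[3]]$torque$values,
                   p2$contractions[[3]]$torque$values)
  expect_identical(p1$contractions[[2]]$emg$values,
                   p2$contractions[[2]]$emg$values)
  # restricting EMG generation leaves the torque stream untouched
  p3 <- generate_protocol(cfg, emg_sets = 2)
  expect_null(p3$contractions[[1]]$emg)
  expect_false(is.null(p3$contractions[[3]]$emg))
  expect_identical(p1$contractions[[1]]$torque$values,
                   p3$contractions[[1]]$torque$values)
  expect_identical(p1$contractions[[3]]$emg$values,
                   p3$contractions[[3]]$emg$values)
})

test_that("ground truth values are strictly positive and complete", {
  proto <- generate_protocol(small_config(seed = 3), emg_sets = 1)
  tru <- proto$truth$contractions
  num <- tru[, c("rtd", "t_peak", "t_mean", "rer", "emg_peak", "emg_mean",
                 "if_center_early", "if_center_late")]
  expect_true(all(num > 0))
  expect_equal(nrow(tru), length(proto$contractions))
  expect_true(all(proto$truth$nm$e_tpeak > 0))
  expect_true(all(proto$truth$nm$va <= 100 & proto$truth$nm$va >= 0))
})

test_that("VO2 series follows the programmed mono-exponential", {
  y <- gen_vo2_series(23.7, 60, baseline = 5, n_points = 20)
  expect_equal(y$vo2, 23.7 - (23.7 - 5) * exp(-y$t_s / 60))
  expect_error(gen_vo2_series(20, -5), "invalid-config")
})

test_that("invalid configurations are rejected with field names", {
  expect_error(protocol_config(decline = list(rtd = 0)), "decline")
  expect_error(protocol_config(decline = list(bogus = 0.5)), "bogus")
  expect_error(protocol_config(noise_levels = list(torque = -1)),
               "noise levels")
  expect_error(protocol_config(torque_rate = 0), "invalid-config")
})
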