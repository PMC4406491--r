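test_that("compute_rtd matches exact slopes on constructed traces", {
  # linear ramp 0 -> 100 N.m over 0.1 s: slope 1000 exactly
  ramp <- sampled_trace(seq(0, 100, length.out = 11), rate = 100)
  expect_equal(compute_rtd(ramp, onset = 0, window = 0.075), 1000)
  # constant trace: zero slope
  flat <- sampled_trace(rep(50, 20), rate = 100)
  expect_equal(compute_rtd(flat, 0), 0)
  # quadratic torque a*t^2: equals the OLS slope on the 8 window samples
  tk <- (0:19) / 100
  quad <- sampled_trace(5000 * tk^2, rate = 100)
  w <- tk[tk <= 0.075]
  oracle <- unname(coef(lm(I(5000 * w^2) ~ w))[2])
  expect_equal(compute_rtd(quad, 0), oracle, tolerance = 1e-12)
})

test_that("compute_rtd is offset-invariant and scales linearly", {
  set.seed(4)
  y <- cumsum(abs(rnorm(30)))
  tr <- sampled_trace(y, rate = 100)
  r0 <- compute_rtd(tr, 0)
  expect_equal(compute_rtd(sampled_trace(y + 37.5, 100), 0), r0)
  expect_equal(compute_rtd(sampled_trace(3 * y, 100), 0), 3 * r0)
})

test_that("onset detection finds a clean ramp start and rejects flat traces", {
  v <- c(rep(0, 50), seq(0, 100, length.out = 50))
  tr <- sampled_trace(v, rate = 100)
  onset <- detect_onset(tr, baseline_window = 0.4)
  expect_lt(abs(onset - 0.5), 0.011)  # within one sample
  expect_error(detect_onset(sampled_trace(rep(0, 100), 100), 0.4),
               "onset-not-found")
})

test_that("onset detection recovers a noisy ramp start within 20 ms", {
  set.seed(11)
  errs <- replicate(300, {
    v <- c(rep(0, 50), 200 * seq(0, 0.5, length.out = 50)) + rnorm(100, 0, 1)
    detect_onset(sampled_trace(v, 100), 0.4) - 0.5
  })
  expect_lt(mean(abs(errs)), 0.02)
})

test_that("onset detection followed by RTD on a pure ramp gives the ramp slope", {
  v <- c(rep(0, 50), seq(0, 150, length.out = 30), rep(150, 20))
  tr <- sampled_trace(v, rate = 100)
  onset <- detect_onset(tr, 0.4)
  slope_true <- 150 / 0.29
  expect_equal(compute_rtd(tr, onset), slope_true, tolerance = 1e-10)
})

test_that("compute_tpeak_tmean returns max, mean and time-to-peak", {
  # half-sine reaching 172.8
  tk <- (0:37) / 100
  y <- 172.8 * sin(pi * tk / max(tk))
  tr <- sampled_trace(y, rate = 100)
  out <- compute_tpeak_tmean(tr, 0, max(tk))
  expect_equal(out$t_peak, 172.8, tolerance = 1e-3)
  expect_equal(out$t_mean, mean(y))  # direct-summation oracle
  # constant window
  cst <- compute_tpeak_tmean(sampled_trace(rep(50, 10), 100), 0, 0.09)
  expect_equal(cst$t_peak, 50)
  expect_equal(cst$t_mean, 50)
  expect_equal(cst$time_to_peak, 0)
  # triangle 0 -> 100 -> 0: mean equals direct summation
  tri <- c(seq(0, 100, length.out = 11), seq(90, 0, length.out = 10))
  trt <- sampled_trace(tri, 100)
  out2 <- compute_tpeak_tmean(trt, 0, 0.20)
  expect_equal(out2$t_mean, mean(tri))
  expect_error(compute_tpeak_tmean(trt, 0.2, 0.1), "insufficient-samples")
})

test_that("time_to_target_velocity interpolates the crossing", {
  # linear ramp reaching 240 deg/s at 57 ms and rising beyond
  tk <- (0:30) / 100
  v <- sampled_trace(240 * tk / 0.057, rate = 100)
  expect_equal(time_to_target_velocity(v, 240, 0), 0.057, tolerance = 1e-10)
  # starts at target
  v0 <- sampled_trace(rep(240, 10), 100)
  expect_equal(time_to_target_velocity(v0, 240, 0), 0)
  # never reached
  v2 <- sampled_trace(rep(200, 10), 100)
  expect_error(time_to_target_velocity(v2, 240, 0), "target-not-reached")
})

test_that("compute_imvc takes the 500-ms pre-stimulus maximum", {
  y <- c(rep(0, 100), rep(320, 200), rep(0, 100))
  tr <- sampled_trace(y, rate = 100)
  expect_equal(compute_imvc(tr, stim_time = 2.5), 320)
  # rising ramp ending at the stimulation: value at the stimulation
  y2 <- seq(0, 300, length.out = 301)
  tr2 <- sampled_trace(y2, rate = 100)
  expect_equal(compute_imvc(tr2, stim_time = 3), 300)
  # a spike after the stimulation is excluded by the window bound
  y3 <- c(rep(250, 300), 400, rep(0, 50))
  tr3 <- sampled_trace(y3, rate = 100)
  expect_equal(compute_imvc(tr3, stim_time = 2.5), 250)
  expect_error(compute_imvc(tr3, stim_time = 0.2), "insufficient-samples")
})

test_that("voluntary activation formula, clipping and monotonicity", {
  expect_equal(voluntary_activation(5, 100), 95)
  expect_equal(voluntary_activation(0, 100), 100)
  expect_equal(voluntary_activation(100, 100), 0)
  expect_warning(va <- voluntary_activation(-2, 100), "clipped")
  expect_equal(va, 100)
  expect_error(voluntary_activation(5, 0), "invalid-input")
  # antitone in the superimposed twitch, isotone in the resting twitch
  sup <- seq(0, 50, by = 10)
  vas <- vapply(sup, voluntary_activation, numeric(1),
                potentiated_resting_twitch = 100)
  expect_true(all(diff(vas) < 0))
  rests <- seq(60, 140, by = 20)
  var <- vapply(rests, function(r) voluntary_activation(30, r), numeric(1))
  expect_true(all(diff(var) > 0))
})

test_that("evoked metrics: peak equals programmed amplitude, eRTD matches analytic derivative", {
  resp <- gen_evoked_response(120.6, 0.02, 0.1, rate = 100)
  out <- evoked_metrics(resp)
  expect_equal(out$e_tpeak, 120.6)
  # at a high sampling rate the central-difference maximum approaches the
  # analytic derivative maximum K*(1/rise - 1/decay) at t = 0+
  rate <- 10000
  r2 <- gen_evoked_response(1, 0.02, 0.1, rate = rate)
  base <- exp(-(0:(0.8 * rate - 1)) / rate / 0.1) -
    exp(-(0:(0.8 * rate - 1)) / rate / 0.02)
  K <- 1 / max(base)
  analytic <- K * (1 / 0.02 - 1 / 0.1)  # derivative is maximal at onset
  expect_equal(evoked_metrics(r2)$e_rtd, analytic, tolerance = 0.01)
  expect_error(evoked_metrics(sampled_trace(rep(0, 10), 100)),
               "invalid-response")
})

test_that("evoked response construction respects its closed form", {
  # analytic peak time for the continuous waveform (sampled argmax falls on
  # the nearest grid point)
  tstar <- log(0.1 / 0.02) / (1 / 0.02 - 1 / 0.1)
  rate <- 10000
  resp <- gen_evoked_response(50, 0.02, 0.1, rate = rate)
  expect_lt(abs(trace_time(resp)[which.max(resp$values)] - tstar), 1 / rate)
  # returns below 1% of amplitude by trace end
  expect_lt(resp$values[length(resp$values)], 0.01 * 50)
  expect_equal(max(gen_evoked_response(0, 0.02, 0.1, 100)$values), 0)
  expect_error(gen_evoked_response(50, 0.1, 0.05, 100), "invalid-config")
})

test_that("doublet ratio is plain division with positivity guards", {
  expect_equal(db_ratio(107.7, 121), 107.7 / 121)
  expect_equal(round(db_ratio(107.7, 121), 2), 0.89)
  expect_equal(db_ratio(5, 5), 1)
  b <- 87.3
  expect_equal(db_ratio(0.64 * b, b), 0.64)
  expect_error(db_ratio(0, 10), "invalid-input")
  expect_error(db_ratio(10, -1), "invalid-input")
})

test_that("superimposed twitch is the increment above the plateau", {
  imvc <- gen_imvc_trace(300, sup_amp = 12, stim_time = 2.5, noise = 0)
  sup <- superimposed_twitch(imvc$trace, imvc$stim_time)
  expect_equal(sup, 12, tolerance = 0.02)
  expect_equal(compute_imvc(imvc$trace, imvc$stim_time), 300)
})
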