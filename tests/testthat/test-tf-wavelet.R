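test_that("wavelet bank reproduces the polynomial center-frequency law", {
  bank <- wavelet_bank()
  closed_form <- (1 / 0.3) * ((0:10) + 1.45)^1.959
  expect_equal(bank$center_freqs, closed_form, tolerance = 1e-12)
  expect_equal(round(bank$center_freqs[1], 2), 6.90)
  expect_equal(round(bank$center_freqs[2], 2), 19.29)
  expect_equal(round(bank$center_freqs[11], 1), 395.4)
  expect_true(all(diff(bank$center_freqs) > 0))
  expect_error(wavelet_bank(scale = -1), "invalid-config")
  expect_error(wavelet_bank(n = 1), "invalid-config")
})

test_that("Morlet CWT localises tones and handles degenerate inputs", {
  bank <- wavelet_bank()
  rate <- 2048
  tt <- (0:4095) / rate
  interior <- 1000:3000
  tone <- sampled_trace(sin(2 * pi * bank$center_freqs[6] * tt), rate)
  I <- wavelet_intensity(cwt_morlet(tone, bank))
  expect_equal(which.max(rowMeans(I[, interior])), 6L)
  zero <- cwt_morlet(sampled_trace(rep(0, 1024), rate), bank)
  expect_equal(max(Mod(zero$coef)), 0)
  expect_error(cwt_morlet(sampled_trace(rnorm(512), rate = 700), bank),
               "nyquist-violation")
})

test_that("impulse response per row matches the analytic Morlet envelope", {
  bank <- wavelet_bank()
  rate <- 2048
  n <- 4096
  imp <- sampled_trace(c(rep(0, n / 2), 1, rep(0, n / 2 - 1)), rate)
  cw <- cwt_morlet(imp, bank)
  tt <- (0:(n - 1)) / rate - (n / 2) / rate
  for (j in c(3, 6, 9)) {
    s <- (6 + sqrt(2 + 36)) / (4 * pi * bank$center_freqs[j])
    expect_gt(cor(Mod(cw$coef[j, ]), exp(-tt^2 / (2 * s^2))), 0.9999)
  }
})

test_that("intensity is squared modulus and scales quadratically", {
  bank <- wavelet_bank()
  set.seed(3)
  x <- rnorm(1024)
  tr1 <- sampled_trace(x, 2048)
  tr3 <- sampled_trace(3 * x, 2048)
  I1 <- wavelet_intensity(cwt_morlet(tr1, bank))
  I3 <- wavelet_intensity(cwt_morlet(tr3, bank))
  expect_true(all(I1 >= 0))
  expect_equal(I3, 9 * I1, tolerance = 1e-10)
})

test_that("instantaneous mean frequency is the intensity-weighted centroid", {
  bank <- wavelet_bank()
  n <- 5
  I <- matrix(0, bank$n_wavelets, n)
  I[4, ] <- 2.3
  expect_equal(instantaneous_mean_freq(I, bank),
               rep(bank$center_freqs[4], n))
  I2 <- matrix(0, bank$n_wavelets, n)
  I2[3, ] <- 1; I2[7, ] <- 1
  expect_equal(instantaneous_mean_freq(I2, bank),
               rep(mean(bank$center_freqs[c(3, 7)]), n))
  # all-zero frames are missing values, not errors
  I3 <- I2; I3[, 2] <- 0
  out <- instantaneous_mean_freq(I3, bank)
  expect_true(is.na(out[2]) && !is.na(out[1]))
  expect_error(instantaneous_mean_freq(I2[-1, ], bank), "invalid-input")
})

test_that("if_mean of a tone at a bank center is within 5% and always bounded", {
  bank <- wavelet_bank()
  rate <- 2048
  tt <- (0:4095) / rate
  f0 <- bank$center_freqs[5]
  tone <- sampled_trace(sin(2 * pi * f0 * tt), rate)
  ifm <- instantaneous_mean_freq(wavelet_intensity(cwt_morlet(tone, bank)),
                                 bank)
  expect_lt(abs(mean(ifm[1000:3000]) / f0 - 1), 0.05)
  # convex-combination bound for an arbitrary signal
  set.seed(5)
  x <- sampled_trace(rnorm(2048), rate)
  ifx <- instantaneous_mean_freq(wavelet_intensity(cwt_morlet(x, bank)), bank)
  ok <- is.finite(ifx)
  expect_true(all(ifx[ok] >= min(bank$center_freqs) - 1e-9))
  expect_true(all(ifx[ok] <= max(bank$center_freqs) + 1e-9))
})

test_that("total intensity of a band-limited tone tracks windowed power", {
  bank <- wavelet_bank()
  rate <- 2048
  tt <- (0:8191) / rate
  x <- sin(2 * pi * bank$center_freqs[5] * tt) * (1 + 0.5 * sin(2 * pi * tt))
  tr <- sampled_trace(x, rate)
  tot <- colSums(wavelet_intensity(cwt_morlet(tr, bank)))
  win <- moving_rms(tr, 0.05)$values^2
  expect_gt(cor(tot[2000:6000], win[2000:6000]), 0.99)
})

test_that("bin_if_mean averages half-open 75-ms intervals", {
  rate <- 2048
  n <- round(0.45 * rate)
  const <- rep(80, n)
  b <- bin_if_mean(const, rate, onset = 0)
  expect_equal(b$mean_hz, rep(80, 5))
  expect_equal(b$bin_label[1], "0-75 ms")
  # a step at 150 ms separates bins 1-2 from 3-5 by the step height
  tt <- (seq_len(n) - 1L) / rate
  stepped <- ifelse(tt < 0.150, 100, 80)
  b2 <- bin_if_mean(stepped, rate, onset = 0)
  expect_equal(b2$mean_hz, c(100, 100, 80, 80, 80))
  # missing values are dropped, masks are honoured
  with_na <- const; with_na[1:10] <- NA
  b3 <- bin_if_mean(with_na, rate, onset = 0)
  expect_equal(b3$mean_hz[1], 80)
  expect_equal(b3$n[1], sum(tt < 0.075) - 10L)
})

test_that("programmed early-window spectral decline appears in early bins only", {
  # one subject, spectral decline isolated from amplitude changes
  cfg <- quiet_config(n_subjects = 1, n_sets = 2, reps_per_set = 2,
                      decline = list(rer = 1, emg_mean = 1, emg_peak = 1,
                                     rtd = 1, t_mean = 1, t_peak = 1,
                                     if_early = 0.8))
  proto <- generate_protocol(cfg, include_nm = FALSE,
                             include_metabolic = FALSE)
  bins <- ifmean_bins_table(proto, sets = c(1, 2))
  agg <- stats::aggregate(mean_hz ~ set + bin_label, bins, mean)
  w <- stats::reshape(agg, idvar = "bin_label", timevar = "set",
                      direction = "wide")
  d <- w$mean_hz.2 - w$mean_hz.1
  names(d) <- w$bin_label
  expect_lt(d[["0-75 ms"]], -10)
  expect_lt(d[["75-150 ms"]], -10)
  expect_lt(d[["150-225 ms"]], -10)
  # the wavelets' finite time support smears the 225-ms spectral switch a
  # little into the neighbouring bin; late-bin shifts stay well below the
  # programmed early-bin decline
  expect_lt(abs(d[["225-300 ms"]]), 8)
  expect_lt(abs(d[["300-375 ms"]]), 8)
})
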