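# Shared fixtures: small, fast protocol configurations.

# All inter-subject variability and measurement noise switched off; the
# deterministic tone carrier replaces the stochastic EMG carrier so that
# envelope recovery is exact up to RMS-window ripple.
quiet_config <- function(n_subjects = 1, n_sets = 2, reps_per_set = 2,
                         seed = 1, ...) {
  protocol_config(
    n_subjects = n_subjects, n_sets = n_sets, reps_per_set = reps_per_set,
    seed = seed, carrier = "tone",
    noise_levels = list(torque = 0, torque_floor = 0, emg_floor = 0.02,
                        evoked = 0, imvc = 0, mwave = 0, vo2 = 0),
    baseline_cv = list(t_peak = 0, rtd_ratio = 0, tmean_ratio = 0,
                       emg_peak = 0, rer_ratio = 0, emean_ratio = 0,
                       if_center = 0, m_max = 0, imvc = 0, e_tpeak = 0,
                       ertd_ratio = 0, db_ratio = 0, va_sd = 0,
                       vo2_asymptote = 0, vo2_tau = 0, lactate_pre = 0,
                       lactate_delta = 0),
    ...)
}

small_config <- function(n_subjects = 2, n_sets = 4, reps_per_set = 2,
                         seed = 1, ...) {
  protocol_config(n_subjects = n_subjects, n_sets = n_sets,
                  reps_per_set = reps_per_set, seed = seed, ...)
}

# periodogram spectral centroid (Hz) over a band, as an independent oracle
# for programmed EMG spectral content
periodogram_centroid <- function(x, rate, band = c(10, 500)) {
  n <- length(x)
  X <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1L) * rate / n
  keep <- f >= band[1] & f <= band[2]
  sum(f[keep] * X[keep]) / sum(X[keep])
}
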