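#' Contraction duration implied by the protocol geometry
#'
#' An isokinetic knee extension through `rom_deg` degrees of range of motion
#' at a constant `velocity` deg/s lasts `rom_deg / velocity` seconds: 90
#' degrees at 240 deg/s gives 0.375 s.
#'
#' @param rom_deg range of motion in degrees (default 90).
#' @param velocity angular velocity in deg/s (default 240).
#' @return duration in seconds.
#' @export
protocol_duration <- function(rom_deg = 90, velocity = 240) {
  if (rom_deg <= 0 || velocity <= 0)
    stop("invalid-config: range of motion and velocity must be positive",
         call. = FALSE)
  rom_deg / velocity
}

# cubic smoothstep: s(0)=0, s(1)=1, zero first derivative at both ends
smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

# Unit torque shape over the contraction samples: rise smoothstep^beta to 1
# at t_rise, hold the peak until `hold` (equal to t_rise by default, i.e.
# no plateau), then fall smoothstep^theta back toward 0 at `duration`.
torque_shape <- function(t, t_rise, duration, beta, theta, hold = t_rise) {
  h <- numeric(length(t))
  r <- t >= 0 & t <= t_rise
  h[r] <- smoothstep(t[r] / t_rise)^beta
  h[t > t_rise & t <= hold] <- 1
  f <- t > hold & t < duration
  h[f] <- smoothstep((duration - t[f]) / (duration - hold))^theta
  h
}

# Solve the rise exponent so the OLS slope of tpeak * shape over the first
# `window` seconds equals rtd. Monotone decreasing in beta for a fixed
# rise time. When the requested slope is steeper than the default rise
# time can represent, the rise time is shortened along the sample grid
# (keeping the sampled peak exact) until the slope becomes representable.
solve_rise_beta <- function(rtd, tpeak, rate, t_rise, window = 0.075) {
  lo <- 0.02; hi <- 200
  candidates <- unique(c(t_rise, rev(seq(1 / rate, t_rise, by = 1 / rate))))
  for (tr in candidates) {
    tk <- seq(0, window, by = 1 / rate)
    u <- smoothstep(pmin(1, tk / tr))
    slope_of <- function(beta) ols_slope(tk, tpeak * u^beta)
    # the slope is monotone in beta for rise times covering the window but
    # not for shorter ones; a sign change over the bracket is what matters
    if ((slope_of(lo) - rtd) * (slope_of(hi) - rtd) <= 0) {
      beta <- stats::uniroot(function(b) slope_of(b) - rtd, c(lo, hi),
                             tol = 1e-12)$root
      hold <- if (tr >= window) tr else ceiling(window * rate) / rate
      return(list(beta = beta, t_rise = tr, hold = hold))
    }
  }
  stop("invalid-config: requested RTD/T_peak ratio is outside the range ",
       "representable by the torque rise model", call. = FALSE)
}

# Solve the fall exponent so the mean of tpeak * shape over the contraction
# samples equals tmean. Monotone decreasing in theta.
solve_fall_theta <- function(tmean, tpeak, beta, rate, t_rise, duration,
                             hold = t_rise) {
  n_c <- round(duration * rate)
  tk <- (seq_len(n_c) - 1L) / rate
  mean_of <- function(theta) mean(tpeak * torque_shape(tk, t_rise, duration,
                                                       beta, theta, hold))
  lo <- 0.02; hi <- 50
  if (mean_of(lo) < tmean || mean_of(hi) > tmean)
    stop("invalid-config: requested T_mean/T_peak ratio is outside the range ",
         "representable by the torque shape model", call. = FALSE)
  stats::uniroot(function(th) mean_of(th) - tmean, c(lo, hi), tol = 1e-12)$root
}

#' Generate one noiseless-or-noisy maximal contraction torque trace
#'
#' The torque rise is a smoothstep-to-peak whose rise exponent is solved
#' analytically so that the least-squares slope of the first 75 ms equals
#' `rtd_true` exactly in the noise-free case; the peak (reached `t_rise`
#' seconds after onset, ~160 ms by default) equals `tpeak_true`; when
#' `tmean_true` is given, the post-peak fall exponent is solved so the mean
#' over the contraction samples equals it.
#'
#' @param rtd_true true 0-75 ms slope, N·m·s^-1 (> 0).
#' @param tpeak_true true peak torque, N·m (> 0).
#' @param duration contraction duration in seconds (>= 0.3; default 0.375).
#' @param rate sampling rate in Hz (default 100).
#' @param noise relative (multiplicative) measurement-noise SD: each sample
#'   is perturbed by `noise * value` Gaussian noise, the proportional-error
#'   model of a torque transducer (default 0).
#' @param noise_floor additive baseline noise SD as a fraction of
#'   `tpeak_true` (default 0).
#' @param tmean_true optional true mean torque over the contraction, N·m.
#' @param t_rise time of the torque peak after onset, seconds (default 0.16).
#' @return a [sampled_trace()] of `round(duration * rate)` samples starting
#'   at the contraction onset (`t0 = 0`).
#' @export
gen_contraction_torque <- function(rtd_true, tpeak_true, duration = 0.375,
                                   rate = 100, noise = 0, noise_floor = 0,
                                   tmean_true = NULL, t_rise = 0.16) {
  if (rate <= 0 || duration <= 0)
    stop("invalid-config: rate and duration must be positive", call. = FALSE)
  if (duration < 0.3)
    stop("invalid-config: contraction duration must be at least 0.3 s",
         call. = FALSE)
  if (rtd_true <= 0 || tpeak_true <= 0)
    stop("invalid-config: rtd_true and tpeak_true must be positive",
         call. = FALSE)
  rise <- solve_rise_beta(rtd_true, tpeak_true, rate, t_rise)
  theta <- if (is.null(tmean_true)) 1 else
    solve_fall_theta(tmean_true, tpeak_true, rise$beta, rate, rise$t_rise,
                     duration, rise$hold)
  n_c <- round(duration * rate)
  tk <- (seq_len(n_c) - 1L) / rate
  y <- tpeak_true * torque_shape(tk, rise$t_rise, duration, rise$beta, theta,
                                 rise$hold)
  if (noise > 0) y <- y * (1 + stats::rnorm(n_c, 0, noise))
  if (noise_floor > 0) y <- y + stats::rnorm(n_c, 0, noise_floor * tpeak_true)
  sampled_trace(y, rate = rate, t0 = 0, unit = "N.m")
}

# ---- EMG carrier synthesis -------------------------------------------------

# Band-pass filtered Gaussian white noise with piecewise-constant center
# frequency, sqrt-crossfaded at breakpoints, normalised to unit standard
# deviation. `fc` is a vector of per-sample center frequencies (Hz).
make_noise_carrier <- function(fc, rate, bandwidth_ratio = 0.6, order = 2,
                               xfade = 0.02) {
  n <- length(fc)
  runs <- rle(round(fc, 6))
  n_seg <- length(runs$lengths)
  if (n_seg > 64) { # quantise pathological inputs into 64 hops
    hop <- ceiling(n / 64)
    fc <- rep(tapply(fc, (seq_len(n) - 1L) %/% hop, mean),
              each = hop)[seq_len(n)]
    runs <- rle(round(fc, 6))
    n_seg <- length(runs$lengths)
  }
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  nf <- max(1L, round(xfade * rate))
  out <- numeric(n)
  wsum <- numeric(n)
  for (i in seq_len(n_seg)) {
    f0 <- runs$values[i]
    band <- c(max(0.5, f0 * (1 - bandwidth_ratio / 2)),
              min(rate / 2 * 0.99, f0 * (1 + bandwidth_ratio / 2)))
    bf <- signal::butter(order, band / (rate / 2), type = "pass")
    y <- signal::filtfilt(bf, stats::rnorm(n))
    y <- y / stats::sd(y)
    # trapezoidal membership with xfade ramps at interior boundaries
    w <- numeric(n)
    w[starts[i]:ends[i]] <- 1
    if (i > 1L) {
      ramp <- seq(0, 1, length.out = nf)
      idx <- (starts[i] - nf %/% 2) + seq_len(nf) - 1L
      ok <- idx >= 1L & idx <= n
      w[idx[ok]] <- ramp[ok]
    }
    if (i < n_seg) {
      ramp <- seq(1, 0, length.out = nf)
      idx <- (ends[i] - nf %/% 2) + seq_len(nf) - 1L
      ok <- idx >= 1L & idx <= n
      w[idx[ok]] <- ramp[ok]
    }
    out <- out + sqrt(w) * y
    wsum <- wsum + w
  }
  out / sqrt(pmax(wsum, 1e-12))
}

# Deterministic unit-RMS tone carrier following the same center-frequency
# trajectory (phase-continuous).
make_tone_carrier <- function(fc, rate) {
  phase <- cumsum(2 * pi * fc / rate)
  sqrt(2) * sin(phase)
}

#' Generate one synthetic surface-EMG contraction burst
#'
#' Amplitude-modulated band-limited noise: Gaussian white noise is passed
#' through a 4th-order (order-2 Butterworth band-pass) filter centered at
#' the programmed spectral center with proportional bandwidth, normalised
#' to unit standard deviation, and multiplied by an envelope that rises
#' from zero after onset with a configurable rise time. The short-window
#' spectral centroid of the result tracks `spectral_center` and the RMS
#' envelope tracks `envelope_scale`.
#'
#' @param envelope_scale plateau RMS amplitude in mV (>= 0).
#' @param spectral_center center frequency in Hz: a scalar or a function of
#'   time (seconds since onset). Must stay within (10, 500) Hz.
#' @param rate sampling rate in Hz (default 2048).
#' @param duration burst duration in seconds.
#' @param rise_time envelope smoothstep rise time in seconds (default 0.05).
#' @param bandwidth_ratio spectral bandwidth as a fraction of the center
#'   frequency (default 0.6).
#' @param carrier `"noise"` (default) or `"tone"` (deterministic unit-RMS
#'   sinusoid, useful for exact envelope-recovery checks).
#' @return a zero-mean [sampled_trace()] of `round(duration * rate)` samples.
#' @export
gen_contraction_emg <- function(envelope_scale, spectral_center, rate = 2048,
                                duration = 0.375, rise_time = 0.05,
                                bandwidth_ratio = 0.6,
                                carrier = c("noise", "tone")) {
  carrier <- match.arg(carrier)
  if (rate <= 0 || duration <= 0)
    stop("invalid-config: rate and duration must be positive", call. = FALSE)
  if (envelope_scale < 0)
    stop("invalid-config: envelope_scale must be >= 0", call. = FALSE)
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1L) / rate
  fc <- if (is.function(spectral_center)) spectral_center(tt) else
    rep(spectral_center, n)
  if (any(!is.finite(fc)) || any(fc <= 10) || any(fc >= 500))
    stop("invalid-config: spectral_center must stay within (10, 500) Hz",
         call. = FALSE)
  if (envelope_scale == 0)
    return(sampled_trace(numeric(n), rate = rate, t0 = 0, unit = "mV"))
  env <- envelope_scale * smoothstep(tt / rise_time)
  x <- env * switch(carrier,
                    noise = make_noise_carrier(fc, rate, bandwidth_ratio),
                    tone = make_tone_carrier(fc, rate))
  x <- x - mean(x)
  sampled_trace(x, rate = rate, t0 = 0, unit = "mV")
}

#' Generate a bi-exponential evoked twitch response
#'
#' `K * (exp(-t/decay_tau) - exp(-t/rise_tau))` with `K` chosen so that the
#' maximum of the sampled waveform equals `amplitude`. The continuous-time
#' peak occurs at `t* = log(decay_tau/rise_tau) / (1/rise_tau - 1/decay_tau)`.
#'
#' @param amplitude peak torque of the response, N·m (>= 0).
#' @param rise_tau rise time constant in seconds (> 0).
#' @param decay_tau decay time constant in seconds (> rise_tau).
#' @param rate sampling rate in Hz.
#' @param duration trace duration in seconds (default 0.8).
#' @return a [sampled_trace()] starting at the stimulation instant.
#' @export
gen_evoked_response <- function(amplitude, rise_tau, decay_tau, rate = 100,
                                duration = 0.8) {
  if (rate <= 0 || duration <= 0)
    stop("invalid-config: rate and duration must be positive", call. = FALSE)
  if (!is.finite(rise_tau) || !is.finite(decay_tau) || rise_tau <= 0 ||
      decay_tau <= rise_tau)
    stop("invalid-config: need decay_tau > rise_tau > 0", call. = FALSE)
  if (amplitude < 0)
    stop("invalid-config: amplitude must be >= 0", call. = FALSE)
  n <- round(duration * rate)
  tk <- (seq_len(n) - 1L) / rate
  base <- exp(-tk / decay_tau) - exp(-tk / rise_tau)
  if (amplitude == 0)
    return(sampled_trace(numeric(n), rate = rate, t0 = 0, unit = "N.m"))
  y <- amplitude * base / max(base)
  sampled_trace(y, rate = rate, t0 = 0, unit = "N.m")
}

# Maximum central-difference derivative of a sampled evoked response with
# unit peak, as a function of rise_tau; used to program eRTD exactly.
evoked_unit_drmax <- function(rise_tau, decay_tau, rate, duration = 0.8) {
  tr <- gen_evoked_response(1, rise_tau, decay_tau, rate, duration)
  evoked_metrics(tr)$e_rtd
}

# Solve rise_tau so that the sampled central-difference derivative maximum
# of a response with peak `amplitude` equals `ertd`.
solve_evoked_rise_tau <- function(amplitude, ertd, decay_tau, rate,
                                  duration = 0.8) {
  target <- ertd / amplitude
  lo <- 5e-4; hi <- decay_tau * 0.9
  flo <- evoked_unit_drmax(lo, decay_tau, rate, duration)
  fhi <- evoked_unit_drmax(hi, decay_tau, rate, duration)
  if (target > flo || target < fhi)
    stop("invalid-config: requested eRTD/eT_peak ratio not representable ",
         "by the bi-exponential twitch at this sampling rate", call. = FALSE)
  stats::uniroot(function(rt) evoked_unit_drmax(rt, decay_tau, rate, duration) -
                   target, c(lo, hi), tol = 1e-10)$root
}

#' Generate a biphasic M-wave
#'
#' One carrier cycle under a Gaussian window, rescaled so the peak-to-peak
#' amplitude of the sampled waveform equals `amplitude`.
#'
#' @param amplitude peak-to-peak amplitude in mV.
#' @param rate sampling rate in Hz (default 2048).
#' @param duration trace duration in seconds (default 0.05).
#' @param f0 carrier frequency in Hz (default 60).
#' @param noise relative noise SD (fraction of `amplitude`).
#' @return a [sampled_trace()].
#' @export
gen_mwave <- function(amplitude, rate = 2048, duration = 0.05, f0 = 60,
                      noise = 0) {
  if (amplitude <= 0) stop("invalid-config: amplitude must be > 0", call. = FALSE)
  n <- round(duration * rate)
  tk <- (seq_len(n) - 1L) / rate
  tc <- duration / 2
  base <- sin(2 * pi * f0 * (tk - tc)) * exp(-((tk - tc) / (duration / 6))^2)
  y <- amplitude * base / (max(base) - min(base))
  if (noise > 0) y <- y + stats::rnorm(n, 0, noise * amplitude)
  sampled_trace(y, rate = rate, t0 = 0, unit = "mV")
}

#' Generate an IMVC trial trace with a superimposed stimulation
#'
#' Torque rises to a plateau at `imvc_true`, a superimposed evoked response
#' of amplitude `sup_amp` is added at `stim_time`, the plateau is held about
#' 1 s beyond the stimulation and then released.
#'
#' @param imvc_true plateau torque, N·m.
#' @param sup_amp superimposed twitch amplitude, N·m (>= 0).
#' @param stim_time stimulation time in seconds from trace start.
#' @param rate sampling rate in Hz (default 100).
#' @param duration trace duration in seconds (default 4).
#' @param noise relative noise SD (fraction of `imvc_true`).
#' @return list with `trace` (a [sampled_trace()]) and `stim_time`.
#' @export
gen_imvc_trace <- function(imvc_true, sup_amp, stim_time = 2.5, rate = 100,
                           duration = 4, noise = 0) {
  if (imvc_true <= 0) stop("invalid-config: imvc_true must be > 0", call. = FALSE)
  if (sup_amp < 0) stop("invalid-config: sup_amp must be >= 0", call. = FALSE)
  if (stim_time < 1 || stim_time > duration - 0.5)
    stop("invalid-config: stim_time must leave a 500-ms pre-stimulus plateau ",
         "and room for the response", call. = FALSE)
  n <- round(duration * rate)
  tk <- (seq_len(n) - 1L) / rate
  rise_end <- 1.0
  hold_end <- min(duration - 0.3, stim_time + 1.0)
  y <- imvc_true * smoothstep(tk / rise_end)
  rel <- tk > hold_end
  y[rel] <- imvc_true * smoothstep((duration - tk[rel]) / (duration - hold_end))
  if (sup_amp > 0) {
    resp <- gen_evoked_response(sup_amp, 0.015, 0.06, rate, duration = 0.4)
    k0 <- which.min(abs(tk - stim_time))
    idx <- k0 + seq_along(resp$values) - 1L
    ok <- idx <= n
    y[idx[ok]] <- y[idx[ok]] + resp$values[ok]
  }
  if (noise > 0) y <- y + stats::rnorm(n, 0, noise * imvc_true)
  list(trace = sampled_trace(y, rate = rate, t0 = 0, unit = "N.m"),
       stim_time = tk[which.min(abs(tk - stim_time))])
}

#' Generate a mono-exponential oxygen-uptake series
#'
#' `y(t) = asymptote - (asymptote - baseline) * exp(-t / tau)` evaluated at
#' the end of consecutive averaging intervals, plus relative Gaussian noise.
#'
#' @param asymptote steady-state VO2, mL·min^-1·kg^-1.
#' @param tau time constant in seconds (> 0).
#' @param baseline resting VO2, same units.
#' @param n_points number of interval averages.
#' @param interval averaging interval in seconds (default 30).
#' @param noise relative noise SD (fraction of `asymptote`).
#' @return data.frame with `t_s` and `vo2`.
#' @export
gen_vo2_series <- function(asymptote, tau, baseline = 5, n_points = 20,
                           interval = 30, noise = 0) {
  if (tau <= 0) stop("invalid-config: tau must be > 0", call. = FALSE)
  tt <- interval * seq_len(n_points)
  y <- asymptote - (asymptote - baseline) * exp(-tt / tau)
  if (noise > 0) y <- y + stats::rnorm(n_points, 0, noise * asymptote)
  data.frame(t_s = tt, vo2 = y)
}
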