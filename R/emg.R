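#' Band-pass filter raw EMG
#'
#' Zero-phase (forward-backward) Butterworth band-pass of the stated order.
#' Zero-phase filtering is used so that activation-onset timing is not
#' lag-shifted; the quoted `order` is the order of the underlying low/high
#' prototypes (an order-2 band-pass has 4 poles).
#'
#' @param raw raw EMG [sampled_trace()] in mV.
#' @param low,high band edges in Hz (defaults 10 and 500).
#' @param order Butterworth order (default 2).
#' @return filtered [sampled_trace()].
#' @export
emg_bandpass <- function(raw, low = 10, high = 500, order = 2) {
  stopifnot(inherits(raw, "sampled_trace"))
  if (raw$rate <= 2 * high)
    stop("nyquist-violation: sampling rate must exceed twice the upper band edge",
         call. = FALSE)
  if (low <= 0 || high <= low)
    stop("invalid-config: need 0 < low < high", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (raw$rate / 2), type = "pass")
  out <- signal::filtfilt(bf, raw$values)
  sampled_trace(out, rate = raw$rate, t0 = raw$t0, unit = raw$unit)
}

#' Moving root-mean-square envelope
#'
#' Centered rectangular-window RMS at the input sampling rate; the window is
#' truncated at the trace edges. A centered window smears the activation
#' onset symmetrically, which fixes the semantics of the rate-of-EMG-rise
#' window (the RMS envelope starts rising half a window before the raw
#' activation onset).
#'
#' @param signal_trace a [sampled_trace()] (typically band-passed EMG).
#' @param window RMS window length in seconds (default 0.05).
#' @return RMS [sampled_trace()].
#' @export
moving_rms <- function(signal_trace, window = 0.05) {
  stopifnot(inherits(signal_trace, "sampled_trace"))
  n_w <- round(window * signal_trace$rate)
  if (n_w < 2L)
    stop("invalid-config: RMS window must span at least 2 sample periods",
         call. = FALSE)
  x2 <- signal_trace$values^2
  n <- length(x2)
  half_lo <- floor((n_w - 1L) / 2)  # samples before the center
  half_hi <- n_w - 1L - half_lo     # samples after the center
  cs <- cumsum(c(0, x2))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  out <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  sampled_trace(out, rate = signal_trace$rate, t0 = signal_trace$t0,
                unit = signal_trace$unit)
}

# Amplitude gain of the zero-phase band-pass for white noise: the fraction
# of a white input's standard deviation that survives forward-backward
# filtering. Used to convert a generated (raw) noise-floor SD into the
# post-filter floor the analysis chain actually sees.
bandpass_noise_gain <- function(rate, low = 10, high = 500, order = 2) {
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  f <- seq(0, rate / 2, length.out = 2048)
  h <- signal::freqz(bf, w = 2 * pi * f / rate)
  sqrt(mean(Mod(h$h)^4))  # filtfilt applies the filter twice
}

#' Rate of EMG rise (0-75 ms OLS slope of the RMS envelope)
#'
#' Ordinary least-squares slope of the RMS-EMG-time curve over the window
#' starting at the activation onset (about 154 samples at 2048 Hz for the
#' default 75-ms window).
#'
#' @param rms RMS-EMG [sampled_trace()] in mV.
#' @param onset activation onset in seconds (absolute).
#' @param window slope window in seconds (default 0.075).
#' @return slope in mV·s^-1.
#' @export
compute_rer <- function(rms, onset, window = 0.075) {
  stopifnot(inherits(rms, "sampled_trace"))
  w <- trace_window(rms, onset, onset + window)
  if (length(w$values) < 3L)
    stop("insufficient-samples: fewer than 3 samples in the RER window",
         call. = FALSE)
  ols_slope(w$time, w$values)
}

#' Mean and peak RMS-EMG over the contraction window
#'
#' @param rms RMS-EMG [sampled_trace()].
#' @param onset window start (seconds, absolute).
#' @param end window end (seconds, absolute); conventionally the end of the
#'   torque isokinetic phase.
#' @return list with `emg_mean` (mV), `emg_peak` (mV) and `time_to_peak`
#'   (seconds relative to onset).
#' @export
compute_emg_mean_peak <- function(rms, onset, end) {
  stopifnot(inherits(rms, "sampled_trace"))
  if (end <= onset)
    stop("insufficient-samples: empty window (end <= onset)", call. = FALSE)
  w <- trace_window(rms, onset, end)
  if (length(w$values) < 1L)
    stop("insufficient-samples: no samples in [onset, end]", call. = FALSE)
  i <- which.max(w$values)
  list(emg_mean = mean(w$values), emg_peak = w$values[i],
       time_to_peak = w$time[i] - onset)
}

#' M-wave peak-to-peak amplitude
#'
#' Voltage difference between the two extreme points of the compound muscle
#' action potential evoked by supramaximal nerve stimulation.
#'
#' @param mwave EMG [sampled_trace()] containing the full M-wave.
#' @return amplitude in mV.
#' @export
mwave_p2p <- function(mwave) {
  stopifnot(inherits(mwave, "sampled_trace"))
  if (length(mwave$values) < 3L)
    stop("insufficient-samples: M-wave trace shorter than 3 samples",
         call. = FALSE)
  max(mwave$values) - min(mwave$values)
}

#' Normalize EMG amplitude metrics
#'
#' Two normalisation schemes are produced from a per-contraction EMG metric
#' table:
#' * M-max normalisation: per-subject averages of the first and last
#'   `n_edge` contractions divided by the pre- and post-fatigue M-wave
#'   amplitude respectively (`nEMG_mean`, `nEMG_peak`, `nRER`).
#' * Protocol-max normalisation: every per-contraction value expressed as a
#'   percentage of that subject's maximum over the whole protocol.
#'
#' @param metrics data.frame with columns `subject`, `set`, `rep`,
#'   `emg_mean`, `emg_peak`, `rer`.
#' @param mmax_pre,mmax_post M-wave peak-to-peak amplitudes in mV, either
#'   scalars or vectors named by subject.
#' @param n_edge number of contractions averaged at each end (default 8).
#' @return list with `mmax_normalized` (one row per subject x phase) and
#'   `pct_of_protocol_max` (per-contraction percentages).
#' @export
normalize_emg_metrics <- function(metrics, mmax_pre, mmax_post, n_edge = 8L) {
  need <- c("subject", "set", "rep", "emg_mean", "emg_peak", "rer")
  if (!all(need %in% names(metrics)))
    stop("invalid-input: metrics must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(c(mmax_pre, mmax_post))) || any(c(mmax_pre, mmax_post) <= 0))
    stop("invalid-input: M-max normalizers must be > 0", call. = FALSE)
  subjects <- sort(unique(metrics$subject))
  pick <- function(mm, s) {
    if (length(mm) == 1L && is.null(names(mm))) mm else {
      if (!s %in% names(mm))
        stop("invalid-input: no M-max value for subject ", s, call. = FALSE)
      unname(mm[[s]])
    }
  }
  vars <- c("emg_mean", "emg_peak", "rer")
  rows <- list()
  for (s in subjects) {
    ms <- metrics[metrics$subject == s, , drop = FALSE]
    ms <- ms[order(ms$set, ms$rep), , drop = FALSE]
    n <- nrow(ms)
    if (n < n_edge)
      stop("invalid-input: fewer than n_edge contractions for subject ", s,
           call. = FALSE)
    first <- ms[seq_len(n_edge), vars, drop = FALSE]
    last <- ms[seq.int(n - n_edge + 1L, n), vars, drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, phase = "pre",
      n_emg_mean = mean(first$emg_mean) / pick(mmax_pre, s),
      n_emg_peak = mean(first$emg_peak) / pick(mmax_pre, s),
      n_rer = mean(first$rer) / pick(mmax_pre, s),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, phase = "post",
      n_emg_mean = mean(last$emg_mean) / pick(mmax_post, s),
      n_emg_peak = mean(last$emg_peak) / pick(mmax_post, s),
      n_rer = mean(last$rer) / pick(mmax_post, s),
      stringsAsFactors = FALSE)
  }
  pct <- metrics
  for (v in vars) {
    mx <- stats::ave(metrics[[v]], metrics$subject, FUN = max)
    if (any(mx <= 0))
      stop("invalid-input: non-positive protocol maximum", call. = FALSE)
    pct[[paste0("pct_", v)]] <- 100 * metrics[[v]] / mx
  }
  list(mmax_normalized = do.call(rbind, rows),
       pct_of_protocol_max = pct)
}
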