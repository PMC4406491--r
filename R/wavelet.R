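#' Polynomially spaced wavelet bank
#'
#' Center frequencies follow `F_aj = (1/scale) * (j + q)^r` for
#' `j = 0 .. n-1`. With the default parameters (`scale = 0.3`, `q = 1.45`,
#' `r = 1.959`, `n = 11`) the bank spans about 6.90 to 395.4 Hz, covering
#' the 10-500 Hz surface-EMG pass band with spacing that widens toward the
#' high frequencies.
#'
#' @param scale,q,r positive spacing parameters.
#' @param n number of wavelets (>= 2).
#' @param omega0 non-dimensional Morlet carrier frequency (default 6).
#' @return object of class `wavelet_bank` with element `center_freqs` (Hz).
#' @examples
#' wavelet_bank()$center_freqs
#' @export
wavelet_bank <- function(scale = 0.3, q = 1.45, r = 1.959, n = 11, omega0 = 6) {
  if (any(!is.finite(c(scale, q, r))) || scale <= 0 || q <= 0 || r <= 0)
    stop("invalid-config: scale, q and r must be positive", call. = FALSE)
  if (n < 2L) stop("invalid-config: need at least 2 wavelets", call. = FALSE)
  f <- (1 / scale) * (seq_len(n) - 1 + q)^r
  structure(list(scale = scale, q = q, r = r, n_wavelets = as.integer(n),
                 omega0 = omega0, center_freqs = f),
            class = "wavelet_bank")
}

#' @export
print.wavelet_bank <- function(x, ...) {
  cat(sprintf("<wavelet_bank> %d Morlet wavelets (omega0 = %g), centers %s Hz\n",
              x$n_wavelets, x$omega0,
              paste(sprintf("%.1f", x$center_freqs), collapse = ", ")))
  invisible(x)
}

# Morlet scale whose Fourier-equivalent frequency is f (Hz):
# lambda = 4 pi s / (omega0 + sqrt(2 + omega0^2)) and lambda = 1/f.
morlet_scale <- function(f, omega0) (omega0 + sqrt(2 + omega0^2)) / (4 * pi * f)

#' Continuous Morlet wavelet transform over a frequency bank
#'
#' Frequency-domain CWT: the signal is zero-padded to the next power of
#' two, Fourier transformed, multiplied by the conjugate Fourier transform
#' of a unit-energy Morlet daughter wavelet at each bank scale, and inverse
#' transformed. Each wavelet's scale is chosen so that its
#' Fourier-equivalent frequency equals the bank center frequency. The
#' result carries a cone-of-influence vector (`coi`, in Hz): coefficients
#' at times where `coi < center_freq` are edge-contaminated.
#'
#' @param signal_trace a [sampled_trace()] (raw EMG by convention).
#' @param bank a [wavelet_bank()].
#' @return object of class `morlet_cwt`: list with complex matrix `coef`
#'   (`n_wavelets` x `n_samples`), the `bank`, sampling `rate`, `t0` and
#'   `coi`.
#' @export
cwt_morlet <- function(signal_trace, bank) {
  stopifnot(inherits(signal_trace, "sampled_trace"), inherits(bank, "wavelet_bank"))
  if (signal_trace$rate <= 2 * max(bank$center_freqs))
    stop("nyquist-violation: sampling rate must exceed twice the highest center frequency",
         call. = FALSE)
  x <- signal_trace$values
  n <- length(x)
  dt <- 1 / signal_trace$rate
  n_pad <- 2^ceiling(log2(n))
  xh <- stats::fft(c(x, rep(0, n_pad - n)))
  # angular frequencies of the padded FFT bins
  k <- seq_len(n_pad) - 1L
  omega <- ifelse(k <= n_pad / 2, k, k - n_pad) * (2 * pi / (n_pad * dt))
  scales <- morlet_scale(bank$center_freqs, bank$omega0)
  coef <- matrix(0 + 0i, nrow = bank$n_wavelets, ncol = n)
  for (j in seq_len(bank$n_wavelets)) {
    s <- scales[j]
    psi_hat <- sqrt(2 * pi * s / dt) * pi^(-1/4) *
      exp(-((s * omega - bank$omega0)^2) / 2) * (omega > 0)
    w <- stats::fft(xh * psi_hat, inverse = TRUE) / n_pad
    coef[j, ] <- w[seq_len(n)]
  }
  # cone of influence: e-folding time sqrt(2)*s mapped to a frequency bound
  tt <- (seq_len(n) - 1L) * dt
  edge <- pmin(tt, (n - 1L) * dt - tt)
  fourier_factor <- 4 * pi / (bank$omega0 + sqrt(2 + bank$omega0^2))
  coi <- 1 / (fourier_factor * edge / sqrt(2))
  coi[!is.finite(coi)] <- Inf
  structure(list(coef = coef, bank = bank, rate = signal_trace$rate,
                 t0 = signal_trace$t0, coi = coi),
            class = "morlet_cwt")
}

#' Per-wavelet intensity (instantaneous power)
#'
#' Squared modulus of the wavelet coefficients: the power of the signal
#' within each wavelet's center frequency, per time sample.
#'
#' @param cwt a [cwt_morlet()] result.
#' @return numeric matrix (`n_wavelets` x `n_samples`), non-negative.
#' @export
wavelet_intensity <- function(cwt) {
  stopifnot(inherits(cwt, "morlet_cwt"))
  Mod(cwt$coef)^2
}

#' Instantaneous mean frequency
#'
#' Intensity-weighted average of the bank center frequencies at each time
#' instant: `if_mean(t) = sum_j F_aj p_j(t) / sum_j p_j(t)`. Time points
#' with (numerically) zero total intensity are returned as `NA` rather than
#' raising an error. Wherever defined, the value is a convex combination of
#' the bank's center frequencies and therefore lies between its extremes.
#'
#' @param intensity matrix from [wavelet_intensity()].
#' @param bank the [wavelet_bank()] that produced it.
#' @return numeric vector of frequencies in Hz (with `NA` at empty frames).
#' @export
instantaneous_mean_freq <- function(intensity, bank) {
  stopifnot(inherits(bank, "wavelet_bank"))
  if (nrow(intensity) != bank$n_wavelets)
    stop("invalid-input: intensity rows must match the bank size", call. = FALSE)
  if (any(intensity < 0))
    stop("invalid-input: intensities must be non-negative", call. = FALSE)
  tot <- colSums(intensity)
  num <- colSums(intensity * bank$center_freqs)
  out <- ifelse(tot > 0, num / tot, NA_real_)
  out
}

#' Bin the instantaneous mean frequency over contraction intervals
#'
#' Arithmetic mean of the non-missing `if_mean` samples within each
#' half-open interval `[onset + k*bin, onset + (k+1)*bin)` for
#' `k = 0 .. n_bins-1` (default: the 0-75, 75-150, 150-225, 225-300 and
#' 300-375 ms intervals of a contraction). When a `morlet_cwt` object is
#' supplied through `cwt`, samples inside the cone of influence of a given
#' wavelet row are excluded from that row's intensity before the centroid
#' is formed upstream; here `coi_freqs` simply masks whole time points whose
#' cone bound falls below `min(center_freqs)` (edge artifacts would
#' otherwise dominate bins near the trace edges).
#'
#' @param if_mean_series numeric vector of if_mean values (Hz, may contain
#'   `NA`) sampled at `rate`.
#' @param rate sampling rate of the series in Hz.
#' @param onset bin origin in seconds (absolute, on the same axis as `t0`).
#' @param t0 time of the first series sample (default 0).
#' @param bin bin width in seconds (default 0.075).
#' @param n_bins number of bins (default 5).
#' @param coi_mask optional logical vector (same length as the series):
#'   `TRUE` marks samples to exclude (e.g. inside the cone of influence).
#' @return data.frame with `bin_label`, `t_start`, `t_end`, `mean_hz`, `n`.
#' @export
bin_if_mean <- function(if_mean_series, rate, onset, t0 = 0, bin = 0.075,
                        n_bins = 5, coi_mask = NULL) {
  tt <- t0 + (seq_along(if_mean_series) - 1L) / rate
  y <- if_mean_series
  if (!is.null(coi_mask)) y[coi_mask] <- NA_real_
  out <- data.frame(
    bin_label = character(n_bins), t_start = numeric(n_bins),
    t_end = numeric(n_bins), mean_hz = numeric(n_bins), n = integer(n_bins),
    stringsAsFactors = FALSE)
  eps <- 1 / (2 * rate) * 1e-6
  for (k in seq_len(n_bins)) {
    lo <- onset + (k - 1L) * bin
    hi <- onset + k * bin
    sel <- tt >= lo - eps & tt < hi - eps
    vals <- y[sel]
    vals <- vals[is.finite(vals)]
    out$bin_label[k] <- sprintf("%d-%d ms", round((k - 1L) * bin * 1000),
                                round(k * bin * 1000))
    out$t_start[k] <- lo; out$t_end[k] <- hi
    out$mean_hz[k] <- if (length(vals)) mean(vals) else NA_real_
    out$n[k] <- length(vals)
  }
  out
}

#' Cone-of-influence mask for a transform
#'
#' Logical vector marking time samples whose cone-of-influence frequency
#' bound exceeds a reference frequency (i.e. the wavelet at that frequency
#' is edge-contaminated there).
#'
#' @param cwt a [cwt_morlet()] result.
#' @param freq reference frequency in Hz (default: lowest bank center).
#' @return logical vector, `TRUE` where contaminated.
#' @export
coi_mask <- function(cwt, freq = min(cwt$bank$center_freqs)) {
  stopifnot(inherits(cwt, "morlet_cwt"))
  cwt$coi > freq  # coi is a lower period bound expressed as frequency
}
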