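#' Uniformly sampled physical signal
#'
#' The carrier for every signal handled by the package: torque (N·m) and
#' angular velocity (deg/s) at the dynamometer rate, raw and RMS-enveloped
#' surface EMG (mV) at the amplifier rate. A `sampled_trace` is a numeric
#' vector plus a sampling rate and the time of its first sample.
#'
#' @param values numeric vector of samples; must be finite, length >= 2.
#' @param rate sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds (default 0).
#' @param unit free-text unit label (e.g. `"N.m"`, `"mV"`), used in printing.
#' @return an object of class `sampled_trace`.
#' @examples
#' tr <- sampled_trace(sin(2 * pi * 5 * seq(0, 1, by = 0.01)), rate = 100)
#' trace_time(tr)[1:5]
#' @export
sampled_trace <- function(values, rate, t0 = 0, unit = "") {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("invalid-config: `rate` must be a single positive number", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("invalid-config: a sampled_trace needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("invalid-config: trace values must all be finite", call. = FALSE)
  structure(
    list(values = values, rate = as.numeric(rate), t0 = as.numeric(t0),
         unit = as.character(unit)),
    class = "sampled_trace"
  )
}

#' @export
print.sampled_trace <- function(x, ...) {
  dur <- (length(x$values) - 1L) / x$rate
  cat(sprintf("<sampled_trace> %d samples @ %g Hz, t = [%g, %g] s%s\n",
              length(x$values), x$rate, x$t0, x$t0 + dur,
              if (nzchar(x$unit)) paste0(", unit = ", x$unit) else ""))
  invisible(x)
}

#' @export
length.sampled_trace <- function(x) length(x$values)

#' Time axis of a trace
#'
#' @param trace a [sampled_trace()].
#' @return numeric vector of sample times in seconds.
#' @export
trace_time <- function(trace) {
  stopifnot(inherits(trace, "sampled_trace"))
  trace$t0 + (seq_along(trace$values) - 1L) / trace$rate
}

#' Extract the samples of a trace falling in a time window
#'
#' Both bounds are inclusive; comparisons use a half-sample-period numeric
#' guard so that windows whose bounds coincide with sample times are closed
#' under floating-point round-off.
#'
#' @param trace a [sampled_trace()].
#' @param from,to window bounds in seconds.
#' @return list with `values`, `time`, and integer `index`.
#' @keywords internal
trace_window <- function(trace, from, to) {
  tt <- trace_time(trace)
  eps <- 1 / (2 * trace$rate) * 1e-6
  idx <- which(tt >= from - eps & tt <= to + eps)
  list(values = trace$values[idx], time = tt[idx], index = idx)
}

# Ordinary least-squares slope of y against t. Used for every "average
# slope over a window" metric in the package.
ols_slope <- function(t, y) {
  if (length(t) < 2L) stop("insufficient-samples: need >= 2 points for a slope",
                           call. = FALSE)
  tc <- t - mean(t)
  sum(tc * y) / sum(tc^2)
}
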