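#' Detect contraction (or activation) onset in a baseline-referenced trace
#'
#' The detector finds where the signal leaves its pre-contraction baseline
#' for good. Candidate crossings are runs of at least `min_hold` seconds
#' whose samples all exceed `baseline mean + k_sd * baseline SD`; among
#' them, the run containing the global signal maximum (the contraction
#' burst itself) is selected, so that isolated baseline noise bumps that
#' happen to clear the threshold cannot be mistaken for the onset. From the
#' start of that run the search walks backwards to the last sample within
#' one baseline SD of the baseline mean, and the onset is reported at that
#' sample. The walk-back makes the detector exact on noise-free traces
#' (where the true onset sample still equals the baseline, and the SD is
#' zero) and removes most of the late bias that a raw threshold crossing
#' carries when the threshold sits well above the noise floor.
#'
#' The same contract serves torque traces and RMS-EMG envelopes
#' (`detect_emg_onset()` is an alias with EMG defaults).
#'
#' @param trace a [sampled_trace()] beginning with pre-contraction baseline.
#' @param baseline_window length of the initial baseline segment in seconds.
#' @param k_sd threshold in baseline standard deviations (default 3).
#' @param min_hold time the signal must stay above threshold, seconds.
#' @param max_lookback bound on the walk-back distance in seconds (default
#'   unbounded). For smoothed envelopes the onset cannot physically precede
#'   the threshold crossing by more than the smoothing half-window, so a
#'   bound of that order stops the walk-back from drifting along elevated
#'   noise shelves.
#' @return onset time in seconds (absolute, on the trace's time axis).
#' @export
detect_onset <- function(trace, baseline_window, k_sd = 3, min_hold = 0.03,
                         max_lookback = Inf) {
  stopifnot(inherits(trace, "sampled_trace"))
  n_base <- floor(baseline_window * trace$rate)
  if (n_base < 2L)
    stop("invalid-config: baseline_window shorter than 2 samples", call. = FALSE)
  if (n_base >= length(trace$values))
    stop("invalid-config: baseline_window covers the whole trace", call. = FALSE)
  base <- trace$values[seq_len(n_base)]
  mu <- mean(base)
  thr <- mu + k_sd * stats::sd(base)
  hold <- max(1L, ceiling(min_hold * trace$rate))
  above <- trace$values > thr
  above[seq_len(n_base)] <- FALSE
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- runs$values & runs$lengths >= hold
  if (!any(ok))
    stop("onset-not-found: signal never exceeds baseline + k_sd*SD for min_hold",
         call. = FALSE)
  i_max <- n_base + which.max(trace$values[-seq_len(n_base)])
  in_run <- which(ok & starts <= i_max & ends >= i_max)
  cross <- if (length(in_run)) starts[in_run[1L]] else starts[which(ok)[1L]]
  back_level <- mu + stats::sd(base)
  k_floor <- if (is.finite(max_lookback))
    max(1L, cross - as.integer(floor(max_lookback * trace$rate))) else 1L
  k <- cross
  while (k > k_floor && trace$values[k] > back_level) k <- k - 1L
  if (trace$values[k] > back_level) {
    # no baseline-level sample inside the look-back range (an elevated
    # noise shelf): anchor at the most baseline-like sample instead
    k <- k_floor - 1L + which.min(trace$values[k_floor:cross])
  }
  trace$t0 + (k - 1L) / trace$rate
}

#' @rdname detect_onset
#' @export
detect_emg_onset <- function(trace, baseline_window, k_sd = 3,
                             min_hold = 0.02, max_lookback = 0.03) {
  detect_onset(trace, baseline_window, k_sd = k_sd, min_hold = min_hold,
               max_lookback = max_lookback)
}

#' Rate of torque development (0-75 ms OLS slope)
#'
#' The average slope of the torque-time curve over the window starting at
#' the contraction onset, realised as the ordinary least-squares slope over
#' every sample with `onset <= t <= onset + window`. At a 100-Hz torque rate
#' and the default 75-ms window this is an 8-point fit; on exactly linear
#' data it equals the endpoint-difference slope.
#'
#' @param trace torque [sampled_trace()] in N·m.
#' @param onset contraction onset in seconds (absolute time).
#' @param window slope window length in seconds (default 0.075).
#' @return slope in N·m·s^-1.
#' @export
compute_rtd <- function(trace, onset, window = 0.075) {
  stopifnot(inherits(trace, "sampled_trace"))
  w <- trace_window(trace, onset, onset + window)
  if (length(w$values) < 3L)
    stop("insufficient-samples: fewer than 3 samples in the RTD window",
         call. = FALSE)
  ols_slope(w$time, w$values)
}

#' Peak and mean torque over the contraction window
#'
#' @param trace torque [sampled_trace()].
#' @param onset window start (seconds, absolute).
#' @param end window end (seconds, absolute); typically the end of the
#'   isokinetic phase from [isokinetic_end()].
#' @return list with `t_peak` (max, N·m), `t_mean` (arithmetic mean, N·m)
#'   and `time_to_peak` (seconds relative to onset).
#' @export
compute_tpeak_tmean <- function(trace, onset, end) {
  stopifnot(inherits(trace, "sampled_trace"))
  if (end <= onset)
    stop("insufficient-samples: empty window (end <= onset)", call. = FALSE)
  w <- trace_window(trace, onset, end)
  if (length(w$values) < 1L)
    stop("insufficient-samples: no samples in [onset, end]", call. = FALSE)
  i <- which.max(w$values)
  list(t_peak = w$values[i], t_mean = mean(w$values),
       time_to_peak = w$time[i] - onset)
}

#' Time to reach the target angular velocity
#'
#' First time at or after `onset` where the velocity reaches `target`, with
#' linear interpolation between the bracketing samples, reported relative to
#' the onset.
#'
#' @param velocity angular-velocity [sampled_trace()] in deg/s.
#' @param target target velocity in deg/s (default 240).
#' @param onset movement onset in seconds (absolute).
#' @return time in seconds.
#' @export
time_to_target_velocity <- function(velocity, target = 240, onset = 0) {
  stopifnot(inherits(velocity, "sampled_trace"))
  tt <- trace_time(velocity)
  v <- velocity$values
  cand <- which(tt >= onset - 1e-12 & v >= target)
  if (length(cand) == 0L)
    stop("target-not-reached: velocity never reaches the target", call. = FALSE)
  k <- cand[1L]
  if (v[k] == target || k == 1L || tt[k - 1L] < onset - 1e-12)
    return(tt[k] - onset)
  # interpolate between the last sub-target sample and the crossing sample
  t_cross <- tt[k - 1L] + (target - v[k - 1L]) / (v[k] - v[k - 1L]) / velocity$rate
  t_cross - onset
}

#' End of the isokinetic phase
#'
#' Last sample time, at or after the first attainment of the target
#' velocity, whose velocity is still at least `(1 - tol) * target`. Used as
#' the analysis-window end for `T_mean`/`T_peak` and the EMG amplitude
#' metrics. The tolerance absorbs servo ripple around the set velocity.
#'
#' @inheritParams time_to_target_velocity
#' @param tol relative tolerance below target still counted as isokinetic.
#' @return time in seconds (absolute).
#' @export
isokinetic_end <- function(velocity, target = 240, onset = 0, tol = 0.05) {
  stopifnot(inherits(velocity, "sampled_trace"))
  tt <- trace_time(velocity)
  v <- velocity$values
  reach <- which(tt >= onset - 1e-12 & v >= target * (1 - tol))
  if (length(reach) == 0L)
    stop("target-not-reached: velocity never reaches the target band", call. = FALSE)
  first <- reach[1L]
  below <- which(tt > tt[first] & v < target * (1 - tol))
  if (length(below) == 0L) return(tt[length(tt)])
  tt[below[1L] - 1L]
}

#' Isometric maximal voluntary contraction torque
#'
#' Maximal torque over the 500-ms period immediately preceding the
#' superimposed stimulation.
#'
#' @param trace torque [sampled_trace()] of the IMVC trial.
#' @param stim_time stimulation time in seconds (absolute).
#' @param window look-back window in seconds (default 0.5).
#' @return IMVC torque in N·m.
#' @export
compute_imvc <- function(trace, stim_time, window = 0.5) {
  stopifnot(inherits(trace, "sampled_trace"))
  if (stim_time - window < trace$t0 - 1e-12)
    stop("insufficient-samples: pre-stimulus window extends before trace start",
         call. = FALSE)
  w <- trace_window(trace, stim_time - window, stim_time)
  max(w$values)
}

#' Superimposed twitch amplitude
#'
#' Peak torque increment evoked by a stimulation delivered on the voluntary
#' plateau: the maximum over the post-stimulus search window minus the
#' torque level at the stimulation instant (linearly interpolated).
#'
#' @param trace torque [sampled_trace()] of the IMVC trial.
#' @param stim_time stimulation time in seconds (absolute).
#' @param search post-stimulus search window in seconds (default 0.25).
#' @return twitch amplitude in N·m (can be ~0 when activation is complete).
#' @export
superimposed_twitch <- function(trace, stim_time, search = 0.25) {
  stopifnot(inherits(trace, "sampled_trace"))
  tt <- trace_time(trace)
  at_stim <- stats::approx(tt, trace$values, xout = stim_time, rule = 2)$y
  w <- trace_window(trace, stim_time, stim_time + search)
  if (length(w$values) < 2L)
    stop("insufficient-samples: no post-stimulus samples", call. = FALSE)
  max(w$values) - at_stim
}

#' Voluntary activation by twitch interpolation
#'
#' `VA = (1 - superimposed / resting) * 100`, clipped to `[0, 100]` with a
#' warning when clipping occurred (measurement noise can drive the
#' superimposed twitch slightly negative).
#'
#' @param superimposed_twitch superimposed evoked twitch amplitude, N·m (>= 0
#'   up to noise).
#' @param potentiated_resting_twitch potentiated resting twitch amplitude,
#'   N·m (> 0).
#' @return voluntary activation in percent.
#' @examples
#' voluntary_activation(5, 100)   # 95
#' @export
voluntary_activation <- function(superimposed_twitch, potentiated_resting_twitch) {
  if (!is.finite(potentiated_resting_twitch) || potentiated_resting_twitch <= 0)
    stop("invalid-input: potentiated resting twitch must be > 0", call. = FALSE)
  va <- (1 - superimposed_twitch / potentiated_resting_twitch) * 100
  if (va < 0 || va > 100) {
    warning("voluntary activation clipped to [0, 100]", call. = FALSE)
    va <- min(100, max(0, va))
  }
  va
}

#' Evoked twitch metrics from a stimulation response
#'
#' The response trace is expected to start at the stimulation artifact.
#' A baseline (mean of the first `baseline` seconds, or 0 when `baseline`
#' is 0) is subtracted; the evoked peak torque is the maximum of the
#' corrected response, and the evoked rate of torque development is the
#' maximum of its first derivative computed by central differences.
#'
#' @param response evoked torque [sampled_trace()].
#' @param baseline seconds of pre-response baseline to subtract (default 0:
#'   the response is already baseline-corrected).
#' @return list with `e_tpeak` (N·m) and `e_rtd` (N·m·s^-1).
#' @export
evoked_metrics <- function(response, baseline = 0) {
  stopifnot(inherits(response, "sampled_trace"))
  y <- response$values
  if (baseline > 0) {
    nb <- max(1L, floor(baseline * response$rate))
    y <- y - mean(y[seq_len(nb)])
  }
  if (max(y) <= 0)
    stop("invalid-response: evoked response has non-positive peak", call. = FALSE)
  n <- length(y)
  if (n < 3L)
    stop("insufficient-samples: response shorter than 3 samples", call. = FALSE)
  dt <- 1 / response$rate
  deriv <- (y[3:n] - y[1:(n - 2L)]) / (2 * dt)
  list(e_tpeak = max(y), e_rtd = max(deriv))
}

#' Low- to high-frequency doublet torque ratio
#'
#' Ratio of the 10-Hz doublet peak torque to the 100-Hz doublet peak torque;
#' a selective fall of the ratio indicates low-frequency
#' (excitation-contraction coupling) fatigue.
#'
#' @param db10_peak peak torque of the 10-Hz doublet, N·m (> 0).
#' @param db100_peak peak torque of the 100-Hz doublet, N·m (> 0).
#' @return dimensionless ratio.
#' @export
db_ratio <- function(db10_peak, db100_peak) {
  if (!is.finite(db10_peak) || db10_peak <= 0 ||
      !is.finite(db100_peak) || db100_peak <= 0)
    stop("invalid-input: doublet peaks must be > 0", call. = FALSE)
  db10_peak / db100_peak
}
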