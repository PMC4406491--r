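#' Extract torque metrics from every contraction of a protocol
#'
#' Runs, per contraction record: torque-onset detection, 0-75 ms OLS slope
#' (RTD), peak/mean torque over the isokinetic phase, time to the target
#' angular velocity and time to peak torque.
#'
#' @param proto an `iso_protocol` from [generate_protocol()] or
#'   [read_protocol()].
#' @param baseline_window onset-detection baseline length in seconds.
#' @param k_sd onset threshold in baseline SDs.
#' @param min_hold sustained-crossing hold time in seconds.
#' @param onset_channel channel used to detect the contraction onset:
#'   `"velocity"` (default; the movement onset of the servo-controlled
#'   lever, which marks the contraction start sharply for every subject)
#'   or `"torque"` (threshold detection on the torque trace itself, which
#'   is ambiguous for contractions with a flat early rise).
#' @return data.frame with one row per contraction: `subject`, `set`,
#'   `rep`, `onset_s`, `rtd`, `t_peak`, `t_mean`, `t2v_s`, `t2p_s`.
#' @export
torque_metrics_table <- function(proto, baseline_window = 0.4, k_sd = 3,
                                 min_hold = 0.03,
                                 onset_channel = c("velocity", "torque")) {
  onset_channel <- match.arg(onset_channel)
  target <- proto$config$target_velocity
  tol <- proto$config$timing$iso_tol
  rows <- lapply(proto$contractions, function(rec) {
    onset <- detect_onset(
      if (onset_channel == "velocity") rec$velocity else rec$torque,
      baseline_window, k_sd, min_hold)
    end <- isokinetic_end(rec$velocity, target, onset, tol)
    pm <- compute_tpeak_tmean(rec$torque, onset, end)
    data.frame(subject = rec$subject, set = rec$set, rep = rec$rep,
               onset_s = onset,
               rtd = compute_rtd(rec$torque, onset),
               t_peak = pm$t_peak, t_mean = pm$t_mean,
               t2v_s = time_to_target_velocity(rec$velocity, target, onset),
               t2p_s = pm$time_to_peak, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract EMG amplitude metrics from every contraction with EMG
#'
#' Chain per record: 10-500 Hz zero-phase band-pass, 50-ms moving RMS,
#' activation-onset detection on the RMS envelope, 0-75 ms OLS slope (RER)
#' and mean/peak RMS over the contraction window (whose end is tied to the
#' torque isokinetic phase).
#'
#' @inheritParams torque_metrics_table
#' @param min_hold sustained-crossing hold time for the EMG onset, seconds.
#' @return data.frame with one row per EMG-bearing contraction: `subject`,
#'   `set`, `rep`, `onset_s`, `rer`, `emg_peak`, `emg_mean`, `t2p_s`.
#' @export
emg_metrics_table <- function(proto, baseline_window = 0.4, k_sd = 3,
                              min_hold = 0.02) {
  target <- proto$config$target_velocity
  tol <- proto$config$timing$iso_tol
  rows <- lapply(proto$contractions, function(rec) {
    if (is.null(rec$emg)) return(NULL)
    filt <- emg_bandpass(rec$emg)
    rms <- moving_rms(filt)
    onset <- detect_emg_onset(rms, baseline_window, k_sd, min_hold)
    t_end <- isokinetic_end(rec$velocity, target,
                            detect_onset(rec$velocity, baseline_window), tol)
    mp <- compute_emg_mean_peak(rms, onset, t_end)
    data.frame(subject = rec$subject, set = rec$set, rep = rec$rep,
               onset_s = onset, rer = compute_rer(rms, onset),
               emg_peak = mp$emg_peak, emg_mean = mp$emg_mean,
               t2p_s = mp$time_to_peak, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no-input: the protocol contains no EMG traces", call. = FALSE)
  out
}

#' Extract neuromuscular-test metrics (pre and post)
#'
#' Per subject and phase: IMVC (500-ms pre-stimulus maximum), superimposed
#' twitch, voluntary activation (against the potentiated resting 100-Hz
#' doublet), evoked peak torque and evoked RTD from the 100-Hz doublet,
#' 10-Hz doublet peak, their ratio, and the M-wave peak-to-peak amplitude.
#'
#' @param proto an `iso_protocol` with neuromuscular tests.
#' @return data.frame with one row per subject x phase.
#' @export
nm_metrics_table <- function(proto) {
  if (!length(proto$nm))
    stop("no-input: the protocol contains no neuromuscular tests", call. = FALSE)
  rows <- list()
  for (subj in names(proto$nm)) {
    for (phase in names(proto$nm[[subj]])) {
      nm <- proto$nm[[subj]][[phase]]
      crop <- function(rec) {
        tr <- rec$trace
        vals <- tr$values
        nb <- max(1L, round(rec$stim_time * tr$rate))
        corrected <- vals - mean(vals[seq_len(nb)])
        i0 <- nb + 1L
        sampled_trace(corrected[i0:length(corrected)], rate = tr$rate, t0 = 0,
                      unit = tr$unit)
      }
      # evoked metrics are averaged over the (up to three) stimulations
      tests100 <- nm[grepl("^db100", names(nm))]
      tests10 <- nm[grepl("^db10_|^db10$", names(nm))]
      ev100 <- lapply(tests100, function(x) evoked_metrics(crop(x)))
      ev10 <- lapply(tests10, function(x) evoked_metrics(crop(x)))
      e_tpeak <- mean(vapply(ev100, `[[`, numeric(1), "e_tpeak"))
      e_rtd <- mean(vapply(ev100, `[[`, numeric(1), "e_rtd"))
      db10 <- mean(vapply(ev10, `[[`, numeric(1), "e_tpeak"))
      ratios <- mapply(function(a, b) db_ratio(a$e_tpeak, b$e_tpeak),
                       ev10, ev100)
      imvc <- compute_imvc(nm$imvc$trace, nm$imvc$stim_time)
      sup <- superimposed_twitch(nm$imvc$trace, nm$imvc$stim_time)
      va <- suppressWarnings(voluntary_activation(max(0, sup), e_tpeak))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, phase = phase, imvc = imvc, sup_twitch = sup,
        va = va, e_tpeak = e_tpeak, e_rtd = e_rtd,
        db10 = db10, db_ratio = mean(ratios),
        m_max = mwave_p2p(nm$mwave), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Instantaneous-mean-frequency bins for selected sets
#'
#' For every EMG-bearing contraction of the selected sets: Morlet CWT of
#' the raw EMG over the wavelet bank, per-wavelet intensity, instantaneous
#' mean frequency, and 75-ms bin means over the contraction (cone-of-
#' influence samples excluded).
#'
#' @param proto an `iso_protocol`.
#' @param sets integer vector of sets to analyse (default: first and last).
#' @param bank a [wavelet_bank()] (default: the standard 11-wavelet bank).
#' @param baseline_window,k_sd,min_hold EMG onset-detection settings.
#' @param exclude_coi drop samples inside the cone of influence (TRUE).
#' @return data.frame: `subject`, `set`, `rep`, `bin_label`, `mean_hz`.
#' @export
ifmean_bins_table <- function(proto, sets = NULL, bank = wavelet_bank(),
                              baseline_window = 0.4, k_sd = 3,
                              min_hold = 0.02, exclude_coi = TRUE) {
  if (is.null(sets)) sets <- unique(c(1L, proto$config$n_sets))
  rows <- list()
  for (rec in proto$contractions) {
    if (is.null(rec$emg) || !(rec$set %in% sets)) next
    rms <- moving_rms(emg_bandpass(rec$emg))
    onset <- detect_emg_onset(rms, baseline_window, k_sd, min_hold)
    cw <- cwt_morlet(rec$emg, bank)
    ifm <- instantaneous_mean_freq(wavelet_intensity(cw), bank)
    mask <- if (exclude_coi) coi_mask(cw) else NULL
    bins <- bin_if_mean(ifm, rate = rec$emg$rate, onset = onset,
                        t0 = rec$emg$t0, coi_mask = mask)
    bins$subject <- rec$subject; bins$set <- rec$set; bins$rep <- rec$rep
    rows[[length(rows) + 1L]] <- bins[, c("subject", "set", "rep",
                                          "bin_label", "mean_hz")]
  }
  if (!length(rows))
    stop("no-input: no EMG traces in the requested sets", call. = FALSE)
  do.call(rbind, rows)
}

# per-subject mean of a variable over one set
set_mean <- function(df, var, set) {
  sub <- df[df$set == set, ]
  stats::aggregate(sub[[var]], list(subject = sub$subject), FUN = mean)
}

# per-subject percent change between first and last set means of a variable
set_change <- function(df, var, first_set, last_set) {
  a <- set_mean(df, var, first_set)
  b <- set_mean(df, var, last_set)
  m <- merge(a, b, by = "subject", suffixes = c("_first", "_last"))
  data.frame(subject = m$subject,
             change = percent_change(m$x_first, m$x_last),
             stringsAsFactors = FALSE)
}

#' Full analysis of a synthetic (or re-loaded) experiment
#'
#' Runs every extraction stage and the aggregation/statistics layer:
#' per-contraction torque and EMG metrics, neuromuscular-test metrics,
#' M-max-normalized EMG summaries, first-vs-last-set and pre-vs-post
#' percent changes, four-set and 20%-interval block averages, wavelet
#' instantaneous-mean-frequency bins for the first and last sets, the
#' torque and EMG regressions (stepwise for `T_mean ~ RTD + T_peak` and
#' `EMG_mean ~ RER + EMG_peak`, simple for `RTD ~ RER`), one-way
#' repeated-measures ANOVAs over sets, mono-exponential VO2 fits and
#' lactate accumulation.
#'
#' @param proto an `iso_protocol`.
#' @param wavelet_sets sets to run the time-frequency analysis on
#'   (default: first and last; `NULL` to skip).
#' @param with_emg run the EMG chain (default: TRUE when EMG is present).
#' @return a list of class `iso_analysis`.
#' @export
analyze_protocol <- function(proto, wavelet_sets = c(1L, proto$config$n_sets),
                             with_emg = NULL) {
  cfg <- proto$config
  has_emg <- any(!vapply(proto$contractions, function(r) is.null(r$emg),
                         logical(1)))
  if (is.null(with_emg)) with_emg <- has_emg
  out <- list(config = cfg)

  tq <- torque_metrics_table(proto)
  out$torque <- tq
  out$changes <- list(
    rtd = set_change(tq, "rtd", 1L, cfg$n_sets),
    t_peak = set_change(tq, "t_peak", 1L, cfg$n_sets),
    t_mean = set_change(tq, "t_mean", 1L, cfg$n_sets))

  out$blocks <- list(
    four_sets = lapply(c(rtd = "rtd", t_peak = "t_peak", t_mean = "t_mean"),
                       function(v) block_average(tq, v, "four_sets")),
    five_intervals = lapply(c(rtd = "rtd", t_peak = "t_peak",
                              t_mean = "t_mean"),
                            function(v) block_average(tq, v, "five_intervals")))

  if (length(proto$nm)) {
    nm <- nm_metrics_table(proto)
    out$nm <- nm
    pre <- nm[nm$phase == "pre", ]; post <- nm[nm$phase == "post", ]
    m <- merge(pre, post, by = "subject", suffixes = c("_pre", "_post"))
    out$nm_changes <- data.frame(
      subject = m$subject,
      imvc = percent_change(m$imvc_pre, m$imvc_post),
      va = percent_change(m$va_pre, m$va_post),
      e_tpeak = percent_change(m$e_tpeak_pre, m$e_tpeak_post),
      e_rtd = percent_change(m$e_rtd_pre, m$e_rtd_post),
      db_ratio = percent_change(m$db_ratio_pre, m$db_ratio_post),
      m_max = percent_change(m$m_max_pre, m$m_max_post),
      stringsAsFactors = FALSE)
  }

  if (with_emg && has_emg) {
    em <- emg_metrics_table(proto)
    out$emg <- em
    if (!is.null(out$nm)) {
      pre <- out$nm[out$nm$phase == "pre", ]
      post <- out$nm[out$nm$phase == "post", ]
      mm_pre <- stats::setNames(pre$m_max, pre$subject)
      mm_post <- stats::setNames(post$m_max, post$subject)
      norm <- normalize_emg_metrics(em, mm_pre, mm_post,
                                    n_edge = cfg$reps_per_set)
      out$emg_normalized <- norm$mmax_normalized
      out$emg_pct_of_max <- norm$pct_of_protocol_max
      nn <- norm$mmax_normalized
      a <- nn[nn$phase == "pre", ]; b <- nn[nn$phase == "post", ]
      mb <- merge(a, b, by = "subject", suffixes = c("_pre", "_post"))
      out$emg_changes <- data.frame(
        subject = mb$subject,
        n_rer = percent_change(mb$n_rer_pre, mb$n_rer_post),
        n_emg_mean = percent_change(mb$n_emg_mean_pre, mb$n_emg_mean_post),
        n_emg_peak = percent_change(mb$n_emg_peak_pre, mb$n_emg_peak_post),
        stringsAsFactors = FALSE)
    }
    emg_full_sets <- length(unique(em$set)) == cfg$n_sets
    if (emg_full_sets)
      out$blocks$four_sets <- c(
        out$blocks$four_sets,
        lapply(c(rer = "rer", emg_peak = "emg_peak", emg_mean = "emg_mean"),
               function(v) block_average(em, v, "four_sets")))
    if (!is.null(wavelet_sets)) {
      wavelet_sets <- intersect(wavelet_sets, unique(em$set))
      if (length(wavelet_sets))
        out$ifmean_bins <- ifmean_bins_table(proto, sets = wavelet_sets)
    }
  }

  # regressions on per-subject-per-set means normalised to subject maxima
  per_set <- function(df, var) {
    ag <- stats::aggregate(df[[var]], list(subject = df$subject, set = df$set),
                           FUN = mean)
    mx <- stats::ave(ag$x, ag$subject, FUN = max)
    ag$x <- 100 * ag$x / mx
    ag
  }
  key <- function(d) paste(d$subject, d$set)
  tm <- per_set(tq, "t_mean"); tp <- per_set(tq, "t_peak")
  rt <- per_set(tq, "rtd")
  stopifnot(identical(key(tm), key(tp)), identical(key(tm), key(rt)))
  out$regressions <- list(
    t_mean_on_rtd_tpeak = forward_stepwise(
      tm$x, cbind(rtd = rt$x, t_peak = tp$x)))
  if (with_emg && has_emg && length(unique(out$emg$set)) == cfg$n_sets) {
    er <- per_set(out$emg, "rer"); ep <- per_set(out$emg, "emg_peak")
    emn <- per_set(out$emg, "emg_mean")
    out$regressions$emg_mean_on_rer_emgpeak <- forward_stepwise(
      emn$x, cbind(rer = er$x, emg_peak = ep$x))
    m2 <- merge(rt, er, by = c("subject", "set"), suffixes = c("_rtd", "_rer"))
    out$regressions$rtd_on_rer <- ols_standardized(
      m2$x_rtd, cbind(rer = m2$x_rer))
  }

  # repeated-measures ANOVA over sets (subject x set means, % of max)
  to_matrix <- function(ag) {
    w <- stats::reshape(ag, idvar = "subject", timevar = "set",
                        direction = "wide")
    as.matrix(w[, -1, drop = FALSE])
  }
  out$anova <- list(
    rtd = rm_anova(to_matrix(rt)), t_peak = rm_anova(to_matrix(tp)),
    t_mean = rm_anova(to_matrix(tm)))

  if (length(proto$vo2)) {
    fits <- lapply(names(proto$vo2), function(s) {
      f <- tryCatch(fit_monoexp(proto$vo2[[s]]$t_s, proto$vo2[[s]]$vo2),
                    error = function(e) {
                      warning("VO2 fit skipped for ", s, ": ",
                              conditionMessage(e), call. = FALSE)
                      list(asymptote = NA_real_, tau = NA_real_,
                           baseline = NA_real_)
                    })
      data.frame(subject = s, asymptote = f$asymptote, tau = f$tau,
                 baseline = f$baseline, stringsAsFactors = FALSE)
    })
    out$vo2_fits <- do.call(rbind, fits)
  }
  if (!is.null(proto$lactate)) {
    out$lactate <- transform(proto$lactate,
                             accumulation = lactate_accumulation(pre, post))
  }
  structure(out, class = "iso_analysis")
}

#' @export
print.iso_analysis <- function(x, ...) {
  cat("<iso_analysis>\n")
  cat(sprintf("  contractions analysed: %d\n", nrow(x$torque)))
  ch <- vapply(x$changes, function(d) mean(d$change), numeric(1))
  cat(sprintf("  set %d vs set 1 change (%%): %s\n", x$config$n_sets,
              paste(sprintf("%s %.1f", names(ch), ch), collapse = ", ")))
  if (!is.null(x$nm_changes))
    cat(sprintf("  pre->post: IMVC %.1f%%, eT_peak %.1f%%, eRTD %.1f%%, Db10:100 %.1f%%\n",
                mean(x$nm_changes$imvc), mean(x$nm_changes$e_tpeak),
                mean(x$nm_changes$e_rtd), mean(x$nm_changes$db_ratio)))
  invisible(x)
}
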