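#' Protocol configuration for the synthetic experiment
#'
#' Builds and validates the ground-truth configuration of a simulated
#' repeated-maximal-contraction experiment: protocol geometry (20 sets of 8
#' isokinetic knee extensions at 240 deg/s, ~375-ms contractions), sampling
#' rates (100 Hz torque/velocity, 2048 Hz EMG), per-metric baseline means
#' with inter-subject variability, per-metric multiplicative decline
#' schedules (linear in set index from 1 at the first set to the configured
#' end fraction at the last), neuromuscular-test pre-to-post changes, noise
#' levels and the master seed.
#'
#' Any element of the nested lists can be overridden; unspecified entries
#' keep their defaults.
#'
#' @param n_subjects number of simulated subjects (default 11).
#' @param n_sets number of sets (default 20).
#' @param reps_per_set repetitions per set (default 8).
#' @param contraction_duration contraction duration in seconds (default
#'   `protocol_duration()` = 0.375).
#' @param torque_rate,emg_rate sampling rates in Hz (defaults 100 and 2048).
#' @param target_velocity isokinetic target velocity in deg/s (default 240).
#' @param seed master seed; every stream is derived from it.
#' @param baseline_means,baseline_cv,decline,nm_change,noise_levels,timing
#'   named lists overriding individual defaults (see Details in the package
#'   vignette).
#' @param within_set_decline extra multiplicative decline across the
#'   repetitions of one set (fraction lost from rep 1 to the last rep;
#'   default 0, i.e. flat within set).
#' @param carrier EMG carrier model: `"noise"` (band-limited Gaussian noise)
#'   or `"tone"` (deterministic sinusoid, for exact envelope checks).
#' @return a validated list of class `protocol_config`.
#' @export
protocol_config <- function(n_subjects = 11, n_sets = 20, reps_per_set = 8,
                            contraction_duration = protocol_duration(),
                            torque_rate = 100, emg_rate = 2048,
                            target_velocity = 240, seed = 1,
                            baseline_means = list(), baseline_cv = list(),
                            decline = list(), nm_change = list(),
                            noise_levels = list(), timing = list(),
                            within_set_decline = 0,
                            carrier = c("noise", "tone")) {
  carrier <- match.arg(carrier)
  merge_defaults <- function(user, def, what) {
    bad <- setdiff(names(user), names(def))
    if (length(bad))
      stop("invalid-config: unknown ", what, " field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    def[names(user)] <- user
    def
  }
  baseline_means <- merge_defaults(baseline_means, list(
    t_peak = 172.8, rtd = 1069, t_mean = 94.0,
    emg_peak = 1.122, rer = 9.0, emg_mean = 0.697, if_center = 92.4,
    m_max = 6.34, imvc = 320, e_tpeak = 120.6, e_rtd = 3463,
    db_ratio = 0.89, va = 96.4,
    vo2_asymptote = 23.7, vo2_tau = 45, vo2_baseline = 5,
    lactate_pre = 1.3, lactate_delta = 5.7), "baseline_means")
  baseline_cv <- merge_defaults(baseline_cv, list(
    t_peak = 0.16, rtd_ratio = 0.12, tmean_ratio = 0.06,
    emg_peak = 0.30, rer_ratio = 0.08, emean_ratio = 0.05, if_center = 0.08,
    m_max = 0.20, imvc = 0.30, e_tpeak = 0.16, ertd_ratio = 0.08,
    db_ratio = 0.10, va_sd = 1.5,
    vo2_asymptote = 0.25, vo2_tau = 0.15,
    lactate_pre = 0.20, lactate_delta = 0.40), "baseline_cv")
  decline <- merge_defaults(decline, list(
    rtd = 0.549, t_mean = 0.686, t_peak = 0.777,
    rer = 0.789, emg_mean = 0.809, emg_peak = 0.968,
    m_max = 1.0, if_early = 0.80), "decline")
  nm_change <- merge_defaults(nm_change, list(
    imvc = -32.6, e_tpeak = -24.3, e_rtd = -24.7, db_ratio = -26.8,
    va = -4.3), "nm_change")
  noise_levels <- merge_defaults(noise_levels, list(
    torque = 0.05, torque_floor = 0.001, velocity = 0, emg_floor = 0.02,
    evoked = 0.02, imvc = 0.02, mwave = 0.02, vo2 = 0.03), "noise_levels")
  timing <- merge_defaults(timing, list(
    pre_baseline = 0.5, trace_duration = 1.0, t_rise = 0.16, t2v = 0.057,
    emg_peak_time = 0.228, iso_tol = 0.05, if_early_window = 0.225), "timing")

  cfg <- list(n_subjects = as.integer(n_subjects), n_sets = as.integer(n_sets),
              reps_per_set = as.integer(reps_per_set),
              contraction_duration = contraction_duration,
              torque_rate = torque_rate, emg_rate = emg_rate,
              target_velocity = target_velocity, seed = as.integer(seed),
              baseline_means = baseline_means, baseline_cv = baseline_cv,
              decline = decline, nm_change = nm_change,
              noise_levels = noise_levels, timing = timing,
              within_set_decline = within_set_decline, carrier = carrier)
  validate_config(cfg)
  structure(cfg, class = "protocol_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid-config: ", msg, call. = FALSE)
  chk(cfg$n_subjects >= 1, "need at least one subject")
  chk(cfg$n_sets >= 1 && cfg$reps_per_set >= 1, "need at least one contraction")
  chk(cfg$torque_rate > 0 && cfg$emg_rate > 0, "sampling rates must be positive")
  chk(cfg$contraction_duration >= 0.3, "contraction duration must be >= 0.3 s")
  chk(all(unlist(cfg$decline) > 0) && all(unlist(cfg$decline) <= 1),
      "decline fractions must lie in (0, 1]")
  chk(all(unlist(cfg$noise_levels) >= 0), "noise levels must be >= 0")
  chk(all(unlist(cfg$baseline_means) > 0), "baseline means must be positive")
  with(cfg$timing, {
    chk(pre_baseline > 0.1, "pre-contraction baseline must exceed 0.1 s")
    chk(pre_baseline + cfg$contraction_duration < trace_duration,
        "trace_duration must cover baseline + contraction")
    chk(t_rise > 0 && t_rise < cfg$contraction_duration,
        "t_rise must fall inside the contraction")
  })
  invisible(cfg)
}

# fraction of a metric remaining at set s (linear schedule, 1 at set 1)
decline_fraction <- function(end_frac, s, n_sets) {
  if (n_sets == 1L) return(rep(1, length(s)))
  1 - (1 - end_frac) * (s - 1) / (n_sets - 1)
}

# fraction remaining at repetition r within a set
rep_fraction <- function(wsd, r, reps) {
  if (reps == 1L || wsd == 0) return(rep(1, length(r)))
  1 - wsd * (r - 1) / (reps - 1)
}

# derived integer seeds, kept below 2^31 - 1 and strictly positive;
# subject index and stream offset live in disjoint ranges so no two
# (subject, stream) pairs ever share a seed
derive_seed <- function(seed, subject, stream) {
  stopifnot(stream < 1000003)
  s <- (as.double(seed) + subject * 1000003 + stream) %% 2147483629
  as.integer(s) + 1L
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# ---- per-subject baseline draws -------------------------------------------

draw_subject_baselines <- function(cfg, i) {
  set.seed(derive_seed(cfg$seed, i, 0))
  bm <- cfg$baseline_means; cv <- cfg$baseline_cv
  t_peak <- rlnorm_mean_cv(1, bm$t_peak, cv$t_peak)
  rtd_ratio <- clamp(rlnorm_mean_cv(1, bm$rtd / bm$t_peak, cv$rtd_ratio), 3.5, 7.6)
  tmean_ratio <- clamp(rlnorm_mean_cv(1, bm$t_mean / bm$t_peak, cv$tmean_ratio),
                       0.42, 0.68)
  emg_peak <- rlnorm_mean_cv(1, bm$emg_peak, cv$emg_peak)
  rer_ratio <- clamp(rlnorm_mean_cv(1, bm$rer / bm$emg_peak, cv$rer_ratio),
                     6.8, 9.0)
  emean_ratio <- clamp(rlnorm_mean_cv(1, bm$emg_mean / bm$emg_peak,
                                      cv$emean_ratio), 0.60, 0.72)
  if_center <- clamp(rlnorm_mean_cv(1, bm$if_center, cv$if_center), 40, 180)
  m_max <- rlnorm_mean_cv(1, bm$m_max, cv$m_max)
  imvc <- rlnorm_mean_cv(1, bm$imvc, cv$imvc)
  e_tpeak <- rlnorm_mean_cv(1, bm$e_tpeak, cv$e_tpeak)
  # the bi-exponential doublet at a 100-Hz torque rate can only represent
  # central-difference derivative maxima between ~23 and ~45 times the peak
  ertd_ratio <- clamp(rlnorm_mean_cv(1, bm$e_rtd / bm$e_tpeak, cv$ertd_ratio),
                      24.5, 42)
  db_ratio <- clamp(rlnorm_mean_cv(1, bm$db_ratio, cv$db_ratio), 0.6, 0.98)
  va <- clamp(stats::rnorm(1, bm$va, cv$va_sd), 88, 99.5)
  vo2_a <- rlnorm_mean_cv(1, bm$vo2_asymptote, cv$vo2_asymptote)
  vo2_tau <- rlnorm_mean_cv(1, bm$vo2_tau, cv$vo2_tau)
  lac_pre <- clamp(rlnorm_mean_cv(1, bm$lactate_pre, cv$lactate_pre), 0.5, 3)
  lac_delta <- rlnorm_mean_cv(1, bm$lactate_delta, cv$lactate_delta)
  data.frame(subject = sprintf("S%02d", i),
             t_peak = t_peak, rtd = rtd_ratio * t_peak,
             t_mean = tmean_ratio * t_peak,
             emg_peak = emg_peak, rer = rer_ratio * emg_peak,
             emg_mean = emean_ratio * emg_peak, if_center = if_center,
             m_max = m_max, imvc = imvc, e_tpeak = e_tpeak,
             e_rtd = ertd_ratio * e_tpeak, db_ratio = db_ratio, va = va,
             vo2_asymptote = vo2_a, vo2_tau = vo2_tau,
             vo2_baseline = bm$vo2_baseline,
             lactate_pre = lac_pre, lactate_post = lac_pre + lac_delta,
             stringsAsFactors = FALSE)
}

# ---- EMG envelope calibration ---------------------------------------------

# Full-trace EMG amplitude envelope (mV RMS): zero before onset, smoothstep
# rise to `epeak` at `onset + t_e`, smoothstep fall back to zero at
# `onset + duration`.
emg_envelope <- function(n, rate, onset, duration, epeak, t_e, beta_e,
                         theta_e) {
  tt <- (seq_len(n) - 1L) / rate
  rel <- tt - onset
  env <- numeric(n)
  r <- rel >= 0 & rel <= t_e
  env[r] <- epeak * smoothstep(rel[r] / t_e)^beta_e
  f <- rel > t_e & rel < duration
  env[f] <- epeak * smoothstep((duration - rel[f]) / (duration - t_e))^theta_e
  env
}

# Deterministic "expected RMS" of envelope-modulated unit-variance carrier
# plus an additive noise floor, matching moving_rms() exactly.
expected_rms <- function(env, floor_sd, rate, window = 0.05) {
  moving_rms(sampled_trace(sqrt(env^2 + floor_sd^2), rate = rate, t0 = 0,
                           unit = "mV"), window = window)
}

# Calibrate (beta_e, theta_e) so the deterministic extraction chain
# (expected RMS -> onset detection -> 0-75 ms OLS slope / window mean)
# returns the programmed RER and EMG_mean. `floor_sd` must be the
# post-band-pass (effective) floor, i.e. the raw generated floor times
# bandpass_noise_gain(). Returns the envelope parameters plus the chain
# onset and the chain-expected peak RMS.
calibrate_emg_envelope <- function(epeak, rer, emg_mean, floor_sd, n, rate,
                                   onset, duration, t_e, end_abs,
                                   rms_window = 0.05) {
  chain <- function(beta_e, theta_e) {
    env <- emg_envelope(n, rate, onset, duration, epeak, t_e, beta_e, theta_e)
    expected_rms(env, floor_sd, rate, rms_window)
  }
  r0 <- chain(1, 1)
  onset_det <- detect_emg_onset(r0, baseline_window = onset * 0.8)
  rer_of <- function(beta_e) compute_rer(chain(beta_e, 1), onset_det)
  lo <- 0.05; hi <- 30
  if (rer_of(lo) < rer || rer_of(hi) > rer)
    stop("invalid-config: requested RER/EMG_peak ratio is outside the range ",
         "representable by the EMG envelope model", call. = FALSE)
  beta_e <- stats::uniroot(function(b) rer_of(b) - rer, c(lo, hi),
                           tol = 1e-9)$root
  mean_of <- function(theta_e)
    compute_emg_mean_peak(chain(beta_e, theta_e), onset_det, end_abs)$emg_mean
  if (mean_of(lo) < emg_mean || mean_of(hi) > emg_mean)
    stop("invalid-config: requested EMG_mean/EMG_peak ratio is outside the ",
         "range representable by the EMG envelope model", call. = FALSE)
  theta_e <- stats::uniroot(function(th) mean_of(th) - emg_mean, c(lo, hi),
                            tol = 1e-9)$root
  r <- chain(beta_e, theta_e)
  pk <- compute_emg_mean_peak(r, onset_det, end_abs)
  list(beta_e = beta_e, theta_e = theta_e, onset_det = onset_det,
       emg_peak_chain = pk$emg_peak, t2p_chain = pk$time_to_peak)
}

# ---- full protocol ---------------------------------------------------------

#' Generate a complete synthetic experiment
#'
#' Produces, for every simulated subject: the exercise protocol
#' (`n_sets x reps_per_set` torque/velocity/EMG contraction records whose
#' true metric values follow the configured decline schedules), pre- and
#' post-exercise neuromuscular tests (IMVC with superimposed stimulation,
#' 100-Hz and 10-Hz doublets, single twitch, M-wave), a 30-s-averaged
#' oxygen-uptake series and pre/post blood lactate values — together with a
#' ground-truth table for every generated quantity. Identical configurations
#' (including the seed) give identical output; EMG generation can be
#' restricted to a subset of sets without changing any other stream.
#'
#' @param config a [protocol_config()].
#' @param include_emg generate EMG traces (default TRUE).
#' @param emg_sets integer vector of sets for which EMG is generated
#'   (default NULL = all sets).
#' @param include_nm generate neuromuscular tests (default TRUE).
#' @param include_metabolic generate VO2 and lactate data (default TRUE).
#' @return a list of class `iso_protocol` with elements `config`,
#'   `subjects`, `contractions` (list of records), `nm`, `vo2`, `lactate`
#'   and `truth` (list of ground-truth data.frames).
#' @export
generate_protocol <- function(config, include_emg = TRUE, emg_sets = NULL,
                              include_nm = TRUE, include_metabolic = TRUE) {
  stopifnot(inherits(config, "protocol_config"))
  cfg <- config
  tm <- cfg$timing
  n_tor <- round(tm$trace_duration * cfg$torque_rate)
  n_emg <- round(tm$trace_duration * cfg$emg_rate)
  n_c <- round(cfg$contraction_duration * cfg$torque_rate)
  onset <- tm$pre_baseline
  i_on <- round(onset * cfg$torque_rate)  # samples before onset
  end_abs <- onset + (n_c - 1L) / cfg$torque_rate
  if (is.null(emg_sets)) emg_sets <- seq_len(cfg$n_sets)

  velocity_values <- local({
    tt <- (seq_len(n_tor) - 1L) / cfg$torque_rate
    rel <- tt - onset
    v <- ifelse(rel >= 0 & rel <= (n_c - 1L) / cfg$torque_rate,
                cfg$target_velocity * pmin(1, rel / tm$t2v), 0)
    v
  })

  floor_gain <- bandpass_noise_gain(cfg$emg_rate)
  subjects <- do.call(rbind, lapply(seq_len(cfg$n_subjects),
                                    function(i) draw_subject_baselines(cfg, i)))
  contractions <- vector("list", cfg$n_subjects * cfg$n_sets * cfg$reps_per_set)
  truth_rows <- vector("list", length(contractions))
  nm <- list(); vo2 <- list(); lactate_rows <- list(); nm_truth <- list()
  rec <- 0L

  for (i in seq_len(cfg$n_subjects)) {
    sb <- subjects[i, ]
    shape_cache <- new.env(parent = emptyenv())
    for (s in seq_len(cfg$n_sets)) {
      f <- lapply(cfg$decline, decline_fraction, s = s, n_sets = cfg$n_sets)
      for (r in seq_len(cfg$reps_per_set)) {
        rec <- rec + 1L
        k <- (s - 1L) * cfg$reps_per_set + r
        g <- rep_fraction(cfg$within_set_decline, r, cfg$reps_per_set)
        rtd_c <- sb$rtd * f$rtd * g
        tpk_c <- sb$t_peak * f$t_peak * g
        tmn_c <- sb$t_mean * f$t_mean * g
        rer_c <- sb$rer * f$rer * g
        epk_c <- sb$emg_peak * f$emg_peak * g
        emn_c <- sb$emg_mean * f$emg_mean * g
        if_early_c <- sb$if_center * f$if_early
        key <- sprintf("T|%.9g|%.9g|%.9g", rtd_c / tpk_c, tmn_c / tpk_c, g)
        shp <- shape_cache[[key]]
        if (is.null(shp)) {
          rise <- solve_rise_beta(rtd_c, tpk_c, cfg$torque_rate, tm$t_rise)
          theta <- solve_fall_theta(tmn_c, tpk_c, rise$beta, cfg$torque_rate,
                                    rise$t_rise, cfg$contraction_duration,
                                    rise$hold)
          shp <- list(rise = rise, theta = theta)
          shape_cache[[key]] <- shp
        }
        tt_rel <- (seq_len(n_tor) - 1L) / cfg$torque_rate - onset
        torque_clean <- tpk_c * torque_shape(tt_rel, shp$rise$t_rise,
                                             cfg$contraction_duration,
                                             shp$rise$beta, shp$theta,
                                             shp$rise$hold)
        set.seed(derive_seed(cfg$seed, i, 1000 + 2L * k))
        torque_vals <- torque_clean
        if (cfg$noise_levels$torque > 0)
          torque_vals <- torque_vals *
            (1 + stats::rnorm(n_tor, 0, cfg$noise_levels$torque))
        if (cfg$noise_levels$torque_floor > 0)
          torque_vals <- torque_vals +
            stats::rnorm(n_tor, 0, cfg$noise_levels$torque_floor * tpk_c)
        emg_trace <- NULL
        ecal <- NULL
        floor_sd <- cfg$noise_levels$emg_floor * sb$emg_peak
        if (include_emg && s %in% emg_sets) {
          ekey <- sprintf("E|%.9g|%.9g|%.9g", rer_c / epk_c, emn_c / epk_c, g)
          ecal <- shape_cache[[ekey]]
          if (is.null(ecal)) {
            ecal <- calibrate_emg_envelope(
              epk_c, rer_c, emn_c, floor_sd * floor_gain, n_emg,
              cfg$emg_rate, onset, cfg$contraction_duration,
              tm$emg_peak_time, end_abs)
            shape_cache[[ekey]] <- ecal
          }
          env <- emg_envelope(n_emg, cfg$emg_rate, onset,
                              cfg$contraction_duration, epk_c,
                              tm$emg_peak_time, ecal$beta_e, ecal$theta_e)
          # the early spectral window is anchored at the operational
          # (RMS-envelope) activation onset so that it coincides with the
          # pipeline's 0-225 ms bins
          tt_e <- (seq_len(n_emg) - 1L) / cfg$emg_rate
          fc <- rep(sb$if_center, n_emg)
          early <- tt_e >= ecal$onset_det &
            tt_e < ecal$onset_det + tm$if_early_window
          fc[early] <- if_early_c
          set.seed(derive_seed(cfg$seed, i, 1001 + 2L * k))
          carrier <- if (cfg$carrier == "noise")
            make_noise_carrier(fc, cfg$emg_rate) else
              make_tone_carrier(fc, cfg$emg_rate)
          floor_noise <- if (floor_sd > 0)
            floor_sd * stats::rnorm(n_emg) else 0
          emg_trace <- sampled_trace(env * carrier + floor_noise,
                                     rate = cfg$emg_rate, t0 = 0, unit = "mV")
        }
        contractions[[rec]] <- list(
          subject = sb$subject, set = s, rep = r,
          torque = sampled_trace(torque_vals, rate = cfg$torque_rate, t0 = 0,
                                 unit = "N.m"),
          velocity = sampled_trace(velocity_values, rate = cfg$torque_rate,
                                   t0 = 0, unit = "deg.s-1"),
          emg = emg_trace, onset_true = onset)
        truth_rows[[rec]] <- data.frame(
          subject = sb$subject, set = s, rep = r, onset_s = onset,
          rtd = rtd_c, t_peak = tpk_c, t_mean = tmn_c, t2v_s = tm$t2v,
          rer = rer_c, emg_peak = epk_c, emg_mean = emn_c,
          emg_peak_chain = if (!is.null(ecal)) ecal$emg_peak_chain else NA_real_,
          if_center_early = if_early_c, if_center_late = sb$if_center,
          stringsAsFactors = FALSE)
      }
    }

    if (include_nm) {
      set.seed(derive_seed(cfg$seed, i, 3))
      nm[[sb$subject]] <- list()
      nm_vals <- list(
        pre = list(imvc = sb$imvc, e_tpeak = sb$e_tpeak, e_rtd = sb$e_rtd,
                   db_ratio = sb$db_ratio, m_max = sb$m_max, va = sb$va),
        post = list(
          imvc = sb$imvc * (1 + cfg$nm_change$imvc / 100),
          e_tpeak = sb$e_tpeak * (1 + cfg$nm_change$e_tpeak / 100),
          e_rtd = sb$e_rtd * (1 + cfg$nm_change$e_rtd / 100),
          db_ratio = sb$db_ratio * (1 + cfg$nm_change$db_ratio / 100),
          m_max = sb$m_max * cfg$decline$m_max,
          va = clamp(sb$va * (1 + cfg$nm_change$va / 100), 0, 100)))
      for (phase in c("pre", "post")) {
        v <- nm_vals[[phase]]
        sup_true <- (1 - v$va / 100) * v$e_tpeak
        rise_tau <- solve_evoked_rise_tau(v$e_tpeak, v$e_rtd, 0.1,
                                          cfg$torque_rate)
        mk_evoked <- function(amp, rt, dt) {
          resp <- gen_evoked_response(amp, rt, dt, cfg$torque_rate,
                                      duration = 0.6)
          nl <- cfg$noise_levels$evoked
          vals <- c(numeric(round(0.1 * cfg$torque_rate)), resp$values)
          if (nl > 0) vals <- vals + stats::rnorm(length(vals), 0, nl * amp)
          list(trace = sampled_trace(vals, rate = cfg$torque_rate, t0 = 0,
                                     unit = "N.m"), stim_time = 0.1)
        }
        imvc_rec <- gen_imvc_trace(v$imvc, sup_true, stim_time = 2.5,
                                   rate = cfg$torque_rate, duration = 4,
                                   noise = cfg$noise_levels$imvc)
        # three stimulations per phase; evoked metrics are trial averages
        tests <- list(imvc = imvc_rec)
        for (trial in 1:3) {
          tests[[paste0("db100_", trial)]] <- mk_evoked(v$e_tpeak, rise_tau, 0.1)
          tests[[paste0("db10_", trial)]] <-
            mk_evoked(v$db_ratio * v$e_tpeak, 0.03, 0.15)
        }
        tests$twitch <- mk_evoked(0.5 * v$e_tpeak, 0.02, 0.1)
        tests$mwave <- gen_mwave(v$m_max, rate = cfg$emg_rate,
                                 noise = cfg$noise_levels$mwave)
        nm[[sb$subject]][[phase]] <- tests
        nm_truth[[length(nm_truth) + 1L]] <- data.frame(
          subject = sb$subject, phase = phase, imvc = v$imvc, va = v$va,
          sup_twitch = sup_true, e_tpeak = v$e_tpeak, e_rtd = v$e_rtd,
          db10 = v$db_ratio * v$e_tpeak, db_ratio = v$db_ratio,
          m_max = v$m_max, stringsAsFactors = FALSE)
      }
    }

    if (include_metabolic) {
      set.seed(derive_seed(cfg$seed, i, 4))
      vo2[[sb$subject]] <- gen_vo2_series(
        sb$vo2_asymptote, sb$vo2_tau, sb$vo2_baseline,
        n_points = cfg$n_sets, interval = 30,
        noise = cfg$noise_levels$vo2)
      lactate_rows[[length(lactate_rows) + 1L]] <- data.frame(
        subject = sb$subject, pre = sb$lactate_pre, post = sb$lactate_post,
        stringsAsFactors = FALSE)
    }
  }

  structure(list(
    config = cfg, subjects = subjects, contractions = contractions,
    nm = nm, vo2 = vo2,
    lactate = if (length(lactate_rows)) do.call(rbind, lactate_rows) else NULL,
    truth = list(
      contractions = do.call(rbind, truth_rows),
      nm = if (length(nm_truth)) do.call(rbind, nm_truth) else NULL,
      vo2 = if (include_metabolic)
        subjects[, c("subject", "vo2_asymptote", "vo2_tau", "vo2_baseline")]
      else NULL)),
    class = "iso_protocol")
}

#' @export
print.iso_protocol <- function(x, ...) {
  cat(sprintf(
    "<iso_protocol> %d subjects x %d sets x %d reps (%d contraction records)\n",
    x$config$n_subjects, x$config$n_sets, x$config$reps_per_set,
    length(x$contractions)))
  invisible(x)
}
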