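#' Write a generated protocol to disk
#'
#' Layout (all text, UTF-8, comma-separated, '.' decimal, header row):
#' * `signals/{subject}/{set}_{rep}.csv` — `t_s`, `torque_Nm`,
#'   `velocity_dps` at the torque rate.
#' * `signals/{subject}/{set}_{rep}_emg.csv` — `t_s`, `emg_mV` at the EMG
#'   rate (only for contractions that carry EMG).
#' * `nm/{subject}_{phase}_{test}.csv` plus `nm_index.csv` (with
#'   stimulation times).
#' * `vo2/{subject}.csv`, `lactate.csv`.
#' * `truth.json` (ground truth), `config.yaml` (configuration echo).
#'
#' @param proto an `iso_protocol` from [generate_protocol()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_protocol <- function(proto, dir) {
  stopifnot(inherits(proto, "iso_protocol"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config_yaml(proto$config, file.path(dir, "config.yaml"))
  jsonlite::write_json(
    list(subjects = proto$subjects,
         contractions = proto$truth$contractions,
         nm = proto$truth$nm, vo2 = proto$truth$vo2),
    file.path(dir, "truth.json"),
    dataframe = "columns", digits = NA, na = "null")

  for (rec in proto$contractions) {
    sdir <- file.path(dir, "signals", rec$subject)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    stem <- sprintf("%02d_%d", rec$set, rec$rep)
    data.table::fwrite(
      data.table::data.table(t_s = trace_time(rec$torque),
                             torque_Nm = rec$torque$values,
                             velocity_dps = rec$velocity$values),
      file.path(sdir, paste0(stem, ".csv")))
    if (!is.null(rec$emg))
      data.table::fwrite(
        data.table::data.table(t_s = trace_time(rec$emg),
                               emg_mV = rec$emg$values),
        file.path(sdir, paste0(stem, "_emg.csv")))
  }

  if (length(proto$nm)) {
    nmdir <- file.path(dir, "nm")
    dir.create(nmdir, showWarnings = FALSE)
    idx <- list()
    for (subj in names(proto$nm)) for (phase in names(proto$nm[[subj]])) {
      tests <- proto$nm[[subj]][[phase]]
      for (test in names(tests)) {
        rec <- tests[[test]]
        tr <- if (inherits(rec, "sampled_trace")) rec else rec$trace
        stim <- if (inherits(rec, "sampled_trace")) NA_real_ else rec$stim_time
        fname <- sprintf("%s_%s_%s.csv", subj, phase, test)
        col <- if (identical(tr$unit, "mV")) "emg_mV" else "torque_Nm"
        dt <- data.table::data.table(t_s = trace_time(tr), v = tr$values)
        data.table::setnames(dt, "v", col)
        data.table::fwrite(dt, file.path(nmdir, fname))
        idx[[length(idx) + 1L]] <- data.frame(
          subject = subj, phase = phase, test = test, file = fname,
          stim_s = stim, rate_hz = tr$rate, stringsAsFactors = FALSE)
      }
    }
    data.table::fwrite(do.call(rbind, idx), file.path(dir, "nm_index.csv"))
  }

  if (length(proto$vo2)) {
    vdir <- file.path(dir, "vo2")
    dir.create(vdir, showWarnings = FALSE)
    for (subj in names(proto$vo2))
      data.table::fwrite(proto$vo2[[subj]],
                         file.path(vdir, paste0(subj, ".csv")))
  }
  if (!is.null(proto$lactate))
    data.table::fwrite(proto$lactate, file.path(dir, "lactate.csv"))
  invisible(dir)
}

#' Read a protocol dataset back from disk
#'
#' Inverse of [write_protocol()]: reconstructs an `iso_protocol` object
#' (traces, neuromuscular tests, VO2, lactate, ground truth, configuration)
#' from the on-disk CSV/JSON/YAML layout.
#'
#' @param dir dataset directory.
#' @return an `iso_protocol` list.
#' @export
read_protocol <- function(dir) {
  cfg_path <- file.path(dir, "config.yaml")
  if (!file.exists(cfg_path))
    stop("no-input: ", cfg_path, " not found", call. = FALSE)
  cfg <- read_config_yaml(cfg_path)
  sig_dir <- file.path(dir, "signals")
  subjects_dirs <- sort(list.dirs(sig_dir, recursive = FALSE))
  if (!length(subjects_dirs))
    stop("no-input: no signal directories under ", sig_dir, call. = FALSE)

  contractions <- list()
  for (sdir in subjects_dirs) {
    subj <- basename(sdir)
    files <- sort(list.files(sdir, pattern = "^\\d+_\\d+\\.csv$"))
    for (f in files) {
      parts <- as.integer(strsplit(sub("\\.csv$", "", f), "_")[[1]])
      dt <- data.table::fread(file.path(sdir, f))
      rate <- round(1 / stats::median(diff(dt$t_s)))
      emg_path <- file.path(sdir, sub("\\.csv$", "_emg.csv", f))
      emg <- NULL
      if (file.exists(emg_path)) {
        de <- data.table::fread(emg_path)
        erate <- round(1 / stats::median(diff(de$t_s)))
        emg <- sampled_trace(de$emg_mV, rate = erate, t0 = de$t_s[1],
                             unit = "mV")
      }
      contractions[[length(contractions) + 1L]] <- list(
        subject = subj, set = parts[1], rep = parts[2],
        torque = sampled_trace(dt$torque_Nm, rate = rate, t0 = dt$t_s[1],
                               unit = "N.m"),
        velocity = sampled_trace(dt$velocity_dps, rate = rate,
                                 t0 = dt$t_s[1], unit = "deg.s-1"),
        emg = emg, onset_true = cfg$timing$pre_baseline)
    }
  }

  nm <- list()
  idx_path <- file.path(dir, "nm_index.csv")
  if (file.exists(idx_path)) {
    idx <- data.table::fread(idx_path)
    for (i in seq_len(nrow(idx))) {
      row <- idx[i, ]
      dt <- data.table::fread(file.path(dir, "nm", row$file))
      col <- setdiff(names(dt), "t_s")[1]
      tr <- sampled_trace(dt[[col]], rate = row$rate_hz, t0 = dt$t_s[1],
                          unit = if (col == "emg_mV") "mV" else "N.m")
      entry <- if (is.na(row$stim_s)) tr else
        list(trace = tr, stim_time = row$stim_s)
      nm[[row$subject]][[row$phase]][[row$test]] <- entry
    }
  }

  vo2 <- list()
  vdir <- file.path(dir, "vo2")
  if (dir.exists(vdir))
    for (f in sort(list.files(vdir, pattern = "\\.csv$")))
      vo2[[sub("\\.csv$", "", f)]] <-
        as.data.frame(data.table::fread(file.path(vdir, f)))
  lactate <- NULL
  if (file.exists(file.path(dir, "lactate.csv")))
    lactate <- as.data.frame(data.table::fread(file.path(dir, "lactate.csv")))

  truth <- NULL
  if (file.exists(file.path(dir, "truth.json"))) {
    tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
    truth <- list(contractions = as.data.frame(tj$contractions),
                  nm = if (!is.null(tj$nm)) as.data.frame(tj$nm) else NULL,
                  vo2 = if (!is.null(tj$vo2)) as.data.frame(tj$vo2) else NULL)
    subjects <- as.data.frame(tj$subjects)
  } else subjects <- NULL

  structure(list(config = cfg, subjects = subjects,
                 contractions = contractions, nm = nm, vo2 = vo2,
                 lactate = lactate, truth = truth),
            class = "iso_protocol")
}

#' Write a protocol configuration as YAML
#'
#' @param cfg a [protocol_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read and validate a protocol configuration from YAML
#'
#' Unknown keys and invalid values raise errors naming the offending field.
#'
#' @param path YAML file written by [write_config_yaml()] or by hand; any
#'   subset of the [protocol_config()] arguments may be present.
#' @return a validated `protocol_config`.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw))
    stop("invalid-config: ", path, " does not contain a mapping", call. = FALSE)
  allowed <- names(formals(protocol_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("invalid-config: unknown top-level field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(protocol_config, raw)
}
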