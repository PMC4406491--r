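#' Simulate a complete experiment to disk
#'
#' Generates the synthetic experiment defined by a configuration (object or
#' YAML path) and writes the dataset plus a run manifest. The manifest
#' records the configuration hash, the seed, the package version and an
#' MD5 inventory of every output file, so a re-run with an identical
#' configuration is byte-identical and verifiably so.
#'
#' @param config a [protocol_config()] or the path to a YAML file.
#' @param out_dir output directory.
#' @param ... passed to [generate_protocol()] (e.g. `emg_sets`).
#' @return the generated `iso_protocol`, invisibly.
#' @export
simulate_experiment <- function(config, out_dir, ...) {
  cfg <- if (inherits(config, "protocol_config")) config else
    read_config_yaml(config)
  t0 <- Sys.time()
  proto <- generate_protocol(cfg, ...)
  write_protocol(proto, out_dir)
  write_manifest(out_dir, cfg, stage = "simulate")
  log_line(out_dir, sprintf("simulate: %d contraction records in %.1f s",
                            length(proto$contractions),
                            as.numeric(Sys.time() - t0, units = "secs")))
  invisible(proto)
}

#' Analyse a dataset directory and write result tables
#'
#' Reads a dataset produced by [simulate_experiment()] (or laid out the
#' same way), runs [analyze_protocol()] and writes: `metrics_torque.csv`,
#' `metrics_emg.csv`, `metrics_nm.csv`, `summary_blocks.csv`,
#' `if_mean_bins.csv`, `changes.csv`, `emg_normalized.csv`,
#' `regressions.json`, `anova.json`, `vo2_fits.csv`, `lactate.csv` and a
#' manifest.
#'
#' @param data_dir dataset directory.
#' @param out_dir results directory.
#' @param ... passed to [analyze_protocol()].
#' @return the `iso_analysis`, invisibly.
#' @export
analyze_experiment <- function(data_dir, out_dir, ...) {
  proto <- read_protocol(data_dir)
  t0 <- Sys.time()
  an <- analyze_protocol(proto, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) if (!is.null(df))
    data.table::fwrite(df, file.path(out_dir, name))
  wr(an$torque, "metrics_torque.csv")
  wr(an$emg, "metrics_emg.csv")
  wr(an$nm, "metrics_nm.csv")
  wr(an$emg_normalized, "emg_normalized.csv")
  wr(an$ifmean_bins, "if_mean_bins.csv")
  wr(an$vo2_fits, "vo2_fits.csv")
  wr(an$lactate, "lactate.csv")

  blocks <- list()
  for (grp in names(an$blocks))
    for (v in names(an$blocks[[grp]])) {
      b <- an$blocks[[grp]][[v]]
      b$grouping <- grp; b$variable <- v
      blocks[[length(blocks) + 1L]] <- b
    }
  wr(do.call(rbind, blocks), "summary_blocks.csv")

  changes <- list()
  add_change <- function(df, which) {
    if (is.null(df)) return()
    long <- stats::reshape(df, direction = "long",
                           varying = setdiff(names(df), "subject"),
                           v.names = "change", timevar = "variable",
                           times = setdiff(names(df), "subject"))
    long$comparison <- which
    changes[[length(changes) + 1L]] <<-
      long[, c("comparison", "variable", "subject", "change")]
  }
  set_ch <- do.call(cbind, c(list(subject = an$changes$rtd$subject),
                             lapply(an$changes, function(d) d$change)))
  add_change(as.data.frame(set_ch), "set1_vs_setN")
  add_change(an$nm_changes, "pre_vs_post")
  add_change(an$emg_changes, "first8_vs_last8")
  ch <- do.call(rbind, changes)
  ch$change <- as.numeric(ch$change)
  wr(ch, "changes.csv")

  reg_json <- lapply(an$regressions, function(r)
    list(r2 = r$r2, beta = as.list(r$beta), p_values = as.list(r$p_values),
         predictors = r$predictors, n = r$n))
  jsonlite::write_json(reg_json, file.path(out_dir, "regressions.json"),
                       auto_unbox = TRUE, digits = NA)
  anova_json <- lapply(an$anova, function(a)
    a[c("F", "df1", "df2", "p", "ms_condition", "ms_error")])
  jsonlite::write_json(anova_json, file.path(out_dir, "anova.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, proto$config, stage = "analyze")
  log_line(out_dir, sprintf("analyze: %d contractions in %.1f s",
                            nrow(an$torque),
                            as.numeric(Sys.time() - t0, units = "secs")))
  invisible(an)
}

#' Write a human-readable markdown report from a results directory
#'
#' Builds `report.md` with the study's table shapes: pre/post
#' neuromuscular metrics (mean +/- SD), first-vs-last-set percent changes,
#' four-set block declines, and the five 75-ms instantaneous-mean-frequency
#' bins for the first and last sets. Report bytes are a deterministic
#' function of the result tables.
#'
#' @param results_dir directory written by [analyze_experiment()].
#' @param file output file name (default `report.md` inside `results_dir`).
#' @return the report path, invisibly.
#' @export
report_experiment <- function(results_dir, file = file.path(results_dir,
                                                            "report.md")) {
  rd <- function(name) {
    p <- file.path(results_dir, name)
    if (file.exists(p)) as.data.frame(data.table::fread(p)) else NULL
  }
  nm <- rd("metrics_nm.csv"); ch <- rd("changes.csv")
  blocks <- rd("summary_blocks.csv"); bins <- rd("if_mean_bins.csv")
  if (is.null(ch))
    stop("no-input: ", results_dir, " has no changes.csv", call. = FALSE)
  ln <- character(0)
  push <- function(...) ln <<- c(ln, sprintf(...))
  push("# Repeated maximal contraction analysis report")
  push("")
  if (!is.null(nm)) {
    push("## Neuromuscular testing (pre vs post)")
    push("")
    push("| Variable | Pre | Post |")
    push("|---|---|---|")
    msd <- function(x) sprintf("%.2f +/- %.2f", mean(x), stats::sd(x))
    for (v in c("imvc", "va", "e_tpeak", "e_rtd", "db_ratio", "m_max"))
      push("| %s | %s | %s |", v, msd(nm[nm$phase == "pre", v]),
           msd(nm[nm$phase == "post", v]))
    push("")
  }
  push("## Percent changes (mean +/- SD across subjects)")
  push("")
  push("| Comparison | Variable | Change (%%) |")
  push("|---|---|---|")
  agg <- stats::aggregate(change ~ comparison + variable, data = ch,
                          FUN = function(x) c(mean(x), stats::sd(x)))
  agg <- agg[order(agg$comparison, agg$variable), ]
  for (i in seq_len(nrow(agg)))
    push("| %s | %s | %.1f +/- %.1f |", agg$comparison[i], agg$variable[i],
         agg$change[i, 1], agg$change[i, 2])
  push("")
  if (!is.null(blocks)) {
    push("## Block means (%% of per-subject maximum)")
    push("")
    fs <- blocks[blocks$grouping == "four_sets", ]
    vars <- unique(fs$variable)
    push("| Block | %s |", paste(vars, collapse = " | "))
    push("|%s|", paste(rep("---", length(vars) + 1L), collapse = "|"))
    for (b in unique(fs$block)) {
      cells <- vapply(vars, function(v) {
        r <- fs[fs$block == b & fs$variable == v, ]
        if (nrow(r)) sprintf("%.1f +/- %.1f", r$mean[1], r$sd[1]) else "-"
      }, character(1))
      push("| %s | %s |", b, paste(cells, collapse = " | "))
    }
    push("")
  }
  if (!is.null(bins)) {
    push("## Instantaneous mean frequency by 75-ms bin (Hz)")
    push("")
    agg2 <- stats::aggregate(mean_hz ~ set + bin_label, data = bins,
                             FUN = mean)
    sets <- sort(unique(agg2$set))
    push("| Bin | %s |", paste(sprintf("set %d", sets), collapse = " | "))
    push("|%s|", paste(rep("---", length(sets) + 1L), collapse = "|"))
    for (b in unique(bins$bin_label)) {
      cells <- vapply(sets, function(s) {
        r <- agg2[agg2$set == s & agg2$bin_label == b, ]
        if (nrow(r)) sprintf("%.1f", r$mean_hz[1]) else "-"
      }, character(1))
      push("| %s | %s |", b, paste(cells, collapse = " | "))
    }
    push("")
  }
  writeLines(ln, file)
  invisible(file)
}

# deterministic manifest: config hash, seed, versions, file inventory
write_manifest <- function(dir, cfg, stage) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE),
                        c("manifest.json", "run.log")))
  inv <- lapply(files, function(f) {
    list(file = f, md5 = unname(tools::md5sum(file.path(dir, f))),
         bytes = file.info(file.path(dir, f))$size)
  })
  cfg_yaml <- yaml::as.yaml(unclass(cfg))
  manifest <- list(
    stage = stage,
    config_md5 = digest_string(cfg_yaml),
    seed = cfg$seed,
    package = "isofatigue",
    version = as.character(utils::packageVersion("isofatigue")),
    files = inv)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# MD5 of a string via a temp file (base tools only)
digest_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

log_line <- function(dir, msg) {
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
      file = file.path(dir, "run.log"), append = TRUE)
}
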