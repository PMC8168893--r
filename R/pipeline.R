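# Cohort-table I/O and the end-to-end driver
# (simulate -> extract -> couple -> metrics -> associate).

.required_table_cols <- c("subject_id", "session_id", "group", "age",
                          "gender", "apoe_e4_count", "suvr_base", "suvr_fu",
                          "mmse_base", "mmse_fu", "batch")

#' Read and validate a session table
#'
#' Reads a TSV (or CSV, by extension) session table and validates it:
#' required columns present, session identifiers unique, diagnostic groups
#' in HC/SMC/MCI/AD, gender in M/F, MMSE within 0-30, APOE e4 count in
#' 0-2. Validation failures name the offending row or column.
#'
#' @param path path to a `.tsv`/`.txt` (tab) or `.csv` file.
#' @return validated data.frame.
#' @export
read_session_table <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(tab, .required_table_cols)
  dup <- tab$session_id[duplicated(tab$session_id)]
  if (length(dup))
    stop_invalid("duplicate session_id: %s", paste(unique(dup),
                                                   collapse = ", "))
  bad_grp <- which(!tab$group %in% .group_levels)
  if (length(bad_grp))
    stop_invalid("row %d: unknown group label '%s' (expected HC/SMC/MCI/AD)",
                 bad_grp[1L], tab$group[bad_grp[1L]])
  bad_gen <- which(!is.na(tab$gender) & !tab$gender %in% c("M", "F"))
  if (length(bad_gen))
    stop_invalid("row %d: unknown gender '%s' (expected M/F)",
                 bad_gen[1L], tab$gender[bad_gen[1L]])
  for (col in c("mmse_base", "mmse_fu")) {
    bad <- which(!is.na(tab[[col]]) & (tab[[col]] < 0 | tab[[col]] > 30))
    if (length(bad))
      stop_invalid("row %d: %s = %s outside [0, 30]", bad[1L], col,
                   tab[[col]][bad[1L]])
  }
  bad_apoe <- which(!is.na(tab$apoe_e4_count) &
                      !tab$apoe_e4_count %in% 0:2)
  if (length(bad_apoe))
    stop_invalid("row %d: apoe_e4_count = %s outside {0, 1, 2}",
                 bad_apoe[1L], tab$apoe_e4_count[bad_apoe[1L]])
  tab
}

#' Write a session table as TSV
#'
#' @param table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> extract -> couple -> metrics -> associate on a
#' synthetic cohort, writing every stage product under `out_dir`:
#' the session table and ground truth (TSV), per-session signals (TSV plus
#' JSON provenance sidecars), the session-mean cross-correlation function
#' with its permutation null (TSV), the cohort table with coupling,
#' amplitude, head-motion (and, in volume mode, arousal-index) columns
#' appended, the association battery (TSV), and a JSON run manifest.
#'
#' @param config a [sim_config()]; its seed drives every stage.
#' @param out_dir output directory (created if needed).
#' @param n_permutations permutations for the coupling null (default 1000).
#' @param signals_only fast signal-only mode (default `TRUE`).
#' @param write_volumes in volume mode, also write per-session NIfTI files.
#' @param max_lag_seconds lag range of the cross-correlation stage.
#' @param quiet suppress per-stage log lines.
#' @return a `run_manifest` (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, n_permutations = 1000,
                         signals_only = TRUE, write_volumes = FALSE,
                         max_lag_seconds = 21, quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(fmt, ...) {
    if (!quiet)
      message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0, "secs")),
              sprintf(fmt, ...))
  }
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  log_stage("simulate: %d subjects x %d sessions (%s mode)",
            config$n_subjects, config$sessions_per_subject,
            if (signals_only) "signal-only" else "volume")
  cohort <- stage("simulate", simulate_cohort(config, signals_only))
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$config <- cfg_json
  paths$cohort_table <- write_tsv(cohort$table,
                                  file.path(out_dir, "cohort.tsv"))
  paths$ground_truth <- write_tsv(cohort$truth,
                                  file.path(out_dir, "ground_truth.tsv"))
  if (!signals_only && write_volumes) {
    vdir <- file.path(out_dir, "volumes")
    dir.create(vdir, showWarnings = FALSE)
    for (s in cohort$sessions)
      write_nifti(s$volumes$data, file.path(vdir, paste0(s$session_id,
                                                         ".nii.gz")),
                  tr_seconds = s$tr_seconds)
    write_nifti(cohort$sessions[[1L]]$gm_mask$data,
                file.path(vdir, "gm_mask.nii.gz"), datatype = "uint8")
    write_nifti(cohort$sessions[[1L]]$csf_mask$data,
                file.path(vdir, "csf_mask.nii.gz"), datatype = "uint8")
    paths$volumes <- vdir
  }

  log_stage("extract: temporal pipeline + signal extraction")
  signals <- stage("extract", extract_cohort_signals(cohort))
  sdir <- file.path(out_dir, "signals")
  dir.create(sdir, showWarnings = FALSE)
  for (nm in names(signals)) {
    s <- signals[[nm]]
    tt <- (seq_along(s$global_bold) - 1 + s$n_discarded_edge_volumes) *
      s$tr_seconds
    write_tsv(data.frame(time_s = tt, value = s$global_bold),
              file.path(sdir, paste0(nm, "_global.tsv")))
    write_tsv(data.frame(time_s = tt, value = s$csf),
              file.path(sdir, paste0(nm, "_csf.tsv")))
    jsonlite::write_json(s$provenance,
                         file.path(sdir, paste0(nm, "_provenance.json")),
                         auto_unbox = TRUE)
  }
  paths$signals <- sdir

  log_stage("couple: cross-correlation + %d permutations", n_permutations)
  fit <- stage("couple",
               bold_csf_coupling(signals, max_lag_seconds = max_lag_seconds,
                                 n_permutations = n_permutations,
                                 seed = config$seed + 1L))
  ccf_df <- data.frame(lag_s = fit$mean$lags_seconds,
                       r_mean = fit$mean$r_mean, sem = fit$mean$sem)
  if (!is.null(fit$null)) {
    ccf_df$null_mean <- fit$null$null_mean
    ccf_df$null_lo <- fit$null$null_lo
    ccf_df$null_hi <- fit$null$null_hi
    ccf_df$p <- fit$null$p
  }
  paths$ccf <- write_tsv(ccf_df, file.path(out_dir, "ccf_mean.tsv"))

  log_stage("metrics: amplitude, head motion%s",
            if (signals_only) "" else ", arousal index")
  tab <- cohort$table
  tab$coupling <- unname(fit$strengths)
  lag_mat <- do.call(rbind, lapply(fit$ccfs, `[[`, "r"))
  colnames(lag_mat) <- lag_col_name(fit$mean$lags_seconds)
  tab <- cbind(tab, lag_mat)
  motion <- lapply(cohort$sessions, `[[`, "motion")
  met <- stage("metrics", session_metrics(signals, motion = motion))
  if (!signals_only)
    met$arousal_index <- vapply(cohort$sessions, function(s)
      arousal_index(s$volumes, s$loading_map), 1)
  tab <- cbind(tab, met)
  paths$cohort_metrics <- write_tsv(tab, file.path(out_dir,
                                                   "cohort_metrics.tsv"))

  log_stage("associate: full battery")
  battery <- stage("associate", run_full_analysis(tab))
  paths$associations <- write_tsv(battery$results,
                                  file.path(out_dir, "associations.tsv"))
  if (!is.null(battery$subject_level))
    paths$subject_level <- write_tsv(battery$subject_level,
                                     file.path(out_dir,
                                               "associations_subject.tsv"))
  if (!is.null(battery$lag_profiles)) {
    lp <- do.call(rbind, Map(function(nm, df) cbind(marker = nm, df),
                             names(battery$lag_profiles),
                             battery$lag_profiles))
    paths$lag_profiles <- write_tsv(lp, file.path(out_dir,
                                                  "lag_profiles.tsv"))
  }

  manifest <- list(tool = "csfcoupling",
                   version = as.character(utils::packageVersion("csfcoupling")),
                   seed = config$seed,
                   config_digest = unname(tools::md5sum(cfg_json)),
                   n_sessions = nrow(tab),
                   n_permutations = n_permutations,
                   signals_only = signals_only,
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   paths = lapply(paths, function(p)
                     sub(paste0("^", out_dir, "/?"), "", p)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("done: %d sessions, outputs in %s", nrow(tab), out_dir)
  invisible(structure(c(manifest,
                        list(fit = fit, table = tab, battery = battery)),
                      class = "run_manifest"))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %s v%s, seed %d, %d sessions\n",
              x$tool, x$version, x$seed, x$n_sessions))
  for (nm in names(x$paths)) cat(sprintf("  %-15s %s\n", nm, x$paths[[nm]]))
  invisible(x)
}
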