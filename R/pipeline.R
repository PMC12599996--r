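#' Evaluate a paired cohort of device and gold timelines
#'
#' Runs the full concordance analysis: per-subject epoch-level confusion
#' counts (pooled for the headline diagnostic metrics with Wilson
#' intervals), the device valid-output rate, a ROC sweep of the AF-beat
#' fraction with trapezoidal AUC, the threshold-sweep table over the
#' 40-70% cut points, per-subject burden profiles for both sources, and
#' the per-metric concordance table (medians, IQRs, MAE, Mann-Whitney p,
#' Spearman rs).
#'
#' @param device_tls,gold_tls Named lists of labeled `rhythm_timeline`
#'   objects; names (or subject ids) are matched across the two lists.
#'   Unmatched subjects are dropped with a warning.
#' @param sweep_thresholds AF-beat-fraction cut points for the sweep table.
#' @param conf Confidence level for Wilson intervals.
#' @param ... Passed to [burden_profile()] via [cohort_profiles()].
#' @return A list of class `evaluation_report` with elements `performance`,
#'   `counts`, `per_subject_counts`, `output_rate`, `roc`, `auc`, `sweep`,
#'   `device_profiles`, `gold_profiles`, `concordance`, `n_subjects`,
#'   `unmatched`.
#' @export
evaluate_cohort <- function(device_tls, gold_tls,
                            sweep_thresholds = seq(0.40, 0.70, by = 0.05),
                            conf = 0.95, ...) {
  dev_ids <- vapply(device_tls, timeline_subject, character(1))
  gold_ids <- vapply(gold_tls, timeline_subject, character(1))
  common <- intersect(dev_ids, gold_ids)
  unmatched <- union(setdiff(dev_ids, gold_ids), setdiff(gold_ids, dev_ids))
  if (length(unmatched)) {
    warning(sprintf("%d unmatched subject(s) excluded: %s",
                    length(unmatched), paste(unmatched, collapse = ", ")))
  }
  if (length(common) == 0L) stop("no matching subjects", call. = FALSE)
  device_tls <- device_tls[match(common, dev_ids)]
  gold_tls <- gold_tls[match(common, gold_ids)]

  per_subject <- Map(confusion, device_tls, gold_tls)
  pooled <- pool_confusion(per_subject)
  output_rate <- sum(vapply(device_tls, monitoring_minutes, numeric(1))) /
    sum(vapply(device_tls, nrow, numeric(1)))
  perf <- performance(pooled, conf = conf, output_rate = output_rate)

  # pooled per-minute AF-beat fractions (device) against gold labels,
  # restricted to minutes valid in both streams
  frac <- list()
  truth <- list()
  for (i in seq_along(common)) {
    d <- device_tls[[i]]; g <- gold_tls[[i]]
    idx <- intersect(d$minute_index[d$valid], g$minute_index[g$valid])
    di <- match(idx, d$minute_index)
    frac[[i]] <- d$n_af_beats[di] / d$n_beats[di]
    truth[[i]] <- g$label[match(idx, g$minute_index)] == "AF"
  }
  frac <- unlist(frac)
  truth <- unlist(truth)
  roc <- if (any(truth) && any(!truth)) roc_auc(frac, truth) else
    list(roc = NULL, auc = NA_real_)

  sweep <- threshold_sweep(device_tls, gold_tls, sweep_thresholds)

  dev_prof <- cohort_profiles(device_tls, ...)
  gold_prof <- cohort_profiles(gold_tls, ...)
  conc <- concordance_table(dev_prof, gold_prof)

  structure(list(
    performance = perf, counts = pooled, per_subject_counts = per_subject,
    output_rate = output_rate, roc = roc$roc, auc = roc$auc, sweep = sweep,
    device_profiles = dev_prof, gold_profiles = gold_prof,
    concordance = conc, n_subjects = length(common), unmatched = unmatched
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d paired subject(s)\n", x$n_subjects))
  print(x$performance)
  if (!is.na(x$auc)) cat(sprintf("  AUC          %5.1f%%\n", 100 * x$auc))
  invisible(x)
}

#' Performance metrics across AF-beat-fraction thresholds
#'
#' Re-labels the device stream at each cut point (without context
#' smoothing), pools the epoch-level confusion against the gold labels
#' (held at `gold_threshold`), and evaluates the diagnostic metrics.
#'
#' @param device_tls,gold_tls Lists of `rhythm_timeline`s, matched by
#'   position.
#' @param thresholds Cut points in `[0, 1]`.
#' @param gold_threshold Fixed labeling threshold for the gold stream.
#' @return A data frame with one row per threshold: `threshold`,
#'   `accuracy`, `precision`, `sensitivity`, `specificity`, `f1`.
#' @export
threshold_sweep <- function(device_tls, gold_tls,
                            thresholds = seq(0.40, 0.70, by = 0.05),
                            gold_threshold = 0.40) {
  gold_tls <- lapply(gold_tls, label_minutes, threshold = gold_threshold)
  rows <- lapply(thresholds, function(t) {
    dev_t <- lapply(device_tls, label_minutes, threshold = t)
    cts <- pool_confusion(Map(confusion, dev_t, gold_tls))
    perf <- performance(cts)
    est <- stats::setNames(perf$estimate, perf$metric)
    data.frame(threshold = t,
               accuracy = est[["accuracy"]], precision = est[["precision"]],
               sensitivity = est[["sensitivity"]],
               specificity = est[["specificity"]], f1 = est[["f1"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort enrolment filter for excluded arrhythmia diagnoses
#'
#' Removes subjects whose diagnosis is atrial flutter or atrioventricular
#' block from the analysis set and reports the retained count and
#' percentage (nearest integer). Unknown diagnosis codes produce a warning
#' and are retained.
#'
#' @param metadata Data frame (or path to a CSV) with columns `subject_id`
#'   and `diagnosis`.
#' @param exclude_codes Diagnosis codes removed from the analysis set.
#' @param known_codes Recognised codes; anything else triggers a warning.
#' @return A list of class `exclusion_report`: `n_enrolled`, `n_excluded`,
#'   `excluded` (data frame of id and diagnosis), `n_retained`,
#'   `pct_retained` (nearest integer), `retained_ids`.
#' @export
exclusion_filter <- function(metadata,
                             exclude_codes = c("atrial_flutter", "av_block"),
                             known_codes = c("paroxysmal_af", "persistent_af",
                                             "af", "sinus_rhythm",
                                             "atrial_flutter", "av_block")) {
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE,
                                colClasses = c(subject_id = "character"))
  }
  stopifnot(all(c("subject_id", "diagnosis") %in% names(metadata)))
  unknown <- setdiff(unique(metadata$diagnosis), known_codes)
  if (length(unknown)) {
    warning("unknown diagnosis code(s) retained: ",
            paste(unknown, collapse = ", "))
  }
  drop <- metadata$diagnosis %in% exclude_codes
  n <- nrow(metadata)
  retained <- metadata$subject_id[!drop]
  out <- list(
    n_enrolled = n,
    n_excluded = sum(drop),
    excluded = metadata[drop, c("subject_id", "diagnosis"), drop = FALSE],
    n_retained = length(retained),
    pct_retained = as.integer(round(100 * length(retained) / max(n, 1L))),
    retained_ids = retained
  )
  class(out) <- "exclusion_report"
  out
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf(
    "<exclusion_report> %d enrolled - %d excluded -> %d analysed (%d%%)\n",
    x$n_enrolled, x$n_excluded, x$n_retained, x$pct_retained
  ))
  invisible(x)
}

fmt_pct1 <- function(x) sprintf("%.1f", 100 * x)

#' Write cohort files for a simulation run
#'
#' Writes the gold and device timeline CSVs, the gold-truth burden-profile
#' CSV, and a JSON manifest (configuration, its hash, per-subject seeds)
#' into `out_dir`, creating it if needed.
#'
#' @param config A `synthetic_config`.
#' @param out_dir Output directory.
#' @return Invisibly, the `synthetic_cohort` object.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config)
  write_timelines(lapply(cohort$pairs, `[[`, "gold"),
                  file.path(out_dir, "gold.csv"))
  write_timelines(lapply(cohort$pairs, `[[`, "device"),
                  file.path(out_dir, "device.csv"))
  truth <- do.call(rbind, lapply(cohort$pairs, function(p) {
    as.data.frame(p$truth_profile)
  }))
  utils::write.csv(truth, file.path(out_dir, "truth_profiles.csv"),
                   row.names = FALSE)
  if (config$beat_mode) {
    write_beat_series(lapply(cohort$pairs, `[[`, "beats"),
                      file.path(out_dir, "beats.csv"))
  }
  jsonlite::write_json(cohort$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}

#' Evaluate device against gold timeline CSVs and write reports
#'
#' Reads the two timeline CSVs, runs [evaluate_cohort()], and writes
#' `performance.csv` (headline metrics as percentages to one decimal, with
#' Wilson intervals and confusion counts), `sweep.csv` (the threshold-sweep
#' table), `concordance.csv` (the 15-row per-metric table), `roc.csv`, and
#' `report.json` combining everything.
#'
#' @param device_csv,gold_csv Paths to timeline CSVs.
#' @param out_dir Output directory.
#' @param ... Passed to [evaluate_cohort()].
#' @return Invisibly, the `evaluation_report`.
#' @export
run_evaluate <- function(device_csv, gold_csv, out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  device_tls <- lapply(read_timelines(device_csv), label_minutes)
  gold_tls <- lapply(read_timelines(gold_csv), label_minutes)
  rep <- evaluate_cohort(device_tls, gold_tls, ...)

  perf <- rep$performance
  perf_out <- data.frame(
    metric = perf$metric,
    estimate_pct = fmt_pct1(perf$estimate),
    ci_low_pct = fmt_pct1(perf$ci_low),
    ci_high_pct = fmt_pct1(perf$ci_high)
  )
  utils::write.csv(perf_out, file.path(out_dir, "performance.csv"),
                   row.names = FALSE)
  sweep_out <- rep$sweep
  for (col in setdiff(names(sweep_out), "threshold")) {
    sweep_out[[col]] <- sprintf("%.2f", sweep_out[[col]])
  }
  utils::write.csv(sweep_out, file.path(out_dir, "sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(rep$concordance),
                   file.path(out_dir, "concordance.csv"), row.names = FALSE)
  if (!is.null(rep$roc)) {
    utils::write.csv(rep$roc, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
  }
  json <- list(
    n_subjects = rep$n_subjects,
    counts = as.list(unclass(rep$counts)),
    output_rate = rep$output_rate,
    performance = as.data.frame(perf),
    auc = rep$auc,
    sweep = rep$sweep,
    concordance = as.data.frame(rep$concordance)
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}

#' Filter an enrolment metadata CSV and write the analysis-set manifest
#'
#' @param metadata_csv Path to a CSV with `subject_id` and `diagnosis`.
#' @param out_path Output JSON path.
#' @param ... Passed to [exclusion_filter()].
#' @return Invisibly, the `exclusion_report`.
#' @export
run_exclusion_filter <- function(metadata_csv, out_path, ...) {
  rep <- exclusion_filter(metadata_csv, ...)
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(n_enrolled = rep$n_enrolled, n_excluded = rep$n_excluded,
         excluded = rep$excluded, n_retained = rep$n_retained,
         pct_retained = rep$pct_retained, retained_ids = rep$retained_ids),
    out_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(rep)
}
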