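#' Read rhythm timelines from CSV
#'
#' The timeline CSV holds one row per minute with columns `subject_id`,
#' `source`, `minute_index`, `clock_hour`, `n_beats`, `n_af_beats`,
#' `mean_rate_bpm`, `valid` (0/1). Rows with `valid = 0` may leave the
#' numeric measurement cells empty. A single file may contain several
#' subjects and both monitor sources.
#'
#' @param path Path to a UTF-8 CSV file with the header above.
#' @return A named list of `rhythm_timeline` objects, one per
#'   subject-by-source combination, named `"<subject_id>.<source>"`.
#' @seealso [write_timelines()]
#' @export
read_timelines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  required <- c("subject_id", "source", "minute_index", "clock_hour",
                "n_beats", "n_af_beats", "mean_rate_bpm", "valid")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("timeline CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$valid <- as.logical(as.integer(df$valid))
  # invalid minutes may have empty measurement cells: normalise to zeros
  for (col in c("n_beats", "n_af_beats")) {
    df[[col]] <- as.integer(df[[col]])
    df[[col]][!df$valid & is.na(df[[col]])] <- 0L
  }
  df$mean_rate_bpm <- as.numeric(df$mean_rate_bpm)
  df$mean_rate_bpm[!df$valid & is.na(df$mean_rate_bpm)] <- 0
  key <- paste(df$subject_id, df$source, sep = ".")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(d) {
    d <- d[order(d$minute_index), , drop = FALSE]
    rhythm_timeline(
      subject_id = d$subject_id[1L], source = d$source[1L],
      minute_index = d$minute_index, clock_hour = d$clock_hour,
      n_beats = d$n_beats, n_af_beats = d$n_af_beats,
      mean_rate_bpm = d$mean_rate_bpm, valid = d$valid
    )
  })
  out
}

#' Write rhythm timelines to CSV
#'
#' Inverse of [read_timelines()]: serialises one or more timelines into the
#' one-row-per-minute timeline CSV format. Invalid minutes are written with
#' `valid = 0` and empty measurement cells.
#'
#' @param timelines A `rhythm_timeline` or a list of them.
#' @param path Output CSV path.
#' @return Invisibly, the path written.
#' @export
write_timelines <- function(timelines, path) {
  if (inherits(timelines, "rhythm_timeline")) timelines <- list(timelines)
  rows <- lapply(timelines, function(tl) {
    d <- as.data.frame(tl)[, c("minute_index", "clock_hour", "n_beats",
                               "n_af_beats", "mean_rate_bpm", "valid")]
    d$subject_id <- timeline_subject(tl)
    d$source <- timeline_source(tl)
    inval <- !d$valid
    d$n_beats[inval] <- NA_integer_
    d$n_af_beats[inval] <- NA_integer_
    d$mean_rate_bpm[inval] <- NA_real_
    d$valid <- as.integer(d$valid)
    d[, c("subject_id", "source", "minute_index", "clock_hour",
          "n_beats", "n_af_beats", "mean_rate_bpm", "valid")]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a beat series from CSV
#'
#' Beat-series CSV columns: `subject_id`, `beat_time_s` (strictly increasing
#' seconds from recording start), `artifact` (0/1 flag marking the interval
#' ending at this beat as motion-corrupted).
#'
#' @param path Path to the CSV file.
#' @return A named list of `beat_series` objects, one per subject.
#' @seealso [beat_series()]
#' @export
read_beat_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  required <- c("subject_id", "beat_time_s", "artifact")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("beat-series CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lapply(split(df, factor(df$subject_id, levels = unique(df$subject_id))),
         function(d) {
           d <- d[order(d$beat_time_s), , drop = FALSE]
           beat_series(d$subject_id[1L], d$beat_time_s,
                       artifact = as.logical(as.integer(d$artifact)))
         })
}

#' Write a beat series to CSV
#'
#' @param series A `beat_series` or a list of them.
#' @param path Output CSV path.
#' @return Invisibly, the path written.
#' @export
write_beat_series <- function(series, path) {
  if (inherits(series, "beat_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(
      subject_id = s$subject_id,
      beat_time_s = s$beat_times_s,
      # per-beat artifact flag applies to the interval ending at the beat;
      # the first beat opens no interval and is written unflagged
      artifact = as.integer(c(FALSE, s$artifact_mask))
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
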