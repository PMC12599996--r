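#' Construct a minute-resolution rhythm timeline
#'
#' A rhythm timeline holds one monitor's per-minute beat summaries for one
#' subject: for every minute epoch, the number of detected beats, the number
#' of beats attributed to atrial fibrillation (AF), the mean pulse rate, and
#' whether the monitor produced a usable output for that minute. Rhythm labels
#' (AF / non-AF / missing) are derived afterwards with [label_minutes()].
#'
#' Minute indices are 0-based and must be strictly increasing; intervals are
#' half-open throughout the package. Invalid minutes (`valid = FALSE`) carry
#' no usable measurements: their beat counts and rates are ignored by every
#' consumer, and all "total monitoring time" denominators count valid minutes
#' only.
#'
#' @param subject_id Subject identifier (scalar character).
#' @param source Monitor source, `"device"` (e.g. a PPG smartwatch) or
#'   `"gold"` (the reference annotation, e.g. 24-hour Holter ECG).
#' @param minute_index Integer vector, 0-based minutes since recording start,
#'   strictly increasing.
#' @param clock_hour Integer vector in `0:23`, local clock hour of each epoch.
#' @param n_beats Nonnegative integer vector, beats detected in each minute.
#' @param n_af_beats Nonnegative integer vector, beats classified as AF;
#'   must not exceed `n_beats` on valid minutes.
#' @param mean_rate_bpm Nonnegative numeric vector, mean pulse rate (beats
#'   per minute) of each epoch.
#' @param valid Logical vector; `FALSE` marks minutes without monitor output.
#'
#' @return An object of class `rhythm_timeline`: a data frame with one row
#'   per minute epoch and columns `minute_index`, `clock_hour`, `n_beats`,
#'   `n_af_beats`, `mean_rate_bpm`, `valid`, `label`, plus attributes
#'   `subject_id` and `source`. `label` is `NA` until [label_minutes()] is
#'   applied.
#' @seealso [label_minutes()], [extract_episodes()], [hourly_counts()],
#'   [burden_profile()]
#' @export
#' @examples
#' tl <- rhythm_timeline(
#'   "S1", "gold",
#'   minute_index = 0:5, clock_hour = rep(0L, 6),
#'   n_beats = rep(70L, 6), n_af_beats = c(0L, 60L, 65L, 0L, 0L, 10L),
#'   mean_rate_bpm = rep(70, 6), valid = rep(TRUE, 6)
#' )
#' tl <- label_minutes(tl)
#' timeline_labels(tl)
rhythm_timeline <- function(subject_id, source = c("device", "gold"),
                            minute_index, clock_hour, n_beats, n_af_beats,
                            mean_rate_bpm, valid = TRUE) {
  source <- match.arg(source)
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  n <- length(minute_index)
  valid <- rep_len(as.logical(valid), n)
  epochs <- data.frame(
    minute_index = as.integer(minute_index),
    clock_hour = as.integer(clock_hour),
    n_beats = as.integer(n_beats),
    n_af_beats = as.integer(n_af_beats),
    mean_rate_bpm = as.numeric(mean_rate_bpm),
    valid = valid,
    label = NA_character_,
    stringsAsFactors = FALSE
  )
  validate_timeline_epochs(epochs)
  structure(epochs,
    subject_id = subject_id, source = source,
    class = c("rhythm_timeline", "data.frame")
  )
}

validate_timeline_epochs <- function(epochs) {
  if (nrow(epochs) == 0L) {
    return(invisible(epochs))
  }
  if (any(diff(epochs$minute_index) <= 0L)) {
    stop("minute_index must be strictly increasing", call. = FALSE)
  }
  if (any(epochs$clock_hour < 0L | epochs$clock_hour > 23L)) {
    stop("clock_hour must lie in 0..23", call. = FALSE)
  }
  v <- epochs$valid
  if (any(v & (is.na(epochs$n_beats) | epochs$n_beats < 0L))) {
    stop("valid epochs need a nonnegative beat count", call. = FALSE)
  }
  if (any(v & (is.na(epochs$n_af_beats) | epochs$n_af_beats < 0L |
                 epochs$n_af_beats > epochs$n_beats))) {
    stop("n_af_beats must satisfy 0 <= n_af_beats <= n_beats on valid epochs",
         call. = FALSE)
  }
  if (any(v & (is.na(epochs$mean_rate_bpm) | epochs$mean_rate_bpm < 0))) {
    stop("valid epochs need a nonnegative mean_rate_bpm", call. = FALSE)
  }
  invisible(epochs)
}

#' @export
print.rhythm_timeline <- function(x, ...) {
  lab <- x$label
  cat(sprintf(
    "<rhythm_timeline> subject %s, source %s: %d epochs (%d valid)\n",
    attr(x, "subject_id"), attr(x, "source"), nrow(x), sum(x$valid)
  ))
  if (!all(is.na(lab))) {
    cat(sprintf(
      "  labels: %d AF, %d non-AF, %d missing\n",
      sum(lab == "AF", na.rm = TRUE), sum(lab == "non-AF", na.rm = TRUE),
      sum(lab == "missing", na.rm = TRUE)
    ))
  }
  invisible(x)
}

#' @rdname rhythm_timeline
#' @param x A `rhythm_timeline`.
#' @export
timeline_subject <- function(x) attr(x, "subject_id")

#' @rdname rhythm_timeline
#' @export
timeline_source <- function(x) attr(x, "source")

#' @rdname rhythm_timeline
#' @export
timeline_labels <- function(x) x$label

#' Total monitoring time of a timeline
#'
#' The number of valid minutes, the denominator of every "relative to total
#' monitoring time" burden statistic.
#'
#' @param x A `rhythm_timeline`.
#' @return Integer count of valid minute epochs.
#' @export
monitoring_minutes <- function(x) sum(x$valid)

#' Derive per-minute rhythm labels from AF-beat fractions
#'
#' A valid minute is labeled `AF` when its fraction of AF-classified beats
#' strictly exceeds `threshold` (default 0.40, i.e. more than 40% AF beats
#' per minute), `non-AF` when the fraction is at or below the threshold, and
#' `missing` when the monitor produced no output for that minute. The
#' operation is idempotent and monotone in the threshold: raising it never
#' turns a non-AF minute into AF.
#'
#' @param timeline A `rhythm_timeline`.
#' @param threshold AF-beat-fraction cut point in `[0, 1]`; the label is AF
#'   iff `n_af_beats / n_beats > threshold` (strict).
#' @return The timeline with its `label` column populated.
#' @export
label_minutes <- function(timeline, threshold = 0.40) {
  stopifnot(inherits(timeline, "rhythm_timeline"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  v <- timeline$valid
  if (any(v & timeline$n_beats == 0L)) {
    stop("valid epoch with n_beats = 0: no beat fraction is defined",
         call. = FALSE)
  }
  frac <- timeline$n_af_beats / timeline$n_beats
  lab <- rep(NA_character_, nrow(timeline))
  lab[!v] <- "missing"
  lab[v] <- ifelse(frac[v] > threshold, "AF", "non-AF")
  timeline$label <- lab
  timeline
}

#' Extract AF episodes from a labeled timeline
#'
#' Episodes are maximal runs of AF-labeled minutes. Runs separated only by at
#' most `gap_bridge_min` consecutive missing minutes are merged into one
#' episode (the bridged missing minutes do not contribute to its duration);
#' a non-AF minute always terminates a run. With the default
#' `gap_bridge_min = 0` any gap breaks the episode.
#'
#' @param timeline A labeled `rhythm_timeline` (see [label_minutes()]).
#' @param gap_bridge_min Nonnegative integer, the longest run of missing
#'   minutes an episode may span.
#' @return An `episode_list`: a data frame with one row per episode and
#'   columns `start_minute` (inclusive), `end_minute` (exclusive, half-open,
#'   both in `minute_index` units), `duration_min` (count of AF minutes),
#'   and `mean_rate_bpm` (beat-count-weighted mean rate over member epochs).
#' @export
extract_episodes <- function(timeline, gap_bridge_min = 0L) {
  stopifnot(inherits(timeline, "rhythm_timeline"),
            gap_bridge_min >= 0L)
  lab <- timeline$label
  if (anyNA(lab)) stop("timeline labels not populated; run label_minutes()",
                       call. = FALSE)
  n <- length(lab)
  eps <- list()
  i <- 1L
  while (i <= n) {
    if (lab[i] != "AF") {
      i <- i + 1L
      next
    }
    # open an episode at the first AF minute of a run
    members <- i
    j <- i + 1L
    gap <- 0L
    while (j <= n) {
      if (lab[j] == "AF") {
        members <- c(members, j)
        gap <- 0L
        j <- j + 1L
      } else if (lab[j] == "missing" && gap < gap_bridge_min) {
        gap <- gap + 1L
        j <- j + 1L
      } else {
        break
      }
    }
    w <- timeline$n_beats[members]
    rate <- if (sum(w) > 0) {
      sum(w * timeline$mean_rate_bpm[members]) / sum(w)
    } else {
      mean(timeline$mean_rate_bpm[members])
    }
    eps[[length(eps) + 1L]] <- data.frame(
      start_minute = timeline$minute_index[members[1L]],
      end_minute = timeline$minute_index[members[length(members)]] + 1L,
      duration_min = length(members),
      mean_rate_bpm = rate
    )
    i <- j
  }
  out <- if (length(eps)) do.call(rbind, eps) else data.frame(
    start_minute = integer(), end_minute = integer(),
    duration_min = integer(), mean_rate_bpm = numeric()
  )
  structure(out,
    gap_bridge_min = as.integer(gap_bridge_min),
    class = c("episode_list", "data.frame")
  )
}

#' @export
print.episode_list <- function(x, ...) {
  cat(sprintf("<episode_list> %d AF episode(s), gap bridge %d min\n",
              nrow(x), attr(x, "gap_bridge_min")))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Hourly AF counts by clock hour
#'
#' Tallies, for each of the 24 clock hours, either the AF-labeled minutes
#' falling in that hour (`unit = "af_minutes"`, the default) or the AF
#' episode onsets whose first epoch falls in that hour
#' (`unit = "episode_onsets"`). Clock hours containing no valid minute are
#' flagged via the `hour_available` attribute and are excluded from the
#' circadian summary statistics downstream.
#'
#' @param timeline A labeled `rhythm_timeline`.
#' @param unit Counting unit, `"af_minutes"` or `"episode_onsets"`.
#' @param gap_bridge_min Passed to [extract_episodes()] when counting onsets.
#' @return Numeric vector of length 24 (hours 0..23) with attribute
#'   `hour_available`, a logical vector marking hours with at least one
#'   valid minute.
#' @export
hourly_counts <- function(timeline, unit = c("af_minutes", "episode_onsets"),
                          gap_bridge_min = 0L) {
  unit <- match.arg(unit)
  lab <- timeline$label
  if (anyNA(lab)) stop("timeline labels not populated; run label_minutes()",
                       call. = FALSE)
  h <- numeric(24L)
  if (unit == "af_minutes") {
    af_hours <- timeline$clock_hour[lab == "AF"]
    if (length(af_hours)) {
      tab <- tabulate(af_hours + 1L, nbins = 24L)
      h <- as.numeric(tab)
    }
  } else {
    eps <- extract_episodes(timeline, gap_bridge_min)
    if (nrow(eps)) {
      onset_hour <- timeline$clock_hour[match(eps$start_minute,
                                              timeline$minute_index)]
      h <- as.numeric(tabulate(onset_hour + 1L, nbins = 24L))
    }
  }
  avail <- vapply(0:23, function(k) {
    any(timeline$valid & timeline$clock_hour == k)
  }, logical(1))
  attr(h, "hour_available") <- avail
  names(h) <- sprintf("h%02d", 0:23)
  h
}
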