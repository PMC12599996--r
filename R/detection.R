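#' Construct a beat series
#'
#' A beat series is the pulse-level abstraction of a continuous recording:
#' strictly increasing beat times (seconds) with derived inter-beat intervals
#' (IBIs, milliseconds) and a per-interval artifact mask marking
#' motion-corrupted stretches.
#'
#' @param subject_id Subject identifier.
#' @param beat_times_s Strictly increasing numeric vector of beat times in
#'   seconds from recording start.
#' @param artifact Logical vector of length `length(beat_times_s) - 1`
#'   (recycled if scalar) flagging each inter-beat interval as corrupted.
#' @return An object of class `beat_series` with elements `subject_id`,
#'   `beat_times_s`, `ibis_ms` and `artifact_mask`.
#' @export
beat_series <- function(subject_id, beat_times_s, artifact = FALSE) {
  stopifnot(is.numeric(beat_times_s))
  if (length(beat_times_s) >= 2L && any(diff(beat_times_s) <= 0)) {
    stop("beat times must be strictly increasing", call. = FALSE)
  }
  n_int <- max(length(beat_times_s) - 1L, 0L)
  structure(list(
    subject_id = as.character(subject_id),
    beat_times_s = as.numeric(beat_times_s),
    ibis_ms = diff(beat_times_s) * 1000,
    artifact_mask = rep_len(as.logical(artifact), n_int)
  ), class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf(
    "<beat_series> subject %s: %d beats over %.1f s (%.1f%% artifact intervals)\n",
    x$subject_id, length(x$beat_times_s),
    if (length(x$beat_times_s)) diff(range(x$beat_times_s)) else 0,
    if (length(x$artifact_mask)) 100 * mean(x$artifact_mask) else 0
  ))
  invisible(x)
}

#' Supported analysis window durations (seconds)
#' @keywords internal
SEGMENT_DURATIONS_S <- c(8L, 16L, 24L, 32L, 40L, 48L)

#' Tile a beat series into fixed-duration analysis windows
#'
#' Divides the recording into consecutive non-overlapping windows of one of
#' the supported durations (8, 16, 24, 32, 40 or 48 s). Tiling is
#' deterministic from time 0 by default; a randomised start offset is
#' available for data augmentation.
#'
#' @param series A `beat_series`.
#' @param duration_s Window length in seconds, one of 8, 16, 24, 32, 40, 48.
#' @param random_start If `TRUE`, offset the tiling by a uniform draw in
#'   `[0, duration_s)` (uses the current RNG state).
#' @return A data frame of window shells with columns `start_s`, `end_s`,
#'   `duration_s`, `n_intervals`, `n_masked`; empty when the series is
#'   shorter than one window.
#' @export
segment_series <- function(series, duration_s = 24L, random_start = FALSE) {
  stopifnot(inherits(series, "beat_series"))
  duration_s <- as.integer(duration_s)
  if (!duration_s %in% SEGMENT_DURATIONS_S) {
    stop("duration_s must be one of ", paste(SEGMENT_DURATIONS_S, collapse = ", "),
         call. = FALSE)
  }
  span <- if (length(series$beat_times_s)) max(series$beat_times_s) else 0
  offset <- if (random_start) stats::runif(1L, 0, duration_s) else 0
  n_win <- floor((span - offset) / duration_s)
  if (n_win < 1L) {
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      duration_s = integer(), n_intervals = integer(),
                      n_masked = integer()))
  }
  start_s <- offset + duration_s * (seq_len(n_win) - 1L)
  end_s <- start_s + duration_s
  # an interval belongs to the window containing its opening beat
  int_start <- series$beat_times_s[-length(series$beat_times_s)]
  win_of <- findInterval(int_start, c(start_s, end_s[n_win]))
  in_range <- win_of >= 1L & int_start < end_s[n_win] & int_start >= start_s[1L]
  tab_all <- tabulate(win_of[in_range], nbins = n_win)
  tab_masked <- tabulate(win_of[in_range & series$artifact_mask], nbins = n_win)
  data.frame(start_s = start_s, end_s = end_s,
             duration_s = duration_s,
             n_intervals = tab_all, n_masked = tab_masked)
}

#' Signal-quality gate for an analysis window
#'
#' A window passes when at most a fraction `q_max` of its inter-beat
#' intervals are artifact-masked and it contains at least `min_intervals`
#' intervals. Deterministic.
#'
#' @param n_intervals Number of inter-beat intervals in the window.
#' @param n_masked Number of those intervals flagged as artifact.
#' @param q_max Maximum tolerated artifact fraction (default 0.2).
#' @param min_intervals Minimum interval count (default 5).
#' @return Logical.
#' @export
quality_gate <- function(n_intervals, n_masked, q_max = 0.2,
                         min_intervals = 5L) {
  n_intervals >= min_intervals &
    ifelse(n_intervals > 0L, n_masked / n_intervals, 1) <= q_max
}

#' Default coefficients of the inter-beat irregularity classifier
#'
#' The window classifier is a fixed two-feature logistic rule over
#' (1) normalised RMSSD of successive IBI differences and (2) the Shannon
#' entropy (natural log, 8 fixed-width bins spanning -300..300 ms) of those
#' differences. The coefficients below were calibrated once on simulated
#' uniform-IBI fibrillation versus respiratory-modulated sinus rhythm and
#' then frozen; they are exposed so alternative operating points can be
#' supplied.
#'
#' @param a Weight on normalised RMSSD.
#' @param b Weight on the IBI-difference entropy.
#' @param c Intercept.
#' @return A named numeric vector `c(a =, b =, c =)`.
#' @export
af_classifier_coefs <- function(a = 28, b = 1.2, c = -7.5) {
  c(a = a, b = b, c = c)
}

#' Score an analysis window for AF-like inter-beat irregularity
#'
#' Computes `af_score = plogis(a * z1 + b * z2 + c)` where `z1` is the root
#' mean square of successive IBI differences divided by the mean IBI and
#' `z2` is the Shannon entropy of the successive-difference histogram
#' (8 equal bins over -300..300 ms, out-of-range differences clamped to the
#' edge bins). The window is called AF when the score exceeds 0.5.
#'
#' @param ibis_ms Numeric vector of unmasked inter-beat intervals (ms);
#'   at least 5 are required.
#' @param coefs Classifier coefficients, see [af_classifier_coefs()].
#' @return A list with `af_score` in `[0, 1]` and logical `af_call`.
#' @export
classify_segment <- function(ibis_ms, coefs = af_classifier_coefs()) {
  if (length(ibis_ms) < 5L) {
    stop("classify_segment needs at least 5 inter-beat intervals",
         call. = FALSE)
  }
  d <- diff(ibis_ms)
  z1 <- sqrt(mean(d^2)) / mean(ibis_ms)
  z2 <- ibi_diff_entropy(d)
  score <- stats::plogis(coefs[["a"]] * z1 + coefs[["b"]] * z2 + coefs[["c"]])
  list(af_score = unname(score), af_call = unname(score > 0.5))
}

# Shannon entropy (nats) of successive IBI differences over 8 fixed-width
# bins spanning [-300, 300] ms; differences beyond the range clamp to the
# edge bins so extreme irregularity still registers.
ibi_diff_entropy <- function(d, n_bins = 8L, range_ms = 300) {
  d <- pmin(pmax(d, -range_ms), range_ms - 1e-9)
  bin <- floor((d + range_ms) / (2 * range_ms / n_bins)) + 1L
  p <- tabulate(bin, nbins = n_bins) / length(d)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Fuse window decisions into a minute-epoch timeline
#'
#' Each beat inherits the AF call of the quality-passing window covering it;
#' per minute, `n_beats` counts beats lying in quality-passing windows and
#' `n_af_beats` those in AF-called windows. A minute is valid when at least
#' `min_coverage` of its 60 seconds are covered by quality-passing windows.
#' Minute labels are then derived with [label_minutes()] and refined by a
#' context pass ([smooth_labels()]) that re-labels any single discordant
#' minute whose flanking neighbours agree — the fusion-calibration step that
#' exploits the continuity of AF episodes.
#'
#' @param series A `beat_series`.
#' @param segments Window decisions: the shell from [segment_series()]
#'   augmented with logical `quality_ok` and `af_call` columns.
#' @param threshold AF-beat-fraction threshold for [label_minutes()].
#' @param min_coverage Minimum fraction of a minute covered by
#'   quality-passing windows for the minute to be valid (default 0.5).
#' @param smoothing_window Odd context-window width for [smooth_labels()];
#'   `0` disables smoothing.
#' @param start_clock_hour Local clock hour at recording start (0..23).
#' @return A labeled `rhythm_timeline` with `source = "device"`.
#' @export
fuse_to_minutes <- function(series, segments, threshold = 0.40,
                            min_coverage = 0.5, smoothing_window = 3L,
                            start_clock_hour = 0L) {
  stopifnot(inherits(series, "beat_series"))
  span <- if (length(series$beat_times_s)) max(series$beat_times_s) else 0
  n_min <- max(1L, ceiling(span / 60))
  ok <- !is.na(segments$quality_ok) & segments$quality_ok
  seg_ok <- segments[ok, , drop = FALSE]

  beats <- series$beat_times_s
  # covering quality-ok window of each beat (0 when uncovered)
  beat_win <- rep(0L, length(beats))
  if (nrow(seg_ok)) {
    idx <- findInterval(beats, seg_ok$start_s)
    hit <- idx >= 1L & beats < seg_ok$end_s[pmax(idx, 1L)]
    beat_win[hit] <- idx[hit]
  }
  covered <- beat_win > 0L
  beat_af <- covered & seg_ok$af_call[pmax(beat_win, 1L)]

  minute_of_beat <- pmin(floor(beats / 60), n_min - 1L) + 1L
  n_beats <- tabulate(minute_of_beat[covered], nbins = n_min)
  n_af <- tabulate(minute_of_beat[covered & beat_af], nbins = n_min)

  cov_s <- minute_coverage_seconds(seg_ok, n_min)
  valid <- cov_s / 60 >= min_coverage & n_beats > 0L
  rate <- ifelse(cov_s > 0, n_beats / cov_s * 60, 0)

  tl <- rhythm_timeline(
    subject_id = series$subject_id, source = "device",
    minute_index = seq_len(n_min) - 1L,
    clock_hour = (start_clock_hour + (seq_len(n_min) - 1L) %/% 60L) %% 24L,
    n_beats = n_beats, n_af_beats = n_af,
    mean_rate_bpm = rate, valid = valid
  )
  tl <- label_minutes(tl, threshold)
  if (smoothing_window >= 3L) tl <- smooth_labels(tl, smoothing_window)
  tl
}

# seconds of each minute covered by quality-ok windows (windows never overlap)
minute_coverage_seconds <- function(seg_ok, n_min) {
  cov <- numeric(n_min)
  for (i in seq_len(nrow(seg_ok))) {
    m0 <- floor(seg_ok$start_s[i] / 60)
    m1 <- ceiling(seg_ok$end_s[i] / 60) - 1L
    for (m in m0:m1) {
      if (m >= n_min) next
      lo <- max(seg_ok$start_s[i], m * 60)
      hi <- min(seg_ok$end_s[i], (m + 1L) * 60)
      if (hi > lo) cov[m + 1L] <- cov[m + 1L] + (hi - lo)
    }
  }
  cov
}

#' Context smoothing of minute labels
#'
#' Re-labels any single discordant minute whose neighbours within the
#' context window unanimously carry the opposite (non-missing) label; with
#' the default window of 3 this is majority-of-three smoothing. All flips
#' are computed from the original label sequence in one pass, so a run of
#' two or more identical labels is never altered.
#'
#' @param timeline A labeled `rhythm_timeline`.
#' @param window Odd integer window width, at least 3.
#' @return The timeline with smoothed labels.
#' @export
smooth_labels <- function(timeline, window = 3L) {
  stopifnot(window >= 3L, window %% 2L == 1L)
  lab <- timeline$label
  if (anyNA(lab)) stop("timeline labels not populated; run label_minutes()",
                       call. = FALSE)
  half <- (window - 1L) %/% 2L
  n <- length(lab)
  out <- lab
  for (i in seq_len(n)) {
    if (lab[i] == "missing") next
    lo <- i - half
    hi <- i + half
    if (lo < 1L || hi > n) next
    nb <- lab[c(lo:(i - 1L), (i + 1L):hi)]
    if (all(nb == nb[1L]) && nb[1L] != "missing" && nb[1L] != lab[i]) {
      out[i] <- nb[1L]
    }
  }
  timeline$label <- out
  timeline
}

#' Run the windowed AF detector on a beat series
#'
#' End-to-end detection for one subject: tile the recording into windows of
#' `duration_s` seconds, apply the signal-quality gate, score each passing
#' window with the irregularity classifier, and fuse the window calls into a
#' labeled minute-epoch device timeline.
#'
#' @inheritParams segment_series
#' @inheritParams fuse_to_minutes
#' @param q_max,min_intervals Quality-gate parameters, see [quality_gate()].
#' @param coefs Classifier coefficients, see [af_classifier_coefs()].
#' @return A labeled `rhythm_timeline` with `source = "device"`.
#' @export
detect_timeline <- function(series, duration_s = 24L, q_max = 0.2,
                            min_intervals = 5L,
                            coefs = af_classifier_coefs(),
                            threshold = 0.40, min_coverage = 0.5,
                            smoothing_window = 3L, start_clock_hour = 0L) {
  segs <- segment_series(series, duration_s)
  if (nrow(segs) == 0L) {
    stop("beat series is shorter than one analysis window", call. = FALSE)
  }
  segs$quality_ok <- quality_gate(segs$n_intervals, segs$n_masked,
                                  q_max, min_intervals)
  segs$af_score <- NA_real_
  segs$af_call <- NA
  int_start <- series$beat_times_s[-length(series$beat_times_s)]
  for (i in which(segs$quality_ok)) {
    in_win <- int_start >= segs$start_s[i] & int_start < segs$end_s[i] &
      !series$artifact_mask
    if (sum(in_win) < min_intervals) {
      # masking left too few clean intervals to score the window
      segs$quality_ok[i] <- FALSE
      next
    }
    res <- classify_segment(series$ibis_ms[in_win], coefs)
    segs$af_score[i] <- res$af_score
    segs$af_call[i] <- res$af_call
  }
  fuse_to_minutes(series, segs, threshold, min_coverage,
                  smoothing_window, start_clock_hour)
}
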