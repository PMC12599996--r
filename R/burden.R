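#' @title AF burden metric families
#' @description
#' Five metric families summarise a labeled minute-epoch rhythm timeline:
#' duration ratios (M1), episode-frequency ratios (M2), AF density (M3),
#' circadian variability statistics (M4), and rapid-ventricular-rate
#' proportions (M5). All "monitoring time" / "total measurements"
#' denominators count valid minutes only.
#' @name burden-metrics
NULL

check_monitored <- function(timeline) {
  t_valid <- monitoring_minutes(timeline)
  if (t_valid == 0L) {
    stop("no valid minutes: burden metrics are undefined", call. = FALSE)
  }
  t_valid
}

#' M1: AF duration as a proportion of total monitoring time
#'
#' Total duration of AF episodes lasting at least `min_episode_duration_min`
#' minutes, divided by the valid-minute count. The duration filters 1, 7 and
#' 61 minutes yield the all-episode, "over 6 minutes" and "over 1 hour" rows
#' (strict inequalities at 1-minute resolution).
#'
#' @param timeline A labeled `rhythm_timeline`.
#' @param min_episode_duration_min Minimum qualifying episode duration
#'   (minutes, inclusive).
#' @param gap_bridge_min Passed to [extract_episodes()].
#' @return A proportion in `[0, 1]`.
#' @export
m1_duration <- function(timeline, min_episode_duration_min = 1L,
                        gap_bridge_min = 0L) {
  t_valid <- check_monitored(timeline)
  eps <- extract_episodes(timeline, gap_bridge_min)
  keep <- eps$duration_min >= min_episode_duration_min
  sum(eps$duration_min[keep]) / t_valid
}

#' M2: AF episode count as a proportion of total measurements
#'
#' Number of AF episodes lasting at least `min_episode_duration_min` minutes
#' divided by the number of valid minute epochs (one epoch = one
#' measurement).
#'
#' @inheritParams m1_duration
#' @return A proportion in `[0, 1]`.
#' @export
m2_episode_ratio <- function(timeline, min_episode_duration_min = 1L,
                             gap_bridge_min = 0L) {
  t_valid <- check_monitored(timeline)
  eps <- extract_episodes(timeline, gap_bridge_min)
  sum(eps$duration_min >= min_episode_duration_min) / t_valid
}

#' M3: AF density
#'
#' Measures how clustered the AF burden is in time. Valid minutes are
#' compacted to a contiguous axis of length `T`; `C(t)` is the
#' piecewise-linear cumulative fraction of all AF minutes accrued by time
#' `t`, and `U(t) = t/T` the uniform-accrual line. The raw area
#' `A = integral of |C(t) - U(t)|` is evaluated exactly on the
#' piecewise-linear grid and normalised by `T * (1 - b) / 2` — the maximum,
#' attained when all AF falls in one contiguous block at a record boundary —
#' so density lies in `[0, 1]`: 0 for evenly spread AF, 1 for a single
#' boundary block. Defined as 0 when the burden fraction `b` is 0 or 1.
#'
#' @param timeline A labeled `rhythm_timeline`.
#' @return Density in `[0, 1]`.
#' @export
m3_density <- function(timeline) {
  check_monitored(timeline)
  lab <- timeline$label[timeline$valid]
  af <- lab == "AF"
  t_total <- length(af)
  n_af <- sum(af)
  if (n_af == 0L || n_af == t_total) {
    return(0)
  }
  b <- n_af / t_total
  # knots of C - U at minute boundaries
  d <- cumsum(af) / n_af - seq_len(t_total) / t_total
  d <- c(0, d)
  area <- 0
  for (i in seq_len(t_total)) {
    d0 <- d[i]
    d1 <- d[i + 1L]
    if (d0 * d1 >= 0) {
      area <- area + (abs(d0) + abs(d1)) / 2
    } else {
      # sign change inside the unit interval: two triangles
      area <- area + (d0^2 + d1^2) / (2 * abs(d1 - d0))
    }
  }
  # guard against floating-point overshoot at the extremes
  min(max(area / (t_total * (1 - b) / 2), 0), 1)
}

#' M4: circadian variability statistics of hourly AF counts
#'
#' Given the hourly AF counts `h` (see [hourly_counts()]), computes
#' * `sd_hourly` — sample standard deviation of `h`;
#' * `variability` — `sd(h) / mean(h)`, the SD normalised by the 24-hour
#'   mean AF frequency (0 when the mean is 0);
#' * `variability_day`, `variability_night` — the same statistic restricted
#'   to the daytime (06:00-22:00) and nighttime (22:00-06:00) hours;
#' * `arv` — average real variability, the mean of the SD and the mean
#'   absolute deviation of `h` about its mean;
#' * `vom_pct` — variation of the mean, `|mean(h_day) - mean(h_night)| /
#'   mean(h) * 100` (per cent; set `signed_vom = TRUE` to keep the sign of
#'   the day-night difference).
#'
#' Hours flagged unavailable (no valid minute) are excluded from every
#' statistic. All statistics are 0 (with `flag_zero` set) when every
#' available hour has zero count.
#'
#' @param h Numeric vector of 24 hourly counts with attribute
#'   `hour_available` (as from [hourly_counts()]); a bare length-24 vector
#'   is treated as fully available.
#' @param day_hours,night_hours Integer clock hours defining the day and
#'   night windows.
#' @param signed_vom Report the signed day-night variation instead of its
#'   absolute value.
#' @return A list with `sd_hourly`, `variability`, `variability_day`,
#'   `variability_night`, `arv`, `vom_pct`, and logical flags `flag_zero`
#'   (all counts zero) and `flag_vom_undefined` (day or night window has
#'   fewer than one available hour).
#' @export
m4_stats <- function(h, day_hours = 6:21, night_hours = c(22L, 23L, 0:5),
                     signed_vom = FALSE) {
  stopifnot(length(h) == 24L)
  avail <- attr(h, "hour_available")
  if (is.null(avail)) avail <- rep(TRUE, 24L)
  hours <- 0:23
  if (sum(avail) < 2L) {
    stop("fewer than 2 available hours: circadian statistics are undefined",
         call. = FALSE)
  }
  ha <- h[avail]
  flag_zero <- all(ha == 0)

  cv <- function(x) {
    if (length(x) < 2L || mean(x) == 0) return(0)
    stats::sd(x) / mean(x)
  }
  sd_hourly <- if (flag_zero) 0 else stats::sd(ha)
  variability <- if (flag_zero) 0 else cv(ha)
  day_avail <- avail & hours %in% day_hours
  night_avail <- avail & hours %in% night_hours
  variability_day <- if (flag_zero) 0 else cv(h[day_avail])
  variability_night <- if (flag_zero) 0 else cv(h[night_avail])
  mad_mean <- if (flag_zero) 0 else mean(abs(ha - mean(ha)))
  arv <- (sd_hourly + mad_mean) / 2

  flag_vom <- sum(day_avail) < 1L || sum(night_avail) < 1L
  vom <- 0
  if (!flag_vom && !flag_zero && mean(ha) > 0) {
    diffm <- mean(h[day_avail]) - mean(h[night_avail])
    vom <- (if (signed_vom) diffm else abs(diffm)) / mean(ha) * 100
  }
  list(sd_hourly = sd_hourly, variability = variability,
       variability_day = variability_day,
       variability_night = variability_night,
       arv = arv, vom_pct = vom,
       flag_zero = flag_zero, flag_vom_undefined = flag_vom)
}

#' M5: rapid ventricular rate (RVR) proportions
#'
#' RVR minutes are AF-labeled valid minutes whose mean pulse rate strictly
#' exceeds `rate_threshold_bpm` (default 120 bpm). `duration_ratio` divides
#' their count by the total valid minutes; `count_ratio` is the same
#' quantity with the minute epoch as the measurement unit (identical at
#' 1-minute resolution). With `episode_level = TRUE`, `count_ratio` instead
#' reports the fraction of AF episodes whose beat-weighted mean rate exceeds
#' the threshold.
#'
#' @param timeline A labeled `rhythm_timeline`.
#' @param rate_threshold_bpm Rate cut point (strict, bpm).
#' @param episode_level Use the episode-level count variant.
#' @param gap_bridge_min Passed to [extract_episodes()] for the episode
#'   variant.
#' @return A list with `duration_ratio` and `count_ratio`, both in `[0, 1]`.
#' @export
m5_rvr <- function(timeline, rate_threshold_bpm = 120,
                   episode_level = FALSE, gap_bridge_min = 0L) {
  t_valid <- check_monitored(timeline)
  if (anyNA(timeline$label)) {
    stop("timeline labels not populated; run label_minutes()", call. = FALSE)
  }
  rvr <- timeline$valid & timeline$label == "AF" &
    timeline$mean_rate_bpm > rate_threshold_bpm
  duration_ratio <- sum(rvr) / t_valid
  if (episode_level) {
    eps <- extract_episodes(timeline, gap_bridge_min)
    count_ratio <- if (nrow(eps) == 0L) 0 else {
      sum(eps$mean_rate_bpm > rate_threshold_bpm) / nrow(eps)
    }
  } else {
    count_ratio <- sum(rvr) / t_valid
  }
  list(duration_ratio = duration_ratio, count_ratio = count_ratio)
}

#' The 15 burden-profile metric names
#'
#' Column order of the per-subject burden profile, used by the concordance
#' table and by the profile CSV writer.
#' @return Character vector of length 15.
#' @export
burden_metric_names <- function() {
  c("m1_duration_ratio", "m1_duration_ratio_gt6min", "m1_duration_ratio_gt1h",
    "m2_episode_ratio", "m2_episode_ratio_gt6min", "m2_episode_ratio_gt1h",
    "m3_density",
    "m4_sd_hourly", "m4_variability", "m4_variability_day",
    "m4_variability_night", "m4_arv", "m4_vom_pct",
    "m5_rvr_duration_ratio", "m5_rvr_count_ratio")
}

#' Compute the full per-subject burden profile
#'
#' Assembles all fifteen burden statistics — the three M1 duration ratios
#' (all episodes, episodes over 6 min, episodes over 1 h), the three M2
#' episode-frequency ratios with the same duration filters, M3 density, the
#' six M4 circadian statistics, and the two M5 RVR proportions — for one
#' labeled timeline. Deterministic.
#'
#' @param timeline A labeled `rhythm_timeline`.
#' @param gap_bridge_min Episode gap bridging (minutes).
#' @param rate_threshold_bpm RVR rate cut point (bpm).
#' @param hourly_unit Counting unit for the circadian statistics, see
#'   [hourly_counts()].
#' @param signed_vom Keep the sign of the day-night variation of the mean.
#' @param episode_level_rvr Episode-level M5 count variant.
#' @return A one-row data frame of class `burden_profile` with the 15
#'   metric columns of [burden_metric_names()], degenerate-case flag columns
#'   (`flag_no_af`, `flag_zero_hourly`, `flag_vom_undefined`), and
#'   `subject_id` / `source` identifiers.
#' @export
burden_profile <- function(timeline, gap_bridge_min = 0L,
                           rate_threshold_bpm = 120,
                           hourly_unit = c("af_minutes", "episode_onsets"),
                           signed_vom = FALSE, episode_level_rvr = FALSE) {
  hourly_unit <- match.arg(hourly_unit)
  check_monitored(timeline)
  h <- hourly_counts(timeline, hourly_unit, gap_bridge_min)
  hours_ok <- sum(attr(h, "hour_available")) >= 2L
  m4 <- if (hours_ok) {
    m4_stats(h, signed_vom = signed_vom)
  } else {
    # recording spans fewer than two clock hours: circadian statistics
    # degenerate to zero and are flagged
    list(sd_hourly = 0, variability = 0, variability_day = 0,
         variability_night = 0, arv = 0, vom_pct = 0,
         flag_zero = TRUE, flag_vom_undefined = TRUE)
  }
  m5 <- m5_rvr(timeline, rate_threshold_bpm, episode_level_rvr,
               gap_bridge_min)
  no_af <- !any(timeline$valid & timeline$label == "AF")
  out <- data.frame(
    subject_id = timeline_subject(timeline),
    source = timeline_source(timeline),
    m1_duration_ratio = m1_duration(timeline, 1L, gap_bridge_min),
    m1_duration_ratio_gt6min = m1_duration(timeline, 7L, gap_bridge_min),
    m1_duration_ratio_gt1h = m1_duration(timeline, 61L, gap_bridge_min),
    m2_episode_ratio = m2_episode_ratio(timeline, 1L, gap_bridge_min),
    m2_episode_ratio_gt6min = m2_episode_ratio(timeline, 7L, gap_bridge_min),
    m2_episode_ratio_gt1h = m2_episode_ratio(timeline, 61L, gap_bridge_min),
    m3_density = m3_density(timeline),
    m4_sd_hourly = m4$sd_hourly,
    m4_variability = m4$variability,
    m4_variability_day = m4$variability_day,
    m4_variability_night = m4$variability_night,
    m4_arv = m4$arv,
    m4_vom_pct = m4$vom_pct,
    m5_rvr_duration_ratio = m5$duration_ratio,
    m5_rvr_count_ratio = m5$count_ratio,
    flag_no_af = no_af,
    flag_zero_hourly = m4$flag_zero,
    flag_vom_undefined = m4$flag_vom_undefined,
    flag_hours_insufficient = !hours_ok,
    stringsAsFactors = FALSE
  )
  class(out) <- c("burden_profile", "data.frame")
  out
}

#' @export
print.burden_profile <- function(x, ...) {
  cat(sprintf("<burden_profile> subject %s (%s)\n",
              x$subject_id[1L], x$source[1L]))
  vals <- unlist(x[1L, burden_metric_names()])
  print(round(vals, 4))
  invisible(x)
}

#' Burden profiles for a set of timelines
#'
#' @param timelines List of labeled `rhythm_timeline` objects.
#' @param ... Passed to [burden_profile()].
#' @return A data frame with one profile row per timeline.
#' @export
cohort_profiles <- function(timelines, ...) {
  rows <- lapply(timelines, burden_profile, ...)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}
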