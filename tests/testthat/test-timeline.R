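test_that("minute labeling applies the strict AF-beat-fraction rule", {
  tl <- rhythm_timeline(
    "S1", "gold", minute_index = 0:2, clock_hour = c(0L, 0L, 0L),
    n_beats = c(60L, 60L, 10L), n_af_beats = c(25L, 24L, 9L),
    mean_rate_bpm = c(60, 60, 60), valid = c(TRUE, TRUE, FALSE)
  )
  tl <- label_minutes(tl, 0.40)
  # 25/60 > 0.40 is AF; 24/60 = 0.40 exactly stays non-AF; invalid is missing
  expect_identical(timeline_labels(tl), c("AF", "non-AF", "missing"))
  # idempotent
  expect_identical(timeline_labels(label_minutes(tl, 0.40)),
                   timeline_labels(tl))
})

test_that("a valid minute without beats is rejected as a data error", {
  tl <- rhythm_timeline("S1", "gold", minute_index = 0L, clock_hour = 0L,
                        n_beats = 0L, n_af_beats = 0L, mean_rate_bpm = 0,
                        valid = TRUE)
  expect_error(label_minutes(tl), "n_beats = 0")
})

test_that("labeling is monotone in the threshold", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 50L
    nb <- sample(30:90, n, replace = TRUE)
    tl <- rhythm_timeline(
      "S1", "gold", minute_index = seq_len(n) - 1L,
      clock_hour = rep(0L, n), n_beats = nb,
      n_af_beats = vapply(nb, function(b) sample.int(b + 1L, 1L) - 1L,
                          integer(1)),
      mean_rate_bpm = nb, valid = TRUE
    )
    taus <- sort(runif(2))
    lo <- timeline_labels(label_minutes(tl, taus[1]))
    hi <- timeline_labels(label_minutes(tl, taus[2]))
    # raising the threshold never converts non-AF to AF
    expect_true(all(!(lo == "non-AF" & hi == "AF")))
  }
})

test_that("episode extraction matches the definition on worked cases", {
  eps <- extract_episodes(make_timeline(c("N", "A", "A", "N", "A")))
  expect_equal(eps$start_minute, c(1L, 4L))
  expect_equal(eps$end_minute, c(3L, 5L))
  expect_equal(eps$duration_min, c(2L, 1L))

  # a bridged gap joins the runs but adds no duration
  eps2 <- extract_episodes(make_timeline(c("A", "M", "A")), gap_bridge_min = 1L)
  expect_equal(nrow(eps2), 1L)
  expect_equal(eps2$duration_min, 2L)
  # without bridging the gap splits them
  expect_equal(nrow(extract_episodes(make_timeline(c("A", "M", "A")))), 2L)
  # a non-AF minute always terminates a run, whatever the bridge
  expect_equal(nrow(extract_episodes(make_timeline(c("A", "N", "A")),
                                     gap_bridge_min = 5L)), 2L)
})

test_that("episode extraction agrees with a brute-force run scan", {
  set.seed(21)
  for (rep in 1:300) {
    labs <- random_label_string(sample(5:40, 1L))
    bridge <- sample(0:3, 1L)
    tl <- make_timeline(labs)
    got <- extract_episodes(tl, bridge)
    want <- bf_episodes(labs, bridge)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start_minute, vapply(want, min, integer(1)) - 1L)
      expect_equal(got$end_minute, vapply(want, max, integer(1)))
      expect_equal(got$duration_min, lengths(want))
    }
  }
})

test_that("episode mean rate is beat-count weighted", {
  tl <- make_timeline(c("A", "A"), rates = c(100, 150))
  eps <- extract_episodes(tl)
  w <- c(100L, 150L) # n_beats = round(rate)
  expect_equal(eps$mean_rate_bpm, sum(w * c(100, 150)) / sum(w))
})

test_that("hourly counts tally AF minutes and episode onsets by clock hour", {
  all_n <- make_timeline(strrep("N", 100))
  expect_equal(unname(hourly_counts(all_n)), rep(0, 24), ignore_attr = TRUE)

  # one 10-minute episode entirely inside clock hour 3
  labs <- c(rep("N", 180), rep("A", 10), rep("N", 50))
  tl <- make_timeline(labs) # minutes 180..189 fall in hour 3
  h <- hourly_counts(tl)
  expect_equal(unname(h[4]), 10)
  expect_equal(sum(h), 10)
  h_on <- hourly_counts(tl, unit = "episode_onsets")
  expect_equal(unname(h_on[4]), 1)
  expect_equal(sum(h_on), 1)
})

test_that("hourly AF-minute counts match a brute-force tally and sum to the total", {
  set.seed(31)
  for (rep in 1:100) {
    labs <- random_label_string(sample(60:400, 1L))
    start <- sample(0:23, 1L)
    tl <- make_timeline(labs, clock_start = start)
    h <- hourly_counts(tl)
    want <- vapply(0:23, function(k) {
      sum(tl$label == "AF" & tl$clock_hour == k)
    }, numeric(1))
    expect_equal(unname(h), want, ignore_attr = TRUE)
    expect_equal(sum(h), sum(labs == "A"))
    # hours with no valid minute are flagged unavailable
    avail <- attr(h, "hour_available")
    expect_equal(avail, vapply(0:23, function(k) {
      any(tl$valid & tl$clock_hour == k)
    }, logical(1)))
  }
})

test_that("episodes with no bridging partition the AF minutes", {
  set.seed(41)
  for (rep in 1:50) {
    labs <- random_label_string(sample(10:80, 1L))
    tl <- make_timeline(labs)
    eps <- extract_episodes(tl, 0L)
    expect_equal(sum(eps$duration_min), sum(labs == "A"))
    if (nrow(eps) > 1L) {
      expect_true(all(diff(eps$start_minute) > 0))
      expect_true(all(eps$start_minute[-1L] >= head(eps$end_minute, -1L)))
    }
  }
})

test_that("timeline CSV round-trips including invalid minutes", {
  tl1 <- make_timeline(c("A", "M", "N", "A"), subject_id = "P1")
  tl2 <- make_timeline(strrep("N", 5), subject_id = "P2", source = "device")
  path <- tempfile(fileext = ".csv")
  write_timelines(list(tl1, tl2), path)
  back <- read_timelines(path)
  expect_named(back, c("P1.gold", "P2.device"))
  got <- label_minutes(back[["P1.gold"]])
  expect_identical(timeline_labels(got), timeline_labels(tl1))
  expect_equal(got$n_beats[got$valid], tl1$n_beats[tl1$valid])
  expect_equal(monitoring_minutes(got), monitoring_minutes(tl1))
})

test_that("timeline validity rules reject malformed input", {
  expect_error(rhythm_timeline("S", "gold", minute_index = c(0L, 0L),
                               clock_hour = c(0L, 0L), n_beats = c(1L, 1L),
                               n_af_beats = c(0L, 0L),
                               mean_rate_bpm = c(60, 60)),
               "strictly increasing")
  expect_error(rhythm_timeline("S", "gold", minute_index = 0L,
                               clock_hour = 24L, n_beats = 1L,
                               n_af_beats = 0L, mean_rate_bpm = 60),
               "clock_hour")
  expect_error(rhythm_timeline("S", "gold", minute_index = 0L,
                               clock_hour = 0L, n_beats = 10L,
                               n_af_beats = 11L, mean_rate_bpm = 60),
               "n_af_beats")
})
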