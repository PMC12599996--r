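#' Configuration of the synthetic paroxysmal-AF cohort generator
#'
#' Defines a two-state (AF / non-AF) per-minute semi-Markov rhythm process
#' with geometric dwell times, a circadian multiplier on the AF entry rate,
#' beat-count and pulse-rate models per state, and an imperfect per-minute
#' observation channel (sensitivity, specificity, output rate) standing in
#' for a wearable device validated against a gold-standard annotation.
#'
#' Defaults emulate a 24-hour simultaneous monitoring session in a
#' paroxysmal-AF cohort: mean AF episode length 40 minutes, stationary
#' burden around 9% before subject-level frailty, more AF entry during the
#' day than at night, AF minutes carrying around 90% AF beats, elevated and
#' dispersed AF rates with a configurable fraction of rapid-ventricular-rate
#' (>120 bpm) minutes, and a device channel with per-minute sensitivity
#' 0.915, specificity 0.972 and output rate 0.866.
#'
#' @param n_subjects Number of subjects.
#' @param minutes_per_subject Minutes per recording (default 1440 = 24 h).
#' @param start_clock_hour Local clock hour at recording start.
#' @param af_entry_rate Per-minute probability of entering AF from non-AF
#'   (before circadian and frailty multipliers).
#' @param af_exit_rate Per-minute probability of leaving AF (geometric dwell,
#'   mean episode length `1 / af_exit_rate` minutes).
#' @param circadian_multiplier Length-24 multiplier on the entry rate by
#'   clock hour (day/night asymmetry).
#' @param frailty_sd SD of the subject-level log-normal frailty on the entry
#'   rate; 0 disables heterogeneity (all subjects share one process).
#' @param af_beat_frac_shape Beta shape parameters `c(a, b)` of the AF-beat
#'   fraction in AF minutes (mean about 0.9).
#' @param nonaf_beat_frac_shape Beta shapes of the AF-beat fraction in
#'   non-AF minutes (mean about 0.05).
#' @param sinus_rate_mean,sinus_rate_sd Pulse rate (bpm) in non-AF minutes.
#' @param af_rate_mean,af_rate_sd Pulse rate (bpm) in AF minutes below the
#'   RVR threshold.
#' @param p_rvr Probability that an AF minute exceeds 120 bpm.
#' @param sensitivity,specificity Per-minute detection operating point of
#'   the device channel.
#' @param output_rate Probability the device emits a valid minute.
#' @param beat_mode Also synthesise a pulse-level `beat_series` for the
#'   windowed detector (sinusoidally modulated sinus IBIs versus dispersed
#'   AF IBIs).
#' @param sinus_ibi_jitter Fractional SD of sinus IBI jitter (beat mode).
#' @param sinus_resp_mod Fractional amplitude of respiratory IBI modulation
#'   (beat mode).
#' @param af_ibi_range_ms AF IBI uniform range in ms (beat mode).
#' @param artifact_rate Per-interval probability of motion artifact
#'   (beat mode).
#' @param seed Master seed (mandatory).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 50L,
                             minutes_per_subject = 1440L,
                             start_clock_hour = 8L,
                             af_entry_rate = 1 / 400,
                             af_exit_rate = 1 / 40,
                             circadian_multiplier =
                               ifelse(0:23 %in% 6:21, 1.3, 0.55),
                             frailty_sd = 1,
                             af_beat_frac_shape = c(18, 2),
                             nonaf_beat_frac_shape = c(1, 19),
                             sinus_rate_mean = 75, sinus_rate_sd = 8,
                             af_rate_mean = 100, af_rate_sd = 12,
                             p_rvr = 0.15,
                             sensitivity = 0.915, specificity = 0.972,
                             output_rate = 0.866,
                             beat_mode = FALSE,
                             sinus_ibi_jitter = 0.02,
                             sinus_resp_mod = 0.05,
                             af_ibi_range_ms = c(400, 1200),
                             artifact_rate = 0,
                             seed) {
  if (missing(seed)) stop("a master seed is mandatory", call. = FALSE)
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    minutes_per_subject = as.integer(minutes_per_subject),
    start_clock_hour = as.integer(start_clock_hour),
    af_entry_rate = af_entry_rate, af_exit_rate = af_exit_rate,
    circadian_multiplier = as.numeric(circadian_multiplier),
    frailty_sd = frailty_sd,
    af_beat_frac_shape = af_beat_frac_shape,
    nonaf_beat_frac_shape = nonaf_beat_frac_shape,
    sinus_rate_mean = sinus_rate_mean, sinus_rate_sd = sinus_rate_sd,
    af_rate_mean = af_rate_mean, af_rate_sd = af_rate_sd,
    p_rvr = p_rvr,
    sensitivity = sensitivity, specificity = specificity,
    output_rate = output_rate,
    beat_mode = isTRUE(beat_mode),
    sinus_ibi_jitter = sinus_ibi_jitter,
    sinus_resp_mod = sinus_resp_mod,
    af_ibi_range_ms = af_ibi_range_ms,
    artifact_rate = artifact_rate,
    seed = as.integer(seed)
  )
  probs <- c(cfg$sensitivity, cfg$specificity, cfg$output_rate, cfg$p_rvr,
             cfg$artifact_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$af_entry_rate < 0 || cfg$af_exit_rate <= 0) {
    stop("rates must be nonnegative (exit rate positive)", call. = FALSE)
  }
  if (length(cfg$circadian_multiplier) != 24L ||
        any(cfg$circadian_multiplier < 0)) {
    stop("circadian_multiplier must be 24 nonnegative values", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Simulate one paired (gold, device) subject
#'
#' Draws the latent minute-state sequence from the circadian-modulated
#' two-state chain, synthesises per-minute beat counts, AF-beat fractions
#' and rates per state, and derives the device stream from the gold labels
#' through the per-minute observation channel: the gold label is kept with
#' probability `sensitivity` (AF minutes) or `specificity` (non-AF minutes)
#' and flipped otherwise, then the minute is masked invalid with
#' probability `1 - output_rate`. Beat fractions are drawn consistently
#' with each stream's label, so re-deriving labels with [label_minutes()]
#' reproduces the channel exactly. Deterministic for a fixed seed.
#'
#' @param config A `synthetic_config`.
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier for the subject.
#' @return A list of class `subject_pair` with elements `gold` and `device`
#'   (labeled `rhythm_timeline`s), `truth_profile` (the gold
#'   [burden_profile()]), and, in beat mode, `beats` (a [beat_series()]).
#' @export
simulate_subject <- function(config, subject_seed, subject_id = "S1") {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subject_seed)
  n <- config$minutes_per_subject
  hours <- (config$start_clock_hour + (seq_len(n) - 1L) %/% 60L) %% 24L

  frailty <- if (config$frailty_sd > 0) {
    stats::rlnorm(1L, meanlog = -config$frailty_sd^2 / 2,
                  sdlog = config$frailty_sd)
  } else {
    1
  }
  p_enter <- pmin(1, config$af_entry_rate * frailty *
                    config$circadian_multiplier[hours + 1L])
  p_exit <- config$af_exit_rate

  state <- logical(n) # TRUE = AF
  p0 <- mean(p_enter) / (mean(p_enter) + p_exit)
  u <- stats::runif(n)
  state[1L] <- u[1L] < p0
  for (i in 2L:n) {
    state[i] <- if (state[i - 1L]) u[i] >= p_exit else u[i] < p_enter[i]
  }

  gold <- make_stream(state, hours, config, subject_id, "gold",
                      valid = rep(TRUE, n))

  # the device shares the physiology of the gold minute; only flipped
  # minutes get their AF-beat count redrawn on the other side of the rule
  dev_state <- ifelse(state,
                      stats::runif(n) < config$sensitivity,
                      stats::runif(n) >= config$specificity)
  dev_valid <- stats::runif(n) < config$output_rate
  dev_n_af <- gold$n_af_beats
  chg <- dev_state != state
  if (any(chg)) {
    dev_n_af[chg] <- draw_n_af(dev_state[chg], gold$n_beats[chg], config)
  }
  device <- label_minutes(rhythm_timeline(
    subject_id = subject_id, source = "device",
    minute_index = gold$minute_index, clock_hour = hours,
    n_beats = gold$n_beats, n_af_beats = dev_n_af,
    mean_rate_bpm = gold$mean_rate_bpm, valid = dev_valid
  ), 0.40)

  out <- list(gold = gold, device = device,
              truth_profile = burden_profile(gold))
  if (config$beat_mode) out$beats <- simulate_beats(state, config, subject_id)
  class(out) <- "subject_pair"
  out
}

# per-minute beat counts, AF-beat fractions and rates for a label sequence;
# fractions are constrained away from the 0.40 decision boundary so derived
# labels reproduce the intended sequence exactly
make_stream <- function(state, hours, config, subject_id, source, valid) {
  n <- length(state)
  n_af_state <- sum(state)
  rate <- numeric(n)
  rate[!state] <- stats::rnorm(n - n_af_state, config$sinus_rate_mean,
                               config$sinus_rate_sd)
  if (n_af_state > 0L) {
    rvr <- stats::runif(n_af_state) < config$p_rvr
    r <- numeric(n_af_state)
    r[rvr] <- 121 + stats::rexp(sum(rvr), rate = 1 / 12)
    r[!rvr] <- truncnorm_below(sum(!rvr), config$af_rate_mean,
                               config$af_rate_sd, 120)
    rate[state] <- r
  }
  rate <- pmax(rate, 30)
  n_beats <- pmax(1L, as.integer(round(rate)))
  n_af <- draw_n_af(state, n_beats, config)
  tl <- rhythm_timeline(
    subject_id = subject_id, source = source,
    minute_index = seq_len(n) - 1L, clock_hour = hours,
    n_beats = n_beats, n_af_beats = n_af,
    mean_rate_bpm = rate, valid = valid
  )
  label_minutes(tl, 0.40)
}

# AF-beat counts per minute, drawn per latent state; realised fractions are
# constrained to the intended side of the strict 0.40 labeling rule so that
# derived labels reproduce the state sequence exactly
draw_n_af <- function(state, n_beats, config) {
  n <- length(state)
  frac <- numeric(n)
  if (any(state)) {
    frac[state] <- pmin(pmax(stats::rbeta(sum(state),
                                          config$af_beat_frac_shape[1L],
                                          config$af_beat_frac_shape[2L]),
                             0.45), 1)
  }
  if (any(!state)) {
    frac[!state] <- pmin(stats::rbeta(sum(!state),
                                      config$nonaf_beat_frac_shape[1L],
                                      config$nonaf_beat_frac_shape[2L]), 0.35)
  }
  n_af <- as.integer(ceiling(frac * n_beats))
  n_af[state] <- pmax(n_af[state], as.integer(ceiling(0.45 * n_beats[state])))
  n_af[!state] <- pmin(n_af[!state],
                       as.integer(floor(0.35 * n_beats[!state])))
  n_af
}

truncnorm_below <- function(n, mean, sd, upper) {
  if (n == 0L) return(numeric())
  p_up <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, 0, p_up), mean, sd)
}

# pulse-level synthesis for the windowed detector: sinus minutes carry
# respiratory-modulated quasi-regular IBIs, AF minutes dispersed IBIs
simulate_beats <- function(state, config, subject_id) {
  times <- numeric(0)
  artifacts <- logical(0)
  t <- 0
  phase <- 0
  for (i in seq_along(state)) {
    t_end <- i * 60
    while (t < t_end) {
      if (state[i]) {
        ibi <- stats::runif(1L, config$af_ibi_range_ms[1L],
                            config$af_ibi_range_ms[2L]) / 1000
      } else {
        base <- 60 / config$sinus_rate_mean
        phase <- phase + 2 * pi * base / 4 # ~4 s respiratory cycle
        ibi <- base * (1 + config$sinus_resp_mod * sin(phase) +
                         stats::rnorm(1L, 0, config$sinus_ibi_jitter))
        ibi <- max(ibi, 0.3)
      }
      t <- t + ibi
      times <- c(times, t)
      artifacts <- c(artifacts, stats::runif(1L) < config$artifact_rate)
    }
  }
  beat_series(subject_id, times, artifact = artifacts[-1L])
}

#' Simulate a paired cohort
#'
#' Derives one reproducible seed per subject from the master seed and
#' simulates each subject independently. The manifest records the resolved
#' configuration, a deterministic hash of it, and every per-subject seed,
#' so a run is reproducible from its manifest alone.
#'
#' @param config A `synthetic_config`.
#' @return A list of class `synthetic_cohort` with `pairs` (list of
#'   `subject_pair`, named by subject id) and `manifest`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_subjects
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, max(n, 1L))[seq_len(n)]
  ids <- sprintf("S%03d", seq_len(n))
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    pairs[[i]] <- simulate_subject(config, subject_seeds[i], ids[i])
  }
  names(pairs) <- ids
  manifest <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    master_seed = config$seed,
    subject_ids = ids,
    subject_seeds = subject_seeds
  )
  structure(list(pairs = pairs, manifest = manifest),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d paired subject(s), master seed %d\n",
              length(x$pairs), x$manifest$master_seed))
  invisible(x)
}

# deterministic polynomial hash of the JSON-serialised configuration
config_hash <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
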