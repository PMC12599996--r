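# Fixture builders and independent brute-force oracles used across tests.

# Build a labeled timeline from a character vector of "A" (AF), "N" (non-AF),
# "M" (missing). Beat counts are chosen so that re-labeling at 0.40
# reproduces the requested sequence; rates default to 75 bpm (sinus) and
# 100 bpm (AF) unless given.
make_timeline <- function(labels, rates = NULL, clock_start = 0L,
                          subject_id = "T1", source = "gold") {
  labels <- strsplit(paste(labels, collapse = ""), "")[[1]]
  n <- length(labels)
  if (is.null(rates)) rates <- ifelse(labels == "A", 100, 75)
  n_beats <- pmax(1L, as.integer(round(rates)))
  n_af <- integer(n)
  n_af[labels == "A"] <- as.integer(ceiling(0.9 * n_beats[labels == "A"]))
  valid <- labels != "M"
  tl <- rhythm_timeline(
    subject_id, source,
    minute_index = seq_len(n) - 1L,
    clock_hour = (clock_start + (seq_len(n) - 1L) %/% 60L) %% 24L,
    n_beats = n_beats, n_af_beats = n_af,
    mean_rate_bpm = rates, valid = valid
  )
  label_minutes(tl, 0.40)
}

random_label_string <- function(n, p = c(A = 0.3, N = 0.5, M = 0.2)) {
  sample(c("A", "N", "M"), n, replace = TRUE, prob = p)
}

# Brute-force episode scan: enumerate maximal AF runs directly via rle(),
# then merge consecutive runs separated only by at most `bridge` missing
# labels. Returns a list of member index vectors (AF minutes only).
bf_episodes <- function(labels, bridge = 0L) {
  n <- length(labels)
  is_af <- labels == "A"
  if (!any(is_af)) return(list())
  r <- rle(is_af)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- Map(seq, starts[r$values], ends[r$values])
  merged <- list(runs[[1L]])
  if (length(runs) > 1L) {
    for (k in 2L:length(runs)) {
      prev <- merged[[length(merged)]]
      gap <- (max(prev) + 1L):(min(runs[[k]]) - 1L)
      if (all(labels[gap] == "M") && length(gap) <= bridge) {
        merged[[length(merged)]] <- c(prev, runs[[k]])
      } else {
        merged[[length(merged) + 1L]] <- runs[[k]]
      }
    }
  }
  merged
}

# Brute-force AUC as the probability of correct pairwise ordering with 1/2
# credit for ties, enumerated over every (positive, negative) pair.
bf_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive two-sided Mann-Whitney p-value over all group assignments of
# the pooled sample (ties included), independent of the implementation.
bf_mann_whitney_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  mu <- n * length(y) / 2
  dev_obs <- abs(u_of(seq_len(n)) - mu)
  combs <- utils::combn(length(pooled), n)
  devs <- apply(combs, 2L, function(idx) abs(u_of(idx) - mu))
  mean(devs >= dev_obs - 1e-9)
}

# Mid-rank Spearman coefficient computed from first principles (explicit
# mid-ranks and the Pearson product-moment formula written out).
bf_spearman <- function(p, g) {
  midrank <- function(v) {
    sapply(v, function(x) sum(v < x) + (1 + sum(v == x)) / 2)
  }
  a <- midrank(p)
  b <- midrank(g)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  num / den
}
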