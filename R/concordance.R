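#' Epoch-level confusion counts of a device stream against the gold standard
#'
#' Minutes are aligned by `minute_index`; only minutes valid in both streams
#' enter the counts. AF is the positive class and the gold stream defines
#' the truth.
#'
#' @param device,gold Labeled `rhythm_timeline` objects for the same
#'   subject.
#' @return A named integer vector `c(tp =, fn =, fp =, tn =)` of class
#'   `confusion_counts`.
#' @export
confusion <- function(device, gold) {
  for (tl in list(device, gold)) {
    if (anyNA(tl$label)) {
      stop("timeline labels not populated; run label_minutes()", call. = FALSE)
    }
  }
  common <- intersect(device$minute_index[device$valid],
                      gold$minute_index[gold$valid])
  if (length(common) == 0L) {
    stop("no minutes are valid in both streams", call. = FALSE)
  }
  d <- device$label[match(common, device$minute_index)] == "AF"
  g <- gold$label[match(common, gold$minute_index)] == "AF"
  structure(
    c(tp = sum(d & g), fn = sum(!d & g), fp = sum(d & !g), tn = sum(!d & !g)),
    class = "confusion_counts"
  )
}

#' Pool confusion counts across subjects
#'
#' @param ... `confusion_counts` objects or a single list of them.
#' @return Pooled `confusion_counts`.
#' @export
pool_confusion <- function(...) {
  items <- list(...)
  if (length(items) == 1L && is.list(items[[1L]]) &&
        !inherits(items[[1L]], "confusion_counts")) {
    items <- items[[1L]]
  }
  out <- Reduce(`+`, lapply(items, unclass))
  structure(out, class = "confusion_counts")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The Wilson score interval without continuity correction. The lower bound
#' is exactly 0 when there are no successes and the upper bound exactly 1
#' when every trial succeeds.
#'
#' @param successes Number of successes, `0 <= successes <= n`.
#' @param n Number of trials, at least 1.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
wilson_ci <- function(successes, n, conf = 0.95) {
  stopifnot(n >= 1L, successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Diagnostic performance metrics from confusion counts
#'
#' Evaluates sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/(TP+FP+FN+TN)` and F1
#' `2*TP/(2*TP+FP+FN)` exactly, each with an epoch-level Wilson score
#' interval built from the metric's own numerator and denominator (F1 is
#' treated as the proportion `2*TP` out of `2*TP+FP+FN`). A metric whose
#' denominator is zero is reported as `NA` with its `defined` flag unset.
#'
#' @param counts A `confusion_counts` vector (or any named vector with
#'   `tp`, `fn`, `fp`, `tn`).
#' @param conf Confidence level for the Wilson intervals.
#' @param output_rate Optional overall valid-output rate to carry in the
#'   report.
#' @return A data frame of class `performance_report` with columns
#'   `metric`, `estimate`, `ci_low`, `ci_high`, `defined`; confusion counts
#'   and the output rate are attached as attributes.
#' @export
performance <- function(counts, conf = 0.95, output_rate = NA_real_) {
  tp <- counts[["tp"]]; fn <- counts[["fn"]]
  fp <- counts[["fp"]]; tn <- counts[["tn"]]
  specs <- list(
    sensitivity = c(tp, tp + fn),
    specificity = c(tn, tn + fp),
    precision   = c(tp, tp + fp),
    accuracy    = c(tp + tn, tp + fn + fp + tn),
    f1          = c(2 * tp, 2 * tp + fp + fn)
  )
  rows <- lapply(names(specs), function(m) {
    s <- specs[[m]][1L]; n <- specs[[m]][2L]
    if (n == 0) {
      data.frame(metric = m, estimate = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, defined = FALSE)
    } else {
      ci <- wilson_ci(s, n, conf)
      data.frame(metric = m, estimate = s / n, ci_low = ci[["low"]],
                 ci_high = ci[["high"]], defined = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "counts") <- unclass(counts)
  attr(out, "output_rate") <- output_rate
  attr(out, "conf") <- conf
  class(out) <- c("performance_report", "data.frame")
  out
}

#' @export
print.performance_report <- function(x, ...) {
  cts <- attr(x, "counts")
  cat(sprintf("<performance_report> tp=%d fn=%d fp=%d tn=%d\n",
              cts[["tp"]], cts[["fn"]], cts[["fp"]], cts[["tn"]]))
  for (i in seq_len(nrow(x))) {
    if (isTRUE(x$defined[i])) {
      cat(sprintf("  %-12s %5.1f%% (%.1f-%.1f)\n", x$metric[i],
                  100 * x$estimate[i], 100 * x$ci_low[i], 100 * x$ci_high[i]))
    } else {
      cat(sprintf("  %-12s undefined\n", x$metric[i]))
    }
  }
  if (!is.na(attr(x, "output_rate"))) {
    cat(sprintf("  output rate  %5.1f%%\n", 100 * attr(x, "output_rate")))
  }
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over per-minute scores (typically AF-beat
#' fractions of the device stream) against binary gold labels; a minute is
#' called positive when its score strictly exceeds the threshold. The
#' default grid is every distinct observed score (plus sentinels), which
#' makes the trapezoidal AUC equal to the probability of correct pairwise
#' ordering with 1/2 credit for ties.
#'
#' @param scores Numeric per-minute scores from the device.
#' @param gold_positive Logical per-minute gold labels (AF = `TRUE`).
#' @param thresholds Optional numeric threshold grid; defaults to all
#'   distinct observed scores.
#' @return A list with `roc` (data frame `threshold`, `tpr`, `fpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, gold_positive, thresholds = NULL) {
  stopifnot(length(scores) == length(gold_positive))
  gold_positive <- as.logical(gold_positive)
  n_pos <- sum(gold_positive)
  n_neg <- sum(!gold_positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative gold minute",
         call. = FALSE)
  }
  if (is.null(thresholds)) thresholds <- sort(unique(scores))
  thresholds <- sort(unique(c(-Inf, thresholds, Inf)))
  tpr <- vapply(thresholds, function(t) sum(scores > t & gold_positive) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores > t & !gold_positive) / n_neg,
                numeric(1))
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) +
                                 utils::tail(tpr[ord], -1)) / 2)
  list(roc = data.frame(threshold = thresholds, tpr = tpr, fpr = fpr),
       auc = auc)
}

#' Mean absolute error between paired metric values
#'
#' @param p,g Equal-length numeric vectors (device and gold per-subject
#'   values).
#' @return Mean of `|p - g|`.
#' @export
mae <- function(p, g) {
  if (length(p) != length(g)) stop("length mismatch", call. = FALSE)
  if (length(p) == 0L) stop("empty input", call. = FALSE)
  mean(abs(p - g))
}

#' Spearman rank correlation with mid-rank ties and t-approximation p-value
#'
#' Computes `rs` as the Pearson correlation of mid-ranked values and its
#' two-sided p-value from the t approximation with `n - 2` degrees of
#' freedom, `t = rs * sqrt((n - 2) / (1 - rs^2))` (p = 0 at `rs = +-1` by
#' continuity).
#'
#' @param p,g Equal-length numeric vectors, `n >= 3`.
#' @return A list with `rs`, `p_value` and logical `defined` (`FALSE` when
#'   either vector has zero rank variance, in which case `rs` is `NA`).
#' @export
spearman_rs <- function(p, g) {
  if (length(p) != length(g)) stop("length mismatch", call. = FALSE)
  n <- length(p)
  if (n < 3L) stop("Spearman correlation needs n >= 3", call. = FALSE)
  rp <- rank(p); rg <- rank(g)
  if (stats::sd(rp) == 0 || stats::sd(rg) == 0) {
    return(list(rs = NA_real_, p_value = NA_real_, defined = FALSE))
  }
  rs <- stats::cor(rp, rg)
  if (abs(rs) >= 1 - 1e-12) {
    pv <- 0
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rs = rs, p_value = pv, defined = TRUE)
}

#' Mann-Whitney U test (two-sided) with ties
#'
#' The U statistic for the first sample counts pairs `x > y` plus half the
#' tied pairs. The two-sided p-value is computed by exhaustive enumeration
#' of all group assignments of the pooled values when that enumeration is
#' small (at most `max_enum` arrangements, ties handled exactly), and by
#' the normal approximation with the tie-corrected variance otherwise.
#' Identical samples yield `p = 1`.
#'
#' @param x,y Nonempty numeric samples.
#' @param max_enum Largest number of arrangements enumerated exactly.
#' @return A list with `U` (for `x`), `p_value`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y, max_enum = 200000) {
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("both samples must be nonempty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (choose(n + m, n) <= max_enum) {
    dev_obs <- abs(u_obs - mu)
    combs <- utils::combn(n + m, n)
    devs <- abs(colSums(matrix(r[combs], nrow = n)) -
                  n * (n + 1) / 2 - mu)
    pv <- mean(devs >= dev_obs - 1e-9)
    method <- "exact"
  } else {
    ties <- table(pooled)
    nt <- n + m
    sigma2 <- n * m / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    if (sigma2 <= 0) {
      pv <- 1
    } else {
      z <- (u_obs - mu) / sqrt(sigma2)
      pv <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(U = u_obs, p_value = pv, method = method)
}

#' Per-metric concordance table of device against gold profiles
#'
#' For each burden metric, reports the per-source medians and interquartile
#' ranges, the mean absolute error over subject pairs, the Mann-Whitney
#' p-value comparing the device and gold metric distributions (a paired
#' Wilcoxon signed-rank alternative is available since the design is
#' paired), and the Spearman rank correlation with its p-value.
#'
#' @param device_profiles,gold_profiles Data frames of per-subject burden
#'   profiles (see [cohort_profiles()]) with a `subject_id` column; subjects
#'   are matched by id.
#' @param metrics Metric columns to tabulate.
#' @param paired_test Use the paired Wilcoxon signed-rank test instead of
#'   the Mann-Whitney comparison.
#' @return A data frame of class `concordance_table` with one row per
#'   metric: `metric`, `device_median`, `device_q25`, `device_q75`,
#'   `gold_median`, `gold_q25`, `gold_q75`, `mae`, `mw_p`, `spearman_rs`,
#'   `rs_p`, `rs_defined`.
#' @export
concordance_table <- function(device_profiles, gold_profiles,
                              metrics = burden_metric_names(),
                              paired_test = FALSE) {
  common <- intersect(device_profiles$subject_id, gold_profiles$subject_id)
  if (length(common) == 0L) stop("no matching subjects", call. = FALSE)
  d <- device_profiles[match(common, device_profiles$subject_id), ,
                       drop = FALSE]
  g <- gold_profiles[match(common, gold_profiles$subject_id), , drop = FALSE]
  rows <- lapply(metrics, function(mname) {
    p <- d[[mname]]; q <- g[[mname]]
    sp <- if (length(p) >= 3L) spearman_rs(p, q) else
      list(rs = NA_real_, p_value = NA_real_, defined = FALSE)
    mwp <- if (paired_test) {
      if (all(p == q)) 1 else
        suppressWarnings(stats::wilcox.test(p, q, paired = TRUE)$p.value)
    } else {
      mann_whitney(p, q)$p_value
    }
    data.frame(
      metric = mname,
      device_median = stats::median(p),
      device_q25 = unname(stats::quantile(p, 0.25)),
      device_q75 = unname(stats::quantile(p, 0.75)),
      gold_median = stats::median(q),
      gold_q25 = unname(stats::quantile(q, 0.25)),
      gold_q75 = unname(stats::quantile(q, 0.75)),
      mae = mae(p, q),
      mw_p = mwp,
      spearman_rs = sp$rs,
      rs_p = sp$p_value,
      rs_defined = sp$defined,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_subjects") <- length(common)
  class(out) <- c("concordance_table", "data.frame")
  out
}

#' Subject-level bootstrap confidence intervals for performance metrics
#'
#' Epoch-level Wilson intervals ignore within-subject clustering of minutes;
#' this percentile bootstrap resamples whole subjects (their confusion
#' counts) and recomputes the pooled metrics, giving cluster-robust
#' intervals.
#'
#' @param counts_list List of per-subject `confusion_counts`.
#' @param conf Confidence level.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed RNG seed for the resampling.
#' @return A data frame with `metric`, `estimate`, `ci_low`, `ci_high`.
#' @export
bootstrap_performance_ci <- function(counts_list, conf = 0.95,
                                     n_boot = 2000L, seed = 1L) {
  stopifnot(length(counts_list) >= 1L)
  point <- performance(pool_confusion(counts_list))
  mat <- do.call(rbind, lapply(counts_list, unclass))
  metric_fun <- function(cts) {
    c(sensitivity = cts[["tp"]] / (cts[["tp"]] + cts[["fn"]]),
      specificity = cts[["tn"]] / (cts[["tn"]] + cts[["fp"]]),
      precision = cts[["tp"]] / (cts[["tp"]] + cts[["fp"]]),
      accuracy = (cts[["tp"]] + cts[["tn"]]) / sum(cts),
      f1 = 2 * cts[["tp"]] / (2 * cts[["tp"]] + cts[["fp"]] + cts[["fn"]]))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boots <- replicate(n_boot, {
    idx <- sample.int(nrow(mat), nrow(mat), replace = TRUE)
    metric_fun(colSums(mat[idx, , drop = FALSE]))
  })
  alpha <- (1 - conf) / 2
  qs <- apply(boots, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  data.frame(
    metric = point$metric,
    estimate = point$estimate,
    ci_low = qs[1L, point$metric],
    ci_high = qs[2L, point$metric],
    row.names = NULL
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
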