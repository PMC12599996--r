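test_that("confusion counts pair minutes valid in both streams", {
  g <- make_timeline(c("A", "A", "N", "N", "M"), source = "gold")
  d <- make_timeline(c("A", "N", "N", "M", "N"), source = "device")
  cts <- confusion(d, g)
  expect_equal(unclass(cts), c(tp = 1L, fn = 1L, fp = 0L, tn = 1L))
  expect_equal(sum(cts), 3L) # minutes valid in both

  same <- confusion(g, g)
  expect_equal(same[["fn"]] + same[["fp"]], 0L)

  d_all_af <- make_timeline(strrep("A", 100), source = "device")
  g_all_n <- make_timeline(strrep("N", 100), source = "gold")
  expect_equal(confusion(d_all_af, g_all_n)[["fp"]], 100L)

  expect_error(confusion(make_timeline("M"), make_timeline("A")),
               "valid in both")
})

test_that("confusion matches a brute-force per-minute tally", {
  set.seed(71)
  for (rep in 1:50) {
    n <- sample(20:100, 1L)
    gl <- random_label_string(n)
    dl <- random_label_string(n)
    g <- make_timeline(gl, source = "gold")
    d <- make_timeline(dl, source = "device")
    both <- gl != "M" & dl != "M"
    if (!any(both)) next
    cts <- confusion(d, g)
    expect_equal(cts[["tp"]], sum(both & dl == "A" & gl == "A"))
    expect_equal(cts[["fn"]], sum(both & dl != "A" & gl == "A"))
    expect_equal(cts[["fp"]], sum(both & dl == "A" & gl != "A"))
    expect_equal(cts[["tn"]], sum(both & dl != "A" & gl != "A"))
  }
})

test_that("performance metrics evaluate the closed-form ratios exactly", {
  cts <- structure(c(tp = 106975, fn = 11941, fp = 8787, tn = 308082),
                   class = "confusion_counts")
  perf <- performance(cts)
  est <- setNames(perf$estimate, perf$metric)
  expect_equal(est[["sensitivity"]], 106975 / 118916)
  expect_equal(est[["specificity"]], 308082 / 316869)
  expect_equal(est[["precision"]], 106975 / 115762)
  expect_equal(est[["accuracy"]], 415057 / 435785)
  expect_equal(est[["f1"]], 213950 / 234678)
  expect_true(all(perf$ci_low <= perf$estimate & perf$estimate <= perf$ci_high))

  ideal <- performance(structure(c(tp = 1, fn = 0, fp = 0, tn = 1),
                                 class = "confusion_counts"))
  expect_true(all(ideal$estimate == 1))

  degenerate <- performance(structure(c(tp = 0, fn = 0, fp = 0, tn = 5),
                                      class = "confusion_counts"))
  expect_false(degenerate$defined[degenerate$metric == "sensitivity"])
})

test_that("the F1 identity with precision and sensitivity holds", {
  set.seed(81)
  for (rep in 1:30) {
    cts <- structure(as.numeric(sample(1:500, 4L)),
                     names = c("tp", "fn", "fp", "tn"),
                     class = "confusion_counts")
    est <- setNames(performance(cts)$estimate, c(
      "sensitivity", "specificity", "precision", "accuracy", "f1"
    ))
    expect_equal(est[["f1"]],
                 2 * est[["precision"]] * est[["sensitivity"]] /
                   (est[["precision"]] + est[["sensitivity"]]))
    expect_gte(est[["accuracy"]], min(est[["sensitivity"]], est[["specificity"]]))
    expect_lte(est[["accuracy"]], max(est[["sensitivity"]], est[["specificity"]]))
  }
})

test_that("Wilson intervals match the score formula and its boundary laws", {
  # hand evaluation of the score interval for 5/10 at 95%
  z <- qnorm(0.975)
  denom <- 1 + z^2 / 10
  center <- (0.5 + z^2 / 20) / denom
  half <- z * sqrt(0.5 * 0.5 / 10 + z^2 / 400) / denom
  got <- wilson_ci(5, 10)
  expect_equal(unname(got), c(center - half, center + half), tolerance = 1e-12)
  expect_equal(unname(round(got, 4)), c(0.2366, 0.7634))

  expect_equal(wilson_ci(0, 10)[["low"]], 0)
  expect_equal(wilson_ci(10, 10)[["high"]], 1)

  # width shrinks monotonically with n at fixed proportion
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    ci <- wilson_ci(round(0.3 * n), n)
    ci[["high"]] - ci[["low"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("ROC sweep AUC equals the pairwise-ordering probability", {
  # perfectly separating scores
  expect_equal(roc_auc(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)

  # small instance with ties against exhaustive pair enumeration
  scores <- c(0.2, 0.5, 0.5, 0.7, 0.2, 0.9)
  truth <- c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(roc_auc(scores, truth)$auc, bf_auc(scores, truth))

  set.seed(91)
  for (rep in 1:30) {
    n <- sample(6:15, 1L)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    tr <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(tr) || all(tr)) next
    expect_equal(roc_auc(sc, tr)$auc, bf_auc(sc, tr))
  }

  # label-independent scores give AUC near 1/2
  set.seed(92)
  sc <- runif(10000)
  tr <- runif(10000) < 0.3
  expect_equal(roc_auc(sc, tr)$auc, 0.5, tolerance = 0.02)

  expect_error(roc_auc(c(0.1, 0.9), c(TRUE, TRUE)), "negative")
})

test_that("ROC sweep agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(93)
  sc <- round(runif(300), 2)
  tr <- runif(300) < plogis(4 * sc - 2)
  if (any(tr) && any(!tr)) {
    ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(tr, sc,
                                                           quiet = TRUE))))
    expect_equal(roc_auc(sc, tr)$auc, ref, tolerance = 1e-10)
  }
})

test_that("refining the threshold grid converges to the exhaustive AUC", {
  set.seed(94)
  sc <- runif(500)
  tr <- runif(500) < plogis(3 * sc - 1.5)
  full <- roc_auc(sc, tr)$auc
  coarse <- roc_auc(sc, tr, thresholds = seq(0, 1, 0.2))$auc
  fine <- roc_auc(sc, tr, thresholds = seq(0, 1, 0.01))$auc
  expect_lt(abs(fine - full), abs(coarse - full) + 1e-12)
})

test_that("mean absolute error matches direct arithmetic", {
  expect_equal(mae(c(0.1, 0.3), c(0.2, 0.1)), 0.15)
  expect_equal(mae(1:5, 1:5), 0)
  set.seed(95)
  p <- runif(40); g <- runif(40)
  acc <- 0
  for (i in seq_along(p)) acc <- acc + abs(p[i] - g[i])
  expect_equal(mae(p, g), acc / 40)
  expect_error(mae(1:3, 1:4), "length")
})

test_that("Spearman correlation uses mid-ranks and the t approximation", {
  expect_equal(spearman_rs(1:10, (1:10)^2)$rs, 1)
  expect_equal(spearman_rs(1:10, -(1:10))$rs, -1)
  expect_equal(spearman_rs(1:10, (1:10)^2)$p_value, 0)

  set.seed(96)
  for (rep in 1:30) {
    n <- sample(5:15, 1L)
    p <- sample(1:4, n, replace = TRUE) # heavy ties
    g <- sample(1:4, n, replace = TRUE)
    if (sd(p) == 0 || sd(g) == 0) next
    got <- spearman_rs(p, g)
    expect_equal(got$rs, bf_spearman(p, g))
    ref <- suppressWarnings(cor.test(p, g, method = "spearman"))
    expect_equal(got$rs, unname(ref$estimate))
  }

  flat <- spearman_rs(rep(1, 5), 1:5)
  expect_false(flat$defined)
  expect_error(spearman_rs(1:2, 1:2), "n >= 3")
})

test_that("Mann-Whitney U and exact p agree with exhaustive enumeration", {
  ident <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p_value, 1)

  sep <- mann_whitney(6:10, 1:5)
  expect_equal(sep$U, 25) # maximal for n = m = 5
  expect_equal(sep$method, "exact")

  set.seed(97)
  for (rep in 1:30) {
    x <- sample(1:6, sample(3:6, 1L), replace = TRUE)
    y <- sample(1:6, sample(3:6, 1L), replace = TRUE)
    got <- mann_whitney(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, bf_mann_whitney_p(x, y))
  }
})

test_that("the exact Mann-Whitney p matches wilcox.test without ties", {
  set.seed(98)
  for (rep in 1:20) {
    x <- runif(sample(4:8, 1L))
    y <- runif(sample(4:8, 1L))
    got <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
  # large samples switch to the tie-corrected normal approximation
  big <- mann_whitney(rnorm(40), rnorm(40, 0.5))
  expect_equal(big$method, "normal")
  ref <- wilcox.test(rnorm(2), rnorm(2)) # structure check only
  expect_true(big$p_value > 0 && big$p_value <= 1)
})

test_that("the concordance table rewards a perfect device and flags n = 1", {
  set.seed(99)
  profs <- lapply(1:8, function(i) {
    labs <- random_label_string(200)
    if (!any(labs == "A")) labs[1] <- "A"
    burden_profile(make_timeline(labs, subject_id = sprintf("S%d", i)))
  })
  profs <- do.call(rbind, lapply(profs, as.data.frame))
  tab <- concordance_table(profs, profs)
  expect_true(all(tab$mae == 0))
  expect_true(all(tab$spearman_rs[tab$rs_defined] == 1))

  one <- concordance_table(profs[1, ], profs[1, ])
  expect_true(all(!one$rs_defined))
})

test_that("subject-level bootstrap intervals cover the pooled estimate", {
  set.seed(100)
  counts <- lapply(1:12, function(i) {
    structure(as.numeric(sample(50:200, 4L)),
              names = c("tp", "fn", "fp", "tn"),
              class = "confusion_counts")
  })
  ci <- bootstrap_performance_ci(counts, n_boot = 200L, seed = 3L)
  expect_true(all(ci$ci_low <= ci$estimate + 1e-12))
  expect_true(all(ci$estimate <= ci$ci_high + 1e-12))
})
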