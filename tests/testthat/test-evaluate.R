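test_that("MCC reproduces its worked examples and degenerate conventions", {
  expect_equal(mcc(list(TP = 50, TN = 50, FP = 0, FN = 0)), 1)
  expect_equal(mcc(list(TP = 0, TN = 0, FP = 50, FN = 50)), -1)
  expect_equal(mcc(list(TP = 40, TN = 30, FP = 10, FN = 20)),
               1000 / sqrt(6e6), tolerance = 1e-12)
  expect_equal(mcc(list(TP = 0, TN = 10, FP = 0, FN = 0)), 0)  # zero factor
})

test_that("precision and recall follow their formulas and 0/0 conventions", {
  expect_equal(precision_score(list(TP = 8, FP = 2, TN = 0, FN = 0)), 0.8)
  expect_equal(recall_score(list(TP = 5, FN = 0, TN = 0, FP = 0)), 1)
  expect_equal(precision_score(list(TP = 0, FP = 0, TN = 3, FN = 2)), 0)
  expect_equal(recall_score(list(TP = 0, FN = 0, TN = 3, FP = 2)), 0)
})

test_that("metric formulas agree with independent oracles on 1000 random tables", {
  set.seed(7)
  for (i in 1:1000) {
    cnt <- as.list(rmultinom(1, sample(4:200, 1), runif(4, 0.05, 1))[, 1])
    names(cnt) <- c("TP", "TN", "FP", "FN")
    # contingency-table correlation oracle: MCC = Pearson phi
    truth <- c(rep(1, cnt$TP + cnt$FN), rep(0, cnt$TN + cnt$FP))
    pred <- c(rep(1, cnt$TP), rep(0, cnt$FN), rep(0, cnt$TN), rep(1, cnt$FP))
    phi <- suppressWarnings(stats::cor(truth, pred))
    if (is.na(phi)) phi <- 0
    expect_equal(mcc(cnt), phi, tolerance = 1e-12)
    # brute-force formula evaluation
    p_or <- if (cnt$TP + cnt$FP == 0) 0 else cnt$TP / (cnt$TP + cnt$FP)
    r_or <- if (cnt$TP + cnt$FN == 0) 0 else cnt$TP / (cnt$TP + cnt$FN)
    expect_equal(precision_score(cnt), p_or, tolerance = 1e-12)
    expect_equal(recall_score(cnt), r_or, tolerance = 1e-12)
    # MCC is invariant under swapping the positive/negative class definition
    swapped <- list(TP = cnt$TN, TN = cnt$TP, FP = cnt$FN, FN = cnt$FP)
    expect_equal(mcc(cnt), mcc(swapped), tolerance = 1e-12)
  }
})

test_that("confusion counting is strict at the threshold and matches a brute-force loop", {
  ps <- c(0.5, 0.51, 0.49, 1, 0)
  labels <- c("active", "active", "inactive", "active", "inactive")
  cnt <- confusion_at_threshold(ps, labels, 0.5)
  expect_equal(cnt$TP, 2L)  # PS exactly 0.50 is predicted inactive
  expect_equal(cnt$FN, 1L)
  expect_equal(cnt$TN, 2L)
  all1 <- confusion_at_threshold(rep(1, 4), rep("active", 4), 0.5)
  expect_equal(unlist(all1[c("TP", "TN", "FP", "FN")]), c(TP = 4L, TN = 0L, FP = 0L, FN = 0L))
  expect_error(confusion_at_threshold(c(0.1), c("active", "inactive")), "lengths")
  set.seed(12)
  for (rep_i in 1:20) {
    n <- sample(5:50, 1)
    ps <- round(runif(n), 2)
    lab <- sample(c("active", "inactive"), n, replace = TRUE)
    t <- sample(ps, 1)
    cnt <- confusion_at_threshold(ps, lab, t)
    tp <- tn <- fp <- fn <- 0L
    for (i in seq_len(n)) {
      pa <- ps[i] > t
      if (pa && lab[i] == "active") tp <- tp + 1L
      if (pa && lab[i] == "inactive") fp <- fp + 1L
      if (!pa && lab[i] == "active") fn <- fn + 1L
      if (!pa && lab[i] == "inactive") tn <- tn + 1L
    }
    expect_equal(unlist(cnt[c("TP", "TN", "FP", "FN")]),
                 c(TP = tp, TN = tn, FP = fp, FN = fn))
  }
})

test_that("the threshold sweep has non-increasing recall and finds the perfect-precision point", {
  # perfectly separating scores: precision 1 everywhere above the top inactive
  ps <- c(0.95, 0.9, 0.85, 0.3, 0.2)
  lab <- c("active", "active", "active", "inactive", "inactive")
  sw <- sweep_thresholds(ps, lab)
  expect_true(all(sw$curve$precision[sw$curve$n_selected > 0] == 1))
  expect_equal(sw$perfect_precision_threshold, 0.5)
  # arbitrary scores: recall monotone non-increasing, order invariant
  set.seed(8)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    ps <- runif(n)
    lab <- sample(c("active", "inactive"), n, replace = TRUE)
    sw <- sweep_thresholds(ps, lab)
    expect_true(all(diff(sw$curve$recall) <= 1e-12))
    perm <- sample(n)
    expect_identical(sweep_thresholds(ps[perm], lab[perm])$curve, sw$curve)
  }
})

test_that("model ranking sorts by MCC with the declared tie-break and is permutation-invariant", {
  df <- data.frame(algorithm = c("RF", "GP", "SVM", "KNN"),
                   representation = c("morgan_fp", "path_fp", "path_fp", "dict_fp"),
                   scheme = "LO",
                   mcc = c(0.6, 0.7, 0.7, 0.5),
                   precision = c(0.9, 0.8, 0.9, 0.7),
                   recall = c(0.8, 0.9, 0.8, 0.6))
  r <- rank_models(df)
  expect_equal(r$algorithm, c("SVM", "GP", "RF", "KNN"))  # tie by precision
  expect_equal(r$rank, 1:4)
  perm <- df[c(3, 1, 4, 2), ]
  expect_equal(rank_models(perm)$algorithm, r$algorithm)
  one <- rank_models(df[1, , drop = FALSE])
  expect_equal(one$rank, 1L)
})
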