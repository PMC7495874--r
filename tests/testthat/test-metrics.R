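test_that("confusion counts are exact", {
  c1 <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(c1)[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 1L, FP = 1L),
               ignore_attr = TRUE)
  # perfect prediction
  y <- c(1, 0, 1, 1, 0)
  cp <- confusion_counts(y, y)
  expect_equal(cp$FP + cp$FN, 0)
  # empty inputs give all zeros
  ce <- confusion_counts(integer(0), integer(0))
  expect_equal(ce$TP + ce$FP + ce$TN + ce$FN, 0)
  expect_error(confusion_counts(c(1, 0), c(1)), "length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "0/1")
})

test_that("metrics reproduce the hand-worked example", {
  m <- compute_metrics(structure(list(TP = 3, FP = 1, TN = 4, FN = 2),
                                 class = "confusion_counts"))
  expect_equal(m$SEN, 0.6)
  expect_equal(m$SPE, 0.8)
  expect_equal(m$PRE, 0.75)
  expect_equal(m$F1, 2 * 0.6 * 0.75 / 1.35)
  expect_equal(m$ACC, 0.7)
  expect_equal(m$MCC, 10 / sqrt(600))
})

test_that("metrics agree exactly with the literal-formula oracle", {
  set.seed(99)
  for (trial in 1:300) {
    cts <- as.list(sample(1:40, 4, replace = TRUE))
    names(cts) <- c("TP", "FP", "TN", "FN")
    m <- compute_metrics(structure(cts, class = "confusion_counts"))
    o <- oracle_metrics(cts$TP, cts$FP, cts$TN, cts$FN)
    for (nm in names(o)) expect_identical(m[[nm]], o[[nm]])
    expect_true(all(unlist(m[c("SEN", "SPE", "PRE", "F1", "ACC")]) >= 0))
    expect_true(all(unlist(m[c("SEN", "SPE", "PRE", "F1", "ACC")]) <= 1))
    expect_true(m$MCC >= -1 && m$MCC <= 1)
  }
})

test_that("zero denominators return 0 with a warning", {
  all_pos <- structure(list(TP = 5, FP = 0, TN = 0, FN = 0),
                       class = "confusion_counts")
  wp <- capture_warnings(m <- compute_metrics(all_pos))
  expect_true(any(grepl("MCC", wp)))
  expect_equal(m$MCC, 0)
  expect_equal(m$SEN, 1); expect_equal(m$ACC, 1)
  no_pred_pos <- structure(list(TP = 0, FP = 0, TN = 4, FN = 3),
                           class = "confusion_counts")
  w <- capture_warnings(m2 <- compute_metrics(no_pred_pos))
  expect_true(any(grepl("PRE", w)))
  expect_equal(m2$PRE, 0); expect_equal(m2$F1, 0)
  expect_error(compute_metrics(structure(list(TP = 0, FP = 0, TN = 0, FN = 0),
                                         class = "confusion_counts")),
               "no evaluated")
})

test_that("AUC handles separation, ties and the worked example", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("rank and trapezoid AUC agree, and match exhaustive pair counting", {
  set.seed(41)
  for (trial in 1:60) {
    n <- sample(6:30, 1)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    expect_equal(roc_auc(y, s), roc_auc(y, s, method = "trapezoid"),
                 tolerance = 1e-12)
    expect_equal(roc_auc(y, s), oracle_auc(y, s), tolerance = 1e-12)
  }
})

test_that("roc_curve is anchored and monotone", {
  y <- c(1, 0, 1, 0, 1)
  s <- c(0.9, 0.9, 0.6, 0.4, 0.2)
  rc <- roc_curve(y, s)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})
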