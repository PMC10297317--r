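test_that("confusion counts match constructed vectors", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(cc[c("TP", "FP", "TN", "FN")],
               list(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  cc2 <- confusion(c(1, 0), c(0, 1))
  expect_equal(cc2$FN, 1L)
  expect_equal(cc2$FP, 1L)
  # constructed 20-element set with known counts
  labels <- c(rep(1, 8), rep(1, 1), rep(0, 9), rep(0, 2))
  preds  <- c(rep(1, 8), rep(0, 1), rep(0, 9), rep(1, 2))
  cc3 <- confusion(labels, preds)
  expect_equal(cc3[c("TP", "FP", "TN", "FN")],
               list(TP = 8L, FP = 2L, TN = 9L, FN = 1L))
  expect_equal(cc3$TP + cc3$FP + cc3$TN + cc3$FN, cc3$n_total)
  expect_error(confusion(integer(0), integer(0)), "empty")
  expect_error(confusion(1:3, 1:2), "length")
})

test_that("weighted metrics reproduce the hand-computed example", {
  labels <- c(rep(1, 9), rep(0, 11))
  preds  <- c(rep(1, 8), 0, rep(0, 9), 1, 1)
  cc <- confusion(labels, preds)
  expect_equal(cc[c("TP", "FP", "TN", "FN")],
               list(TP = 8L, FP = 2L, TN = 9L, FN = 1L))
  # one-vs-rest metrics of the positive class, per the defining ratios
  per <- selfonn_ns$one_vs_rest_metrics(cc)
  expect_equal(unname(per["precision"]), 0.8)
  expect_equal(unname(per["recall"]), 8 / 9)
  expect_equal(unname(per["specificity"]), 9 / 11)
  expect_equal(unname(per["f1"]), 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  wm <- weighted_metrics(labels, preds)
  expect_equal(wm$overall_accuracy, 17 / 20)
  # perfect prediction: everything 1
  wp <- weighted_metrics(labels, labels)
  expect_equal(unlist(wp[2:5], use.names = FALSE), rep(1, 4))
  expect_equal(wp$overall_accuracy, 1)
})

test_that("support-weighted recall equals overall accuracy on 1000 random configurations", {
  set.seed(30)
  for (i in 1:1000) {
    n <- sample(4:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.1, 0.9))
    preds <- rbinom(n, 1, runif(1, 0.1, 0.9))
    wm <- suppressWarnings(weighted_metrics(labels, preds, classes = 0:1))
    expect_equal(wm$weighted_recall, wm$overall_accuracy, tolerance = 1e-12)
    expect_true(all(unlist(wm[1:5]) >= 0 & unlist(wm[1:5]) <= 1))
  }
})

test_that("ROC endpoints behave like the theory says", {
  labels <- c(rep(0, 10), rep(1, 10))
  scores <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(1 - scores, labels)$auc, 0)
  expect_equal(r$roc_points$fpr[1], 0)
  expect_equal(r$roc_points$tpr[1], 0)
  expect_equal(tail(r$roc_points$fpr, 1), 1)
  expect_equal(tail(r$roc_points$tpr, 1), 1)
  expect_true(all(diff(r$roc_points$fpr) >= 0))
  expect_true(all(diff(r$roc_points$tpr) >= 0))
  set.seed(31)
  shuffled <- roc_auc(runif(4000), rbinom(4000, 1, 0.5))
  expect_lt(abs(shuffled$auc - 0.5), 0.05)
  expect_error(roc_auc(runif(5), rep(1, 5)), "undefined")
})

test_that("AUC equals the Mann-Whitney rank statistic and is monotone-invariant", {
  set.seed(32)
  for (i in 1:25) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    labels <- c(rep(1, n1), rep(0, n0))
    scores <- c(rnorm(n1, mean = runif(1, 0, 2)), rnorm(n0))
    auc <- roc_auc(scores, labels)$auc
    u <- unname(wilcox.test(scores[labels == 1], scores[labels == 0],
                            exact = FALSE)$statistic)
    expect_equal(auc, u / (n1 * n0), tolerance = 1e-10)
    expect_equal(roc_auc(exp(3 * scores), labels)$auc, auc, tolerance = 1e-12)
  }
})

test_that("classification report bundles counts, weighted metrics and ROC", {
  set.seed(33)
  labels <- rbinom(60, 1, 0.6)
  scores <- runif(60) * 0.5 + labels * 0.4
  preds <- as.integer(scores > 0.5)
  rep_ <- classification_report(labels, preds, scores)
  expect_s3_class(rep_, "classification_report")
  expect_equal(rep_$weighted_recall, rep_$overall_accuracy)
  expect_equal(rep_$n, 60L)
  expect_true(rep_$auc >= 0 && rep_$auc <= 1)
  expect_true(rep_$accuracy_ci[1] <= rep_$overall_accuracy &&
              rep_$overall_accuracy <= rep_$accuracy_ci[2])
  counts <- rep_$counts[["1"]]
  expect_equal(counts$TP + counts$FP + counts$TN + counts$FN, 60L)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rep_$auc, ref, tolerance = 1e-10)
  }
})
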