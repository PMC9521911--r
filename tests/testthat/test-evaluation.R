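test_that("confusion counts: worked cases and brute-force agreement", {
  y <- c(rep("a", 4), rep("b", 6))
  cc <- confusion_counts(y, y, "a")
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 4, tn = 6, fp = 0, fn = 0))

  all_pos <- confusion_counts(y, rep("a", 10), "a")
  expect_equal(all_pos$fp, 6)

  truth <- glcmfusion:::with_seed(1, sample(c("x", "y", "z"), 50, TRUE))
  pred <- glcmfusion:::with_seed(2, sample(c("x", "y", "z"), 50, TRUE))
  cc2 <- confusion_counts(truth, pred, "y")
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in 1:50) {
    if (truth[i] == "y" && pred[i] == "y") tp <- tp + 1
    if (truth[i] != "y" && pred[i] != "y") tn <- tn + 1
    if (truth[i] != "y" && pred[i] == "y") fp <- fp + 1
    if (truth[i] == "y" && pred[i] != "y") fn <- fn + 1
  }
  expect_equal(unlist(cc2[c("tp", "tn", "fp", "fn")]),
               c(tp = tp, tn = tn, fp = fp, fn = fn))
  expect_equal(cc2$tp + cc2$tn + cc2$fp + cc2$fn, 50)

  expect_error(confusion_counts(y, y[-1], "a"), "equal length")
  expect_error(confusion_counts(character(0), character(0), "a"), "non-empty")
})

test_that("F1 percent formatting follows the 2TP/(2TP+FP+FN) convention", {
  expect_equal(f1_from_counts(106, fp = 3, fn = 4), 96.8)
  expect_equal(f1_from_counts(95, fp = 5, fn = 17), 89.6)
  expect_equal(f1_from_counts(50, fp = 0, fn = 0), 100)
  cc <- confusion_counts(c("a", "a", "b"), c("a", "b", "b"), "a")
  expect_equal(f1_from_counts(cc), round(100 * 2 / 3, 1))
  expect_error(f1_from_counts(0, fp = 0, fn = 0), "undefined")
})

test_that("multiclass metrics: perfect, constant, and tally cross-check", {
  y <- rep(c("benign", "malignant", "ambiguous"), each = 10)
  perfect <- multiclass_metrics(y, y)
  expect_equal(unlist(perfect), c(accuracy = 100, sensitivity = 100,
                                  specificity = 100))

  const <- multiclass_metrics(y, rep("benign", 30))
  expect_equal(const$accuracy, 100 / 3, tolerance = 1e-9)
  expect_equal(const$sensitivity, 100 / 3, tolerance = 1e-9)

  truth <- glcmfusion:::with_seed(3, sample(c("a", "b", "c"), 60, TRUE))
  pred <- glcmfusion:::with_seed(4, sample(c("a", "b", "c"), 60, TRUE))
  got <- multiclass_metrics(truth, pred, classes = c("a", "b", "c"))
  sens <- mean(vapply(c("a", "b", "c"), function(cl) {
    cc <- confusion_counts(truth, pred, cl)
    cc$tp / (cc$tp + cc$fn)
  }, numeric(1)))
  spec <- mean(vapply(c("a", "b", "c"), function(cl) {
    cc <- confusion_counts(truth, pred, cl)
    cc$tn / (cc$tn + cc$fp)
  }, numeric(1)))
  expect_equal(got$sensitivity, 100 * sens)
  expect_equal(got$specificity, 100 * spec)
  expect_equal(got$accuracy, 100 * mean(truth == pred))
})

test_that("OvR AUC: separation, pair-count oracle, and rank invariance", {
  y <- c("a", "a", "b", "b", "c", "c")
  scores <- rbind(c(.9, .05, .05), c(.8, .1, .1), c(.1, .8, .1),
                  c(.2, .7, .1), c(.05, .05, .9), c(.1, .2, .7))
  colnames(scores) <- c("a", "b", "c")
  expect_equal(ovr_roc_auc(y, scores, "macro"), 1)
  expect_equal(ovr_roc_auc(y, scores, "micro"), 1)

  set.seed(8)
  n <- 40
  truth <- sample(c("a", "b", "c"), n, TRUE)
  sc <- matrix(stats::runif(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  sc <- sc / rowSums(sc)
  macro_oracle <- mean(vapply(c("a", "b", "c"), function(cl) {
    pair_count_auc(truth == cl, sc[, cl])
  }, numeric(1)))
  expect_equal(ovr_roc_auc(truth, sc, "macro"), macro_oracle)
  micro_oracle <- pair_count_auc(as.vector(outer(truth, c("a", "b", "c"), "==")),
                                 as.vector(sc))
  expect_equal(ovr_roc_auc(truth, sc, "micro"), micro_oracle)

  # invariance under a strictly monotone score transform
  expect_equal(ovr_roc_auc(truth, exp(3 * sc), "macro"),
               ovr_roc_auc(truth, sc, "macro"))

  expect_error(ovr_roc_auc(c("a", "a"), sc[1:2, ], "macro"),
               "absent from y_true")
})

test_that("own AUC agrees with pROC on a binary problem", {
  set.seed(21)
  lab <- sample(c(0, 1), 60, TRUE)
  sc <- stats::runif(60) + 0.4 * lab
  ours <- glcmfusion:::binary_auc(lab == 1, sc)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("micro equals macro on a balanced symmetric construction", {
  # balanced classes with identical per-class score distributions
  y <- rep(c("a", "b", "c"), each = 4)
  base <- c(.7, .6, .3, .2)
  sc <- matrix(0.15, 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  for (k in 1:3) sc[(k - 1) * 4 + 1:4, k] <- base
  expect_equal(ovr_roc_auc(y, sc, "micro"), ovr_roc_auc(y, sc, "macro"))
})

test_that("k-fold splits partition, balance, and stratify", {
  folds <- kfold_split(10, 10, seed = 1)
  expect_length(folds, 10)
  expect_true(all(vapply(folds, function(f) length(f$test), numeric(1)) == 1))

  folds2 <- kfold_split(23, 5, seed = 2)
  tests <- unlist(lapply(folds2, `[[`, "test"))
  expect_equal(sort(tests), 1:23)
  sizes <- vapply(folds2, function(f) length(f$test), numeric(1))
  expect_lte(max(sizes) - min(sizes), 1)
  for (f in folds2) {
    expect_length(intersect(f$train, f$test), 0)
    expect_equal(sort(c(f$train, f$test)), 1:23)
  }

  labels <- rep(c("x", "y", "z"), times = c(12, 9, 9))
  for (seed in 1:50) {
    sf <- kfold_split(30, 3, seed = seed, labels = labels)
    for (f in sf) {
      for (cl in c("x", "y", "z")) {
        n_fc <- sum(labels[f$test] == cl)
        expected <- length(f$test) * mean(labels == cl)
        expect_lte(abs(n_fc - expected), 1)
      }
    }
  }
  expect_error(kfold_split(4, 10), "n must be >= k")
})
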