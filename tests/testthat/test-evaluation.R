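test_that("confusion counts are exact and symmetric", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cm)[c("tp", "tn", "fp", "fn")],
               list(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
  cm2 <- confusion(c(1, 0, 1, 0), c(0, 0, 1, 1))
  expect_equal(unclass(cm2)[c("tp", "tn", "fp", "fn")],
               list(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
  # swapping the positive-class convention swaps TP/TN and FP/FN
  y <- rbinom(50, 1, 0.4); p <- rbinom(50, 1, 0.5)
  a <- confusion(y, p); b <- confusion(1 - y, 1 - p)
  expect_equal(a$tp, b$tn); expect_equal(a$fp, b$fn)
  expect_error(confusion(c(1, 0), c(1)), "equal length")
  expect_error(confusion(integer(0), integer(0)), "empty")
})

test_that("metrics reproduce their defining ratios", {
  m <- eval_metrics(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity",
                          "precision")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 precision = 1))
  cm <- structure(list(tp = 80L, tn = 0L, fp = 0L, fn = 20L),
                  class = "confusion_matrix")
  expect_warning(m2 <- eval_metrics(cm))  # specificity undefined
  expect_equal(m2$sensitivity, 0.80)
  m3 <- eval_metrics(confusion(c(1, 0, 1, 0), c(0, 0, 1, 1)))
  expect_equal(m3$accuracy, 0.5)
  expect_equal(m3$precision, 0.5)
  # identities: sensitivity (TP+FN) = TP; accuracy = prevalence-weighted mean
  y <- rbinom(200, 1, 0.35); p <- rbinom(200, 1, 0.5)
  mm <- eval_metrics(confusion(y, p))
  expect_equal(mm$sensitivity * (mm$tp + mm$fn), mm$tp)
  prev <- mean(y)
  expect_equal(mm$accuracy,
               prev * mm$sensitivity + (1 - prev) * mm$specificity)
  expect_equal(unname(format_report(m3)["accuracy"]), "50.00%")
})

test_that("AUROC equals the pairwise-concordance oracle exactly", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  set.seed(1)
  y <- rbinom(200, 1, 0.4)
  s <- round(rnorm(200), 1)  # coarse scores force plenty of ties
  brute <- 0
  pos <- which(y == 1); neg <- which(y == 0)
  for (i in pos) for (j in neg)
    brute <- brute + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  brute <- brute / (length(pos) * length(neg))
  expect_equal(auroc(y, s), brute, tolerance = 1e-12)
  # monotone-transform invariance and score-negation antisymmetry
  expect_equal(auroc(y, exp(3 * s)), auroc(y, s), tolerance = 1e-12)
  expect_equal(auroc(y, s) + auroc(y, -s), 1, tolerance = 1e-12)
  expect_error(auroc(rep(1, 5), 1:5), "both classes")
  # label-independent scores: AUROC near one half
  set.seed(2)
  yy <- rbinom(5000, 1, 0.4)
  expect_equal(auroc(yy, rnorm(5000)), 0.5, tolerance = 0.03)
})

test_that("ROC points integrate to the same area", {
  set.seed(3)
  y <- rbinom(300, 1, 0.4)
  s <- rnorm(300) + y
  pts <- roc_points(y, s)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  expect_equal(trap, auroc(y, s), tolerance = 1e-12)
})

test_that("cross-validation folds are record-disjoint and balanced", {
  rec_ids <- rep(sprintf("r%02d", 1:11), times = sample(5:12, 11, TRUE))
  seen <- list()
  res <- crossval(rec_ids, k = 5, seed = 4, pipeline = function(tr, te) {
    seen[[length(seen) + 1]] <<- list(tr = tr, te = te)
    list(labels = rbinom(length(te), 1, 0.5),
         predictions = rep(1, length(te)))
  })
  expect_length(res$folds, 5)
  test_ids <- lapply(seen, function(x) unique(rec_ids[x$te]))
  expect_equal(sort(unlist(test_ids)), sort(unique(rec_ids)))
  expect_true(all(vapply(test_ids, length, integer(1)) %in% 2:3))
  for (f in seq_along(seen))
    expect_length(intersect(rec_ids[seen[[f]]$tr], rec_ids[seen[[f]]$te]), 0)
  # the always-positive classifier: sensitivity 1, specificity 0
  for (fold in res$folds) {
    expect_equal(fold$sensitivity, 1)
    expect_equal(fold$specificity, 0)
  }
  expect_error(crossval(c("a", "b"), k = 5, pipeline = identity),
               "fewer records")
})
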