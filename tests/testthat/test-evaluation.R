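test_that("accuracy follows its count formula", {
  expect_equal(accuracy(metrics_counts(tp = 8, tn = 2)), 100)
  expect_equal(accuracy(metrics_counts(tp = 3, tn = 5, fp = 1, fn = 1)), 80)
  expect_equal(accuracy(metrics_counts(fp = 1, fn = 1)), 0)
  expect_error(accuracy(metrics_counts()), "zero total")
  expect_error(metrics_counts(tp = -1), "non-negative")
})

test_that("precision/recall/F1 follow their formulas with the zero convention", {
  prf <- precision_recall_f1(metrics_counts(tp = 6, fp = 2, fn = 3, tn = 9))
  expect_equal(unname(prf["precision"]), 6 / 8)
  expect_equal(unname(prf["recall"]), 6 / 9)
  expect_equal(unname(prf["f1"]),
               2 * (6 / 8) * (6 / 9) / (6 / 8 + 6 / 9))
  # zero denominators -> 0
  zero <- precision_recall_f1(metrics_counts(tn = 10))
  expect_equal(unname(zero), c(0, 0, 0))
  # harmonic-mean identity: P = R = p gives F1 = p
  expect_equal(f1_score(0.7, 0.7), 0.7)
  # F1 lies between min and max of P and R
  set.seed(9)
  for (i in 1:20) {
    p <- runif(1, 0.05, 1); r <- runif(1, 0.05, 1)
    f <- f1_score(p, r)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
  }
})

test_that("confusion matrix counts pairs and inverts to per-class counts", {
  y <- c(0, 1, 2, 2, 1, 0)
  expect_equal(diag(confusion_matrix(y, y, 3)), rep(2, 3), ignore_attr = TRUE)
  expect_equal(sum(confusion_matrix(y, y, 3)), 6)

  m <- confusion_matrix(5, 7, 16)
  expect_equal(m[6, 8], 1)
  expect_equal(sum(m), 1)

  expect_error(confusion_matrix(c(0, 16), c(0, 1), 16), "outside")
  expect_error(confusion_matrix(0:2, 0:1, 3), "equal length")

  # property: metrics derived from the matrix equal brute-force pair counts
  set.seed(31)
  for (rep in 1:3) {
    y_true <- sample(0:15, 200, replace = TRUE)
    y_pred <- sample(0:15, 200, replace = TRUE)
    conf <- confusion_matrix(y_true, y_pred, 16)
    pc <- per_class_metrics(conf)
    for (cls in 0:15) {
      bf <- brute_force_counts(y_true, y_pred, cls)
      cnt <- driveact:::counts_from_confusion(conf, cls + 1L)
      expect_equal(cnt$tp, bf$tp)
      expect_equal(cnt$fp, bf$fp)
      expect_equal(cnt$fn, bf$fn)
      expect_equal(cnt$tn, bf$tn)
      p <- if (bf$tp + bf$fp == 0) 0 else bf$tp / (bf$tp + bf$fp)
      r <- if (bf$tp + bf$fn == 0) 0 else bf$tp / (bf$tp + bf$fn)
      expect_equal(pc$precision[cls + 1L], p)
      expect_equal(pc$recall[cls + 1L], r)
    }
  }
})

test_that("weighted averages are support-weighted means", {
  expect_equal(weighted_average(c(0.2, 0.4, 0.9), c(5, 5, 5)), 0.5)
  expect_equal(weighted_average(c(0.2, 0.4, 0.9), c(0, 0, 3)), 0.9)
  expect_equal(weighted_average(c(0.9, 0.6, 0.3), c(1, 2, 3)), 0.5)
  expect_error(weighted_average(0.5, 0), "positive total")
})

test_that("type-level report collapses classes to the four groups", {
  # perfect predictions: every group at 100% / F1 1
  y <- rep(0:15, each = 5)
  rep_perfect <- type_level_report(confusion_matrix(y, y, 16))
  expect_equal(rep_perfect$groups$accuracy, rep(100, 4))
  expect_equal(rep_perfect$groups$f1, rep(1, 4), ignore_attr = TRUE)
  expect_equal(rep_perfect$binary_primary_secondary_accuracy, 100)

  # confusing parallel-left (5) with parallel-right (6) only: both map to
  # Parking, so Parking recall stays 1
  y_pred <- y
  y_pred[y == 5] <- 6
  rep_swap <- type_level_report(confusion_matrix(y, y_pred, 16))
  parking <- rep_swap$groups[rep_swap$groups$group == "Parking", ]
  expect_equal(parking$recall, 1, ignore_attr = TRUE)
  expect_equal(parking$accuracy, 100)
  expect_equal(rep_swap$binary_primary_secondary_accuracy, 100)

  # coarsening cannot reduce correctness below the 16-class accuracy
  set.seed(17)
  for (i in 1:5) {
    yt <- sample(0:15, 120, replace = TRUE)
    yp <- sample(0:15, 120, replace = TRUE)
    conf <- confusion_matrix(yt, yp, 16)
    acc16 <- 100 * sum(diag(conf)) / sum(conf)
    g4 <- type_level_report(conf)$group_confusion
    acc4 <- 100 * sum(diag(g4)) / sum(g4)
    expect_gte(acc4, acc16)
  }
})

test_that("evaluation_report assembles consistent totals", {
  set.seed(23)
  yt <- sample(0:15, 160, replace = TRUE)
  yp <- yt
  flip <- sample(160, 40)
  yp[flip] <- sample(0:15, 40, replace = TRUE)
  rep <- evaluation_report(yt, yp)
  expect_equal(rowSums(rep$confusion), as.numeric(table(factor(yt, 0:15))),
               ignore_attr = TRUE)
  expect_equal(rep$overall_accuracy, 100 * mean(yt == yp))
  expect_equal(rep$weighted[["precision"]],
               weighted_average(rep$per_class$precision, rep$per_class$support))
  expect_output(print(rep), "Overall accuracy")
})

test_that("pca_embed projects onto principal axes", {
  set.seed(12)
  # colinear data: second component carries (almost) no variance
  u <- rnorm(50)
  line <- cbind(u, 2 * u, -u)
  emb <- pca_embed(line, 2)
  ev <- attr(emb, "explained_variance")
  expect_lt(ev[2] / ev[1], 1e-20)
  expect_true(all(diff(ev) <= 0))

  # known covariance: component variances match the eigenvalues
  n <- 4000
  z <- matrix(rnorm(2 * n), n)
  A <- matrix(c(2, 0.5, 0.5, 1), 2)
  x <- z %*% chol(crossprod(A) / 2)
  cov_true <- crossprod(A) / 2
  emb2 <- pca_embed(x, 2)
  ev2 <- attr(emb2, "explained_variance")
  eig <- sort(eigen(cov_true)$values, decreasing = TRUE)
  expect_equal(ev2, eig, tolerance = 0.1)

  expect_error(pca_embed(line, 4), "exceeds")
})
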