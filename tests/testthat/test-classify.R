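test_that("confusion metrics reproduce hand arithmetic", {
  perfect <- c(tp = 50, fn = 0, fp = 0, tn = 50)
  expect_equal(unname(confusionMetrics(perfect)), rep(1, 5))

  cm <- c(tp = 40, fn = 10, fp = 5, tn = 45)
  m <- confusionMetrics(cm)
  expect_equal(unname(m["acc"]), 0.85)
  expect_equal(unname(m["sen"]), 0.8)
  expect_equal(unname(m["spe"]), 0.9)
  expect_equal(unname(m["precision"]), 8 / 9, tolerance = 1e-12)
  expect_equal(unname(m["f1"]), 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8),
               tolerance = 1e-12)

  degenerate <- c(tp = 0, fn = 10, fp = 0, tn = 90)
  expect_true(is.na(confusionMetrics(degenerate)["precision"]))
  expect_error(confusionMetrics(c(tp = 0, fn = 0, fp = 0, tn = 0)), "empty")
})

test_that("metric identities hold on random confusion matrices", {
  withr::with_seed(51, {
    for (i in 1:50) {
      cm <- c(tp = sample(1:50, 1), fn = sample(1:50, 1),
              fp = sample(1:50, 1), tn = sample(1:50, 1))
      m <- confusionMetrics(cm)
      expect_equal(m[["f1"]],
                   2 * m[["precision"]] * m[["sen"]] /
                     (m[["precision"]] + m[["sen"]]), tolerance = 1e-12)
      P <- cm[["tp"]] + cm[["fn"]]; N <- cm[["fp"]] + cm[["tn"]]
      expect_equal(m[["acc"]], (m[["sen"]] * P + m[["spe"]] * N) / (P + N),
                   tolerance = 1e-12)
    }
  })
})

test_that("Cohen's kappa matches the marginal-product formula", {
  expect_equal(cohenKappa(c(tp = 30, fn = 0, fp = 0, tn = 70)), 1)
  expect_equal(cohenKappa(c(tp = 25, fn = 25, fp = 25, tn = 25)), 0)
  expect_equal(cohenKappa(c(tp = 45, fn = 5, fp = 10, tn = 40)), 0.70,
               tolerance = 1e-12)
  expect_true(is.na(cohenKappa(c(tp = 100, fn = 0, fp = 0, tn = 0))))
})

test_that("rank-statistic AUC agrees with enumeration and integration", {
  sep <- c(0.1, 0.2, 0.8, 0.9)
  labs <- c("normal", "normal", "apnea", "apnea")
  expect_equal(rocAuc(sep, labs), 1)
  expect_equal(rocAuc(rep(0.5, 4), labs), 0.5)
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c("normal", "normal", "apnea",
                                                "apnea")), 0.75)
  expect_error(rocAuc(1:3, rep("apnea", 3)), "both classes")

  withr::with_seed(52, {
    for (i in 1:100) {
      n <- sample(10:40, 1)
      sc <- round(runif(n), 2)  # rounding forces ties
      y <- sample(c("normal", "apnea"), n, replace = TRUE)
      if (length(unique(y)) < 2) next
      expect_equal(rocAuc(sc, y), oracleAucTrapezoid(sc, y), tolerance = 1e-12)
    }
  })
})

test_that("AUC matches pROC on random score sets", {
  withr::with_seed(53, {
    for (i in 1:10) {
      sc <- runif(30)
      y <- sample(c("normal", "apnea"), 30, replace = TRUE,
                  prob = c(0.6, 0.4))
      if (length(unique(y)) < 2) next
      ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = sc,
                                            levels = c("normal", "apnea"),
                                            direction = "<", quiet = TRUE)))
      expect_equal(rocAuc(sc, y), ref, tolerance = 1e-12)
    }
  })
})

test_that("cross-validation separates the separable and not the shuffled", {
  withr::with_seed(54, toy <- separableToy(80L))
  rep1 <- runCv(toy$x, toy$y, scheme = "kfold", k = 5L, repeats = 3L,
                classifier = "rf", seed = 7L)
  s <- metricSummary(rep1)
  expect_equal(s$mean[s$metric == "acc"], 1)
  expect_equal(s$sd[s$metric == "acc"], 0)

  # determinism: same seed twice gives an identical report
  rep2 <- runCv(toy$x, toy$y, scheme = "kfold", k = 5L, repeats = 3L,
                classifier = "rf", seed = 7L)
  expect_identical(perRepeatMetrics(rep1), perRepeatMetrics(rep2))

  # shuffled labels: chance-level accuracy and kappa near zero
  withr::with_seed(55, {
    big <- separableToy(200L)
    yshuf <- sample(big$y)
  })
  repS <- runCv(big$x, yshuf, scheme = "kfold", k = 5L, repeats = 3L,
                classifier = "rf", seed = 8L)
  ss <- metricSummary(repS)
  expect_lt(abs(ss$mean[ss$metric == "acc"] - 0.5), 0.15)
  expect_lt(abs(ss$mean[ss$metric == "kappa"]), 0.2)
})

test_that("hold-out supports stratified and subject-wise splitting", {
  withr::with_seed(56, toy <- separableToy(80L))
  repH <- runCv(toy$x, toy$y, scheme = "holdout", repeats = 3L,
                classifier = "lda", seed = 9L)
  expect_equal(metricSummary(repH)$mean[1L], 1)

  groups <- rep(sprintf("subj%d", 1:8), each = 10L)
  repG <- runCv(toy$x, toy$y, scheme = "holdout", repeats = 3L,
                classifier = "lda", seed = 9L, groups = groups)
  expect_s4_class(repG, "MetricsReport")
})

test_that("every row lands in exactly one test fold per repeat", {
  y <- factor(rep(c("normal", "apnea"), c(33, 27)),
              levels = c("normal", "apnea"))
  withr::with_seed(57, {
    fold <- apneaScatter:::stratifiedFolds(y, 10L)
  })
  expect_identical(sort(unique(fold)), 1:10)
  expect_identical(length(fold), 60L)
  # stratification: each fold's class mix within one of the global mix
  for (f in 1:10) {
    expect_lte(abs(sum(y[fold == f] == "apnea") - 2.7), 1.3)
  }
})

test_that("the comparison harness runs every classifier on identical folds", {
  withr::with_seed(58, toy <- separableToy(60L))
  cls <- c("rf", "gaussiannb", "lda", "knn", "sgd", "adaboost", "xgboost",
           "svm", "extratrees", "qda", "lr")
  reports <- compareClassifiers(toy$x, toy$y, classifiers = cls,
                                scheme = "kfold", k = 5L, repeats = 1L,
                                seed = 11L)
  expect_named(reports, cls)
  for (r in reports) expect_s4_class(r, "MetricsReport")
  accs <- vapply(reports, function(r)
    metricSummary(r)$mean[metricSummary(r)$metric == "acc"], numeric(1L))
  expect_true(all(accs > 0.8))  # trivially separable for every family
  expect_error(trainClassifier("nosuch", toy$x, factor(toy$y)), "arg")
})

test_that("random forest beats naive Bayes on the synthetic benchmark", {
  fix <- easyBenchmarkFeatures()
  withr::with_seed(59, idx <- sample(nrow(fix$x), 400L))
  x <- fix$x[idx, ]; y <- fix$y[idx]
  accOf <- function(cl) {
    r <- metricSummary(runCv(x, y, scheme = "kfold", k = 5L, repeats = 1L,
                             classifier = cl, seed = 21L))
    r$mean[r$metric == "acc"]
  }
  expect_gte(accOf("rf"), accOf("gaussiannb"))
})

test_that("PCA reduction is train-fitted, orthogonal and rank-aware", {
  withr::with_seed(60, {
    train <- matrix(rnorm(300), 30, 10)
    test <- matrix(rnorm(100), 10, 10)
  })
  full <- pcaReduce(train, test, varianceTarget = 1.0)
  expect_identical(full$nComponents, 10L)
  recon <- full$train %*% t(full$fit$rotation) +
    matrix(full$fit$center, 30, 10, byrow = TRUE)
  expect_equal(recon, train, tolerance = 1e-10)

  # train projection has diagonal covariance
  cv <- cov(full$train)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)

  dup <- cbind(train, train[, 1L])
  red <- pcaReduce(dup, varianceTarget = 0.999)
  expect_lt(red$nComponents, ncol(dup))

  expect_error(pcaReduce(train, test, varianceTarget = 0), "varianceTarget")
  expect_error(pcaReduce(train, test, varianceTarget = 1.5), "varianceTarget")
})

test_that("sequential selection finds an informative feature first", {
  withr::with_seed(61, {
    n <- 120L
    y <- factor(rep(c("normal", "apnea"), each = n / 2),
                levels = c("normal", "apnea"))
    x <- cbind(labelCopy = as.numeric(y == "apnea") + rnorm(n, sd = 0.05),
               noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n),
               noise4 = rnorm(n))
  })
  fwd <- sequentialFeatureSelection(x, y, kTarget = 2L, direction = "forward",
                                    seed = 31L, nTree = 50L)
  expect_identical(fwd$selected[1L], "labelCopy")
  bi <- sequentialFeatureSelection(x, y, kTarget = 2L,
                                   direction = "bidirectional", seed = 31L,
                                   nTree = 50L)
  expect_identical(bi$selected[1L], fwd$selected[1L])
  expect_error(sequentialFeatureSelection(x, y, kTarget = 9L), "exceeds")
})
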