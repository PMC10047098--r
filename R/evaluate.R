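# Confusion-matrix metrics, Cohen's kappa, rank-statistic AUC, the two
# repeated validation protocols (stratified 50/50 hold-out and 10-fold CV,
# each repeated with fresh partitions), PCA reduction and sequential feature
# selection. Apnea is the positive class everywhere.

#' Build a confusion matrix from labels and predictions
#'
#' @param truth,predicted Vectors over normal/apnea.
#' @return Named integer vector `c(tp, fn, fp, tn)` (apnea positive).
#' @export
confusionCounts <- function(truth, predicted) {
  truth <- asBinaryFactor(truth)
  predicted <- asBinaryFactor(predicted)
  c(tp = sum(truth == "apnea" & predicted == "apnea"),
    fn = sum(truth == "apnea" & predicted == "normal"),
    fp = sum(truth == "normal" & predicted == "apnea"),
    tn = sum(truth == "normal" & predicted == "normal"))
}

#' Confusion-derived performance metrics
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)` (correctly identified
#' apnea minutes), specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` and the
#' F1 harmonic mean of precision and sensitivity. Ratios with zero
#' denominator are returned as `NA` (flagged undefined).
#'
#' @param cm Named vector with elements `tp`, `fn`, `fp`, `tn`.
#' @return Named numeric vector `acc`, `sen`, `spe`, `precision`, `f1`.
#' @export
confusionMetrics <- function(cm) {
  cm <- cm[c("tp", "fn", "fp", "tn")]
  if (anyNA(cm) || any(cm < 0)) stopf("confusion counts must be nonnegative")
  total <- sum(cm)
  if (total == 0) stopf("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sen <- ratio(cm["tp"], cm["tp"] + cm["fn"])
  prec <- ratio(cm["tp"], cm["tp"] + cm["fp"])
  f1 <- if (is.na(sen) || is.na(prec) || sen + prec == 0) NA_real_ else
    2 * prec * sen / (prec + sen)
  c(acc = unname((cm["tp"] + cm["tn"]) / total), sen = unname(sen),
    spe = unname(ratio(cm["tn"], cm["tn"] + cm["fp"])),
    precision = unname(prec), f1 = unname(f1))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e)/(1 - p_e)` with the expected
#' agreement `p_e` from the marginal products. A perfectly imbalanced table
#' (`p_e = 1`) is degenerate and returns `NA`.
#'
#' @param cm Named vector with elements `tp`, `fn`, `fp`, `tn`.
#' @return Kappa in `[-1, 1]`, or `NA` when degenerate.
#' @export
cohenKappa <- function(cm) {
  cm <- cm[c("tp", "fn", "fp", "tn")]
  total <- sum(cm)
  if (total == 0) stopf("empty confusion matrix")
  po <- (cm[["tp"]] + cm[["tn"]]) / total
  pe <- ((cm[["tp"]] + cm[["fn"]]) * (cm[["tp"]] + cm[["fp"]]) +
         (cm[["tn"]] + cm[["fp"]]) * (cm[["tn"]] + cm[["fn"]])) / total^2
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Area under the ROC curve
#'
#' Computed from the rank statistic (Mann-Whitney U normalisation) with ties
#' averaged, which equals the trapezoidal area under the empirical ROC.
#'
#' @param scores Numeric scores, larger meaning more apnea-like.
#' @param labels Labels over normal/apnea; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(scores, labels) {
  labels <- asBinaryFactor(labels)
  nP <- sum(labels == "apnea"); nN <- sum(labels == "normal")
  if (nP == 0L || nN == 0L) stopf("both classes must be present for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == "apnea"]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' ROC curve points
#'
#' False-positive and true-positive rates at every distinct threshold,
#' suitable for plotting or export.
#'
#' @inheritParams rocAuc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
rocPoints <- function(scores, labels) {
  labels <- asBinaryFactor(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- ifelse(scores >= t, "apnea", "normal")
    cm <- confusionCounts(labels, pred)
    c(fpr = unname(cm["fp"] / max(cm["fp"] + cm["tn"], 1L)),
      tpr = unname(cm["tp"] / max(cm["tp"] + cm["fn"], 1L)))
  }, numeric(2L)))
  data.frame(threshold = thr, fpr = pts[, 1L], tpr = pts[, 2L])
}

# Stratified fold assignment: within each class, shuffle and deal round-robin
# into k folds. Returns an integer fold id per row.
stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

evaluateSplit <- function(x, y, trainIdx, testIdx, classifier, seed, ...) {
  zs <- zscoreFit(x[trainIdx, , drop = FALSE])
  xtr <- zscoreApply(zs, x[trainIdx, , drop = FALSE])
  xte <- zscoreApply(zs, x[testIdx, , drop = FALSE])
  model <- trainClassifier(classifier, xtr, y[trainIdx], seed = seed, ...)
  predictProb(model, xte)
}

#' Repeated cross-validated evaluation
#'
#' The two validation protocols: `"holdout"` draws a stratified 50/50
#' train/test split per repeat (optionally subject-wise via `groups`);
#' `"kfold"` partitions the rows into `k` stratified folds per repeat and
#' pools the held-out predictions of one repeat before computing metrics.
#' Both are repeated `repeats` times (default 10) and reported as mean and
#' standard deviation across repeats. Z-score statistics are fitted inside
#' each training split only; a split that leaves one class empty is redrawn
#' with a warning.
#'
#' @param x Feature matrix, samples in rows (raw, not yet z-scored).
#' @param y Labels over normal/apnea.
#' @param scheme `"kfold"` or `"holdout"`.
#' @param k Folds for the k-fold scheme (default 10).
#' @param repeats Number of repeats (default 10).
#' @param classifier Classifier name (see [trainClassifier()]).
#' @param seed Integer seed; the same seed reproduces identical folds,
#'   training and therefore an identical report.
#' @param groups Optional per-row subject identifiers; under `"holdout"`
#'   whole subjects are assigned to one side of the split.
#' @param trainFraction Training share of the hold-out split (default 0.5).
#' @param threshold Probability cut for the confusion matrix (default 0.5).
#' @param ... Hyperparameters forwarded to [trainClassifier()].
#' @return A [MetricsReport-class].
#' @export
runCv <- function(x, y, scheme = c("kfold", "holdout"), k = 10L,
                  repeats = 10L, classifier = "rf", seed = 1L, groups = NULL,
                  trainFraction = 0.5, threshold = 0.5, ...) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  y <- asBinaryFactor(y)
  if (nrow(x) < 20L) stopf("need at least 20 rows for cross-validation")
  if (repeats < 1L) stopf("repeats must be >= 1")
  metricNames <- c("acc", "sen", "spe", "precision", "f1", "kappa", "auc")
  per <- matrix(NA_real_, nrow = repeats, ncol = length(metricNames),
                dimnames = list(NULL, metricNames))
  for (rep_i in seq_len(repeats)) {
    res <- withLocalSeed(childSeed(seed, rep_i), {
      scores <- rep(NA_real_, nrow(x))
      if (scheme == "holdout") {
        for (attempt in 1:20) {
          trainIdx <- holdoutTrainIndex(y, groups, trainFraction)
          testIdx <- setdiff(seq_len(nrow(x)), trainIdx)
          if (nlevels(droplevels(y[trainIdx])) == 2L &&
              nlevels(droplevels(y[testIdx])) == 2L) break
          warnf("degenerate hold-out split (single class); redrawing")
        }
        scores[testIdx] <- evaluateSplit(x, y, trainIdx, testIdx, classifier,
                                         childSeed(seed, 1000L + rep_i), ...)
        evalIdx <- testIdx
      } else {
        for (attempt in 1:20) {
          fold <- stratifiedFolds(y, k)
          if (all(vapply(seq_len(k), function(f)
            nlevels(droplevels(y[fold != f])) == 2L, logical(1L)))) break
          warnf("degenerate fold (single-class training set); redrawing")
        }
        for (f in seq_len(k)) {
          testIdx <- which(fold == f)
          trainIdx <- which(fold != f)
          scores[testIdx] <- evaluateSplit(x, y, trainIdx, testIdx, classifier,
                                           childSeed(seed, 1000L * f + rep_i), ...)
        }
        evalIdx <- seq_len(nrow(x))
      }
      list(scores = scores, evalIdx = evalIdx)
    })
    sc <- res$scores[res$evalIdx]
    truth <- y[res$evalIdx]
    pred <- ifelse(sc >= threshold, "apnea", "normal")
    cm <- confusionCounts(truth, pred)
    per[rep_i, ] <- c(confusionMetrics(cm), kappa = cohenKappa(cm),
                      auc = rocAuc(sc, truth))
  }
  perDf <- as.data.frame(per)
  summary <- data.frame(metric = metricNames,
                        mean = colMeans(per),
                        sd = apply(per, 2L, stats::sd),
                        row.names = NULL)
  new("MetricsReport", classifier = classifier, scheme = scheme,
      perRepeat = perDf, summary = summary)
}

holdoutTrainIndex <- function(y, groups, trainFraction) {
  if (is.null(groups)) {
    unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, round(length(idx) * trainFraction))
    }))
  } else {
    g <- unique(groups)
    gTrain <- sample(g, max(1L, round(length(g) * trainFraction)))
    which(groups %in% gTrain)
  }
}

#' Serialise a MetricsReport
#'
#' Writes the summary as tab-delimited text and, optionally, the full report
#' (including per-repeat values) as JSON.
#'
#' @param report A [MetricsReport-class].
#' @param path Output path for the delimited summary.
#' @param jsonPath Optional output path for the JSON form.
#' @return `path`, invisibly.
#' @export
writeMetricsReport <- function(report, path, jsonPath = NULL) {
  s <- metricSummary(report)
  s$classifier <- report@classifier
  s$scheme <- report@scheme
  utils::write.table(s, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(classifier = report@classifier,
                              scheme = report@scheme,
                              summary = s,
                              perRepeat = perRepeatMetrics(report)),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' PCA reduction fitted on the training split
#'
#' Principal components are fitted on the training rows only (centred, not
#' rescaled) and the projection retaining at least `varianceTarget` of the
#' training variance is applied to both splits.
#'
#' @param train,test Numeric matrices with identical columns (`test` may be
#'   `NULL`).
#' @param varianceTarget Fraction of variance to retain, in `(0, 1]`.
#' @return List with `train`, `test` (projected matrices), `nComponents`,
#'   and the fitted `prcomp` object `fit`.
#' @export
pcaReduce <- function(train, test = NULL, varianceTarget = 0.95) {
  if (!(varianceTarget > 0 && varianceTarget <= 1))
    stopf("varianceTarget must be in (0, 1]")
  fit <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  cumVar <- cumsum(fit$sdev^2) / sum(fit$sdev^2)
  nc <- which(cumVar >= varianceTarget - 1e-12)[1L]
  list(train = fit$x[, seq_len(nc), drop = FALSE],
       test = if (!is.null(test))
         stats::predict(fit, test)[, seq_len(nc), drop = FALSE],
       nComponents = nc, fit = fit)
}

# Internal CV accuracy of a feature subset, used as the SFS scorer: 5-fold
# stratified CV with a random forest (small, fixed-size for speed).
sfsScore <- function(x, y, cols, seed, nTree = 100L, folds = 5L) {
  withLocalSeed(seed, {
    fold <- stratifiedFolds(y, folds)
    acc <- vapply(seq_len(folds), function(f) {
      tr <- which(fold != f); te <- which(fold == f)
      m <- randomForest::randomForest(x[tr, cols, drop = FALSE], y[tr],
                                      ntree = nTree)
      mean(stats::predict(m, x[te, cols, drop = FALSE]) == y[te])
    }, numeric(1L))
    mean(acc)
  })
}

#' Sequential feature selection
#'
#' Greedy selection of `kTarget` features scored by 5-fold cross-validated
#' random-forest accuracy. `"forward"` adds the best feature at each step;
#' `"bidirectional"` (sequential floating forward) additionally tries to
#' discard a previously selected feature whenever that improves the score.
#' Deterministic under a fixed seed.
#'
#' @param x Feature matrix with named columns, samples in rows.
#' @param y Labels over normal/apnea.
#' @param kTarget Number of features to select (default 5).
#' @param direction `"forward"` or `"bidirectional"`.
#' @param seed Integer seed for the internal CV folds and forests.
#' @param nTree Trees per scoring forest.
#' @return List with `selected` (feature names in selection order),
#'   `scores` (CV accuracy when each feature entered), and `history`.
#' @export
sequentialFeatureSelection <- function(x, y, kTarget = 5L,
                                       direction = c("forward", "bidirectional"),
                                       seed = 1L, nTree = 100L) {
  direction <- match.arg(direction)
  x <- as.matrix(x)
  y <- asBinaryFactor(y)
  p <- ncol(x)
  if (kTarget > p) stopf("kTarget (%d) exceeds the %d candidate features", kTarget, p)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(p))
  selected <- integer(0)
  scores <- numeric(0)
  history <- list()
  step <- 0L
  while (length(selected) < kTarget) {
    step <- step + 1L
    candidates <- setdiff(seq_len(p), selected)
    candScores <- vapply(candidates, function(j)
      sfsScore(x, y, c(selected, j), childSeed(seed, step)), numeric(1L))
    best <- candidates[which.max(candScores)]
    selected <- c(selected, best)
    scores <- c(scores, max(candScores))
    history[[length(history) + 1L]] <-
      list(action = "add", feature = colnames(x)[best], score = max(candScores))
    if (direction == "bidirectional" && length(selected) > 2L) {
      # floating step: drop the least useful feature if doing so improves
      repeat {
        dropScores <- vapply(seq_along(selected), function(i)
          sfsScore(x, y, selected[-i], childSeed(seed, step)), numeric(1L))
        i <- which.max(dropScores)
        if (dropScores[i] > scores[length(scores)] + 1e-12 &&
            selected[i] != selected[length(selected)]) {
          history[[length(history) + 1L]] <-
            list(action = "drop", feature = colnames(x)[selected[i]],
                 score = dropScores[i])
          selected <- selected[-i]
          scores[length(scores)] <- dropScores[i]
        } else break
      }
    }
  }
  list(selected = colnames(x)[selected], scores = scores, history = history)
}
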