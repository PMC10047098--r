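# Classifier harness. Every entry fits on a numeric feature matrix (samples
# in rows) with a binary factor response (levels normal/apnea, apnea
# positive) and returns an object whose `predictProb` gives P(apnea) so the
# same ROC/AUC machinery applies to all of them.

CLASSIFIER_NAMES <- c("adaboost", "extratrees", "gaussiannb", "knn", "lda",
                      "lr", "qda", "rf", "sgd", "svm", "xgboost")

asBinaryFactor <- function(y) {
  y <- factor(as.character(y), levels = c("normal", "apnea"))
  if (anyNA(y)) stopf("labels must be 'normal' or 'apnea'")
  y
}

#' Train a classifier by name
#'
#' Dispatches to one of the supported classifiers. Features are assumed
#' already z-scored. Defaults follow common practice: the random forest uses
#' 500 trees with sqrt(p) candidate features per split and unlimited depth.
#'
#' @param name One of `adaboost`, `extratrees`, `gaussiannb`, `knn`, `lda`,
#'   `lr`, `qda`, `rf`, `sgd`, `svm`, `xgboost`.
#' @param x Numeric matrix, samples in rows.
#' @param y Labels (factor or character over normal/apnea).
#' @param seed Integer seed controlling any training randomness.
#' @param ... Hyperparameter overrides passed to the backend.
#' @return An object of class `"apneaClassifier"` usable with
#'   [predictProb()].
#' @export
trainClassifier <- function(name, x, y, seed = 1L, ...) {
  name <- match.arg(tolower(name), CLASSIFIER_NAMES)
  y <- asBinaryFactor(y)
  x <- as.matrix(x)
  fit <- withLocalSeed(seed, switch(name,
    rf = randomForest::randomForest(x, y, ntree = 500L, ...),
    extratrees = ranger::ranger(x = x, y = y, num.trees = 500L,
                                splitrule = "extratrees", probability = TRUE,
                                num.random.splits = 1L, seed = seed,
                                num.threads = 1L, ...),
    gaussiannb = e1071::naiveBayes(x, y, ...),
    knn = list(x = x, y = y, k = list(...)$k %||% 5L),
    lda = MASS::lda(x, grouping = y, ...),
    qda = MASS::qda(x, grouping = y, ...),
    lr = suppressWarnings(stats::glm.fit(cbind(1, x), y == "apnea",
                                         family = stats::binomial())),
    sgd = sgdLogisticFit(x, y, ...),
    svm = e1071::svm(x, y, probability = TRUE, kernel = "radial", ...),
    adaboost = adaboostFit(x, y, ...),
    xgboost = {
      dtr <- xgboost::xgb.DMatrix(x, label = as.numeric(y == "apnea"))
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       max_depth = 3L, eta = 0.3, nthread = 1L),
                         data = dtr, nrounds = 100L, verbose = 0L, ...)
    }))
  structure(list(name = name, fit = fit, levels = levels(y)),
            class = "apneaClassifier")
}

#' Probability of the apnea class
#'
#' @param model An `"apneaClassifier"` from [trainClassifier()].
#' @param newx Numeric matrix of rows to score.
#' @return Numeric vector of P(apnea) scores in `[0, 1]`.
#' @export
predictProb <- function(model, newx) {
  newx <- as.matrix(newx)
  fit <- model$fit
  switch(model$name,
    rf = unname(stats::predict(fit, newx, type = "prob")[, "apnea"]),
    extratrees = unname(stats::predict(fit, data = newx,
                                       num.threads = 1L)$predictions[, "apnea"]),
    gaussiannb = unname(stats::predict(fit, newx, type = "raw")[, "apnea"]),
    knn = {
      pr <- class::knn(fit$x, newx, fit$y, k = fit$k, prob = TRUE)
      p <- attr(pr, "prob")  # proportion of votes for the winning class
      ifelse(pr == "apnea", p, 1 - p)
    },
    lda = unname(stats::predict(fit, newx)$posterior[, "apnea"]),
    qda = unname(stats::predict(fit, newx)$posterior[, "apnea"]),
    lr = drop(stats::plogis(cbind(1, newx) %*% fit$coefficients)),
    sgd = drop(stats::plogis(cbind(1, newx) %*% fit$beta)),
    svm = {
      pr <- stats::predict(fit, newx, probability = TRUE)
      unname(attr(pr, "probabilities")[, "apnea"])
    },
    adaboost = adaboostProb(fit, newx),
    xgboost = stats::predict(fit, xgboost::xgb.DMatrix(newx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- AdaBoost.M1 with depth-1 rpart stumps ---------------------------------
# Weighted exponential-loss boosting; the additive margin is squashed to a
# probability via the logistic link (Friedman et al.'s half-margin relation).
adaboostFit <- function(x, y, nRounds = 50L) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(.y = y, x)
  stumps <- vector("list", nRounds)
  alpha <- numeric(nRounds)
  for (b in seq_len(nRounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1L, cp = -1,
                                                       minsplit = 2L,
                                                       xval = 0L))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != y))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha[b] <- 0.5 * log((1 - err) / err)
    w <- w * exp(alpha[b] * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    stumps[[b]] <- fit
    if (err >= 0.5) { stumps <- stumps[seq_len(b)]; alpha <- alpha[seq_len(b)]; break }
  }
  list(stumps = stumps, alpha = alpha, xnames = colnames(df)[-1L])
}

adaboostProb <- function(fit, newx) {
  df <- as.data.frame(newx)
  colnames(df) <- fit$xnames
  margin <- rep(0, nrow(df))
  for (b in seq_along(fit$stumps)) {
    pred <- stats::predict(fit$stumps[[b]], df, type = "class")
    margin <- margin + fit$alpha[b] * ifelse(pred == "apnea", 1, -1)
  }
  stats::plogis(2 * margin)
}

# --- Logistic regression trained by stochastic gradient descent ------------
sgdLogisticFit <- function(x, y, epochs = 30L, rate = 0.1, l2 = 1e-4) {
  n <- nrow(x)
  X <- cbind(1, x)
  t01 <- as.numeric(y == "apnea")
  beta <- numeric(ncol(X))
  step <- 0L
  for (e in seq_len(epochs)) {
    for (i in sample.int(n)) {
      step <- step + 1L
      eta <- rate / (1 + 0.01 * step)  # decaying schedule
      p <- stats::plogis(sum(X[i, ] * beta))
      g <- (p - t01[i]) * X[i, ] + l2 * c(0, beta[-1L])
      beta <- beta - eta * g
    }
  }
  list(beta = beta)
}

#' Compare classifiers on identical folds
#'
#' Runs [runCv()] once per classifier with the same seed, so every
#' classifier sees exactly the same fold assignments (paired comparison).
#'
#' @param x Feature matrix, samples in rows.
#' @param y Labels over normal/apnea.
#' @param classifiers Character vector of classifier names (default: all 11).
#' @param ... Passed to [runCv()] (scheme, repeats, seed, ...).
#' @return Named list of [MetricsReport-class], one per classifier.
#' @export
compareClassifiers <- function(x, y, classifiers = CLASSIFIER_NAMES, ...) {
  out <- lapply(classifiers, function(cl) runCv(x, y, classifier = cl, ...))
  names(out) <- classifiers
  out
}
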