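# The ten-measure feature bank computed on each scattering row: four
# population moments plus six complexity measures (Shannon, approximate,
# sample, spectral, attention and cumulative residual entropy). Natural
# logarithms throughout.

FEATURE_NAMES <- c("mean", "std", "skewness", "kurtosis", "shannon",
                   "apen", "sampen", "spen", "atten", "cre")

#' Population moment features
#'
#' Mean, standard deviation, skewness and kurtosis in their population (1/N)
#' forms; kurtosis is non-excess (a Gaussian gives 3). With zero variance the
#' shape moments are undefined and returned as `NA`.
#'
#' @param x Numeric vector, length >= 2.
#' @return Named vector `mean`, `std`, `skewness`, `kurtosis`.
#' @export
momentFeatures <- function(x) {
  n <- length(x)
  if (n < 2L) stopf("need at least 2 samples")
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  if (m2 == 0)
    return(c(mean = mu, std = 0, skewness = NA_real_, kurtosis = NA_real_))
  c(mean = mu, std = sqrt(m2), skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2)
}

#' Shannon entropy of a histogram
#'
#' Bins `x` into `nBins` equal-width bins over its range and returns
#' `-sum(p log p)` in nats; empty bins contribute zero. Degenerate data (one
#' occupied bin, or constant) give 0.
#'
#' @param x Numeric vector.
#' @param nBins Number of bins (default 32).
#' @return Nonnegative entropy in nats.
#' @export
shannonEntropy <- function(x, nBins = 32L) {
  if (nBins < 2L) stopf("nBins must be >= 2")
  r <- range(x)
  if (r[1L] == r[2L]) return(0)
  breaks <- seq(r[1L], r[2L], length.out = nBins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nBins)
  p <- counts[counts > 0] / length(x)
  -sum(p * log(p))
}

# entropy of a probability vector (zeros allowed), nats
entropyOfProbs <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Approximate entropy
#'
#' `ApEn(m, r, N) = Phi^m(r) - Phi^{m+1}(r)` with Chebyshev template
#' distances, self-matches included and denominator `N - m + 1`. The
#' similarity tolerance defaults to 0.25 STD of the series
#' (population standard deviation), which makes the measure invariant to
#' rescaling of the input. A constant series has zero tolerance and ApEn
#' defined 0.
#'
#' @param u Numeric series of length >= m + 2.
#' @param m Embedding dimension (default 2).
#' @param r Similarity tolerance; default `0.25 * sqrt(mean((u - mean(u))^2))`.
#' @return Scalar ApEn.
#' @export
approximateEntropy <- function(u, m = 2L, r = NULL) {
  if (is.null(r)) r <- 0.25 * sqrt(mean((u - mean(u))^2))
  .apenC(as.numeric(u), as.integer(m), as.numeric(r))
}

#' Sample entropy
#'
#' `SampEn = -ln(A/B)` where `B` and `A` count template pairs (`i != j`)
#' matching within `r` at lengths `m` and `m + 1`, templates drawn so both
#' lengths exist (denominator `N - m`). Zero matches yield `+Inf`, reported
#' rather than capped. A constant series gives 0 (`A = B`).
#'
#' @inheritParams approximateEntropy
#' @return Scalar SampEn (possibly `Inf`).
#' @export
sampleEntropy <- function(u, m = 2L, r = NULL) {
  if (is.null(r)) r <- 0.25 * sqrt(mean((u - mean(u))^2))
  .sampenC(as.numeric(u), as.integer(m), as.numeric(r))
}

#' Spectral entropy
#'
#' Shannon entropy of the periodogram normalised to a probability
#' distribution, scaled by `log(N_f)` to `[0, 1]` (`N_f` = number of
#' one-sided frequencies, DC through Nyquist). A flat spectrum approaches 1,
#' a pure tone approaches 0; an all-zero signal is defined 0.
#'
#' @param x Numeric vector, length >= 4.
#' @return SpEn in `[0, 1]`.
#' @export
spectralEntropy <- function(x) {
  n <- length(x)
  if (n < 4L) stopf("need at least 4 samples")
  P <- Mod(stats::fft(x))^2
  P <- P[seq_len(n %/% 2L + 1L)]  # one-sided
  tot <- sum(P)
  if (tot == 0) return(0)
  entropyOfProbs(P / tot) / log(length(P))
}

#' Attention entropy
#'
#' Key observations are the strict local maxima and minima of the series
#' (one combined stream); the measure is the Shannon entropy of the
#' distribution of index intervals between successive key points. Monotone
#' series (no interior extrema) and series with fewer than two key points are
#' defined 0, as are strictly alternating series (all intervals equal).
#'
#' @param x Numeric vector, length >= 3.
#' @return Nonnegative entropy in nats.
#' @export
attentionEntropy <- function(x) {
  n <- length(x)
  if (n < 3L) stopf("need at least 3 samples")
  i <- 2:(n - 1L)
  isMax <- x[i] > x[i - 1L] & x[i] > x[i + 1L]
  isMin <- x[i] < x[i - 1L] & x[i] < x[i + 1L]
  key <- i[isMax | isMin]
  if (length(key) < 2L) return(0)
  intervals <- diff(key)
  entropyOfProbs(as.numeric(table(intervals)) / length(intervals))
}

#' Cumulative residual entropy
#'
#' Entropy functional of the empirical survival function
#' `CRE = -integral p(X > x) log p(X > x) dx`, estimated as the
#' spacing-weighted sum `sum_i (x_(i+1) - x_(i)) * (-p_i log p_i)` with
#' `p_i = p(X > x_(i))` the fraction of the sample strictly above the i-th
#' order statistic; terms with `p = 0` contribute 0. Unlike a bare sum over
#' sample points (which depends only on ranks, i.e. is constant for
#' continuous data), this estimator responds to the spread of the values.
#' Always nonnegative; a constant sample gives 0. For the two-point sample
#' (0, 1): `p(X > 0) = 1/2`, so CRE = `-(1/2) log(1/2)` (about 0.3466 nats).
#'
#' @param x Numeric vector.
#' @return Nonnegative CRE (units of `x` times nats).
#' @export
cumulativeResidualEntropy <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  xs <- sort(x)
  p <- (n - seq_len(n - 1L)) / n  # survival just above each order statistic
  h <- ifelse(p > 0, -p * log(p), 0)
  sum(diff(xs) * h)
}

#' Ten-feature vector of one scattering row
#'
#' Applies the full feature bank to one row of flattened scattering
#' coefficients (the coefficient sequence across paths of one time window).
#'
#' @param x Numeric vector of length >= 8.
#' @param nBins Histogram bins for the Shannon measure.
#' @param m,rFactor ApEn/SampEn embedding dimension and tolerance factor
#'   (tolerance is rFactor times the population STD of the row).
#' @return Named numeric vector of the 10 features (NA where a measure is
#'   undefined, e.g. moments of a constant row).
#' @export
featureRow <- function(x, nBins = 32L, m = 2L, rFactor = 0.25) {
  if (length(x) < 8L) stopf("feature rows need >= 8 coefficients")
  r <- rFactor * sqrt(mean((x - mean(x))^2))
  c(momentFeatures(x),
    shannon = shannonEntropy(x, nBins),
    apen = approximateEntropy(x, m, r),
    sampen = sampleEntropy(x, m, r),
    spen = spectralEntropy(x),
    atten = attentionEntropy(x),
    cre = cumulativeResidualEntropy(x))
}

#' Feature bank over a flattened scattering experiment
#'
#' Computes [featureRow()] on every sample column (one scattering time
#' window's coefficients across paths) of the experiment produced by
#' [flattenWindows()], returning a new `SummarizedExperiment` with a
#' `10 x n_samples` assay `"features"` carrying the same column metadata.
#'
#' @param se `SummarizedExperiment` from [flattenWindows()], or a plain
#'   matrix with one column per sample.
#' @param ... Passed to [featureRow()].
#' @return `SummarizedExperiment` (or matrix for matrix input) of features.
#' @export
featureBank <- function(se, ...) {
  m <- if (is(se, "SummarizedExperiment"))
    SummarizedExperiment::assay(se, "scattering") else se
  f <- vapply(seq_len(ncol(m)), function(j) featureRow(m[, j], ...),
              numeric(length(FEATURE_NAMES)))
  rownames(f) <- FEATURE_NAMES
  colnames(f) <- colnames(m)
  if (!is(se, "SummarizedExperiment")) return(f)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = f),
    colData = SummarizedExperiment::colData(se))
}

#' Fit z-score statistics on training rows
#'
#' Per-feature centre (mean) and scale (population standard deviation),
#' intended to be fitted on the training split only and then applied to both
#' splits with [zscoreApply()]. Zero-variance features are passed through
#' unscaled with a warning.
#'
#' @param x Matrix with samples in rows and features in columns.
#' @return Object of class `"zscoreStats"` with fields `center` and `scale`.
#' @export
zscoreFit <- function(x) {
  if (nrow(x) < 2L) stopf("need >= 2 rows to fit z-score statistics")
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2L, center)^2))
  if (any(scale == 0)) {
    warnf("%d zero-variance feature(s) passed through unscaled",
          sum(scale == 0))
    scale[scale == 0] <- 1
  }
  structure(list(center = center, scale = scale), class = "zscoreStats")
}

#' Apply (or invert) fitted z-score statistics
#'
#' @param stats A `"zscoreStats"` object from [zscoreFit()].
#' @param x Matrix with samples in rows, same columns as the fitted data.
#' @param invert Undo the transform instead of applying it.
#' @return Transformed matrix.
#' @export
zscoreApply <- function(stats, x, invert = FALSE) {
  if (!inherits(stats, "zscoreStats"))
    stopf("stats must come from zscoreFit() (state error: unfitted statistics)")
  if (invert)
    sweep(sweep(x, 2L, stats$scale, "*"), 2L, stats$center, "+")
  else
    sweep(sweep(x, 2L, stats$center), 2L, stats$scale, "/")
}

#' One-step z-score of a feature matrix
#'
#' Fits on `x` and transforms `x` (training-only convenience; inside
#' cross-validation the fit happens on each training split).
#'
#' @param x Matrix with samples in rows.
#' @return List with `z` (transformed matrix) and `stats`.
#' @export
zscoreFitTransform <- function(x) {
  s <- zscoreFit(x)
  list(z = zscoreApply(s, x), stats = s)
}

#' Write a feature matrix as delimited text
#'
#' Tab-separated with a header naming the ten features plus label and
#' provenance columns (record, minute, window).
#'
#' @param se `SummarizedExperiment` from [featureBank()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(se, path) {
  cd <- SummarizedExperiment::colData(se)
  df <- cbind(as.data.frame(cd[, intersect(c("record", "minute", "window", "label"),
                                           colnames(cd)), drop = FALSE]),
              as.data.frame(t(SummarizedExperiment::assay(se, "features"))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
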