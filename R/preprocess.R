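# Preprocessing: one-minute segmentation, zero-phase FIR band-pass, and the
# autocorrelation-similarity quality weighting that rejects noisy segments.
#
# The weight between segments s and t is the centred cosine similarity of
# their autocorrelation vectors X_s, X_t:
#   w_st = (X_s - mean(X_s)) (X_t - mean(X_t))' /
#          (||X_s - mean(X_s)|| ||X_t - mean(X_t)||)
# which is exactly the Pearson correlation of the two ACF vectors. A segment's
# weight is the mean of w_st over the other segments of the same record, and
# segments with weight < lambda (default 0.8) are dropped as noisy.

#' Cut a record into 60-second segments
#'
#' Produces one column per complete minute; a trailing partial minute is
#' dropped. Each segment inherits the record's label for its minute (or
#' `unlabeled` when the record carries no labels).
#'
#' @param record An [EcgRecord-class].
#' @return A [SegmentSet-class]; empty (0 columns) with a warning when the
#'   record is shorter than one minute.
#' @export
segmentRecord <- function(record) {
  fs <- samplingRate(record)
  segLen <- as.integer(round(60 * fs))
  x <- ecgSamples(record)
  n <- floor(length(x) / segLen)
  if (n == 0L)
    warnf("record '%s' is shorter than one minute; no segments", recordId(record))
  dropped <- length(x) - n * segLen
  if (dropped > 0L)
    message(sprintf("record '%s': trailing %d samples (< 1 min) dropped",
                    recordId(record), dropped))
  m <- matrix(x[seq_len(n * segLen)], nrow = segLen, ncol = n)
  labels <- minuteLabels(record)
  if (!length(labels)) labels <- rep("unlabeled", n)
  new("SegmentSet", parentId = recordId(record), fs = fs, samples = m,
      minuteIndex = seq_len(n) - 1L, labels = asMinuteLabels(labels[seq_len(n)]),
      weights = rep(NA_real_, n))
}

# Linear-phase windowed-sinc band-pass, applied forward with group-delay
# compensation for zero net phase; reflection padding absorbs the edges.
designBandpass <- function(fs, lowHz, highHz, taps) {
  if (!(lowHz > 0 && lowHz < highHz && highHz < fs / 2))
    stopf("band-pass cutoffs must satisfy 0 < low < high < fs/2 (got %g, %g at fs=%g)",
          lowHz, highHz, fs)
  if (taps %% 2L == 0L) taps <- taps + 1L  # odd length => integer group delay
  h <- signal::fir1(taps - 1L, c(lowHz, highHz) / (fs / 2), type = "pass",
                    window = signal::hamming(taps))
  h - sum(h) / length(h)  # exact DC null; perturbs other bands by O(1/taps^2)
}

#' Zero-phase FIR band-pass filter
#'
#' Filters each segment (or a plain vector/matrix) with a linear-phase
#' windowed-sinc band-pass (Hamming window, 101 taps by default) and removes
#' the group delay, so the output has identical length and zero net phase.
#' The default 3-45 Hz band suppresses baseline wander and 50 Hz power-line
#' interference around the QRS energy band.
#'
#' @param x A [SegmentSet-class], numeric vector or matrix (samples in rows).
#' @param fs Sampling rate; taken from the object when `x` is a `SegmentSet`.
#' @param lowHz,highHz Band edges in Hz (defaults 3 and 45).
#' @param taps Filter length (forced odd).
#' @return Object of the same shape as `x`, filtered.
#' @export
bandpassFir <- function(x, fs = NULL, lowHz = 3, highHz = 45, taps = 101L) {
  if (is(x, "SegmentSet")) {
    out <- x
    out@samples <- bandpassFir(x@samples, samplingRate(x), lowHz, highHz, taps)
    return(out)
  }
  if (is.null(fs)) stopf("fs is required for plain numeric input")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  h <- designBandpass(fs, lowHz, highHz, taps)
  taps <- length(h)
  delay <- (taps - 1L) %/% 2L
  n <- nrow(x)
  pad <- min(taps, n)
  # reflect both ends, filter, then realign by the group delay
  xp <- rbind(x[pad:1L, , drop = FALSE], x, x[n:(n - pad + 1L), , drop = FALSE])
  y <- apply(xp, 2L, function(col) stats::filter(col, h, sides = 1L))
  y <- y[pad + delay + seq_len(n), , drop = FALSE]
  if (vec) drop(y) else y
}

#' Normalized autocorrelation vector of a segment
#'
#' Biased-normalised ACF at lags `0..nLags-1` with value 1 at lag 0. A
#' zero-variance or non-finite segment is degenerate: a vector of `NA` is
#' returned (such segments are classified noisy downstream).
#'
#' @param x Numeric vector.
#' @param nLags Number of lags (default 500, i.e. 5 s at 100 Hz — several
#'   RR intervals).
#' @return Numeric vector of length `nLags` (all `NA` when degenerate).
#' @export
acfVector <- function(x, nLags = 500L) {
  if (!all(is.finite(x)) || stats::var(x) == 0)
    return(rep(NA_real_, nLags))
  drop(stats::acf(x, lag.max = nLags - 1L, plot = FALSE, demean = TRUE)$acf)
}

#' Pairwise segment weight: centred cosine similarity of two ACF vectors
#'
#' Algebraically this equals the Pearson correlation of the two vectors and
#' lies in `[-1, 1]`, symmetric in its arguments.
#'
#' @param acfS,acfT Equal-length numeric vectors.
#' @return Scalar weight, or `NA` when either vector is degenerate (zero
#'   centred norm or non-finite).
#' @export
pairwiseWeight <- function(acfS, acfT) {
  if (length(acfS) != length(acfT))
    stopf("ACF vectors must have equal length")
  if (anyNA(acfS) || anyNA(acfT)) return(NA_real_)
  cs <- acfS - mean(acfS)
  ct <- acfT - mean(acfT)
  ns <- sqrt(sum(cs^2)); nt <- sqrt(sum(ct^2))
  if (ns == 0 || nt == 0) return(NA_real_)
  sum(cs * ct) / (ns * nt)
}

#' Quality weights and the noisy-segment decision for one record
#'
#' Computes the symmetric matrix of pairwise ACF similarities between all
#' segments of a record, averages each segment's similarity to the others
#' (the diagonal self-similarity is excluded by default), and drops segments
#' whose weight falls below `lambda` (default 0.8) or that are degenerate.
#' Weights are computed per record, i.e. per patient.
#'
#' @param segments A [SegmentSet-class] or a numeric matrix of segment
#'   columns.
#' @param lambda Rejection threshold in `[-1, 1]`.
#' @param nLags ACF length passed to [acfVector()].
#' @param includeSelf Include the unit diagonal in each segment's mean
#'   (default `FALSE`; including it shifts all weights toward 1 by the same
#'   amount).
#' @return A [SegmentWeights-class]. With fewer than 2 non-degenerate
#'   segments the weights are undefined (`NA`), nothing is dropped except
#'   degenerate segments, and a warning is raised.
#' @export
segmentWeights <- function(segments, lambda = 0.8, nLags = 500L,
                           includeSelf = FALSE) {
  m <- if (is(segments, "SegmentSet")) segmentMatrix(segments) else segments
  n <- ncol(m)
  acfs <- vapply(seq_len(n), function(i) acfVector(m[, i], nLags),
                 numeric(nLags))
  degenerate <- which(vapply(seq_len(n), function(i) anyNA(acfs[, i]), logical(1L)))
  ok <- setdiff(seq_len(n), degenerate)
  sim <- matrix(NA_real_, n, n)
  diag(sim) <- 1
  if (length(ok) >= 2L) {
    a <- acfs[, ok, drop = FALSE]
    a <- sweep(a, 2L, colMeans(a))
    a <- sweep(a, 2L, sqrt(colSums(a^2)), "/")
    sim[ok, ok] <- crossprod(a)
    sim[ok, ok][abs(sim[ok, ok]) > 1] <- sign(sim[ok, ok][abs(sim[ok, ok]) > 1])
    diag(sim) <- 1
  }
  weights <- rep(NA_real_, n)
  if (length(ok) >= 2L) {
    for (i in ok) {
      others <- if (includeSelf) ok else setdiff(ok, i)
      weights[i] <- mean(sim[i, others])
    }
  } else {
    warnf("fewer than 2 non-degenerate segments; weights undefined, nothing dropped")
  }
  dropped <- sort(unique(c(degenerate, which(!is.na(weights) & weights < lambda))))
  out <- new("SegmentWeights", similarity = sim, weights = weights,
             lambda = lambda, dropped = as.integer(dropped),
             degenerate = as.integer(degenerate), includeSelf = includeSelf)
  out
}

#' Attach weights and drop noisy segments
#'
#' Convenience wrapper: computes [segmentWeights()] for a `SegmentSet`,
#' stores the per-segment weights, and returns the set restricted to clean
#' segments.
#'
#' @param segments A [SegmentSet-class].
#' @param lambda,nLags,includeSelf Passed to [segmentWeights()].
#' @return List with elements `clean` (the filtered [SegmentSet-class] with
#'   weights filled in) and `weights` (the [SegmentWeights-class]).
#' @export
dropNoisySegments <- function(segments, lambda = 0.8, nLags = 500L,
                              includeSelf = FALSE) {
  w <- segmentWeights(segments, lambda = lambda, nLags = nLags,
                      includeSelf = includeSelf)
  keep <- setdiff(seq_len(nSegments(segments)), droppedSegments(w))
  out <- segments
  out@weights <- segmentWeightValues(w)
  out@samples <- out@samples[, keep, drop = FALSE]
  out@minuteIndex <- out@minuteIndex[keep]
  out@labels <- out@labels[keep]
  out@weights <- out@weights[keep]
  list(clean = out, weights = w)
}

#' Write a dropped-segment report
#'
#' Tab-delimited report (record, minute, weight, dropped flag) of the
#' quality-weighting outcome for one record.
#'
#' @param segments The [SegmentSet-class] the weights were computed from.
#' @param weights The matching [SegmentWeights-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeWeightReport <- function(segments, weights, path) {
  df <- data.frame(record = recordId(segments),
                   minute = segments@minuteIndex,
                   weight = segmentWeightValues(weights),
                   dropped = seq_len(nSegments(segments)) %in%
                     droppedSegments(weights))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
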