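LABEL_LEVELS <- c("normal", "apnea", "unlabeled")

asMinuteLabels <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  factor(x, levels = LABEL_LEVELS)
}

#' EcgRecord: a single-lead ECG waveform with per-minute apnea labels
#'
#' Container for one continuous single-lead ECG recording in physical units
#' (mV) together with its sampling rate and, optionally, one expert label per
#' minute over `{normal, apnea, unlabeled}`. A minute is labelled apnea when
#' at least one apneic or hypopneic event occurs within it; minute `m` covers
#' the half-open sample range `[m*60*fs, (m+1)*60*fs)` with 0-based minutes.
#'
#' @slot recordId Character scalar identifying the recording.
#' @slot samples Numeric vector of samples in mV.
#' @slot fs Sampling frequency in Hz (100 for the Apnea-ECG convention).
#' @slot labels Factor over `normal`, `apnea`, `unlabeled`; either empty or of
#'   length `floor(length(samples)/(60*fs))`.
#'
#' @export
setClass("EcgRecord",
  representation(recordId = "character", samples = "numeric",
                 fs = "numeric", labels = "factor"),
  prototype(recordId = "record", samples = numeric(0), fs = 100,
            labels = factor(character(0), levels = LABEL_LEVELS)))

setValidity("EcgRecord", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (anyNA(object@samples) || !all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  nmin <- if (length(object@fs) == 1L && object@fs > 0)
    floor(length(object@samples) / (60 * object@fs)) else NA_integer_
  if (length(object@labels) && !is.na(nmin) && length(object@labels) != nmin)
    msg <- c(msg, sprintf("labels must be empty or of length %d (one per full minute)", nmin))
  if (!identical(levels(object@labels), LABEL_LEVELS))
    msg <- c(msg, "labels must use levels normal/apnea/unlabeled")
  if (length(msg)) msg else TRUE
})

#' Construct an EcgRecord
#'
#' @param samples Numeric vector of ECG samples (mV).
#' @param fs Sampling frequency in Hz.
#' @param labels Optional per-minute labels (character or factor over
#'   `normal`/`apnea`/`unlabeled`), one per complete minute.
#' @param recordId Identifier string.
#' @return An [EcgRecord-class] object.
#' @examples
#' rec <- EcgRecord(sin(2 * pi * 1.25 * seq(0, 60, by = 0.01))[1:6000],
#'                  fs = 100, labels = "normal")
#' nMinutes(rec)
#' @export
EcgRecord <- function(samples, fs = 100, labels = character(0),
                      recordId = "record") {
  new("EcgRecord", recordId = as.character(recordId),
      samples = as.numeric(samples), fs = as.numeric(fs),
      labels = asMinuteLabels(labels))
}

#' @rdname apneaScatter-generics
#' @export
setMethod("recordId", "EcgRecord", function(x) x@recordId)
#' @rdname apneaScatter-generics
#' @export
setMethod("samplingRate", "EcgRecord", function(x) x@fs)
#' @rdname apneaScatter-generics
#' @export
setMethod("ecgSamples", "EcgRecord", function(x) x@samples)
#' @rdname apneaScatter-generics
#' @export
setMethod("minuteLabels", "EcgRecord", function(x) x@labels)

#' Number of complete minutes in a record
#' @param x An [EcgRecord-class].
#' @return Integer count of complete 60-s minutes.
#' @export
nMinutes <- function(x) floor(length(ecgSamples(x)) / (60 * samplingRate(x)))

setMethod("show", "EcgRecord", function(object) {
  n <- length(object@samples)
  cat(sprintf("EcgRecord '%s': %d samples @ %g Hz (%.1f min)\n",
              object@recordId, n, object@fs, n / (60 * object@fs)))
  if (length(object@labels))
    cat("  labels:", paste(sprintf("%s=%d", levels(object@labels),
                                   tabulate(object@labels, 3L)), collapse = " "), "\n")
  else cat("  labels: none\n")
})

#' SegmentSet: 60-second ECG segments from one record
#'
#' Column-wise matrix of fixed-length one-minute segments cut from a single
#' record, with the minute index, inherited label and (once computed) the
#' autocorrelation-similarity quality weight of each segment.
#'
#' @slot parentId Identifier of the source record.
#' @slot fs Sampling frequency in Hz.
#' @slot samples Numeric matrix `60*fs x n` of segment samples.
#' @slot minuteIndex 0-based minute of each column.
#' @slot labels Per-segment factor over `normal`/`apnea`/`unlabeled`.
#' @slot weights Per-segment quality weights (NA until computed).
#' @export
setClass("SegmentSet",
  representation(parentId = "character", fs = "numeric", samples = "matrix",
                 minuteIndex = "integer", labels = "factor",
                 weights = "numeric"))

setValidity("SegmentSet", function(object) {
  msg <- character(0)
  n <- ncol(object@samples)
  if (nrow(object@samples) != round(60 * object@fs))
    msg <- c(msg, "segments must hold exactly 60*fs samples")
  if (length(object@minuteIndex) != n || length(object@labels) != n ||
      length(object@weights) != n)
    msg <- c(msg, "per-segment metadata must match the number of columns")
  if (anyDuplicated(object@minuteIndex))
    msg <- c(msg, "minute indices must be unique")
  w <- object@weights[!is.na(object@weights)]
  if (length(w) && any(w < -1 - 1e-9 | w > 1 + 1e-9))
    msg <- c(msg, "weights must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname apneaScatter-generics
#' @export
setMethod("segmentMatrix", "SegmentSet", function(x) x@samples)
#' @rdname apneaScatter-generics
#' @export
setMethod("minuteLabels", "SegmentSet", function(x) x@labels)
#' @rdname apneaScatter-generics
#' @export
setMethod("samplingRate", "SegmentSet", function(x) x@fs)
#' @rdname apneaScatter-generics
#' @export
setMethod("recordId", "SegmentSet", function(x) x@parentId)
#' @rdname apneaScatter-generics
#' @export
setMethod("segmentWeightValues", "SegmentSet", function(x) x@weights)

#' Number of segments
#' @param x A [SegmentSet-class].
#' @return Integer.
#' @export
nSegments <- function(x) ncol(segmentMatrix(x))

setMethod("show", "SegmentSet", function(object) {
  cat(sprintf("SegmentSet from '%s': %d segments of %d samples @ %g Hz\n",
              object@parentId, ncol(object@samples), nrow(object@samples),
              object@fs))
  if (!all(is.na(object@weights)))
    cat(sprintf("  weights: [%.3f, %.3f]\n",
                min(object@weights, na.rm = TRUE),
                max(object@weights, na.rm = TRUE)))
})

#' SegmentWeights: pairwise ACF similarity and the noisy-segment decision
#'
#' Result of the quality-weighting step: the symmetric matrix of pairwise
#' centred cosine similarities between per-segment autocorrelation vectors,
#' the per-segment mean similarity, and the indices rejected at threshold
#' lambda.
#'
#' @slot similarity Symmetric similarity matrix with unit diagonal.
#' @slot weights Per-segment mean similarity (degenerate segments NA).
#' @slot lambda Rejection threshold (segments with weight < lambda drop).
#' @slot dropped Integer indices of rejected segments.
#' @slot degenerate Integer indices flagged degenerate (zero variance or
#'   non-finite), always rejected.
#' @slot includeSelf Whether the diagonal entered the per-segment mean.
#' @export
setClass("SegmentWeights",
  representation(similarity = "matrix", weights = "numeric",
                 lambda = "numeric", dropped = "integer",
                 degenerate = "integer", includeSelf = "logical"))

#' @rdname apneaScatter-generics
#' @export
setMethod("segmentWeightValues", "SegmentWeights", function(x) x@weights)
#' @rdname apneaScatter-generics
#' @export
setMethod("similarityMatrix", "SegmentWeights", function(x) x@similarity)
#' @rdname apneaScatter-generics
#' @export
setMethod("droppedSegments", "SegmentWeights", function(x) x@dropped)

setMethod("show", "SegmentWeights", function(object) {
  cat(sprintf("SegmentWeights: %d segments, lambda = %g, %d dropped (%d degenerate)\n",
              length(object@weights), object@lambda, length(object@dropped),
              length(object@degenerate)))
})

#' ScatteringFilterBank: Gabor wavelet filters for the scattering network
#'
#' Frequency-domain filter bank for a two-layer (optionally three-layer)
#' wavelet scattering network: a Gaussian low-pass `phi` whose time support
#' sets the invariance scale `T`, and per-order families of analytic Gabor
#' (admissibility-corrected Morlet) band-pass wavelets with `Q_k` wavelets per
#' octave. Filters are stored sampled on the FFT grid of the reflection-padded
#' signal and are normalised so the Littlewood-Paley sum of each layer is
#' bounded by 1.
#'
#' @slot fs Sampling rate (Hz).
#' @slot invarianceScale Invariance scale T in seconds.
#' @slot Q Integer vector of wavelets per octave, one per order.
#' @slot signalLen Expected input length in samples.
#' @slot padLen FFT length after reflection padding.
#' @slot nWindows Number of averaged output frames per segment.
#' @slot phiHat Low-pass transfer function on the FFT grid (real).
#' @slot psiHat List of matrices (`padLen x n_filters`), one per order.
#' @slot filterInfo List of data frames (`centerHz`, `sigmaHz`) per order.
#' @export
setClass("ScatteringFilterBank",
  representation(fs = "numeric", invarianceScale = "numeric", Q = "integer",
                 signalLen = "integer", padLen = "integer",
                 nWindows = "integer", phiHat = "numeric", psiHat = "list",
                 filterInfo = "list"))

setValidity("ScatteringFilterBank", function(object) {
  msg <- character(0)
  for (k in seq_along(object@filterInfo)) {
    f <- object@filterInfo[[k]]$centerHz
    if (is.unsorted(rev(f), strictly = TRUE))
      msg <- c(msg, sprintf("order-%d center frequencies must be strictly decreasing", k))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname apneaScatter-generics
#' @export
setMethod("samplingRate", "ScatteringFilterBank", function(x) x@fs)
#' @rdname apneaScatter-generics
#' @export
setMethod("nWindows", "ScatteringFilterBank", function(x) x@nWindows)

setMethod("show", "ScatteringFilterBank", function(object) {
  cat(sprintf("ScatteringFilterBank: fs=%g Hz, T=%g s, Q=(%s), len=%d\n",
              object@fs, object@invarianceScale,
              paste(object@Q, collapse = ","), object@signalLen))
  for (k in seq_along(object@psiHat))
    cat(sprintf("  order %d: %d wavelets, %.3g-%.3g Hz\n", k,
                ncol(object@psiHat[[k]]),
                min(object@filterInfo[[k]]$centerHz),
                max(object@filterInfo[[k]]$centerHz)))
})

#' ScatteringCoefficients: path x window x segment scattering tensor
#'
#' Order-0/1/2 (optionally 3) scattering coefficients for a batch of equal
#' length segments, stored as a 3-D array `paths x windows x segments` with a
#' path table (order, wavelet indices, center frequencies) aligned to rows.
#' Rows of order >= 1 average a modulus signal and are nonnegative; the
#' order-0 row is a plain low-pass average and may take either sign.
#'
#' @slot values Numeric array `n_paths x n_windows x n_segments`.
#' @slot paths `DataFrame` describing each path row.
#' @slot windowHop Hop between averaged output frames, seconds.
#' @slot fs Sampling rate of the input segments (Hz).
#' @slot segmentInfo `DataFrame` of per-segment metadata (record, minute,
#'   label).
#' @export
setClass("ScatteringCoefficients",
  representation(values = "array", paths = "DataFrame", windowHop = "numeric",
                 fs = "numeric", segmentInfo = "DataFrame"))

setValidity("ScatteringCoefficients", function(object) {
  msg <- character(0)
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be a 3-D array")
  else {
    if (nrow(object@paths) != d[1L])
      msg <- c(msg, "path table must align with rows")
    if (nrow(object@segmentInfo) != d[3L])
      msg <- c(msg, "segmentInfo must align with segments")
    mrows <- which(object@paths$order >= 1L)
    if (length(mrows) && min(object@values[mrows, , , drop = FALSE]) < -1e-10)
      msg <- c(msg, "modulus-derived coefficients (order >= 1) must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname apneaScatter-generics
#' @export
setMethod("scatteringPaths", "ScatteringCoefficients", function(x) x@paths)
#' @rdname apneaScatter-generics
#' @export
setMethod("coefficientArray", "ScatteringCoefficients", function(x) x@values)
#' @rdname apneaScatter-generics
#' @export
setMethod("nWindows", "ScatteringCoefficients", function(x) dim(x@values)[2L])

setMethod("show", "ScatteringCoefficients", function(object) {
  d <- dim(object@values)
  cat(sprintf("ScatteringCoefficients: %d paths x %d windows x %d segments (orders %s)\n",
              d[1L], d[2L], d[3L],
              paste(sort(unique(object@paths$order)), collapse = "/")))
})

#' MetricsReport: cross-validated classification metrics, mean +/- sd
#'
#' Holds per-repeat values and the mean/sd summary of accuracy, sensitivity,
#' specificity, precision, F1, Cohen's kappa and AUC for one classifier under
#' one validation scheme. Apnea is the positive class throughout.
#'
#' @slot classifier Classifier name.
#' @slot scheme Validation scheme (`holdout` or `kfold`).
#' @slot perRepeat Data frame of raw per-repeat metric values.
#' @slot summary Data frame with columns `metric`, `mean`, `sd`.
#' @export
setClass("MetricsReport",
  representation(classifier = "character", scheme = "character",
                 perRepeat = "data.frame", summary = "data.frame"))

#' @rdname apneaScatter-generics
#' @export
setMethod("metricSummary", "MetricsReport", function(x) x@summary)
#' @rdname apneaScatter-generics
#' @export
setMethod("perRepeatMetrics", "MetricsReport", function(x) x@perRepeat)

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: %s, %s, %d repeats\n", object@classifier,
              object@scheme, nrow(object@perRepeat)))
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %6.4f +/- %6.4f\n", s$metric[i], s$mean[i], s$sd[i]))
})
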