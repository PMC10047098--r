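# Wavelet scattering for 1-D ECG segments.
#
# The network cascades analytic Gabor wavelet convolutions and modulus
# nonlinearities, then averages each modulus signal with a Gaussian low-pass
# phi whose time support equals the invariance scale T:
#   S0 f      = f * phi
#   S1 f(j1)  = |f * psi_j1| * phi
#   S2 f(j1,j2) = ||f * psi_j1| * psi_j2| * phi,  xi(j2) < xi(j1)
# All convolutions are circular on a reflection-padded FFT grid.

# Gaussian frequency response (unit peak) centred at `xi` Hz, corrected so the
# wavelet has exactly zero mean (admissibility): g(w - xi) - g(xi) g(w) / g(0).
gaborHat <- function(freqHz, xi, sigma) {
  g <- function(w) exp(-w^2 / (2 * sigma^2))
  g(freqHz - xi) - g(xi) * g(freqHz)
}

# Signed frequencies (Hz) of the length-n FFT grid.
fftFreqs <- function(n, fs) {
  k <- 0:(n - 1L)
  f <- k / n * fs
  f[f >= fs / 2] <- f[f >= fs / 2] - fs
  f
}

# Geometric ladder of wavelet centre frequencies with Q per octave, from
# xiMax down to xiMin; bandwidths floored at the low-pass bandwidth so the
# slowest wavelets never outlast the averaging window.
waveletLadder <- function(xiMax, xiMin, Q, sigmaPhi) {
  xi <- xiMax * 2^(-(0:1000) / Q)
  xi <- xi[xi >= xiMin]
  sigma <- pmax(xi * (1 - 2^(-1 / Q)) / sqrt(2 * log(2)), sigmaPhi)
  data.frame(centerHz = xi, sigmaHz = sigma)
}

#' Build the scattering filter bank
#'
#' Constructs the Gaussian low-pass `phi` (time-domain FWHM equal to the
#' invariance scale `T`) and per-order families of analytic Gabor wavelets
#' logarithmically spaced with `Q[k]` wavelets per octave, sampled on the FFT
#' grid of the reflection-padded segment. Each layer is rescaled so its
#' Littlewood-Paley sum `|phi|^2 + sum_j |psi_j|^2` is bounded by 1 on the
#' grid, which makes the transform non-expansive.
#'
#' @param fs Sampling rate in Hz.
#' @param T Invariance scale in seconds (low-pass time support). Must satisfy
#'   `T * fs <= signalLen`.
#' @param Q Wavelets per octave for orders 1 and 2 (default `c(8, 1)`); a
#'   third entry may be given for order-3 diagnostics, otherwise the order-2
#'   family is reused.
#' @param signalLen Segment length in samples.
#' @param nWindows Number of averaged output frames per segment (default 6,
#'   i.e. a 10-s hop on a 60-s segment).
#' @param xiMaxFrac Highest wavelet centre frequency as a fraction of `fs`.
#' @return A [ScatteringFilterBank-class].
#' @examples
#' bank <- buildFilterBank(fs = 100, T = 60, Q = c(8, 1), signalLen = 6000)
#' bank
#' @export
buildFilterBank <- function(fs = 100, T = 60, Q = c(8L, 1L),
                            signalLen = 6000L, nWindows = 6L,
                            xiMaxFrac = 0.35) {
  if (T * fs > signalLen)
    stopf("invariance scale T=%g s exceeds the segment (%d samples at %g Hz)",
          T, signalLen, fs)
  if (any(Q < 1)) stopf("Q must be >= 1 per octave")
  signalLen <- as.integer(signalLen)
  padLen <- 2L * signalLen
  freqs <- fftFreqs(padLen, fs)

  # phi: Gaussian with time-domain FWHM = T  =>  sigma_t = T/(2 sqrt(2 ln 2)),
  # sigma_f = 1/(2 pi sigma_t).
  sigmaT <- T / (2 * sqrt(2 * log(2)))
  sigmaPhi <- 1 / (2 * pi * sigmaT)
  phiHat <- exp(-freqs^2 / (2 * sigmaPhi^2))

  xiMax <- xiMaxFrac * fs
  xiMin <- 4 * sigmaPhi
  psiHat <- list()
  filterInfo <- list()
  for (k in seq_along(Q)) {
    info <- waveletLadder(xiMax, xiMin, Q[k], sigmaPhi)
    psi <- vapply(seq_len(nrow(info)),
                  function(i) gaborHat(freqs, info$centerHz[i], info$sigmaHz[i]),
                  numeric(padLen))
    # Littlewood-Paley normalisation: scale the wavelet family so
    # |phi|^2 + sum |psi|^2 <= 1 everywhere on the grid.
    sumPsi <- rowSums(psi^2)
    sel <- sumPsi > 1e-8
    c2 <- min((1 - phiHat[sel]^2) / sumPsi[sel])
    psi <- psi * sqrt(max(c2, 0))
    psiHat[[k]] <- psi
    filterInfo[[k]] <- info
  }
  new("ScatteringFilterBank", fs = as.numeric(fs), invarianceScale = as.numeric(T),
      Q = as.integer(Q), signalLen = signalLen, padLen = padLen,
      nWindows = as.integer(nWindows), phiHat = phiHat, psiHat = psiHat,
      filterInfo = filterInfo)
}

#' Littlewood-Paley sums of a filter bank
#'
#' @param bank A [ScatteringFilterBank-class].
#' @return A matrix (`padLen x n_orders`) of `|phi|^2 + sum_j |psi_j|^2`
#'   evaluated on the FFT grid, one column per wavelet family.
#' @export
littlewoodPaley <- function(bank) {
  vapply(bank@psiHat, function(psi) bank@phiHat^2 + rowSums(psi^2),
         numeric(bank@padLen))
}

# Wavelet family used at cascade depth `order` (>= 2 reuses the last bank).
familyAt <- function(bank, order) min(order, length(bank@psiHat))

# Enumerate the frequency-decreasing scattering paths up to maxOrder.
# Returns a list of integer matrices, one per order, rows = (j1[, j2[, j3]]).
enumeratePaths <- function(bank, maxOrder) {
  out <- list(matrix(integer(0), nrow = 1L, ncol = 0L))  # order 0: one path
  if (maxOrder >= 1L)
    out[[2L]] <- matrix(seq_len(nrow(bank@filterInfo[[1L]])), ncol = 1L)
  for (m in 2:maxOrder) {
    if (maxOrder < 2L) break
    prev <- out[[m]]
    fPrev <- bank@filterInfo[[familyAt(bank, m - 1L)]]$centerHz
    fCur <- bank@filterInfo[[familyAt(bank, m)]]$centerHz
    rows <- list()
    for (r in seq_len(nrow(prev))) {
      jlast <- prev[r, ncol(prev)]
      keep <- which(fCur < fPrev[jlast])
      if (length(keep))
        rows[[length(rows) + 1L]] <-
          cbind(matrix(prev[r, ], nrow = length(keep), ncol = ncol(prev),
                       byrow = TRUE), keep)
    }
    out[[m + 1L]] <- do.call(rbind, rows)
  }
  out[seq_len(maxOrder + 1L)]
}

# Build the path metadata table aligned with coefficient rows.
pathTable <- function(bank, paths) {
  rows <- list()
  for (m in seq_along(paths) - 1L) {
    p <- paths[[m + 1L]]
    n <- nrow(p)
    if (n == 0L) next
    j1 <- if (m >= 1L) p[, 1L] else NA_integer_
    j2 <- if (m >= 2L) p[, 2L] else NA_integer_
    f1 <- if (m >= 1L) bank@filterInfo[[1L]]$centerHz[j1] else NA_real_
    f2 <- if (m >= 2L) bank@filterInfo[[familyAt(bank, 2L)]]$centerHz[j2] else NA_real_
    rows[[m + 1L]] <- S4Vectors::DataFrame(order = rep(m, n), j1 = j1, j2 = j2,
                                           centerHz1 = f1, centerHz2 = f2)
  }
  do.call(rbind, rows)
}

# The low-pass phi is essentially a delta in frequency (a handful of FFT
# bins), so averaging-then-subsampling reduces to a small inverse-DFT matrix
# applied to those bins: out[w, s] = (1/P) sum_k E[w, k] Uhat[K_k, s] with
# E[w, k] = exp(2i pi (idx_w - 1)(K_k - 1)/P) phiHat[K_k]. This avoids one
# full-length FFT per scattering path.
phiAverageOperator <- function(bank, idx, tol = 1e-8) {
  K <- which(bank@phiHat > tol)
  E <- exp(2i * pi * outer(idx - 1, K - 1) / bank@padLen) *
    matrix(bank@phiHat[K], nrow = length(idx), ncol = length(K), byrow = TRUE)
  list(K = K, E = E, P = bank@padLen)
}

phiAverage <- function(Uhat, op) {
  Re(op$E %*% Uhat[op$K, , drop = FALSE]) / op$P
}

# Equivalent operator acting on time-domain (real, nonnegative) modulus
# signals: rows are the periodized phi impulse response centred on each
# output frame, so averaging is a single real matrix product.
phiTimeOperator <- function(bank, idx) {
  P <- bank@padLen
  phiTime <- Re(stats::fft(complex(real = bank@phiHat), inverse = TRUE)) / P
  shift <- outer(idx, seq_len(P), function(i, n) ((i - n) %% P) + 1L)
  matrix(phiTime[shift], nrow = length(idx))
}

windowIndices <- function(bank) {
  hop <- bank@signalLen / bank@nWindows
  as.integer(round(hop * (seq_len(bank@nWindows) - 0.5)))
}

#' Wavelet scattering transform of one or more segments
#'
#' Computes order-0..`maxOrder` scattering coefficients of equal-length
#' segments. Order-0 is the low-pass average `f * phi`; order-m rows iterate
#' wavelet convolution and modulus before the final average (only
#' frequency-decreasing paths are kept). Averaged outputs are subsampled to
#' `nWindows(bank)` frames per segment.
#'
#' @param x Numeric vector (one segment), matrix (`signalLen x n_segments`),
#'   or [SegmentSet-class].
#' @param bank A [ScatteringFilterBank-class] built for the same length.
#' @param maxOrder Maximum scattering order (default 2; 3 supported for
#'   energy-decay diagnostics).
#' @param segmentInfo Optional `DataFrame` of per-segment metadata; derived
#'   automatically from a `SegmentSet`.
#' @param chunkSize Number of segments transformed per FFT batch.
#' @return A [ScatteringCoefficients-class].
#' @examples
#' bank <- buildFilterBank(signalLen = 1500, T = 15)
#' co <- scatteringTransform(rnorm(1500), bank)
#' co
#' @export
scatteringTransform <- function(x, bank, maxOrder = 2L, segmentInfo = NULL,
                                chunkSize = 64L) {
  if (is(x, "SegmentSet")) {
    if (is.null(segmentInfo))
      segmentInfo <- S4Vectors::DataFrame(record = recordId(x),
                                          minute = x@minuteIndex,
                                          label = minuteLabels(x))
    x <- segmentMatrix(x)
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (nrow(x) != bank@signalLen)
    stopf("segment length %d does not match the filter bank (%d)",
          nrow(x), bank@signalLen)
  if (anyNA(x) || !all(is.finite(x))) stopf("segments must be finite (no NaN)")
  if (maxOrder < 0L || maxOrder > 3L) stopf("maxOrder must be in 0..3")
  nseg <- ncol(x)
  if (is.null(segmentInfo))
    segmentInfo <- S4Vectors::DataFrame(record = rep("segment", nseg),
                                        minute = seq_len(nseg) - 1L,
                                        label = asMinuteLabels(rep("unlabeled", nseg)))

  paths <- enumeratePaths(bank, maxOrder)
  ptab <- pathTable(bank, paths)
  nPaths <- nrow(ptab)
  idx <- windowIndices(bank)
  values <- array(0, dim = c(nPaths, bank@nWindows, nseg))
  opF <- phiAverageOperator(bank, idx)
  opT <- phiTimeOperator(bank, idx)

  # Row offsets per order in the stacked path table.
  offset <- cumsum(c(0L, vapply(paths, nrow, integer(1L))))

  for (start in seq(1L, nseg, by = chunkSize)) {
    cols <- start:min(start + chunkSize - 1L, nseg)
    xc <- x[, cols, drop = FALSE]
    xpad <- rbind(xc, xc[nrow(xc):1L, , drop = FALSE])  # reflection padding
    Xhat <- stats::mvfft(xpad)

    # order 0
    values[1L, , cols] <- phiAverage(Xhat, opF)
    if (maxOrder == 0L) next

    psi1 <- bank@psiHat[[1L]]
    psi2 <- bank@psiHat[[familyAt(bank, 2L)]]
    ord2 <- if (maxOrder >= 2L) paths[[3L]] else NULL
    ord3 <- if (maxOrder >= 3L) paths[[4L]] else NULL

    for (j1 in seq_len(ncol(psi1))) {
      U1 <- Mod(stats::mvfft(Xhat * psi1[, j1], inverse = TRUE)) / bank@padLen
      U1hat <- stats::mvfft(U1)
      values[offset[2L] + j1, , cols] <- phiAverage(U1hat, opF)
      if (maxOrder < 2L) next
      rows2 <- which(ord2[, 1L] == j1)
      for (r in rows2) {
        j2 <- ord2[r, 2L]
        U2 <- Mod(stats::mvfft(U1hat * psi2[, j2], inverse = TRUE)) / bank@padLen
        values[offset[3L] + r, , cols] <- opT %*% U2
        if (maxOrder < 3L) next
        U2hat <- stats::mvfft(U2)
        rows3 <- which(ord3[, 1L] == j1 & ord3[, 2L] == j2)
        for (r3 in rows3) {
          j3 <- ord3[r3, 3L]
          U3 <- Mod(stats::mvfft(U2hat * psi2[, j3], inverse = TRUE)) / bank@padLen
          values[offset[4L] + r3, , cols] <- opT %*% U3
        }
      }
    }
  }
  # Orders >= 1 average a modulus and are nonnegative up to FFT round-off;
  # clip that round-off. Order 0 is a plain average and may be negative.
  if (nPaths > 1L) {
    mrows <- which(ptab$order >= 1L)
    v <- values[mrows, , , drop = FALSE]
    v[v < 0] <- 0
    values[mrows, , ] <- v
  }
  new("ScatteringCoefficients", values = values, paths = ptab,
      windowHop = bank@signalLen / bank@nWindows / bank@fs,
      fs = bank@fs, segmentInfo = segmentInfo)
}

#' Scattering energy by order
#'
#' Energy of the averaged coefficients, `hop * sum(S^2)` per order, so values
#' are comparable with the input energy `sum(f^2)` (the non-expansiveness
#' bound `sum_m ||S_m f||^2 <= ||f||^2` holds under the Littlewood-Paley
#' normalisation of the bank).
#'
#' @param x A [ScatteringCoefficients-class].
#' @param ... Unused.
#' @return Named numeric vector of per-order energies summed over segments.
#' @export
setMethod("scatteringEnergy", "ScatteringCoefficients", function(x, ...) {
  ords <- sort(unique(x@paths$order))
  hopSamples <- x@windowHop * x@fs
  vapply(ords, function(m) {
    rows <- which(x@paths$order == m)
    hopSamples * sum(x@values[rows, , , drop = FALSE]^2)
  }, numeric(1L), USE.NAMES = FALSE) |>
    stats::setNames(paste0("order", ords))
})

#' Flatten scattering windows into a feature-by-sample experiment
#'
#' Reshapes a `paths x windows x segments` coefficient tensor into a
#' `SummarizedExperiment` whose assay has one row per scattering path and one
#' column per (segment, window) pair, segment-major. Each column inherits its
#' parent segment's label and provenance, which is the sample layout the
#' classifier consumes (e.g. 489 segments x 6 windows give 2934 samples).
#'
#' @param x A [ScatteringCoefficients-class] or a list of them sharing one
#'   filter bank (same path table).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"scattering"`, `rowData` the path table and `colData` columns
#'   `record`, `minute`, `window`, `label`, `segment`.
#' @export
flattenWindows <- function(x) {
  if (is(x, "ScatteringCoefficients")) x <- list(x)
  ptab <- scatteringPaths(x[[1L]])
  for (co in x)
    if (!identical(as.data.frame(scatteringPaths(co)), as.data.frame(ptab)))
      stopf("all coefficient sets must share one filter bank (path sets differ)")
  mats <- list(); cd <- list(); segBase <- 0L
  for (co in x) {
    d <- dim(co@values)
    mats[[length(mats) + 1L]] <- matrix(co@values, nrow = d[1L])
    info <- co@segmentInfo
    cd[[length(cd) + 1L]] <- S4Vectors::DataFrame(
      record = rep(info$record, each = d[2L]),
      minute = rep(info$minute, each = d[2L]),
      window = rep(seq_len(d[2L]), times = d[3L]),
      label = rep(info$label, each = d[2L]),
      segment = segBase + rep(seq_len(d[3L]), each = d[2L]))
    segBase <- segBase + d[3L]
  }
  assay <- do.call(cbind, mats)
  colData <- do.call(rbind, cd)
  colnames(assay) <- sprintf("s%d.w%d", colData$segment, colData$window)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(scattering = assay), rowData = ptab, colData = colData)
}

#' Restore the 3-D tensor from a flattened experiment
#'
#' Inverse of [flattenWindows()] for a single coefficient set:
#' `unflattenWindows(flattenWindows(co))` reproduces `coefficientArray(co)`.
#'
#' @param se A `SummarizedExperiment` produced by [flattenWindows()].
#' @return Numeric array `paths x windows x segments`.
#' @export
unflattenWindows <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  nw <- max(cd$window)
  a <- SummarizedExperiment::assay(se, "scattering")
  array(a, dim = c(nrow(a), nw, ncol(a) %/% nw))
}
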