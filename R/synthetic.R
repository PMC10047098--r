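# Deterministic synthetic single-lead ECG with minute labels. Normal minutes
# are a QRS template train at a base RR interval with respiratory sinus
# modulation; apnea minutes superimpose the cyclical variation of heart rate
# (CVHR): a 30-60 s oscillation of both RR interval and R-wave amplitude,
# the bradycardia/tachycardia swing that accompanies apneic events. Noise
# sources: white noise, sub-1-Hz baseline wander, 50 Hz power-line
# interference, and optional high-amplitude broadband artifact bursts.

#' Configuration for the synthetic ECG generator
#'
#' Defaults describe a plausible overnight recording at 100 Hz: 0.8 s base
#' RR interval (75 bpm), respiratory modulation at 0.25 Hz, CVHR period
#' drawn once per record from 30-60 s, and modest noise amplitudes (mV).
#'
#' @param fs Sampling rate, Hz.
#' @param nMinutes Number of minutes to generate.
#' @param labels Per-minute labels (`"normal"`/`"apnea"`); recycled if a
#'   single value.
#' @param rrBase Base RR interval, seconds.
#' @param apneaCyclePeriod CVHR period in seconds, in `[30, 60]`; `NULL`
#'   draws one uniformly per record.
#' @param apneaRrDepth Fractional RR modulation depth during apnea minutes.
#' @param apneaAmpDepth Fractional R-amplitude modulation depth during apnea.
#' @param respDepth Fractional RR modulation depth of normal respiration.
#' @param rrJitterSd Beat-to-beat fractional RR jitter (broadband heart-rate
#'   variability; the 0.05 default approximates a physiologic sleep SDNN of ~40 ms at 75 bpm).
#' @param whiteSd White-noise standard deviation, mV.
#' @param baselineAmp Baseline-wander amplitude, mV (0.3 Hz).
#' @param powerlineAmp 50 Hz interference amplitude, mV.
#' @param artifactMinutes 0-based minute indices receiving broadband
#'   high-amplitude burst artifacts.
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `"synthConfig"`.
#' @export
synthConfig <- function(fs = 100, nMinutes = 10L, labels = "normal",
                        rrBase = 0.8, apneaCyclePeriod = NULL,
                        apneaRrDepth = 0.25, apneaAmpDepth = 0.25,
                        respDepth = 0.05, rrJitterSd = 0.05,
                        whiteSd = 0.05, baselineAmp = 0.1,
                        powerlineAmp = 0.02, artifactMinutes = integer(0),
                        seed = 1L) {
  stopifnot(fs > 0, rrBase > 0, whiteSd >= 0, baselineAmp >= 0,
            powerlineAmp >= 0)
  if (!is.null(apneaCyclePeriod) &&
      (apneaCyclePeriod < 30 || apneaCyclePeriod > 60))
    stopf("apneaCyclePeriod must lie in [30, 60] s")
  labels <- rep_len(as.character(labels), max(nMinutes, 0L))
  structure(list(fs = fs, nMinutes = as.integer(nMinutes), labels = labels,
                 rrBase = rrBase, apneaCyclePeriod = apneaCyclePeriod,
                 apneaRrDepth = apneaRrDepth, apneaAmpDepth = apneaAmpDepth,
                 respDepth = respDepth, rrJitterSd = rrJitterSd,
                 whiteSd = whiteSd,
                 baselineAmp = baselineAmp, powerlineAmp = powerlineAmp,
                 artifactMinutes = as.integer(artifactMinutes),
                 seed = as.integer(seed)),
            class = "synthConfig")
}

# Gaussian-derivative QRS template: biphasic spike of ~80 ms width, peak 1.
qrsTemplate <- function(fs, widthSec = 0.022) {
  t <- seq(-0.06, 0.06, by = 1 / fs)
  w <- -t / widthSec * exp(0.5 - 0.5 * (t / widthSec)^2)
  w / max(abs(w))
}

#' Generate a labelled synthetic ECG record
#'
#' @param config A [synthConfig()] list.
#' @return An [EcgRecord-class] with one label per minute. Zero requested
#'   minutes give an empty record.
#' @export
generateRecord <- function(config) {
  stopifnot(inherits(config, "synthConfig"))
  fs <- config$fs
  nMin <- config$nMinutes
  if (nMin == 0L)
    return(EcgRecord(numeric(0), fs = fs, recordId = sprintf("synth%d", config$seed)))
  withLocalSeed(config$seed, {
    period <- config$apneaCyclePeriod %||% stats::runif(1L, 30, 60)
    segLen <- round(60 * fs)
    tpl <- qrsTemplate(fs)
    half <- (length(tpl) - 1L) %/% 2L
    x <- numeric(nMin * segLen)
    for (m in seq_len(nMin) - 1L) {
      apnea <- config$labels[m + 1L] == "apnea"
      phase <- stats::runif(1L, 0, 2 * pi)
      respPhase <- stats::runif(1L, 0, 2 * pi)
      # beat times within the minute from the instantaneous RR interval
      tBeat <- stats::runif(1L, 0, config$rrBase)
      while (tBeat < 60) {
        rr <- config$rrBase *
          (1 + config$respDepth * sin(2 * pi * 0.25 * tBeat + respPhase) +
             config$rrJitterSd * stats::rnorm(1L) +
             (if (apnea) config$apneaRrDepth * sin(2 * pi * tBeat / period + phase) else 0))
        amp <- 1 + 0.03 * stats::rnorm(1L) +
          (if (apnea) config$apneaAmpDepth * sin(2 * pi * tBeat / period + phase) else 0)
        c0 <- m * segLen + round(tBeat * fs)  # 0-based centre sample
        lo <- max(c0 - half, 0L); hi <- min(c0 + half, length(x) - 1L)
        x[(lo + 1L):(hi + 1L)] <- x[(lo + 1L):(hi + 1L)] +
          amp * tpl[(lo - (c0 - half) + 1L):(hi - (c0 - half) + 1L)]
        tBeat <- tBeat + max(rr, 0.3)
      }
    }
    n <- length(x)
    tAll <- (seq_len(n) - 1L) / fs
    x <- x + config$whiteSd * stats::rnorm(n) +
      config$baselineAmp * sin(2 * pi * 0.3 * tAll + stats::runif(1L, 0, 2 * pi)) +
      config$powerlineAmp * sin(2 * pi * 50 * tAll)
    for (m in config$artifactMinutes) {
      if (m < 0L || m >= nMin) next
      for (b in seq_len(3L)) {  # a few 2-4 s broadband bursts
        start <- m * segLen + sample.int(segLen - 4L * fs, 1L)
        len <- round(stats::runif(1L, 2, 4) * fs)
        x[start:(start + len)] <- x[start:(start + len)] +
          2 * stats::rnorm(len + 1L)
      }
    }
    EcgRecord(x, fs = fs, labels = config$labels,
              recordId = sprintf("synth%d", config$seed))
  })
}

#' Standard synthetic benchmark
#'
#' A fixed-seed set of mixed-label records for end-to-end evaluation. The
#' `easy` difficulty uses deep CVHR modulation and low noise; `hard` uses
#' shallow modulation and substantially more noise (classes overlap more).
#' Minutes are interleaved normal/apnea within each record so the per-record
#' quality weighting sees both classes.
#'
#' @param nPerClass Labelled minutes per class across the whole benchmark.
#' @param difficulty `"easy"` or `"hard"`.
#' @param seed Base seed (per-record seeds derive from it).
#' @param minutesPerRecord Minutes in each record (default 40).
#' @return List with `records` (list of [EcgRecord-class]) and `config`
#'   (the per-difficulty generator settings).
#' @export
makeBenchmark <- function(nPerClass, difficulty = c("easy", "hard"),
                          seed = 20230399L, minutesPerRecord = 40L) {
  difficulty <- match.arg(difficulty)
  pars <- switch(difficulty,
    easy = list(rrDepth = 0.30, ampDepth = 0.30, whiteSd = 0.03),
    hard = list(rrDepth = 0.10, ampDepth = 0.10, whiteSd = 0.15))
  nRecords <- ceiling(2 * nPerClass / minutesPerRecord)
  labels <- rep(c("normal", "apnea"), length.out = 2 * nPerClass)
  records <- vector("list", nRecords)
  at <- 1L
  for (i in seq_len(nRecords)) {
    take <- min(minutesPerRecord, length(labels) - at + 1L)
    cfg <- synthConfig(nMinutes = take, labels = labels[at:(at + take - 1L)],
                       apneaRrDepth = pars$rrDepth,
                       apneaAmpDepth = pars$ampDepth,
                       whiteSd = pars$whiteSd,
                       seed = childSeed(seed, i))
    records[[i]] <- generateRecord(cfg)
    records[[i]]@recordId <- sprintf("%s%02d", difficulty, i)
    at <- at + take
  }
  list(records = records, config = pars)
}
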