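# End-to-end orchestration: records -> band-pass -> quality weighting ->
# scattering -> feature bank -> z-scored classification -> metric reports,
# with every intermediate persisted alongside a provenance stamp.

#' Pipeline configuration
#'
#' All tunable parameters of the pipeline with their conventional defaults
#' (band 3-45 Hz, lambda 0.8, invariance scale 60 s, Q1=8/Q2=1, 6 output
#' windows, r = 0.25 STD, 10 repeats of each validation scheme).
#'
#' @param synth Either `NULL` (caller supplies records) or a list
#'   `list(nPerClass =, difficulty =)` describing a [makeBenchmark()] run.
#' @param inputPaths Character vector of delimited-signal paths (with
#'   optional `annotationPaths`) read via [readDelimitedSignal()].
#' @param annotationPaths Label sidecars matching `inputPaths`.
#' @param fs Sampling rate for delimited inputs.
#' @param bandpass List `low`, `high`, `taps`.
#' @param weight List `lambda`, `nLags`, `includeSelf`.
#' @param scattering List `T`, `Q1`, `Q2`, `nWindows`, `maxOrder`.
#' @param features List `nBins`, `m`, `rFactor`.
#' @param cv List `scheme`, `k`, `repeats`, `classifiers`.
#' @param seed Master seed.
#' @param outDir Output directory (created if missing); `NULL` keeps results
#'   in memory only.
#' @return A list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(synth = list(nPerClass = 100L, difficulty = "easy"),
                           inputPaths = NULL, annotationPaths = NULL,
                           fs = 100,
                           bandpass = list(low = 3, high = 45, taps = 101L),
                           weight = list(lambda = 0.8, nLags = 500L,
                                         includeSelf = FALSE),
                           scattering = list(T = 60, Q1 = 8L, Q2 = 1L,
                                             nWindows = 6L, maxOrder = 2L),
                           features = list(nBins = 32L, m = 2L, rFactor = 0.25),
                           cv = list(scheme = "kfold", k = 10L, repeats = 10L,
                                     classifiers = "rf"),
                           seed = 1L, outDir = NULL) {
  structure(list(synth = synth, inputPaths = inputPaths,
                 annotationPaths = annotationPaths, fs = fs,
                 bandpass = bandpass, weight = weight,
                 scattering = scattering, features = features, cv = cv,
                 seed = as.integer(seed), outDir = outDir),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the [pipelineConfig()] defaults; nested
#' blocks (`bandpass`, `weight`, `scattering`, `features`, `cv`) are merged
#' key-wise.
#'
#' @param path YAML file path.
#' @return A `"pipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  base <- pipelineConfig()
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      for (k2 in names(user[[k]])) base[[k]][[k2]] <- user[[k]][[k2]]
    } else base[[k]] <- user[[k]]
  }
  base
}

stageError <- function(stage, fmt, ...) {
  stop(sprintf("[stage %s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}

#' Run the full detection pipeline
#'
#' Executes read/simulate -> band-pass -> per-record quality weighting ->
#' scattering -> feature bank -> repeated cross-validated classification.
#' When `config$outDir` is set, every intermediate is written there
#' (weight reports, flattened features, metric summaries) together with
#' `provenance.json` holding the config hash, seed and package version, so a
#' rerun with the same config reproduces the artifacts bit-identically.
#' Failures abort with a stage-tagged error; artifacts written before the
#' failure are retained.
#'
#' @param config A `"pipelineConfig"` list.
#' @param records Optional list of [EcgRecord-class] overriding the config's
#'   input specification.
#' @return Invisible list: `records`, `segments`, `weightReports`,
#'   `features` (a `SummarizedExperiment`), `metrics` (named list of
#'   [MetricsReport-class]), `counts` (per-stage bookkeeping).
#' @export
runPipeline <- function(config, records = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  outDir <- config$outDir
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  # --- input ---------------------------------------------------------------
  if (is.null(records)) {
    if (!is.null(config$inputPaths)) {
      records <- lapply(seq_along(config$inputPaths), function(i)
        readDelimitedSignal(config$inputPaths[i], fs = config$fs,
                            annotationPath = config$annotationPaths[i]))
    } else if (!is.null(config$synth)) {
      records <- makeBenchmark(config$synth$nPerClass,
                               config$synth$difficulty,
                               seed = childSeed(config$seed, 77L))$records
    } else stageError("input", "no input records, paths or synth block given")
  }
  counts <- list(records = length(records),
                 minutes = sum(vapply(records, nMinutes, numeric(1L))))
  message(sprintf("[input] %d records, %d labelled minutes",
                  counts$records, counts$minutes))

  # --- preprocess ----------------------------------------------------------
  segs <- list(); weightReports <- list()
  for (rec in records) {
    ss <- segmentRecord(rec)
    if (nSegments(ss) == 0L) next
    ss <- bandpassFir(ss, lowHz = config$bandpass$low,
                      highHz = config$bandpass$high,
                      taps = config$bandpass$taps)
    res <- dropNoisySegments(ss, lambda = config$weight$lambda,
                             nLags = config$weight$nLags,
                             includeSelf = config$weight$includeSelf)
    weightReports[[recordId(rec)]] <- res$weights
    if (!is.null(outDir))
      writeWeightReport(ss, res$weights,
                        file.path(outDir, sprintf("weights_%s.tsv", recordId(rec))))
    segs[[recordId(rec)]] <- res$clean
  }
  counts$segmentsIn <- sum(vapply(records, nMinutes, numeric(1L)))
  counts$segmentsClean <- sum(vapply(segs, nSegments, integer(1L)))
  counts$segmentsDropped <- counts$segmentsIn - counts$segmentsClean
  message(sprintf("[preprocess] %d/%d segments clean (%d dropped as noisy)",
                  counts$segmentsClean, counts$segmentsIn,
                  counts$segmentsDropped))
  if (counts$segmentsClean == 0L)
    stageError("preprocess", "no clean segments survive lambda=%g",
               config$weight$lambda)

  # --- scattering ----------------------------------------------------------
  sc <- config$scattering
  bank <- buildFilterBank(fs = config$fs, T = sc$T, Q = c(sc$Q1, sc$Q2),
                          signalLen = round(60 * config$fs),
                          nWindows = sc$nWindows)
  coeffs <- lapply(segs, function(s)
    scatteringTransform(s, bank, maxOrder = sc$maxOrder))
  flat <- flattenWindows(coeffs)
  counts$windows <- ncol(flat)
  message(sprintf("[scattering] %d paths x %d windows", nrow(flat), ncol(flat)))

  # --- features ------------------------------------------------------------
  feats <- featureBank(flat, nBins = config$features$nBins,
                       m = config$features$m,
                       rFactor = config$features$rFactor)
  if (!is.null(outDir))
    writeFeatureTable(feats, file.path(outDir, "features.tsv"))
  message(sprintf("[features] %d x %d feature matrix",
                  nrow(feats), ncol(feats)))

  # --- classification ------------------------------------------------------
  lab <- SummarizedExperiment::colData(feats)$label
  keep <- which(lab %in% c("normal", "apnea"))
  if (length(keep) < 20L)
    stageError("classify", "no clean labelled windows to classify (got %d)",
               length(keep))
  x <- t(SummarizedExperiment::assay(feats, "features"))[keep, , drop = FALSE]
  y <- droplevels(factor(lab[keep], levels = c("normal", "apnea")))
  if (nlevels(y) < 2L)
    stageError("classify", "need both classes among clean windows")
  metrics <- list()
  for (cl in config$cv$classifiers) {
    rep <- runCv(x, y, scheme = config$cv$scheme, k = config$cv$k,
                 repeats = config$cv$repeats, classifier = cl,
                 seed = childSeed(config$seed, 99L))
    metrics[[cl]] <- rep
    if (!is.null(outDir))
      writeMetricsReport(rep, file.path(outDir, sprintf("metrics_%s_%s.tsv",
                                                        cl, config$cv$scheme)),
                         file.path(outDir, sprintf("metrics_%s_%s.json",
                                                   cl, config$cv$scheme)))
    message(sprintf("[classify] %s %s: acc %.3f", cl, config$cv$scheme,
                    metricSummary(rep)$mean[metricSummary(rep)$metric == "acc"]))
  }

  if (!is.null(outDir)) {
    cfgNoOut <- config; cfgNoOut$outDir <- NULL
    jsonlite::write_json(list(configHash = objectHash(cfgNoOut),
                              seed = config$seed,
                              package = as.character(utils::packageVersion("apneaScatter")),
                              counts = counts),
                         file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(records = records, segments = segs,
                 weightReports = weightReports, features = feats,
                 metrics = metrics, counts = counts, bank = bank))
}

#' Empirical complexity probe of the scattering transform
#'
#' Times the transform at several signal lengths and fits the log-log slope
#' of runtime against `N log2 N` (the expected scaling of the FFT-based
#' cascade). Diagnostic only: the slope depends on the machine and on
#' constant overheads at small N.
#'
#' @param lengths Integer vector of signal lengths (>= 3 for a fit).
#' @param fs Sampling rate used for the probe banks.
#' @param reps Transforms averaged per length.
#' @return List with `table` (length, paths, seconds) and `slope` (`NA`
#'   when fewer than 3 lengths are given, with a message).
#' @export
complexityProbe <- function(lengths, fs = 100, reps = 2L) {
  lengths <- sort(as.integer(lengths))
  rows <- lapply(lengths, function(n) {
    bank <- buildFilterBank(fs = fs, T = n / fs, Q = c(8L, 1L),
                            signalLen = n, nWindows = min(6L, n %/% 2L))
    x <- matrix(stats::rnorm(n * reps), n, reps)
    t0 <- proc.time()[["elapsed"]]
    co <- scatteringTransform(x, bank)
    data.frame(n = n, paths = nrow(scatteringPaths(co)),
               seconds = (proc.time()[["elapsed"]] - t0) / reps)
  })
  tab <- do.call(rbind, rows)
  slope <- NA_real_
  if (length(lengths) >= 3L) {
    work <- tab$n * log2(tab$n)
    slope <- stats::coef(stats::lm(log(tab$seconds) ~ log(work)))[[2L]]
  } else message("complexity probe needs >= 3 lengths to fit a slope")
  list(table = tab, slope = slope)
}
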