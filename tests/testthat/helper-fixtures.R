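# Shared fixtures, computed lazily once per test run and cached. The main
# one is the standard easy synthetic benchmark (200 labelled minutes per
# class) carried through preprocessing, scattering and the feature bank; it
# backs both the end-to-end recovery checks and the feature-separation
# property.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache, inherits = FALSE)
}

easyBenchmarkFeatures <- function() cachedFixture("easyFeatures", {
  bench <- makeBenchmark(200L, "easy", seed = 20230399L)
  bank <- buildFilterBank(fs = 100, T = 60, Q = c(8L, 1L), signalLen = 6000L)
  segs <- lapply(bench$records, function(rec) {
    ss <- bandpassFir(segmentRecord(rec))
    dropNoisySegments(ss)$clean
  })
  segs <- segs[vapply(segs, nSegments, integer(1L)) > 0L]
  flat <- flattenWindows(lapply(segs, scatteringTransform, bank = bank))
  feats <- featureBank(flat)
  lab <- SummarizedExperiment::colData(feats)$label
  keep <- which(lab %in% c("normal", "apnea"))
  list(x = t(SummarizedExperiment::assay(feats, "features"))[keep, ],
       y = droplevels(factor(lab[keep], levels = c("normal", "apnea"))),
       segments = segs)
})

# Small filter bank + deterministic noise segments for scattering unit tests.
smallBank <- function() cachedFixture("smallBank",
  buildFilterBank(fs = 100, T = 15, Q = c(8L, 1L), signalLen = 1500L,
                  nWindows = 3L))

# Band-limited Gaussian noise: white noise band-passed to lowHz..highHz.
bandlimitedNoise <- function(n, fs = 100, lowHz = 3, highHz = 30) {
  x <- stats::rnorm(n)
  bandpassFir(x, fs = fs, lowHz = lowHz, highHz = highHz)
}

# A linearly separable toy feature set for classifier tests.
separableToy <- function(n = 60L) {
  y <- rep(c("normal", "apnea"), each = n / 2)
  x <- cbind(f1 = ifelse(y == "apnea", 2, -2) + stats::rnorm(n, sd = 0.2),
             f2 = stats::rnorm(n))
  list(x = x, y = y)
}
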