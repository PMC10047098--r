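test_that("segmentation yields one column per complete minute with labels", {
  rec <- EcgRecord(rnorm(6000), fs = 100, labels = "apnea")
  ss <- segmentRecord(rec)
  expect_identical(nSegments(ss), 1L)
  expect_identical(as.character(minuteLabels(ss)), "apnea")

  rec2 <- EcgRecord(rnorm(6150), fs = 100, labels = "normal")
  expect_message(ss2 <- segmentRecord(rec2), "150 samples")
  expect_identical(nSegments(ss2), 1L)

  labs <- rep(c("normal", "apnea"), 5L)
  rec10 <- generateRecord(synthConfig(nMinutes = 10L, labels = labs, seed = 2L))
  ss10 <- segmentRecord(rec10)
  expect_identical(nSegments(ss10), 10L)
  expect_identical(as.character(minuteLabels(ss10)), labs)
  # minute m covers samples [m*60*fs, (m+1)*60*fs)
  expect_identical(segmentMatrix(ss10)[, 3L],
                   ecgSamples(rec10)[(2 * 6000 + 1):(3 * 6000)])

  expect_warning(short <- segmentRecord(EcgRecord(rnorm(100), fs = 100)),
                 "shorter than one minute")
  expect_identical(nSegments(short), 0L)
})

test_that("band-pass rejects DC and power line but passes the QRS band", {
  fs <- 100
  t <- (0:5999) / fs
  expect_lt(max(abs(bandpassFir(rep(1, 6000), fs = fs))), 1e-3)

  mid <- 1000:5000  # judge amplitudes away from the edges
  s10 <- sin(2 * pi * 10 * t)
  expect_lt(abs(max(abs(bandpassFir(s10, fs = fs)[mid])) - 1), 0.05)

  s50 <- sin(2 * pi * 49.9 * t)  # power-line band, near Nyquist
  atten <- max(abs(bandpassFir(s50, fs = fs)[mid]))
  expect_lt(20 * log10(atten), -20)

  expect_error(bandpassFir(s10, fs = fs, lowHz = 0), "cutoffs")
  expect_error(bandpassFir(s10, fs = fs, lowHz = 10, highHz = 60), "cutoffs")
})

test_that("filtering preserves length and is stable under reapplication", {
  set.seed(3)
  x <- matrix(rnorm(6000 * 3), 6000, 3)
  y1 <- bandpassFir(x, fs = 100)
  expect_identical(dim(y1), dim(x))
  y2 <- bandpassFir(y1, fs = 100)
  expect_identical(dim(y2), dim(x))
  # twice ~ once up to the filter's own passband shaping: compare a
  # mid-band sine through one vs two passes
  t <- (0:5999) / 100
  s <- sin(2 * pi * 15 * t)
  mid <- 1000:5000
  onePass <- bandpassFir(s, fs = 100)[mid]
  twoPass <- bandpassFir(bandpassFir(s, fs = 100), fs = 100)[mid]
  expect_lt(max(abs(twoPass - onePass)) / max(abs(onePass)), 0.02)
})

test_that("the ACF vector matches a brute-force oracle and flags degeneracy", {
  set.seed(4)
  x <- rnorm(2000)
  a <- acfVector(x, nLags = 200L)
  expect_equal(a[1L], 1)
  expect_equal(a, oracleAcf(x, 200L), tolerance = 1e-10)
  expect_lt(max(abs(a[-1L])), 0.1)

  s <- sin(2 * pi * 1 * (0:1999) / 100)  # 1 Hz periodic at fs=100
  as <- acfVector(s, nLags = 150L)
  expect_equal(which.max(as[-1L]), 100L, tolerance = 2)

  expect_true(all(is.na(acfVector(rep(2, 500)))))
})

test_that("pairwise weights equal Pearson correlation of the ACF vectors", {
  a <- c(1, 2, 3)
  expect_equal(pairwiseWeight(a, a), 1)
  expect_equal(pairwiseWeight(a, -a + 10), -1)
  expect_equal(pairwiseWeight(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_equal(pairwiseWeight(c(1, 2, 3), c(1, 3, 2)),
               oraclePearson(c(1, 2, 3), c(1, 3, 2)))
  set.seed(8)
  for (i in 1:50) {
    u <- rnorm(40); v <- rnorm(40)
    expect_equal(pairwiseWeight(u, v), oraclePearson(u, v), tolerance = 1e-12)
    expect_equal(pairwiseWeight(u, v), pairwiseWeight(v, u))
    expect_true(abs(pairwiseWeight(u, v)) <= 1 + 1e-12)
  }
  expect_true(is.na(pairwiseWeight(rep(1, 10), rnorm(10))))
})

test_that("segment weighting averages similarities and applies the threshold", {
  seg <- matrix(rep(sin(2 * pi * 1.25 * (0:5999) / 100), 3L), ncol = 3L)
  w <- segmentWeights(seg)
  expect_equal(segmentWeightValues(w), rep(1, 3L))
  expect_identical(droppedSegments(w), integer(0))
  S <- similarityMatrix(w)
  expect_equal(S, t(S))
  expect_equal(diag(S), rep(1, 3L))
  expect_true(all(abs(S) <= 1 + 1e-12))

  # threshold extremes
  set.seed(9)
  m <- segmentMatrix(segmentRecord(generateRecord(synthConfig(nMinutes = 5L,
                                                              seed = 10L))))
  expect_identical(droppedSegments(segmentWeights(m, lambda = 1.01)), 1:5)
  expect_identical(droppedSegments(segmentWeights(m, lambda = -1.01)), integer(0))

  # degenerate handling
  m2 <- cbind(m[, 1:2], 0)
  w2 <- segmentWeights(m2)
  expect_identical(w2@degenerate, 3L)
  expect_true(3L %in% droppedSegments(w2))
  expect_warning(segmentWeights(cbind(m[, 1L], 0)), "fewer than 2")
})

test_that("an artifact segment weighs strictly below every clean segment", {
  cfg <- synthConfig(nMinutes = 8L, labels = "normal", artifactMinutes = 2L,
                     seed = 13L)
  ss <- bandpassFir(segmentRecord(generateRecord(cfg)))
  w <- segmentWeightValues(segmentWeights(ss))
  expect_lt(w[3L], min(w[-3L]))
})

test_that("weights are permutation-equivariant", {
  set.seed(14)
  ss <- bandpassFir(segmentRecord(generateRecord(
    synthConfig(nMinutes = 6L, labels = c(rep("normal", 5L), "apnea"),
                seed = 15L))))
  m <- segmentMatrix(ss)
  w <- segmentWeightValues(segmentWeights(m))
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  wp <- segmentWeightValues(segmentWeights(m[, perm]))
  expect_equal(wp, w[perm], tolerance = 1e-12)
})

test_that("dropNoisySegments filters and reports consistently", {
  cfg <- synthConfig(nMinutes = 6L, labels = "normal", artifactMinutes = 1L,
                     seed = 16L)
  ss <- bandpassFir(segmentRecord(generateRecord(cfg)))
  res <- dropNoisySegments(ss, lambda = 0.8)
  expect_s4_class(res$clean, "SegmentSet")
  expect_identical(nSegments(res$clean),
                   6L - length(droppedSegments(res$weights)))
  expect_true(all(segmentWeightValues(res$clean) >= 0.8))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeWeightReport(ss, res$weights, p)
  rep <- read.delim(p)
  expect_identical(nrow(rep), 6L)
  expect_identical(sum(rep$dropped), length(droppedSegments(res$weights)))
})
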