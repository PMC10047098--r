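test_that("population moments match hand-derived values and Gaussian limits", {
  m <- momentFeatures(c(1, 1, 1, 1))
  expect_equal(unname(m[c("mean", "std")]), c(1, 0))
  expect_true(all(is.na(m[c("skewness", "kurtosis")])))

  m2 <- momentFeatures(c(0, 0, 0, 1))
  expect_equal(unname(m2["mean"]), 0.25)
  expect_equal(unname(m2["std"]), sqrt(3) / 4, tolerance = 1e-12)
  expect_equal(unname(m2["skewness"]), 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(unname(m2["kurtosis"]), 7 / 3, tolerance = 1e-12)

  withr::with_seed(31, z <- rnorm(1e5))
  mz <- momentFeatures(z)
  expect_lt(abs(mz[["skewness"]]), 0.1)
  expect_lt(abs(mz[["kurtosis"]] - 3), 0.1)
})

test_that("histogram Shannon entropy evaluates known distributions", {
  expect_equal(shannonEntropy(rep(3.7, 50)), 0)  # one occupied bin

  # four equally occupied bins -> log 4
  x4 <- c(0.1, 0.12, 0.35, 0.37, 0.6, 0.62, 0.85, 0.87)
  expect_equal(shannonEntropy(x4, nBins = 4L), log(4), tolerance = 1e-12)

  # probabilities (1/2, 1/4, 1/4) -> 1.0397 nats
  x3 <- c(0, 0.05, 0.35, 0.65)
  expect_equal(shannonEntropy(x3, nBins = 4L), 1.5 * log(2), tolerance = 1e-12)
  expect_equal(1.5 * log(2), 1.0397, tolerance = 1e-4)

  withr::with_seed(32, x <- runif(500))
  expect_equal(shannonEntropy(x, 16L), oracleShannonHist(x, 16L),
               tolerance = 1e-12)
  expect_error(shannonEntropy(x, nBins = 1L), "nBins")
})

test_that("approximate entropy matches its brute-force oracle", {
  expect_equal(approximateEntropy(rep(5, 50)), 0)

  alt <- rep(c(1, -1), 30)
  expect_equal(approximateEntropy(alt, m = 2L, r = 0.5),
               oracleApEn(alt, 2L, 0.5), tolerance = 1e-12)

  withr::with_seed(33, {
    for (i in 1:20) {
      u <- rnorm(60)
      r <- 0.25 * sqrt(mean((u - mean(u))^2))
      expect_equal(approximateEntropy(u, 2L, r), oracleApEn(u, 2L, r),
                   tolerance = 1e-12)
    }
  })

  # irregularity ordering: white noise above a pure tone
  withr::with_seed(34, {
    noise <- rnorm(300)
    tone <- sin(2 * pi * (1:300) / 100)
    tone <- tone * sd(noise) / sd(tone)
  })
  expect_gt(approximateEntropy(noise), approximateEntropy(tone))
})

test_that("sample entropy matches its oracle and flags degeneracy", {
  expect_equal(sampleEntropy(rep(2, 30)), 0)

  u <- rep(c(1, 2, 3), 3L)
  expect_equal(sampleEntropy(u, m = 2L, r = 0.5), oracleSampEn(u, 2L, 0.5),
               tolerance = 1e-12)

  withr::with_seed(35, {
    for (i in 1:20) {
      v <- rnorm(60)
      r <- 0.25 * sqrt(mean((v - mean(v))^2))
      expect_equal(sampleEntropy(v, 2L, r), oracleSampEn(v, 2L, r),
                   tolerance = 1e-12)
    }
  })

  ramp <- seq(0, 10, length.out = 40)  # increments ~0.256
  expect_identical(sampleEntropy(ramp, m = 2L, r = 0.1), Inf)
})

test_that("ApEn and SampEn are scale-invariant with the relative tolerance", {
  withr::with_seed(36, u <- rnorm(150))
  for (c0 in c(0.1, 3, 250)) {
    expect_equal(approximateEntropy(u * c0), approximateEntropy(u),
                 tolerance = 1e-12)
    expect_equal(sampleEntropy(u * c0), sampleEntropy(u), tolerance = 1e-12)
  }
})

test_that("spectral entropy separates tones from broadband noise", {
  n <- 4096L
  tone <- sin(2 * pi * 200 * (0:(n - 1)) / n)
  expect_lte(spectralEntropy(tone), 0.2)

  withr::with_seed(37, noise <- rnorm(n))
  sp <- spectralEntropy(noise)
  expect_gte(sp, 0.9)
  expect_lte(sp, 1)

  # two equal-power on-grid tones: closed form -log(1/2)/log(Nf)
  two <- sin(2 * pi * 100 * (0:(n - 1)) / n) + cos(2 * pi * 400 * (0:(n - 1)) / n)
  expect_equal(spectralEntropy(two), log(2) / log(n / 2 + 1), tolerance = 1e-6)
  expect_equal(spectralEntropy(two), oracleSpEn(two), tolerance = 1e-12)

  expect_equal(spectralEntropy(rep(0, 64)), 0)
})

test_that("attention entropy counts extrema intervals", {
  expect_equal(attentionEntropy(1:50), 0)           # monotone: no extrema
  expect_equal(attentionEntropy(rep(c(1, -1), 25)), 0)  # all intervals 1
  withr::with_seed(38, {
    for (i in 1:20) {
      x <- rnorm(80)
      expect_equal(attentionEntropy(x), oracleAttEn(x), tolerance = 1e-12)
    }
  })
})

test_that("cumulative residual entropy follows the survival integral", {
  expect_equal(cumulativeResidualEntropy(rep(4, 20)), 0)
  expect_equal(cumulativeResidualEntropy(c(0, 1)), -0.5 * log(0.5),
               tolerance = 1e-12)
  expect_equal(-0.5 * log(0.5), 0.3466, tolerance = 1e-4)
  withr::with_seed(39, {
    for (i in 1:20) {
      x <- rnorm(50)
      expect_gte(cumulativeResidualEntropy(x), 0)
      expect_equal(cumulativeResidualEntropy(x), oracleCre(x),
                   tolerance = 1e-12)
    }
  })
  # scales linearly with the data spread (survival integral over x)
  withr::with_seed(40, x <- runif(100))
  expect_equal(cumulativeResidualEntropy(3 * x),
               3 * cumulativeResidualEntropy(x), tolerance = 1e-12)
})

test_that("featureRow composes the ten measures", {
  z <- rep(0, 64)
  fz <- featureRow(z)
  expect_equal(unname(fz[c("mean", "std", "shannon", "apen", "sampen",
                           "spen", "atten", "cre")]),
               rep(0, 8))
  expect_true(all(is.na(fz[c("skewness", "kurtosis")])))

  withr::with_seed(41, x <- rnorm(64))
  fx <- featureRow(x)
  fshift <- featureRow(x + 100)
  expect_equal(fshift[c("std", "skewness", "kurtosis")],
               fx[c("std", "skewness", "kurtosis")], tolerance = 1e-9)
  expect_equal(unname(fshift["mean"] - fx["mean"]), 100, tolerance = 1e-9)

  r <- 0.25 * sqrt(mean((x - mean(x))^2))
  expect_equal(unname(fx), unname(c(momentFeatures(x),
                                    oracleShannonHist(x, 32L),
                                    oracleApEn(x, 2L, r),
                                    oracleSampEn(x, 2L, r),
                                    oracleSpEn(x),
                                    oracleAttEn(x),
                                    oracleCre(x))),
               tolerance = 1e-10)
  expect_error(featureRow(rnorm(4)), ">= 8")
})

test_that("z-scoring is exact, invertible and stateful", {
  expect_equal(unname(zscoreFitTransform(matrix(c(1, 2, 3)))$z[, 1L]),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(sqrt(3 / 2), 1.2247, tolerance = 1e-4)

  withr::with_seed(42, x <- matrix(rnorm(200), 20, 10))
  ft <- zscoreFitTransform(x)
  expect_lt(max(abs(colMeans(ft$z))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(sweep(ft$z, 2L, colMeans(ft$z))^2)) - 1)),
            1e-9)
  expect_equal(zscoreApply(ft$stats, ft$z, invert = TRUE), x,
               tolerance = 1e-12)

  # train statistics applied unchanged to new data
  xnew <- matrix(rnorm(50), 5, 10)
  expect_equal(zscoreApply(ft$stats, xnew),
               sweep(sweep(xnew, 2L, ft$stats$center), 2L, ft$stats$scale, "/"))
  expect_error(zscoreApply(list(center = 0, scale = 1), xnew), "zscoreFit")
  expect_warning(zscoreFit(cbind(rnorm(10), 1)), "zero-variance")
})

test_that("synthetic classes separate on spectral entropy and spread", {
  fix <- easyBenchmarkFeatures()
  withr::with_seed(43, {
    idxN <- sample(which(fix$y == "normal"), 200L)
    idxA <- sample(which(fix$y == "apnea"), 200L)
  })
  for (f in c("spen", "std")) {
    p <- wilcox.test(fix$x[idxN, f], fix$x[idxA, f])$p.value
    expect_lt(p, 0.01)
  }
})
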