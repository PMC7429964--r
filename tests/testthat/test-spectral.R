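test_that("welch PSD locates an on-grid sinusoid and satisfies Parseval", {
  fs <- 100
  tt <- (0:511) / fs
  tr <- 3 * sin(2 * pi * 12.5 * tt)
  ps <- welchPSD(tr, fs)
  expect_equal(ps$f[which.max(ps$psd)], 12.5)
  set.seed(11)
  noise <- rnorm(512, sd = 3)
  pn <- welchPSD(noise, fs)
  df <- pn$f[2L] - pn$f[1L]
  expect_lt(abs(sum(pn$psd) * df - var(noise)) / var(noise), 0.05)
})

test_that("white-noise spectra are flat under sufficient averaging", {
  set.seed(1)
  x <- rnorm(2^15)
  ps <- welchPSD(x, 100, segmentLength = 1024L)
  cv <- sd(ps$psd[-1L]) / mean(ps$psd[-1L])
  expect_lt(cv, 0.2)
})

test_that("a constant trace concentrates all power in the DC bin", {
  ps <- welchPSD(rep(7, 64), 100, segmentLength = 32L, detrend = FALSE,
                 window = "boxcar")
  expect_gt(ps$psd[1L], 0)
  expect_equal(ps$psd[-1L], rep(0, length(ps$psd) - 1L))
})

test_that("traces shorter than one segment are rejected", {
  expect_error(welchPSD(rnorm(16), 100, segmentLength = 32L),
               class = "dynoct_short_trace")
})

test_that("single-segment untapered welch equals the direct DFT periodogram", {
  fs <- 100
  for (n in c(64L, 100L, 256L)) {
    set.seed(n)
    tr <- rnorm(n) + sin(2 * pi * 5 * (0:(n - 1L)) / fs)
    w <- welchPSD(tr, fs, segmentLength = n, window = "boxcar")
    o <- directPeriodogram(tr, fs)
    expect_equal(w$f, o$f)
    relErr <- abs(w$psd - o$psd) / pmax(max(o$psd) * 1e-12, abs(o$psd))
    expect_lt(max(relErr[o$psd > max(o$psd) * 1e-12]), 1e-9)
  }
})

test_that("L1 normalization turns spectra into unit-sum distributions", {
  sp <- l1Normalize(c(2, 6, 2), f = c(1, 2, 3))
  expect_equal(as.numeric(sp@P), c(0.2, 0.6, 0.2))
  set.seed(2)
  raw <- matrix(rexp(50 * 20), 50, 20)
  sp2 <- l1Normalize(raw, f = seq_len(20))
  expect_equal(rowSums(sp2@P), rep(1, 50))
})

test_that("all-zero spectra become silent rather than dividing by zero", {
  sp <- l1Normalize(c(0, 0, 0, 0), f = 1:4)
  expect_true(sp@silent)
  expect_equal(as.numeric(sp@P), rep(0, 4))
  expect_true(is.na(meanFrequency(sp)))
  expect_true(is.na(bandwidthS(sp)))
})

test_that("trimming removes ceil(fraction * nbins) bins and renormalizes", {
  sp <- l1Normalize(rep(1, 100), f = seq(0.5, 50, by = 0.5))
  tr <- trimLowFrequencies(sp, 0.03)
  expect_equal(length(tr@f), 97L)
  expect_equal(min(tr@f), 2)
  expect_equal(rowSums(tr@P), 1)
  expect_identical(trimLowFrequencies(sp, 0), sp)
  expect_error(trimLowFrequencies(sp, 1), class = "dynoct_bad_args")
})

test_that("a spectrum concentrated in the trimmed band becomes silent", {
  raw <- c(1, rep(0, 99))
  sp <- trimLowFrequencies(l1Normalize(raw, f = seq(0.5, 50, by = 0.5)), 0.03)
  expect_true(sp@silent)
})

test_that("mean frequency: delta, uniform and monotone-in-rate recovery", {
  f <- seq(1, 50, by = 1)
  delta <- l1Normalize(as.numeric(f == 17), f)
  expect_equal(meanFrequency(delta), 17)
  unif <- l1Normalize(rep(1, length(f)), f)
  expect_equal(meanFrequency(unif), mean(range(f)))
  mfs <- vapply(c(1, 5, 20), function(r) {
    sc <- motilityScene(12, 12, nFrames = 512L, seed = 21L,
      regions = list(list(mask = rectMask(12L, 12L, 1L, 12L, 1L, 12L),
        model = fluctuationModel("relaxation_phase", 800, r, seed = 31L))))
    spec <- cubeSpectra(normalizeFrames(simulateCube(sc)$cube))
    median(meanFrequency(spec))
  }, numeric(1L))
  expect_true(all(diff(mfs) > 0))
})

test_that("bandwidth closed forms: delta, two-point and uniform limit", {
  f <- seq(0.5, 50, by = 0.5)
  delta <- l1Normalize(as.numeric(f == 10), f)
  expect_equal(bandwidthS(delta), 0)
  two <- l1Normalize(as.numeric(f %in% c(10, 30)) / 2, f)
  expect_equal(bandwidthS(two), ((30 - 10) / 2)^2)
  # discrete uniform converges to the continuous f_N^2 / 12
  fN <- 50
  err <- vapply(c(64L, 256L, 1024L), function(n) {
    fg <- seq(0, fN, length.out = n)
    sp <- l1Normalize(rep(1, n), fg)
    brute <- sum((fg - mean(fg))^2) / n  # brute-force discrete variance
    expect_equal(bandwidthS(sp), brute, tolerance = 1e-12)
    abs(bandwidthS(sp) - fN^2 / 12) / (fN^2 / 12)
  }, numeric(1L))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3L], 2e-3)
})

test_that("bandwidth matches the definitional variance on random spectra", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(8:128, 1L)
    f <- sort(runif(n, 0, 50))
    P <- rexp(n); P <- P / sum(P)
    sp <- new("FrequencySpectrum", P = matrix(P, 1L), f = f,
              totalPower = 1, silent = FALSE, trimFraction = 0,
              spatialDim = integer(0))
    definitional <- sum(P * (f - sum(P * f))^2)
    expect_equal(bandwidthS(sp), definitional, tolerance = 1e-9)
  }
})

test_that("cube spectra drop DC, trim, and keep Nyquist as the last bin", {
  sc <- twoRegionScene(side = 12L, nFrames = 256L)
  spec <- cubeSpectra(normalizeFrames(simulateCube(sc)$cube))
  expect_true(all(spec@f > 0))
  expect_equal(max(spec@f), 50)
  expect_equal(rowSums(spec@P)[!spec@silent],
               rep(1, sum(!spec@silent)), tolerance = 1e-9)
  expect_identical(spec@spatialDim, c(12L, 12L))
})
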