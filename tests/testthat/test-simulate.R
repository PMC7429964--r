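test_that("static models produce constant, reproducible traces", {
  m <- fluctuationModel("static", amplitude = 250, rate = 0, seed = 4L)
  tr <- simulateTrace(m, 128, 100, background = 1000)
  expect_equal(var(tr), 0)
  expect_identical(tr, simulateTrace(m, 128, 100, background = 1000))
})

test_that("equal fields and seed give bit-identical traces; seeds matter", {
  m1 <- fluctuationModel("brownian_phase", 100, 2, seed = 9L)
  m2 <- fluctuationModel("brownian_phase", 100, 2, seed = 9L)
  m3 <- fluctuationModel("brownian_phase", 100, 2, seed = 10L)
  expect_identical(simulateTrace(m1, 256, 100), simulateTrace(m2, 256, 100))
  expect_false(identical(simulateTrace(m1, 256, 100),
                         simulateTrace(m3, 256, 100)))
})

test_that("invalid model kinds and arguments are rejected by name", {
  expect_error(fluctuationModel("hyperdiffusive"), class = "dynoct_bad_model")
  m <- fluctuationModel("white_intensity", 1)
  expect_error(simulateTrace(m, 1, 100), class = "dynoct_bad_args")
  expect_error(simulateTrace(m, 64, 0), class = "dynoct_bad_args")
})

test_that("relaxation traces decorrelate on the 1/rate time scale", {
  # fit an exponential to the empirical autocorrelation of a long trace
  r <- 5
  m <- fluctuationModel("relaxation_phase", amplitude = 1, rate = r, seed = 2L)
  tr <- simulateTrace(m, 1e5, 100)
  a <- acf(tr, lag.max = 80, plot = FALSE)$acf[, 1, 1]
  k <- which(a < 0.05)[1L]
  if (is.na(k)) k <- length(a) else k <- k - 1L
  fit <- lm(log(a[1:k]) ~ I(0:(k - 1L)))
  tau <- -1 / coef(fit)[2L] / 100
  expect_lt(abs(tau - 1 / r) / (1 / r), 0.2)
})

test_that("trace variance increases with amplitude at fixed model", {
  vs <- vapply(c(50, 200, 800), function(A) {
    var(simulateTrace(fluctuationModel("brownian_phase", A, 3, seed = 5L),
                      512, 100))
  }, numeric(1L))
  expect_true(all(diff(vs) > 0))
})

test_that("identical scene and seed give identical cubes", {
  sc <- twoRegionScene(seed = 7L)
  expect_identical(simulateCube(sc)$cube@frames, simulateCube(sc)$cube@frames)
})

test_that("a fully static, drift-free, noise-free scene yields identical frames", {
  sc <- motilityScene(12, 12, nFrames = 16L, seed = 3L)
  cube <- simulateCube(sc)$cube
  for (t in 2:16) expect_equal(cube@frames[t, , ], cube@frames[1, , ])
})

test_that("exposure drift scales frame means proportionally", {
  drift <- 1 + 0.05 * sin(2 * pi * (1:64) / 64)
  sc <- motilityScene(10, 10, nFrames = 64L, exposureDrift = drift, seed = 3L)
  cube <- simulateCube(sc)$cube
  means <- apply(cube@frames, 1L, mean)
  expect_equal(means / means[1L], drift / drift[1L], tolerance = 1e-12)
})

test_that("overlapping region masks are rejected", {
  m <- fluctuationModel("white_intensity", 10)
  mk <- rectMask(8L, 8L, 1L, 5L, 1L, 5L)
  expect_error(
    motilityScene(8, 8, regions = list(list(mask = mk, model = m),
                                       list(mask = mk, model = m)),
                  nFrames = 8L),
    "overlap")
})

test_that("ground-truth labels map pixels to their regions", {
  sc <- twoRegionScene(side = 16L, nFrames = 8L)
  sim <- simulateCube(sc)
  expect_identical(dim(sim$labels), c(16L, 16L))
  expect_setequal(unique(as.integer(sim$labels)), c(0L, 1L, 2L))
  expect_true(all(sim$labels[sc@regions[[1L]]$mask] == 1L))
})

test_that("region layout does not change other pixels' streams", {
  base <- motilityScene(10, 10, nFrames = 32L, seed = 5L)
  withReg <- motilityScene(10, 10, nFrames = 32L, seed = 5L,
    regions = list(list(mask = rectMask(10L, 10L, 1L, 3L, 1L, 3L),
                        model = fluctuationModel("white_intensity", 50,
                                                 seed = 2L))))
  c1 <- simulateCube(base)$cube@frames
  c2 <- simulateCube(withReg)$cube@frames
  expect_identical(c1[, 8:10, 8:10], c2[, 8:10, 8:10])
})

test_that("analytic spectra: flat for white intensity, delta for static", {
  f <- seq(0, 50, length.out = 64L)
  w <- analyticPSD(fluctuationModel("white_intensity", 3), 100, f)
  expect_equal(diff(range(w)), 0)
  expect_equal(attr(w, "power"), 9)
  s <- analyticPSD(fluctuationModel("static", 3), 100, f)
  expect_true(all(s[f > 0] == 0))
  expect_true(is.infinite(s[1L]))
})

test_that("relaxation spectrum is the Wiener-Khinchin Lorentzian", {
  # oracle: numerically Fourier transform the exponential autocorrelation
  r <- 4
  dt <- 1e-4
  tgrid <- seq(0, 40, by = dt)
  f <- c(0.5, 1, 2, 5, 10)
  oracle <- vapply(f, function(ff) {
    y <- exp(-r * tgrid) * cos(2 * pi * ff * tgrid)
    4 * (sum(y) - y[1L] / 2) * dt  # trapezoid; one-sided = 2 * two-sided
  }, numeric(1L))
  curve <- analyticPSD(fluctuationModel("relaxation_phase", 1, r, 1L), 100, f)
  pw <- attr(curve, "power")
  expect_equal(as.numeric(curve) / pw, oracle, tolerance = 1e-3)
  # half-width at half max sits at rate/(2*pi) Hz
  fhwhm <- r / (2 * pi)
  at0 <- analyticPSD(fluctuationModel("relaxation_phase", 1, r, 1L), 100, 0)
  athw <- analyticPSD(fluctuationModel("relaxation_phase", 1, r, 1L), 100, fhwhm)
  expect_equal(as.numeric(athw / at0), 0.5, tolerance = 1e-12)
})

test_that("brownian phase has no closed-form spectrum", {
  expect_error(analyticPSD(fluctuationModel("brownian_phase", 1, 2), 100),
               class = "dynoct_no_closed_form")
})

test_that("long relaxation traces reproduce the analytic spectrum shape", {
  r <- 5
  P <- 0
  for (s in 1:16) {
    m <- fluctuationModel("relaxation_phase", amplitude = 1, rate = r,
                          seed = 100L + s)
    w <- welchPSD(simulateTrace(m, 2^14, 100), 100, segmentLength = 1024L)
    P <- P + w$psd
  }
  keep <- w$f > 0
  emp <- P[keep] / sum(P[keep])
  ana <- analyticPSD(fluctuationModel("relaxation_phase", 1, r, 1L),
                     100, w$f[keep])
  ana <- ana / sum(ana)
  expect_lt(sum(abs(emp - ana)), 0.10)
})
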