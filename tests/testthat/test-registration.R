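test_that("plane locking recovers a known axial offset exactly", {
  offs <- seq(-5, 5, by = 0.5)
  stack <- lapply(seq_along(offs), function(k) texturedImage(64L, 64L, seed = k))
  target <- stack[[which(offs == 2)]]
  res <- planeLock(stack, target, offs)
  expect_equal(bestOffset(res), 2)
  expect_equal(peakCorrelation(res), 1)
  # additive noise at SNR 10 does not move the lock
  set.seed(9)
  noisy <- target + rnorm(length(target), sd = sd(target) / sqrt(10))
  res2 <- planeLock(stack, noisy, offs)
  expect_equal(bestOffset(res2), 2)
  expect_lt(peakCorrelation(res2), 1)
})

test_that("plane locking is translation-consistent in the offset labels", {
  offs <- seq(-5, 5, by = 0.5)
  stack <- lapply(seq_along(offs), function(k) texturedImage(32L, 32L, seed = k))
  target <- stack[[8L]]
  r1 <- planeLock(stack, target, offs)
  r2 <- planeLock(stack, target, offs + 1.5)
  expect_equal(bestOffset(r2), bestOffset(r1) + 1.5)
})

test_that("degenerate lock inputs are rejected", {
  flat <- matrix(1, 16L, 16L)
  expect_error(planeLock(list(flat), flat, 0), class = "dynoct_zero_variance")
  expect_error(planeLock(list(), matrix(0, 2L, 2L), numeric(0)),
               class = "dynoct_bad_args")
})

test_that("relock triggers on decorrelated images only", {
  a <- texturedImage(32L, 32L, seed = 1L)
  expect_false(needsRelock(a, a, 0.3))
  set.seed(2)
  b <- matrix(rnorm(32 * 32), 32L)
  set.seed(3)
  cc <- matrix(rnorm(32 * 32), 32L)
  expect_true(needsRelock(b, cc, 0.3))
  expect_false(needsRelock(b, cc, 0))
  expect_error(needsRelock(a, matrix(0, 4L, 4L)), class = "dynoct_bad_args")
})

test_that("rigid registration recovers synthetic translation and rotation", {
  ref <- texturedImage(128L, 128L, seed = 1L)
  mov <- warpImage(ref, rigidTransform(0, 5, -3), direction = "forward")
  tr <- registerLateral(list(ref, mov))[[2L]]
  M <- transformMatrix(tr)
  expect_lt(sqrt(sum((M[1:2, 3L] - c(-5, 3))^2)), 0.5)
  expect_lt(abs(atan2(M[2L, 1L], M[1L, 1L])), 0.2 * pi / 180)
  ang <- 2 * pi / 180
  mov2 <- warpImage(ref, rigidTransform(ang, 0, 0, centre = c(63.5, 63.5)),
                    direction = "forward")
  tr2 <- registerLateral(list(ref, mov2))[[2L]]
  M2 <- transformMatrix(tr2)
  expect_lt(abs(atan2(M2[2L, 1L], M2[1L, 1L]) + ang), 0.2 * pi / 180)
})

test_that("identical planes register to the identity", {
  ref <- texturedImage(96L, 96L, seed = 4L)
  tr <- registerLateral(list(ref, ref))[[2L]]
  expect_lt(max(abs(transformMatrix(tr) - diag(3))), 1e-3)
})

test_that("registration reduces the misalignment error (round trip)", {
  ref <- texturedImage(128L, 128L, seed = 2L)
  mov <- warpImage(ref, rigidTransform(1 * pi / 180, 4, 2,
                                       centre = c(63.5, 63.5)),
                   direction = "forward")
  tr <- registerLateral(list(ref, mov))[[2L]]
  back <- warpImage(mov, tr, direction = "forward")
  inner <- 20:108  # avoid warp borders
  mseBefore <- mean((mov[inner, inner] - ref[inner, inner])^2)
  mseAfter <- mean((back[inner, inner] - ref[inner, inner])^2)
  expect_lt(mseAfter, mseBefore / 10)
})

test_that("featureless planes fall back to a flagged identity", {
  set.seed(5)
  a <- texturedImage(64L, 64L, seed = 1L)
  b <- matrix(rnorm(64 * 64, sd = 1e-6), 64L)  # no usable structure
  expect_warning(trs <- registerLateral(list(a, b)), "insufficient")
  expect_equal(transformMatrix(trs[[2L]]), diag(3))
  expect_false(attr(trs[[2L]], "registered"))
})

test_that("depth interpolation hits 220 nm voxels and reproduces ramps", {
  nz <- 5L
  const <- lapply(seq_len(nz), function(k) matrix(7, 8L, 8L))
  v <- interpolateDepth(const, lateralPitch = 0.22, zStep = 1.1)
  expect_equal(v$voxelEdge, 0.22)
  expect_length(v$z, (nz - 1L) * 5L + 1L)  # 1.1 / 0.22 = 5 planes/interval
  expect_equal(max(abs(v$volume - 7)), 0)
  ramp <- lapply(seq_len(nz), function(k) matrix(2 * k + 1, 8L, 8L))
  vr <- interpolateDepth(ramp, lateralPitch = 0.22, zStep = 1.1)
  expected <- 3 + 2 * vr$z / 1.1
  expect_equal(as.numeric(vr$volume[4L, 4L, ]), expected, tolerance = 1e-12)
})

test_that("depth interpolation conserves the mean of smooth volumes", {
  nz <- 9L
  sm <- lapply(seq_len(nz), function(k)
    texturedImage(24L, 24L, seed = 1L) * (1 + 0.1 * sin(k / 2)))
  v <- interpolateDepth(sm, lateralPitch = 0.22, zStep = 0.88)
  expect_lt(abs(mean(v$volume) - mean(unlist(sm))) / mean(unlist(sm)), 0.005)
})

test_that("too few planes fall back to linear interpolation with a warning", {
  st <- lapply(1:3, function(k) matrix(k, 6L, 6L))
  expect_warning(v <- interpolateDepth(st, 0.22, 1.1), "linear")
  expect_equal(as.numeric(v$volume[1L, 1L, ]), 1 + v$z / 1.1,
               tolerance = 1e-12)
})

test_that("non-local means smooths noise, preserves means and the identity", {
  img <- texturedImage(32L, 32L, seed = 6L)
  expect_equal(denoiseNLM(img, strength = 0), img)
  flat <- matrix(5, 20L, 20L)
  expect_equal(denoiseNLM(flat, strength = 0.5), flat)
  set.seed(7)
  noisy <- 10 + matrix(rnorm(32 * 32), 32L)
  den <- denoiseNLM(noisy, strength = 2)
  expect_lt(var(as.numeric(den)), var(as.numeric(noisy)))
  expect_lt(abs(mean(den) - mean(noisy)) / mean(noisy), 0.01)
  expect_error(denoiseNLM(matrix(1, 3L, 3L), patchSize = 5L),
               class = "dynoct_bad_args")
})
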