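.cubeFromMatrix <- function(mat, h, w, frameRate = 100) {
  # every pixel gets one column of mat (recycled); t down the rows
  arr <- array(mat, dim = c(nrow(mat), h, w))
  new("InterferogramCube", frames = arr - min(arr, 0), frameRate = frameRate,
      metadata = list())
}

test_that("value channel: constant, i.i.d. noise and sinusoid amplitudes", {
  cube <- .cubeFromMatrix(matrix(5, 128, 1), 4L, 4L)
  expect_equal(valueChannel(cube, 50L), matrix(0, 4L, 4L))
  set.seed(8)
  sigma <- 2.5
  arr <- array(100 + rnorm(512 * 8 * 8, sd = sigma), dim = c(512L, 8L, 8L))
  ncube <- new("InterferogramCube", frames = arr, frameRate = 100,
               metadata = list())
  v <- valueChannel(ncube, 50L)
  expect_lt(abs(mean(v) - sigma) / sigma, 0.05)
  A <- 10
  tr <- 50 + A * sin(2 * pi * 10 * (0:511) / 100)  # period 10 << window 50
  vs <- valueChannel(.cubeFromMatrix(matrix(tr, ncol = 1L), 2L, 2L), 50L)
  expect_lt(abs(vs[1L] - A / sqrt(2)) / (A / sqrt(2)), 0.02)
})

test_that("value channel rejects windows longer than the trace", {
  cube <- .cubeFromMatrix(matrix(1:32, 32, 1), 2L, 2L)
  expect_error(valueChannel(cube, 50L), class = "dynoct_bad_args")
})

test_that("clipping saturates exactly the top fraction of distinct pixels", {
  set.seed(3)
  v <- matrix(sample(seq(0.1, 100, length.out = 1000)), 25L, 40L)
  cl <- clipValue(v, 0.001)
  expect_identical(cl$nClipped, 1L)
  expect_equal(sum(cl$map == 1), 2L)  # the clipped pixel + the threshold pixel
  expect_equal(cl$threshold, sort(as.numeric(v))[999L])
  expect_true(all(cl$map >= 0 & cl$map <= 1))
})

test_that("clip fraction 0 is a pure max rescale; constant maps become ones", {
  v <- matrix(runif(64), 8L)
  cl <- clipValue(v, 0)
  expect_identical(cl$nClipped, 0L)
  expect_equal(cl$map, v / max(v))
  cc <- clipValue(matrix(3, 5L, 5L), 0.001)
  expect_equal(cc$map, matrix(1, 5L, 5L))
  expect_warning(z <- clipValue(matrix(0, 4L, 4L)), "all-zero")
  expect_equal(z$map, matrix(0, 4L, 4L))
})

test_that("hue endpoints: low frequencies blue (0.66), high red (0)", {
  mf <- matrix(c(2, 50, 26, 60, 0), 1L)
  h <- hueChannel(mf, c(2, 50))
  expect_equal(h[1L, 1:3], c(0.66, 0, 0.33))
  expect_equal(h[1L, 4L], 0)     # above range clamps to red
  expect_equal(h[1L, 5L], 0.66)  # below range clamps to blue
  expect_error(hueChannel(mf, c(5, 5)), class = "dynoct_bad_args")
})

test_that("saturation falls with bandwidth: narrow vivid, broad grey", {
  S <- matrix(c(0, 600, 300), 1L)
  s <- saturationChannel(S, c(0, 600))
  expect_equal(s[1L, ], c(0.8, 0, 0.4))
  set.seed(5)
  Sr <- sort(runif(20, 0, 600))
  sr <- saturationChannel(matrix(Sr, 1L), c(0, 600))
  expect_true(all(diff(as.numeric(sr)) <= 0))
})

test_that("HSV composition follows the colour-space definition", {
  one <- function(h, s, v) {
    img <- composeHSV(matrix(h), matrix(s), matrix(v))
    rgbArray(img)[1L, 1L, ]
  }
  red <- one(0, 0.8, 1)
  expect_gt(red[1L], red[2L]); expect_gt(red[1L], red[3L])
  expect_equal(one(0.4, 0.5, 0), c(0, 0, 0))
  grey <- one(0.33, 0, 0.7)
  expect_equal(grey, rep(0.7, 3L))
})

test_that("processed cubes colour fast regions redder than slow regions", {
  sim <- simulateCube(twoRegionScene(rateSlow = 1, rateFast = 20, seed = 1L))
  img <- processCube(sim$cube)
  h <- hueMap(img)
  expect_lt(median(h[sim$labels == 2L]), median(h[sim$labels == 1L]))
  expect_true(all(hueMap(img) <= 0.66 + 1e-12))
  expect_true(all(saturationMap(img) <= 0.8 + 1e-12))
  expect_true(all(valueMap(img) <= 1 + 1e-12))
})

test_that("static scenes render black and processing is deterministic", {
  sc <- motilityScene(10, 10, nFrames = 256L)
  cube <- simulateCube(sc)$cube
  img <- suppressWarnings(processCube(cube))
  expect_equal(max(rgbArray(img)), 0)
  sim <- simulateCube(twoRegionScene(side = 16L, nFrames = 256L))
  i1 <- processCube(sim$cube); i2 <- processCube(sim$cube)
  expect_identical(rgbArray(i1), rgbArray(i2))
})

test_that("per-region hue is stable across simulation seeds", {
  h <- lapply(c(1L, 2L), function(s) {
    sim <- simulateCube(twoRegionScene(seed = s))
    list(h = hueMap(processCube(sim$cube)), lab = sim$labels)
  })
  for (reg in 1:2) {
    d <- abs(median(h[[1L]]$h[h[[1L]]$lab == reg]) -
               median(h[[2L]]$h[h[[2L]]$lab == reg]))
    expect_lt(d, 0.03)
  }
})

test_that("stacks share the clip threshold so amplitude ratios survive", {
  sim <- simulateCube(twoRegionScene(side = 16L, nFrames = 256L))
  cube1 <- sim$cube
  cube2 <- new("InterferogramCube",
               frames = (frames(cube1) - mean(frames(cube1))) * 2 +
                 mean(frames(cube1)),
               frameRate = frameRate(cube1), metadata = list())
  imgs <- processStack(list(cube1, cube2))
  b1 <- channelBounds(imgs[[1L]]); b2 <- channelBounds(imgs[[2L]])
  expect_identical(b1$clip_threshold, b2$clip_threshold)
  v1 <- valueMap(imgs[[1L]]); v2 <- valueMap(imgs[[2L]])
  keep <- v2 < 1 & v1 > 0.05  # below clip, away from zero
  expect_equal(median(v2[keep] / v1[keep]), 2, tolerance = 0.02)
  # identical cubes give identical images; one-plane stack matches processCube
  same <- processStack(list(cube1, cube1))
  expect_identical(rgbArray(same[[1L]]), rgbArray(same[[2L]]))
  single <- processStack(list(cube1))[[1L]]
  expect_equal(rgbArray(single), rgbArray(processCube(cube1)))
})
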