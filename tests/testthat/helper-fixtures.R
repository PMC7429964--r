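# Fixtures built in code: simulator scenes, textured images, and the
# independent spectral oracle (direct DFT periodogram).

# smooth, feature-rich synthetic en face image (sum of Gaussian blobs)
texturedImage <- function(h, w, nBlobs = 150L, seed = 1L) {
  set.seed(seed)
  img <- matrix(0, h, w)
  xs <- matrix(rep(0:(w - 1L), each = h), h, w)
  ys <- matrix(rep(0:(h - 1L), times = w), h, w)
  for (i in seq_len(nBlobs)) {
    cx <- runif(1, 0, w - 1); cy <- runif(1, 0, h - 1)
    s <- runif(1, 1.5, 4)
    img <- img + runif(1, 0.3, 1) * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
  }
  img
}

rectMask <- function(h, w, y0, y1, x0, x1) {
  m <- matrix(FALSE, h, w)
  m[y0:y1, x0:x1] <- TRUE
  m
}

# two relaxation regions (left slow, right fast) on a speckle background
twoRegionScene <- function(rateSlow = 1, rateFast = 20, side = 32L,
                           nFrames = 512L, seed = 1L, ...) {
  half <- side %/% 2L
  motilityScene(
    width = side, height = side,
    regions = list(
      list(mask = rectMask(side, side, 2L, side - 1L, 2L, half - 1L),
           model = fluctuationModel("relaxation_phase", amplitude = 800,
                                    rate = rateSlow, seed = 11L)),
      list(mask = rectMask(side, side, 2L, side - 1L, half + 1L, side - 1L),
           model = fluctuationModel("relaxation_phase", amplitude = 800,
                                    rate = rateFast, seed = 12L))),
    nFrames = nFrames, seed = seed, ...)
}

# independent oracle: one-sided periodogram by explicit DFT sums (no fft)
directPeriodogram <- function(trace, frameRate, detrend = TRUE) {
  n <- length(trace)
  x <- if (detrend) trace - mean(trace) else trace
  nfreq <- n %/% 2L + 1L
  t0 <- 0:(n - 1L)
  psd <- vapply(seq_len(nfreq) - 1L, function(k) {
    re <- sum(x * cos(2 * pi * k * t0 / n))
    im <- sum(x * sin(2 * pi * k * t0 / n))
    (re^2 + im^2) / (frameRate * n)
  }, numeric(1L))
  dbl <- 2:(if (n %% 2L == 0L) nfreq - 1L else nfreq)
  psd[dbl] <- 2 * psd[dbl]
  list(f = (seq_len(nfreq) - 1L) * frameRate / n, psd = psd)
}

# intensity centroid (x, y), 0-based, of a non-negative weight image
centroidOf <- function(wimg) {
  tot <- sum(wimg)
  xs <- matrix(rep(0:(ncol(wimg) - 1L), each = nrow(wimg)), nrow(wimg))
  ys <- matrix(rep(0:(nrow(wimg) - 1L), times = ncol(wimg)), nrow(wimg))
  c(sum(xs * wimg), sum(ys * wimg)) / tot
}
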