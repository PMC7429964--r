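# Composition of the quantitative HSV dynamic image: value = fluctuation
# amplitude (running std), hue = mean frequency, saturation = inverse
# spectral bandwidth; rendered to RGB for display.

#' Fluctuation-amplitude (value) channel
#'
#' For each pixel, the standard deviation of the intensity trace is computed
#' in dense sliding windows (stride 1 frame; windows truncated at the trace
#' end are excluded) and averaged over window positions.
#'
#' @param cube an \linkS4class{InterferogramCube} or
#'   \linkS4class{NormalizedCube}.
#' @param window window length in samples (default 50).
#' @return non-negative (height x width) amplitude matrix in camera counts.
#' @export
valueChannel <- function(cube, window = 50L) {
  stopifnot(is(cube, "InterferogramCube"))
  d <- dim(cube@frames)
  n <- d[1L]
  window <- as.integer(window)
  if (window < 2L) .err("window must be >= 2 samples", "dynoct_bad_args")
  if (window > n)
    .err(sprintf("window (%d) exceeds trace length (%d)", window, n),
         "dynoct_bad_args")
  mat <- matrix(cube@frames, n, d[2L] * d[3L])
  cs1 <- apply(mat, 2L, cumsum)
  cs2 <- apply(mat * mat, 2L, cumsum)
  z <- matrix(0, 1L, ncol(mat))
  lo <- seq_len(n - window + 1L)            # window start positions
  s1 <- cs1[lo + window - 1L, , drop = FALSE] - rbind(z, cs1)[lo, , drop = FALSE]
  s2 <- cs2[lo + window - 1L, , drop = FALSE] - rbind(z, cs2)[lo, , drop = FALSE]
  v <- (s2 - s1 * s1 / window) / (window - 1)
  sdw <- sqrt(pmax(v, 0))
  matrix(colMeans(sdw), d[2L], d[3L])
}

#' Clip and rescale an amplitude map
#'
#' The brightest \code{clipFraction} of pixels are saturated to improve
#' contrast: the clip threshold is the nearest-rank \code{(1 - clipFraction)}
#' quantile of the pooled pixel values, the top \code{floor(clipFraction * m)}
#' pixels (ties broken by value, then index) are set to it, and the map is
#' divided by the threshold so values land in [0, 1].
#'
#' @param map non-negative amplitude matrix.
#' @param clipFraction fraction of highest-value pixels to saturate
#'   (default 0.001, i.e. 0.1\%).
#' @return list with \code{map} (rescaled to [0, 1]), \code{threshold} (the
#'   clip level in input units) and \code{nClipped}.
#' @export
clipValue <- function(map, clipFraction = 0.001) {
  if (clipFraction < 0 || clipFraction >= 1)
    .err("clipFraction must be in [0, 1)", "dynoct_bad_args")
  v <- as.numeric(map)
  m <- length(v)
  if (all(v == 0)) {
    warning("all-zero amplitude map; returned unchanged")
    return(list(map = map, threshold = 0, nClipped = 0L))
  }
  rank <- min(max(ceiling((1 - clipFraction) * m), 1L), m)
  threshold <- sort(v, partial = rank)[rank]
  nClipped <- floor(clipFraction * m)
  if (threshold <= 0) {
    warning("clip threshold is zero; rescaling by the maximum instead")
    threshold <- max(v)
    nClipped <- 0L
  }
  if (nClipped > 0L) {
    # ties broken by value order, then original index (order() is stable)
    idx <- order(v, seq_along(v), decreasing = TRUE)[seq_len(nClipped)]
    v[idx] <- threshold
  }
  out <- matrix(pmin(v / threshold, 1), nrow(map), ncol(map))
  list(map = out, threshold = threshold, nClipped = as.integer(nClipped))
}

.affineInvert <- function(x, lo, hi, top) {
  out <- top * (hi - x) / (hi - lo)
  out[is.na(out)] <- 0
  pmin(pmax(out, 0), top)
}

#' Mean-frequency (hue) channel
#'
#' Affinely maps and inverts mean frequencies onto the hue interval
#' [0, 0.66]: the low end of the frequency range maps to H = 0.66 (blue) and
#' the high end to H = 0 (red), so slow pixels are blue and fast pixels red.
#' Out-of-range frequencies are clamped; silent pixels (NA) get hue 0 and are
#' blacked out by the value channel.
#'
#' @param meanFreq (height x width) mean-frequency matrix in Hz.
#' @param frequencyRange numeric(2), \code{c(f_lo, f_hi)} with
#'   \code{f_lo < f_hi}.
#' @return hue matrix in [0, 0.66].
#' @export
hueChannel <- function(meanFreq, frequencyRange) {
  if (length(frequencyRange) != 2L || !(frequencyRange[1L] < frequencyRange[2L]))
    .err("frequencyRange must be c(f_lo, f_hi) with f_lo < f_hi",
         "dynoct_bad_args")
  .affineInvert(meanFreq, frequencyRange[1L], frequencyRange[2L], 0.66)
}

#' Spectral-bandwidth (saturation) channel
#'
#' Larger bandwidth gives lower saturation: a narrow spectrum renders vivid
#' (S = 0.8) and a maximally broad, noise-like spectrum renders grey (S = 0).
#' The map is affine in the bandwidth, inverted and clamped to [0, 0.8].
#'
#' @param bandwidth (height x width) bandwidth matrix (Hz^2, or Hz when the
#'   square-root statistic is used upstream).
#' @param bandwidthRange numeric(2) giving the bandwidth values mapped to
#'   S = 0.8 and S = 0 respectively.
#' @return saturation matrix in [0, 0.8].
#' @export
saturationChannel <- function(bandwidth, bandwidthRange) {
  if (length(bandwidthRange) != 2L ||
      !(bandwidthRange[1L] < bandwidthRange[2L]))
    .err("bandwidthRange must be increasing numeric(2)", "dynoct_bad_args")
  .affineInvert(bandwidth, bandwidthRange[1L], bandwidthRange[2L], 0.8)
}

# vectorised HSV -> RGB, H on the [0, 1] circle
.hsv2rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Compose HSV channels into a dynamic image
#'
#' Standard HSV to RGB conversion with H interpreted on the [0, 1] circle.
#' Pixels flagged silent (or with value 0) render black regardless of hue.
#'
#' @param hue matrix in [0, 0.66].
#' @param saturation matrix in [0, 0.8].
#' @param value matrix in [0, 1].
#' @param silent optional logical matrix; silent pixels get value 0.
#' @param channelBounds optional list recording the rescale bounds used.
#' @return a \linkS4class{DynamicImage}.
#' @export
composeHSV <- function(hue, saturation, value, silent = NULL,
                       channelBounds = list()) {
  d <- dim(hue)
  if (!identical(dim(saturation), d) || !identical(dim(value), d))
    .err("hue, saturation and value must share dimensions", "dynoct_bad_args")
  if (!is.null(silent)) value[silent] <- 0
  rgb <- .hsv2rgb(hue, saturation, value)
  arr <- array(c(rgb$r, rgb$g, rgb$b), dim = c(d, 3L))
  new("DynamicImage", hue = hue, saturation = saturation, value = value,
      rgb = arr, channelBounds = channelBounds)
}

# shared channel computation; bounds override enables consistent 3D stacks
.processOne <- function(cube, config, bounds = NULL) {
  ncube <- if (is(cube, "NormalizedCube")) cube else normalizeFrames(cube)
  rawValue <- valueChannel(ncube, config$value_window)
  spec <- cubeSpectra(ncube,
                      segmentLength = config$welch$segment_length,
                      overlapFraction = config$welch$overlap,
                      window = config$welch$window,
                      trimFraction = config$trim_fraction)
  mf <- meanFrequency(spec)
  S <- bandwidthS(spec)
  if (identical(config$saturation_statistic, "sd")) S <- sqrt(S)
  silent <- matrix(spec@silent, dim(rawValue)[1L], dim(rawValue)[2L])
  list(ncube = ncube, rawValue = rawValue, spec = spec, mf = mf, S = S,
       silent = silent)
}

.channelRanges <- function(parts, config) {
  f <- parts[[1L]]$spec@f
  if (isTRUE(config$autoscale)) {
    mfAll <- unlist(lapply(parts, function(p) p$mf))
    SAll <- unlist(lapply(parts, function(p) p$S))
    fr <- range(mfAll, na.rm = TRUE)
    br <- range(SAll, na.rm = TRUE)
    if (diff(fr) == 0) fr <- fr + c(0, 1e-9)
    if (diff(br) == 0) br <- br + c(0, 1e-9)
  } else {
    # fixed bounds: post-trim grid minimum to Nyquist, so a given frequency
    # always renders the same colour across acquisitions
    fr <- c(min(f), max(f))
    smax <- ((max(f) - min(f)) / 2)^2
    if (identical(config$saturation_statistic, "sd")) smax <- sqrt(smax)
    br <- c(0, smax)
  }
  list(frequency = fr, bandwidth = br)
}

.composeFromParts <- function(p, ranges, threshold, config) {
  hue <- hueChannel(p$mf, ranges$frequency)
  sat <- saturationChannel(p$S, ranges$bandwidth)
  if (threshold > 0) val <- pmin(p$rawValue / threshold, 1)
  else val <- p$rawValue  # all-zero map
  composeHSV(hue, sat, val, silent = p$silent,
             channelBounds = list(frequency_range = ranges$frequency,
                                  bandwidth_range = ranges$bandwidth,
                                  clip_threshold = threshold,
                                  saturation_statistic =
                                    config$saturation_statistic))
}

#' Process a cube into a dynamic image
#'
#' Full chain: exposure normalisation, per-pixel Welch PSD, L1
#' normalisation, low-frequency trim, mean frequency and bandwidth, channel
#' rescaling and HSV composition.  Deterministic for fixed input and
#' configuration.
#'
#' @param cube an \linkS4class{InterferogramCube}.
#' @param config a \code{\link{pipelineConfig}}.
#' @return a \linkS4class{DynamicImage}.
#' @export
processCube <- function(cube, config = pipelineConfig()) {
  p <- .processOne(cube, config)
  ranges <- .channelRanges(list(p), config)
  cl <- clipValue(p$rawValue, config$clip_fraction)
  .composeFromParts(p, ranges, cl$threshold, config)
}

#' Process a z-stack of cubes with shared channel bounds
#'
#' The value clip threshold (and, under autoscaling, the hue/saturation
#' rescale ranges) is computed once from the pooled pixel population of the
#' whole stack and applied identically to every plane, so the colour map is
#' consistent through depth.
#'
#' @param cubes list of \linkS4class{InterferogramCube}s, z-ordered, all of
#'   the same shape.
#' @param config a \code{\link{pipelineConfig}}.
#' @return list of \linkS4class{DynamicImage}s sharing \code{channelBounds}.
#' @export
processStack <- function(cubes, config = pipelineConfig()) {
  if (length(cubes) < 1L) .err("empty stack", "dynoct_bad_args")
  dims <- lapply(cubes, function(x) dim(frames(x)))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    .err("all cubes in a stack must share dimensions", "dynoct_bad_args")
  parts <- lapply(cubes, .processOne, config = config)
  ranges <- .channelRanges(parts, config)
  pooled <- unlist(lapply(parts, function(p) p$rawValue))
  cl <- clipValue(matrix(pooled, ncol = 1L), config$clip_fraction)
  lapply(parts, .composeFromParts, ranges = ranges,
         threshold = cl$threshold, config = config)
}
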