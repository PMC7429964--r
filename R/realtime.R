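# Fast, non-quantitative display variant: per-pixel DFT magnitude integrated
# into three frequency bands (blue = low, green = mid, red = high), streamed
# over a sliding window.  This path trades the quantitative spectral
# summaries for speed and is more noise-sensitive by construction.

#' Define the three frequency bands
#'
#' Four increasing edges \code{[e0, e1, e2, e3]} partition the frequency axis
#' into low ([e0, e1)), mid ([e1, e2)) and high ([e2, e3]) bands.
#'
#' @param edges numeric(4), strictly increasing, in Hz.
#' @return object of class \code{"BandDefinition"}.
#' @export
bandDefinition <- function(edges) {
  edges <- as.numeric(edges)
  if (length(edges) != 4L || any(diff(edges) <= 0))
    .err("band edges must be four strictly increasing frequencies",
         "dynoct_bad_args")
  structure(list(edges = edges), class = "BandDefinition")
}

#' Default bands: tertiles of the post-DC frequency axis
#'
#' @param frameRate sampling rate in Hz.
#' @param windowLength DFT window length in frames (sets the grid spacing).
#' @return a \code{\link{bandDefinition}} spanning the first non-DC bin to
#'   Nyquist in three equal-width bands.
#' @export
defaultBands <- function(frameRate, windowLength) {
  e0 <- frameRate / windowLength
  e3 <- frameRate / 2
  bandDefinition(seq(e0, e3, length.out = 4L))
}

#' Three-band RGB image of a cube window
#'
#' Per pixel, the DFT magnitude of the temporal signal (mean-detrended, so
#' static pixels go dark) is summed over the low, mid and high bands; the low
#' band is coded blue, the mid band green and the high band red.  Each
#' channel is independently rescaled to [0, 1] by its own maximum
#' (\code{normalize = "image"}), by supplied maxima (\code{"fixed"}), or left
#' raw (\code{"none"}).
#'
#' @param cube an \linkS4class{InterferogramCube} (or window thereof) with at
#'   least 8 frames.
#' @param bands a \code{\link{bandDefinition}}; default
#'   \code{\link{defaultBands}}.
#' @param normalize \code{"image"}, \code{"fixed"} or \code{"none"}.
#' @param maxima numeric(3) channel maxima for \code{normalize = "fixed"}.
#' @return (height, width, 3) array, channels ordered R, G, B; raw channel
#'   maxima attached as attribute \code{"maxima"}.
#' @export
threeBandRGB <- function(cube, bands = NULL,
                         normalize = c("image", "fixed", "none"),
                         maxima = NULL) {
  stopifnot(is(cube, "InterferogramCube"))
  normalize <- match.arg(normalize)
  d <- dim(cube@frames)
  n <- d[1L]
  if (n < 8L) .err("window must contain at least 8 frames", "dynoct_bad_args")
  if (is.null(bands)) bands <- defaultBands(cube@frameRate, n)
  e <- bands$edges
  nyq <- cube@frameRate / 2
  if (e[4L] > nyq + 1e-9)
    .err(sprintf("band edge %.3g Hz exceeds Nyquist (%.3g Hz)", e[4L], nyq),
         "dynoct_bad_args")
  mat <- matrix(cube@frames, n, d[2L] * d[3L])
  mat <- sweep(mat, 2L, colMeans(mat))  # DC exclusion
  nfreq <- n %/% 2L + 1L
  f <- (seq_len(nfreq) - 1L) * cube@frameRate / n
  mag <- abs(stats::mvfft(mat)[seq_len(nfreq), , drop = FALSE])
  inBand <- function(lo, hi, closed) f > 0 & f >= lo & (if (closed) f <= hi else f < hi)
  sumBand <- function(sel)
    matrix(colSums(mag[sel, , drop = FALSE]), d[2L], d[3L])
  B <- sumBand(inBand(e[1L], e[2L], FALSE))
  G <- sumBand(inBand(e[2L], e[3L], FALSE))
  R <- sumBand(inBand(e[3L], e[4L], TRUE))
  raw <- array(c(R, G, B), dim = c(d[2L], d[3L], 3L))
  mx <- apply(raw, 3L, max)
  out <- switch(normalize,
    none = raw,
    image = {
      sc <- ifelse(mx > 0, mx, 1)
      sweep(raw, 3L, sc, "/")
    },
    fixed = {
      if (is.null(maxima) || length(maxima) != 3L)
        .err("normalize='fixed' needs numeric(3) maxima", "dynoct_bad_args")
      sc <- ifelse(maxima > 0, maxima, 1)
      pmin(sweep(raw, 3L, sc, "/"), 1)
    })
  attr(out, "maxima") <- mx
  out
}

#' Stream three-band images over a sliding window
#'
#' Emits one RGB image per \code{hop} frames over a sliding window, the
#' real-time display mode: at a 100 Hz frame rate and hop 2 the output
#' interval is 20 ms, i.e. a 50 Hz display rate.  With \code{hop} equal to
#' the window length the outputs are non-overlapping and identical to batch
#' \code{\link{threeBandRGB}} on each block.
#'
#' @param cube an \linkS4class{InterferogramCube} source.
#' @param windowLength sliding-window length in frames (default 128).
#' @param hop frames between successive outputs (default 2).
#' @param bands a \code{\link{bandDefinition}}; default tertiles.
#' @param normalize \code{"image"} (each output scaled by its own channel
#'   maxima; default) or \code{"running"} (running channel maxima with
#'   exponential forgetting).
#' @param forgetting per-frame forgetting factor for the running maxima
#'   (default 0.99).
#' @return list with \code{images} (list of RGB arrays), \code{times}
#'   (window-start times, s), \code{interval} (s between outputs) and
#'   \code{outputRate} (Hz).
#' @export
streamCube <- function(cube, windowLength = 128L, hop = 2L, bands = NULL,
                       normalize = c("image", "running"), forgetting = 0.99) {
  stopifnot(is(cube, "InterferogramCube"))
  normalize <- match.arg(normalize)
  n <- nFrames(cube)
  windowLength <- as.integer(windowLength)
  hop <- as.integer(hop)
  if (hop < 1L) .err("hop must be >= 1", "dynoct_bad_args")
  if (n < windowLength) {
    warning("source shorter than one window; no output")
    return(list(images = list(), times = numeric(0),
                interval = hop / cube@frameRate,
                outputRate = cube@frameRate / hop))
  }
  if (is.null(bands)) bands <- defaultBands(cube@frameRate, windowLength)
  starts <- seq.int(1L, n - windowLength + 1L, by = hop)
  images <- vector("list", length(starts))
  runMax <- rep(0, 3L)
  for (k in seq_along(starts)) {
    s <- starts[k]
    sub <- new("InterferogramCube",
               frames = cube@frames[s:(s + windowLength - 1L), , , drop = FALSE],
               frameRate = cube@frameRate, metadata = list())
    if (normalize == "image") {
      images[[k]] <- threeBandRGB(sub, bands, normalize = "image")
    } else {
      raw <- threeBandRGB(sub, bands, normalize = "none")
      runMax <- pmax(runMax * forgetting^hop, attr(raw, "maxima"))
      sc <- ifelse(runMax > 0, runMax, 1)
      img <- pmin(sweep(raw, 3L, sc, "/"), 1)
      attr(img, "maxima") <- attr(raw, "maxima")
      images[[k]] <- img
    }
  }
  list(images = images, times = (starts - 1L) / cube@frameRate,
       interval = hop / cube@frameRate, outputRate = cube@frameRate / hop)
}
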