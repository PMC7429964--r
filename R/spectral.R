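# Per-pixel power-spectrum estimation and the scalar summaries (mean
# frequency, spectral bandwidth) that drive the colour channels.

.taper <- function(window, L) {
  switch(window,
    hann = 0.5 * (1 - cos(2 * pi * seq_len(L) / L)),  # periodic Hann
    boxcar = ,
    rect = ,
    none = rep(1, L),
    .err(sprintf("unknown taper '%s'", window), "dynoct_bad_args"))
}

.defaultSegmentLength <- function(n) {
  # n/8 rounded down to a power of two (64 for 512 frames), floor 8
  max(8L, 2L^floor(log2(max(n / 8, 8))))
}

# Welch PSD of every column of mat (time down the rows).
# Returns list(f, psd) with psd of dim (nfreq, ncol(mat)).
.welchCore <- function(mat, frameRate, segmentLength, overlapFraction,
                       window, detrend = TRUE) {
  n <- nrow(mat)
  L <- as.integer(segmentLength)
  if (L < 8L) .err("segment_length must be >= 8", "dynoct_bad_args")
  if (n < L)
    .err(sprintf("trace length %d shorter than one segment (%d)", n, L),
         "dynoct_short_trace")
  if (overlapFraction < 0 || overlapFraction >= 1)
    .err("overlap_fraction must be in [0, 1)", "dynoct_bad_args")
  win <- .taper(window, L)
  step <- max(1L, as.integer(round(L * (1 - overlapFraction))))
  starts <- seq.int(1L, n - L + 1L, by = step)
  nfreq <- L %/% 2L + 1L
  acc <- matrix(0, nfreq, ncol(mat))
  for (s in starts) {
    seg <- mat[s:(s + L - 1L), , drop = FALSE]
    if (detrend) seg <- sweep(seg, 2L, colMeans(seg))
    X <- stats::mvfft(seg * win)
    acc <- acc + abs(X[seq_len(nfreq), , drop = FALSE])^2
  }
  U <- sum(win^2)
  psd <- acc / (length(starts) * frameRate * U)
  # one-sided: double all bins except DC and (for even L) Nyquist
  dbl <- 2:(if (L %% 2L == 0L) nfreq - 1L else nfreq)
  psd[dbl, ] <- 2 * psd[dbl, , drop = FALSE]
  list(f = (seq_len(nfreq) - 1L) * frameRate / L, psd = psd)
}

#' Welch power spectral density of an intensity trace
#'
#' Averaged modified periodogram over tapered, overlapping segments.  Each
#' segment is detrended by its mean (the static backscatter level is FFOCT
#' signal, not dynamic signal), tapered, and Fourier transformed; the
#' one-sided PSD is averaged across segments.  The grid spacing is
#' \code{frameRate / segmentLength} and the density satisfies Parseval's
#' relation (its integral approximates the detrended trace variance).
#'
#' @param trace numeric vector (one pixel's intensity time series).
#' @param frameRate sampling rate in Hz.
#' @param segmentLength samples per segment; default the trace length / 8
#'   rounded down to a power of two (minimum 8).
#' @param overlapFraction fractional overlap between segments in [0, 1);
#'   default 0.5.
#' @param window taper name: \code{"hann"} (default) or \code{"boxcar"}.
#' @param detrend subtract each segment's mean before tapering (default TRUE).
#' @return list with \code{f} (Hz, DC to Nyquist) and \code{psd}
#'   (counts^2/Hz).
#' @examples
#' tr <- sin(2 * pi * 10 * (0:511) / 100)
#' ps <- welchPSD(tr, frameRate = 100)
#' ps$f[which.max(ps$psd)]  # 10 Hz
#' @export
welchPSD <- function(trace, frameRate, segmentLength = NULL,
                     overlapFraction = 0.5, window = "hann", detrend = TRUE) {
  trace <- as.numeric(trace)
  if (is.null(segmentLength)) segmentLength <- .defaultSegmentLength(length(trace))
  out <- .welchCore(matrix(trace, ncol = 1L), frameRate, segmentLength,
                    overlapFraction, window, detrend)
  list(f = out$f, psd = as.numeric(out$psd))
}

#' L1-normalise raw power spectra into probability-like distributions
#'
#' Each pixel's raw PSD is divided by its sum so it can be treated as a
#' probability distribution over frequency; the pre-normalisation fluctuation
#' power (integral of the raw PSD) is retained separately.  All-zero spectra
#' (perfectly constant pixels) are flagged \emph{silent} rather than divided
#' by zero; downstream channels render them black.
#'
#' @param psd raw PSD: a numeric vector (one pixel) or a matrix with one row
#'   per pixel and one column per frequency bin.
#' @param f the frequency grid in Hz.
#' @param spatialDim optional integer(2) (height, width) when the rows of
#'   \code{psd} raster a cube's pixels.
#' @return a \linkS4class{FrequencySpectrum}.
#' @examples
#' sp <- l1Normalize(c(2, 6, 2), f = c(1, 2, 3))
#' sp@P  # 0.2 0.6 0.2
#' @export
l1Normalize <- function(psd, f, spatialDim = integer(0)) {
  if (is.null(dim(psd))) psd <- matrix(psd, nrow = 1L)
  if (any(psd < 0)) .err("raw PSD must be non-negative", "dynoct_bad_args")
  s <- rowSums(psd)
  silent <- s == 0
  P <- psd / ifelse(s == 0, 1, s)
  P[silent, ] <- 0
  df <- if (length(f) > 1L) f[2L] - f[1L] else 1
  new("FrequencySpectrum", P = P, f = as.numeric(f), totalPower = s * df,
      silent = silent, trimFraction = 0, spatialDim = as.integer(spatialDim))
}

#' Trim the lowest-frequency bins of normalised spectra
#'
#' Removes the lowest \code{ceiling(fraction * nbins)} frequency bins (the
#' band where sensor and mechanical instabilities concentrate) and
#' renormalises the retained bins to sum to 1.  Pixels whose retained power
#' is zero become silent.
#'
#' @param spectrum a \linkS4class{FrequencySpectrum}.
#' @param fraction fraction of bins to drop, in [0, 1); default 0.03.
#' @return a \linkS4class{FrequencySpectrum} on the retained grid.
#' @export
trimLowFrequencies <- function(spectrum, fraction = 0.03) {
  stopifnot(is(spectrum, "FrequencySpectrum"))
  if (fraction < 0 || fraction >= 1)
    .err("trim fraction must be in [0, 1)", "dynoct_bad_args")
  nb <- length(spectrum@f)
  nrem <- ceiling(fraction * nb)
  if (nrem == 0L) return(spectrum)
  keep <- seq.int(nrem + 1L, nb)
  P <- spectrum@P[, keep, drop = FALSE]
  s <- rowSums(P)
  silent <- spectrum@silent | s == 0
  P <- P / ifelse(s == 0, 1, s)
  P[silent, ] <- 0
  new("FrequencySpectrum", P = P, f = spectrum@f[keep],
      totalPower = spectrum@totalPower, silent = silent,
      trimFraction = fraction, spatialDim = spectrum@spatialDim)
}

.shapeSummary <- function(x, spec) {
  if (length(spec@spatialDim) == 2L)
    matrix(x, spec@spatialDim[1L], spec@spatialDim[2L])
  else if (length(x) == 1L) as.numeric(x)
  else x
}

#' @describeIn FrequencySpectrum-class mean frequency per pixel: the dot
#'   product of the normalised PSD with the frequency array (Hz).  Silent
#'   pixels yield \code{NA}.  Returns a (height x width) matrix when the
#'   spectra came from a cube.
#' @param ... unused.
#' @export
setMethod("meanFrequency", "FrequencySpectrum", function(x, ...) {
  mf <- as.numeric(x@P %*% x@f)
  mf[x@silent] <- NA_real_
  .shapeSummary(mf, x)
})

#' @describeIn FrequencySpectrum-class spectral bandwidth per pixel
#'   (Hz^2): the variance of frequency under the normalised PSD,
#'   \eqn{S = P\cdot f^2 - (P\cdot f)^2}.  Silent pixels yield \code{NA}.
#' @export
setMethod("bandwidthS", "FrequencySpectrum", function(x, ...) {
  m1 <- as.numeric(x@P %*% x@f)
  m2 <- as.numeric(x@P %*% (x@f^2))
  S <- pmax(m2 - m1^2, 0)
  S[x@silent] <- NA_real_
  .shapeSummary(S, x)
})

#' Per-pixel normalised spectra of a cube
#'
#' Runs Welch's method on every pixel of a (normalised) cube, discards the DC
#' bin, L1-normalises each pixel's PSD and trims the lowest-frequency bins.
#'
#' @param cube an \linkS4class{InterferogramCube} (normally a
#'   \linkS4class{NormalizedCube}).
#' @param segmentLength,overlapFraction,window,detrend Welch parameters, see
#'   \code{\link{welchPSD}}.
#' @param trimFraction fraction of the lowest frequency bins to drop
#'   (default 0.03).
#' @return a \linkS4class{FrequencySpectrum} with one row per pixel and
#'   \code{spatialDim} set, ready for \code{\link{meanFrequency}} and
#'   \code{\link{bandwidthS}}.
#' @export
cubeSpectra <- function(cube, segmentLength = NULL, overlapFraction = 0.5,
                        window = "hann", detrend = TRUE, trimFraction = 0.03) {
  stopifnot(is(cube, "InterferogramCube"))
  d <- dim(cube@frames)
  if (is.null(segmentLength)) segmentLength <- .defaultSegmentLength(d[1L])
  mat <- matrix(cube@frames, d[1L], d[2L] * d[3L])
  w <- .welchCore(mat, cube@frameRate, segmentLength, overlapFraction,
                  window, detrend)
  keep <- w$f > 0  # DC holds the static backscatter level, not dynamics
  spec <- l1Normalize(t(w$psd[keep, , drop = FALSE]), w$f[keep],
                      spatialDim = d[2:3])
  trimLowFrequencies(spec, trimFraction)
}
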