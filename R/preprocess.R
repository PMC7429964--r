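# Exposure correction: camera frame-to-frame instability is multiplicative and
# global, so each frame is rescaled to a common spatial mean before any
# spectral analysis.

#' Normalise frames for exposure instability
#'
#' Rescales every frame of an interferogram cube so that all frames share the
#' same spatial mean, compensating multiplicative frame-to-frame exposure
#' variations.  By default the common mean is the global mean of the cube
#' (preserving total intensity); \code{reference = "first"} instead matches
#' every frame to the first frame's mean.
#'
#' The operation is idempotent and exactly inverts a multiplicative per-frame
#' drift \eqn{d(t)}: the recorded factors are proportional to \eqn{1/d(t)}.
#'
#' @param cube an \linkS4class{InterferogramCube}.
#' @param reference \code{"global"} (default) or \code{"first"}.
#' @return a \linkS4class{NormalizedCube}; per-frame factors are available
#'   through \code{\link{normalizationFactors}}.
#' @export
normalizeFrames <- function(cube, reference = c("global", "first")) {
  stopifnot(is(cube, "InterferogramCube"))
  reference <- match.arg(reference)
  d <- dim(cube@frames)
  n <- d[1L]
  mat <- matrix(cube@frames, n, d[2L] * d[3L])
  means <- rowMeans(mat)
  zero <- which(means == 0)
  if (length(zero))
    .err(sprintf("frame %s has zero mean; cannot normalize",
                 paste(zero, collapse = ", ")), "dynoct_zero_frame")
  target <- if (reference == "global") mean(means) else means[1L]
  factors <- target / means
  out <- array(mat * factors, dim = d)  # factors recycle down columns (time)
  new("NormalizedCube", frames = out, frameRate = cube@frameRate,
      metadata = c(cube@metadata, list(normalization_reference = reference)),
      normalizationFactors = factors)
}
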