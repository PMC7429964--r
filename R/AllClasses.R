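#' @import methods
#' @importFrom stats fft mvfft rnorm runif rpois cor quantile sd var spline
NULL

.modelKinds <- c("static", "brownian_phase", "relaxation_phase", "white_intensity")

#' Per-pixel fluctuation model for the interferogram simulator
#'
#' Describes the temporal statistics of the interferometric signal in one
#' scene region.  The physical picture is two-beam interference: backscatterer
#' displacement modulates the optical phase \eqn{\phi(t)}, and the camera sees
#' \eqn{I(t) = B + A\cos\phi(t)} plus noise.  Four kinds are supported:
#' \describe{
#'   \item{static}{constant phase; no fluctuation (rate must be 0).}
#'   \item{brownian_phase}{Wiener phase, increment variance \eqn{2\,r\,\Delta t};
#'     models free diffusion of scatterers.}
#'   \item{relaxation_phase}{mean-reverting (Ornstein--Uhlenbeck) phase with
#'     correlation time \eqn{1/r}; models confined motion.  In the
#'     small-modulation limit its intensity spectrum is Lorentzian with
#'     half-width \eqn{r/(2\pi)} Hz.}
#'   \item{white_intensity}{i.i.d. additive intensity fluctuations (null model
#'     with a flat spectrum).}
#' }
#'
#' @slot kind character; one of \code{"static"}, \code{"brownian_phase"},
#'   \code{"relaxation_phase"}, \code{"white_intensity"}.
#' @slot amplitude non-negative interference amplitude in camera counts.
#' @slot rate characteristic rate in Hz (diffusion linewidth or inverse
#'   correlation time); 0 for static.
#' @slot seed integer seed; equal fields and equal seed give identical traces.
#' @export
setClass("FluctuationModel",
  representation(kind = "character", amplitude = "numeric",
                 rate = "numeric", seed = "integer"),
  prototype(kind = "static", amplitude = 0, rate = 0, seed = 1L))

setValidity("FluctuationModel", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !(object@kind %in% .modelKinds))
    msg <- c(msg, sprintf("kind must be one of: %s",
                          paste(.modelKinds, collapse = ", ")))
  if (length(object@amplitude) != 1L || is.na(object@amplitude) ||
      object@amplitude < 0)
    msg <- c(msg, "amplitude must be a single non-negative number")
  if (length(object@rate) != 1L || is.na(object@rate) || object@rate < 0)
    msg <- c(msg, "rate must be a single non-negative number")
  if (identical(object@kind, "static") && length(object@rate) == 1L &&
      !is.na(object@rate) && object@rate != 0)
    msg <- c(msg, "static model must have rate = 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Simulator scene: regions, models and acquisition settings
#'
#' Ground truth for the forward simulation of an interferogram cube.  Each
#' region is a boolean mask paired with a \linkS4class{FluctuationModel};
#' uncovered pixels are frozen speckle (static model at the scene's
#' \code{referenceLevel} with per-pixel random phase).
#'
#' @slot width,height image size in pixels.
#' @slot regions list of \code{list(mask = <logical matrix>, model =
#'   <FluctuationModel>)}; masks must be pairwise disjoint.
#' @slot backgroundLevel incoherent background in camera counts.
#' @slot referenceLevel static interference amplitude of uncovered pixels.
#' @slot frameRate camera frame rate in Hz.
#' @slot nFrames number of frames to simulate.
#' @slot exposureDrift per-frame multiplicative exposure factor (length
#'   \code{nFrames}), emulating camera frame-to-frame instability.
#' @slot shotNoise logical; add Gaussian noise with variance equal to the mean
#'   counts (high-count shot-noise limit).
#' @slot seed root seed; per-pixel substreams are derived by pixel counter so
#'   the region layout does not perturb individual pixel streams.
#' @export
setClass("MotilityScene",
  representation(width = "integer", height = "integer", regions = "list",
                 backgroundLevel = "numeric", referenceLevel = "numeric",
                 frameRate = "numeric", nFrames = "integer",
                 exposureDrift = "numeric", shotNoise = "logical",
                 seed = "integer"))

setValidity("MotilityScene", function(object) {
  msg <- character()
  if (object@width < 1L || object@height < 1L)
    msg <- c(msg, "width and height must be >= 1")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
  if (length(object@exposureDrift) != object@nFrames)
    msg <- c(msg, "exposureDrift must have one factor per frame")
  if (any(object@exposureDrift <= 0))
    msg <- c(msg, "exposureDrift factors must be positive")
  cover <- matrix(0L, object@height, object@width)
  for (i in seq_along(object@regions)) {
    reg <- object@regions[[i]]
    if (!is.list(reg) || !all(c("mask", "model") %in% names(reg))) {
      msg <- c(msg, "each region must be list(mask = , model = )"); next
    }
    if (!is.logical(reg$mask) ||
        !identical(dim(reg$mask), c(object@height, object@width)))
      msg <- c(msg, sprintf("region %d mask must be a height x width logical matrix", i))
    else cover <- cover + reg$mask
    if (!is(reg$model, "FluctuationModel"))
      msg <- c(msg, sprintf("region %d model must be a FluctuationModel", i))
  }
  if (any(cover > 1L)) msg <- c(msg, "region masks overlap")
  if (length(msg)) msg else TRUE
})

#' Raw interferogram cube
#'
#' The (t, y, x) stack of camera frames acquired at fixed depth without
#' reference-arm modulation: the pipeline's sole raw input.  Intensities are
#' non-negative camera counts; frames are equally spaced at
#' \code{1/frameRate} seconds.
#'
#' @slot frames numeric array with dimensions (time, y, x).
#' @slot frameRate camera frame rate in Hz.
#' @slot metadata free-form acquisition descriptors (named list).
#' @export
setClass("InterferogramCube",
  representation(frames = "array", frameRate = "numeric", metadata = "list"))

setValidity("InterferogramCube", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L) msg <- c(msg, "frames must be a 3D (t, y, x) array")
  else if (d[1L] < 2L) msg <- c(msg, "cube must contain at least 2 frames")
  if (length(object@frameRate) != 1L || is.na(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (any(object@frames < 0)) msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Exposure-normalised interferogram cube
#'
#' An \linkS4class{InterferogramCube} whose frames have been rescaled so every
#' frame shares the same spatial mean, undoing multiplicative frame-to-frame
#' exposure variation.  The per-frame factors applied are retained.
#'
#' @slot normalizationFactors the per-frame scalars the frames were multiplied
#'   by.
#' @export
setClass("NormalizedCube", contains = "InterferogramCube",
  representation(normalizationFactors = "numeric"))

setValidity("NormalizedCube", function(object) {
  if (length(object@normalizationFactors) != dim(object@frames)[1L])
    return("one normalization factor per frame required")
  TRUE
})

#' Per-pixel normalised power spectra
#'
#' Holds L1-normalised power spectral densities for one trace or for every
#' pixel of a cube: each row of \code{P} sums to 1 over the retained frequency
#' grid and is treated as a probability distribution over frequency.
#' Pixels with no fluctuation power are flagged \emph{silent} (their P rows
#' are zero) and render black downstream.
#'
#' @slot P numeric matrix, one row per pixel, one column per retained
#'   frequency bin; rows sum to 1 (or 0 for silent pixels).
#' @slot f retained frequency grid in Hz, strictly increasing, ending at the
#'   Nyquist frequency.
#' @slot totalPower pre-normalisation fluctuation power per pixel
#'   (camera-counts squared).
#' @slot silent logical per pixel; TRUE when the raw spectrum was all-zero.
#' @slot trimFraction fraction of lowest-frequency bins that were excluded.
#' @slot spatialDim integer(2) (height, width) when the spectra came from a
#'   cube, or integer(0) for a single trace.
#' @export
setClass("FrequencySpectrum",
  representation(P = "matrix", f = "numeric", totalPower = "numeric",
                 silent = "logical", trimFraction = "numeric",
                 spatialDim = "integer"))

setValidity("FrequencySpectrum", function(object) {
  msg <- character()
  if (ncol(object@P) != length(object@f))
    msg <- c(msg, "ncol(P) must equal length(f)")
  if (length(object@f) > 1L && any(diff(object@f) <= 0))
    msg <- c(msg, "f must be strictly increasing")
  if (any(object@P < -1e-12)) msg <- c(msg, "P must be non-negative")
  s <- rowSums(object@P)
  bad <- !object@silent & abs(s - 1) > 1e-9
  if (any(bad)) msg <- c(msg, "non-silent rows of P must sum to 1 (1e-9)")
  if (length(object@silent) != nrow(object@P) ||
      length(object@totalPower) != nrow(object@P))
    msg <- c(msg, "silent and totalPower must have one entry per pixel")
  if (length(msg)) msg else TRUE
})

#' HSV dynamic image
#'
#' The quantitative colour rendering of a processed cube.  Hue encodes the
#' mean temporal frequency (blue = slow at H = 0.66, red = fast at H = 0),
#' saturation the inverse spectral bandwidth (narrow spectra are vivid, broad
#' noise-like spectra grey), and value the fluctuation amplitude (average
#' running standard deviation).  Silent pixels have value 0 and render black.
#'
#' @slot hue matrix in [0, 0.66].
#' @slot saturation matrix in [0, 0.8].
#' @slot value matrix in [0, 1].
#' @slot rgb (y, x, 3) array, the HSV triplet converted for display.
#' @slot channelBounds list recording the frequency range, bandwidth range and
#'   value clip threshold used for rescaling.
#' @export
setClass("DynamicImage",
  representation(hue = "matrix", saturation = "matrix", value = "matrix",
                 rgb = "array", channelBounds = "list"))

setValidity("DynamicImage", function(object) {
  msg <- character()
  d <- dim(object@hue)
  if (!identical(dim(object@saturation), d) || !identical(dim(object@value), d))
    msg <- c(msg, "hue, saturation and value must share dimensions")
  if (any(object@hue < -1e-9 | object@hue > 0.66 + 1e-9))
    msg <- c(msg, "hue must lie in [0, 0.66]")
  if (any(object@saturation < -1e-9 | object@saturation > 0.8 + 1e-9))
    msg <- c(msg, "saturation must lie in [0, 0.8]")
  if (any(object@value < -1e-9 | object@value > 1 + 1e-9))
    msg <- c(msg, "value must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Planar mapping between image planes
#'
#' A 3x3 homogeneous transform acting on 0-based pixel coordinates
#' \code{(x, y, 1)} (column vectors; origin top-left, x rightward, y
#' downward).  Rigid transforms (rotation + translation) have an orthonormal
#' upper-left 2x2 block with determinant +1; projective transforms
#' (homographies) are invertible and normalised so the bottom-right entry
#' is 1.
#'
#' @slot kind \code{"rigid"} or \code{"projective"}.
#' @slot matrix the 3x3 transform matrix.
#' @export
setClass("PlanarTransform",
  representation(kind = "character", matrix = "matrix"))

setValidity("PlanarTransform", function(object) {
  msg <- character()
  m <- object@matrix
  if (!identical(dim(m), c(3L, 3L))) return("matrix must be 3x3")
  if (!(object@kind %in% c("rigid", "projective")))
    msg <- c(msg, "kind must be 'rigid' or 'projective'")
  if (identical(object@kind, "rigid")) {
    R <- m[1:2, 1:2]
    if (max(abs(crossprod(R) - diag(2))) > 1e-6 || det(R) < 0)
      msg <- c(msg, "rigid transform needs orthonormal 2x2 block, det +1")
    if (max(abs(m[3, ] - c(0, 0, 1))) > 1e-9)
      msg <- c(msg, "rigid transform bottom row must be (0, 0, 1)")
  } else {
    if (abs(det(m)) < 1e-12) msg <- c(msg, "projective matrix must be invertible")
    if (abs(m[3, 3] - 1) > 1e-9)
      msg <- c(msg, "projective matrix must be normalised to m[3,3] = 1")
  }
  if (length(msg)) msg else TRUE
})

#' Result of an axial plane-locking scan
#'
#' @slot bestOffset axial offset (micrometres) of the candidate plane that
#'   maximises the zero-mean normalised cross-correlation with the target.
#' @slot peakCorrelation the correlation at that plane, in [-1, 1].
#' @slot profile data.frame with columns \code{offset} and \code{correlation}.
#' @export
setClass("PlaneLockResult",
  representation(bestOffset = "numeric", peakCorrelation = "numeric",
                 profile = "data.frame"))

setValidity("PlaneLockResult", function(object) {
  p <- object@profile
  if (!all(c("offset", "correlation") %in% names(p)))
    return("profile needs 'offset' and 'correlation' columns")
  if (!isTRUE(all.equal(object@peakCorrelation, max(p$correlation))))
    return("peakCorrelation must equal max(profile$correlation)")
  if (!object@bestOffset %in% p$offset)
    return("bestOffset must lie on the scanned grid")
  TRUE
})
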