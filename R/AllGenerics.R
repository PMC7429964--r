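#' @rdname InterferogramCube-class
#' @param object,x an object.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname InterferogramCube-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname InterferogramCube-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrequencySpectrum-class
#' @export
setGeneric("meanFrequency", function(x, ...) standardGeneric("meanFrequency"))

#' @rdname FrequencySpectrum-class
#' @export
setGeneric("bandwidthS", function(x, ...) standardGeneric("bandwidthS"))

#' @rdname DynamicImage-class
#' @export
setGeneric("hueMap", function(x) standardGeneric("hueMap"))

#' @rdname DynamicImage-class
#' @export
setGeneric("saturationMap", function(x) standardGeneric("saturationMap"))

#' @rdname DynamicImage-class
#' @export
setGeneric("valueMap", function(x) standardGeneric("valueMap"))

#' @rdname DynamicImage-class
#' @export
setGeneric("rgbArray", function(x) standardGeneric("rgbArray"))

#' @rdname DynamicImage-class
#' @export
setGeneric("channelBounds", function(x) standardGeneric("channelBounds"))

#' @rdname PlanarTransform-class
#' @export
setGeneric("transformMatrix", function(x) standardGeneric("transformMatrix"))

#' @export
#' @rdname InterferogramCube-class
setMethod("frames", "InterferogramCube", function(x) x@frames)

#' @export
#' @rdname InterferogramCube-class
setMethod("frameRate", "InterferogramCube", function(x) x@frameRate)

#' @export
#' @rdname InterferogramCube-class
setMethod("nFrames", "InterferogramCube", function(x) dim(x@frames)[1L])

#' @export
#' @rdname InterferogramCube-class
setMethod("dim", "InterferogramCube", function(x) dim(x@frames))

#' Per-frame factors applied during exposure normalisation
#' @param x a NormalizedCube.
#' @return numeric vector, one factor per frame.
#' @export
normalizationFactors <- function(x) {
  stopifnot(is(x, "NormalizedCube"))
  x@normalizationFactors
}

#' @export
#' @rdname DynamicImage-class
setMethod("hueMap", "DynamicImage", function(x) x@hue)

#' @export
#' @rdname DynamicImage-class
setMethod("saturationMap", "DynamicImage", function(x) x@saturation)

#' @export
#' @rdname DynamicImage-class
setMethod("valueMap", "DynamicImage", function(x) x@value)

#' @export
#' @rdname DynamicImage-class
setMethod("rgbArray", "DynamicImage", function(x) x@rgb)

#' @export
#' @rdname DynamicImage-class
setMethod("channelBounds", "DynamicImage", function(x) x@channelBounds)

#' @export
#' @rdname PlanarTransform-class
setMethod("transformMatrix", "PlanarTransform", function(x) x@matrix)

#' Accessors for plane-lock results
#' @param x a PlaneLockResult.
#' @return \code{bestOffset}: the locking offset in micrometres;
#'   \code{peakCorrelation}: the correlation at that offset;
#'   \code{lockProfile}: the full correlation-vs-offset profile.
#' @export
bestOffset <- function(x) { stopifnot(is(x, "PlaneLockResult")); x@bestOffset }

#' @rdname bestOffset
#' @export
peakCorrelation <- function(x) {
  stopifnot(is(x, "PlaneLockResult")); x@peakCorrelation
}

#' @rdname bestOffset
#' @export
lockProfile <- function(x) { stopifnot(is(x, "PlaneLockResult")); x@profile }

setMethod("show", "InterferogramCube", function(object) {
  d <- dim(object@frames)
  cat(sprintf("%s: %d frames of %d x %d px at %g Hz (%.2f s)\n",
              class(object), d[1L], d[3L], d[2L], object@frameRate,
              d[1L] / object@frameRate))
  if (is(object, "NormalizedCube"))
    cat(sprintf("  normalization factors in [%.4g, %.4g]\n",
                min(object@normalizationFactors),
                max(object@normalizationFactors)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "FluctuationModel", function(object) {
  cat(sprintf("FluctuationModel '%s': amplitude %g, rate %g Hz, seed %d\n",
              object@kind, object@amplitude, object@rate, object@seed))
})

setMethod("show", "MotilityScene", function(object) {
  cat(sprintf("MotilityScene %d x %d px, %d regions, %d frames at %g Hz\n",
              object@width, object@height, length(object@regions),
              object@nFrames, object@frameRate))
  cat(sprintf("  background %g, reference %g, shot noise %s, seed %d\n",
              object@backgroundLevel, object@referenceLevel,
              object@shotNoise, object@seed))
})

setMethod("show", "FrequencySpectrum", function(object) {
  cat(sprintf("FrequencySpectrum: %d pixel(s), %d bins over [%.3g, %.3g] Hz\n",
              nrow(object@P), length(object@f), min(object@f), max(object@f)))
  cat(sprintf("  trim fraction %.3g, %d silent pixel(s)\n",
              object@trimFraction, sum(object@silent)))
})

setMethod("show", "DynamicImage", function(object) {
  d <- dim(object@hue)
  cat(sprintf("DynamicImage %d x %d px (HSV + RGB)\n", d[2L], d[1L]))
  cat(sprintf("  hue in [%.3f, %.3f], saturation in [%.3f, %.3f], value in [%.3f, %.3f]\n",
              min(object@hue), max(object@hue), min(object@saturation),
              max(object@saturation), min(object@value), max(object@value)))
})

setMethod("show", "PlanarTransform", function(object) {
  cat(sprintf("PlanarTransform (%s):\n", object@kind))
  print(round(object@matrix, 6))
})

setMethod("show", "PlaneLockResult", function(object) {
  cat(sprintf("PlaneLockResult: best offset %+.2f um, peak correlation %.3f (%d planes scanned)\n",
              object@bestOffset, object@peakCorrelation, nrow(object@profile)))
})
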