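# Readers/writers, configuration and run logs.  Cubes travel as multi-page
# 16-bit TIFF (one page per frame, page order = time order) with a JSON
# sidecar holding the frame rate and metadata.

#' Pipeline configuration
#'
#' All processing parameters in one place, with defaults matching the
#' standard acquisition (100 Hz, 512 frames) and the published processing
#' constants: 3\% low-frequency trim, running-std window of 50 samples,
#' 0.1\% highlight clipping, hue rescaled to [0, 0.66], saturation to
#' [0, 0.8], streaming hop of 2 frames.
#'
#' @param ... named overrides of any default, nested lists merged (e.g.
#'   \code{welch = list(window = "boxcar")}).
#' @return a list of class \code{"dynoctConfig"}.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    frame_rate = 100,
    n_frames = 512L,
    welch = list(segment_length = NULL, overlap = 0.5, window = "hann"),
    trim_fraction = 0.03,
    value_window = 50L,
    clip_fraction = 0.001,
    hue_range = c(0, 0.66),
    sat_range = c(0, 0.8),
    saturation_statistic = "variance",
    autoscale = FALSE,
    realtime = list(hop = 2L, window = 128L, bands = NULL),
    registration = list(max_features = 200L, patch_radius = 8L,
                        iterations = 500L, inlier_tol = 1.5,
                        lock_threshold = 0.3),
    overlay = list(alpha = 1),
    interp = list(target_edge = 0.22),
    seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  cfg <- utils::modifyList(cfg, over)
  class(cfg) <- c("dynoctConfig", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override \code{\link{pipelineConfig}}
#'   defaults.
#' @return a \code{"dynoctConfig"} list.
#' @export
readPipelineConfig <- function(path) {
  pipelineConfig(yaml::read_yaml(path))
}

.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read an interferogram cube from multi-page TIFF
#'
#' Pages are camera frames in time order.  The frame rate is taken from the
#' JSON sidecar written by \code{\link{writeCube}} (same basename, .json
#' extension) unless supplied explicitly.
#'
#' @param path multi-page TIFF with at least 2 pages of identical shape.
#' @param frameRate frame rate in Hz; overrides or replaces the sidecar.
#' @return an \linkS4class{InterferogramCube}.
#' @export
readCube <- function(path, frameRate = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    .err(sprintf("'%s' has %d page(s); a cube needs at least 2 frames",
                 path, length(pages)), "dynoct_bad_file")
  dims <- unique(vapply(pages, function(p) paste(dim(p), collapse = "x"), ""))
  if (length(dims) != 1L)
    .err(sprintf("'%s' has ragged pages (%s)", path,
                 paste(dims, collapse = ", ")), "dynoct_bad_file")
  meta <- list()
  sc <- .sidecarPath(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(frameRate)) frameRate <- meta$frame_rate
  if (is.null(frameRate))
    .err(sprintf(paste0("no frame rate for '%s': provide frameRate= or a ",
                        "sidecar '%s' with a frame_rate field"), path, sc),
         "dynoct_bad_file")
  d <- dim(pages[[1L]])
  arr <- array(0, dim = c(length(pages), d[1L], d[2L]))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  meta$frame_rate <- NULL
  new("InterferogramCube", frames = arr, frameRate = as.numeric(frameRate),
      metadata = if (is.list(meta)) meta else list())
}

.writeJSON <- function(x, path) {
  # deterministic bytes: sorted keys, fixed formatting
  srt <- function(v) {
    if (is.list(v) && !is.null(names(v))) {
      v <- v[order(names(v))]
      lapply(v, srt)
    } else v
  }
  txt <- jsonlite::toJSON(srt(x), auto_unbox = TRUE, digits = NA,
                          pretty = TRUE, null = "null")
  writeLines(txt, path)
}

#' Write an interferogram cube as 16-bit multi-page TIFF plus JSON sidecar
#'
#' Counts are rounded to integers and stored uncompressed; a cube of integer
#' counts round-trips bit-identically through \code{\link{readCube}}.
#'
#' @param cube an \linkS4class{InterferogramCube}.
#' @param path output TIFF path; the sidecar goes to the same basename with
#'   a .json extension.
#' @return \code{path}, invisibly.
#' @export
writeCube <- function(cube, path) {
  stopifnot(is(cube, "InterferogramCube"))
  n <- nFrames(cube)
  pages <- lapply(seq_len(n), function(t)
    pmin(pmax(round(cube@frames[t, , ]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  .writeJSON(c(list(frame_rate = cube@frameRate, n_frames = n),
               cube@metadata), .sidecarPath(path))
  invisible(path)
}

#' Write a dynamic image as RGB PNG plus JSON sidecar
#'
#' @param img a \linkS4class{DynamicImage} or (y, x, 3) array in [0, 1].
#' @param path output PNG path.
#' @param config optional configuration recorded in the sidecar.
#' @return \code{path}, invisibly.
#' @export
writeDynamicImage <- function(img, path, config = NULL) {
  if (is(img, "DynamicImage")) {
    arr <- rgbArray(img)
    meta <- list(channel_bounds = channelBounds(img))
  } else {
    arr <- img
    meta <- list()
  }
  png::writePNG(pmin(pmax(arr, 0), 1), path)
  if (!is.null(config)) meta$config <- unclass(config)
  if (length(meta)) .writeJSON(meta, .sidecarPath(path))
  invisible(path)
}

#' Read a single-channel image (TIFF or PNG)
#'
#' Multi-channel inputs are reduced to their mean across channels.
#'
#' @param path image path.
#' @return numeric matrix.
#' @export
readGrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  img
}

#' Build a simulator scene from a configuration list
#'
#' The list (typically parsed from YAML) names the image size, acquisition
#' settings and regions.  Each region has a \code{model} block
#' (\code{kind, amplitude, rate, seed}) and a shape: either
#' \code{rect: [x0, y0, x1, y1]} (0-based, inclusive) or
#' \code{circle: [cx, cy, radius]}.
#'
#' @param conf named list (see \code{inst/extdata/example_scene.yaml}).
#' @return a \linkS4class{MotilityScene}.
#' @export
sceneFromConfig <- function(conf) {
  w <- conf$width; h <- conf$height
  regions <- lapply(conf$regions, function(r) {
    mask <- matrix(FALSE, h, w)
    if (!is.null(r$rect)) {
      rc <- as.numeric(r$rect)
      mask[(rc[2L]:rc[4L]) + 1L, (rc[1L]:rc[3L]) + 1L] <- TRUE
    } else if (!is.null(r$circle)) {
      cc <- as.numeric(r$circle)
      xs <- matrix(rep(0:(w - 1L), each = h), h, w)
      ys <- matrix(rep(0:(h - 1L), times = w), h, w)
      mask[(xs - cc[1L])^2 + (ys - cc[2L])^2 <= cc[3L]^2] <- TRUE
    } else .err("region needs a 'rect' or 'circle' shape", "dynoct_bad_args")
    m <- r$model
    list(mask = mask,
         model = fluctuationModel(m$kind, m$amplitude %||% 1,
                                  m$rate %||% 0, m$seed %||% 1L))
  })
  drift <- conf$exposure_drift
  motilityScene(width = w, height = h, regions = regions,
                backgroundLevel = conf$background_level %||% 10000,
                referenceLevel = conf$reference_level %||% 1000,
                frameRate = conf$frame_rate %||% 100,
                nFrames = conf$n_frames %||% 512L,
                exposureDrift = if (is.null(drift)) NULL else as.numeric(drift),
                shotNoise = conf$shot_noise %||% FALSE,
                seed = conf$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a labelled ground-truth image as PNG
#'
#' @param labels integer matrix of region indices (0 = background).
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeLabels <- function(labels, path) {
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Write a run log
#'
#' Deterministic JSON (sorted keys) recording the fully resolved
#' configuration plus any extra entries.
#'
#' @param path output JSON path.
#' @param config a \code{\link{pipelineConfig}}.
#' @param ... further named entries.
#' @return \code{path}, invisibly.
#' @export
writeRunLog <- function(path, config, ...) {
  .writeJSON(list(config = unclass(config), ...), path)
  invisible(path)
}
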