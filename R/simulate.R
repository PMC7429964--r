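# Forward simulation of interferogram cubes with known per-region motility.
# Signal model: two-beam interference I(t) = B + A*cos(phi(t)) + noise, with
# the phase process prescribed by a FluctuationModel.

# stationary phase std (rad) of the relaxation model; small-modulation regime
# so the intensity autocorrelation tracks the phase autocorrelation exp(-r|t|)
.PHASE_SIGMA <- 0.4

.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dynoct_error")))
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  force(expr)
}

# counter-based substream seed: independent of region layout, always < 2^31
.pixelSeed <- function(root, counter, salt = 0L) {
  as.integer((abs(as.numeric(root)) * 48271 + as.numeric(counter) * 1299709 +
                as.numeric(salt) * 7919) %% 2147483629)
}

#' Construct a fluctuation model
#'
#' @param kind one of \code{"static"}, \code{"brownian_phase"},
#'   \code{"relaxation_phase"}, \code{"white_intensity"}.
#' @param amplitude interference amplitude (camera counts), \eqn{\ge 0}.
#' @param rate characteristic rate in Hz: the phase-diffusion linewidth
#'   (brownian) or inverse correlation time (relaxation).  Must be 0 for
#'   static models.
#' @param seed integer; traces are reproducible from it.
#' @return a \linkS4class{FluctuationModel}.
#' @examples
#' fluctuationModel("relaxation_phase", amplitude = 500, rate = 5, seed = 7)
#' @export
fluctuationModel <- function(kind, amplitude = 1, rate = 0, seed = 1L) {
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% .modelKinds))
    .err(sprintf("unknown fluctuation model kind '%s'", as.character(kind)[1L]),
         "dynoct_bad_model")
  new("FluctuationModel", kind = kind, amplitude = as.numeric(amplitude),
      rate = as.numeric(rate), seed = as.integer(seed))
}

#' Construct a simulator scene
#'
#' Defaults follow the acquisition conditions the processing pipeline is
#' designed for: 512 frames at 100 Hz.  Background and reference levels are
#' set so the simulated counts sit well inside a 16-bit range, as for a
#' camera operated near saturation.
#'
#' @param width,height image size in pixels.
#' @param regions list of \code{list(mask = <logical matrix (height x width)>,
#'   model = <FluctuationModel>)}; masks must be disjoint.  Uncovered pixels
#'   are frozen speckle at \code{referenceLevel}.
#' @param backgroundLevel incoherent background (camera counts).
#' @param referenceLevel static interference amplitude of uncovered pixels.
#' @param frameRate camera frame rate in Hz.
#' @param nFrames number of frames.
#' @param exposureDrift per-frame multiplicative factors (length
#'   \code{nFrames}); default all 1 (stable exposure).
#' @param shotNoise add Gaussian noise with variance equal to mean counts.
#' @param seed root seed for the whole scene.
#' @return a \linkS4class{MotilityScene}.
#' @export
motilityScene <- function(width, height, regions = list(),
                          backgroundLevel = 10000, referenceLevel = 1000,
                          frameRate = 100, nFrames = 512L,
                          exposureDrift = NULL, shotNoise = FALSE,
                          seed = 1L) {
  if (is.null(exposureDrift)) exposureDrift <- rep(1, nFrames)
  new("MotilityScene", width = as.integer(width), height = as.integer(height),
      regions = regions, backgroundLevel = as.numeric(backgroundLevel),
      referenceLevel = as.numeric(referenceLevel),
      frameRate = as.numeric(frameRate), nFrames = as.integer(nFrames),
      exposureDrift = as.numeric(exposureDrift),
      shotNoise = isTRUE(shotNoise), seed = as.integer(seed))
}

# phase/intensity trace for one pixel under a known seed; no background
.simTraceCore <- function(kind, amplitude, rate, n, frameRate, seed) {
  .withSeed(seed, {
    dt <- 1 / frameRate
    phi0 <- runif(1L, 0, 2 * pi)
    switch(kind,
      static = rep(amplitude * cos(phi0), n),
      brownian_phase = {
        phi <- phi0 + cumsum(rnorm(n, sd = sqrt(2 * rate * dt)))
        amplitude * cos(phi)
      },
      relaxation_phase = {
        a <- exp(-rate * dt)
        innov <- rnorm(n)
        x <- c(.PHASE_SIGMA * innov[1L],
               .PHASE_SIGMA * sqrt(1 - a^2) * innov[-1L])
        dphi <- as.numeric(stats::filter(x, a, method = "recursive"))
        amplitude * cos(phi0 + dphi)
      },
      white_intensity = amplitude * rnorm(n),
      .err(sprintf("unknown fluctuation model kind '%s'", kind),
           "dynoct_bad_model"))
  })
}

#' Simulate one pixel's intensity trace
#'
#' Generates \eqn{I(t) = B + A\cos\phi(t)} (or \eqn{B + A\,\eta(t)} for the
#' white-intensity model) at a fixed frame rate.  Brownian phases take Wiener
#' increments with variance \eqn{2 r \Delta t}; relaxation phases follow a
#' mean-reverting process with correlation time \eqn{1/r}.  Bit-identical
#' traces are produced for identical models and seeds.
#'
#' @param model a \linkS4class{FluctuationModel}.
#' @param nFrames number of samples (>= 2).
#' @param frameRate sampling rate in Hz (> 0).
#' @param background additive background level B (camera counts).
#' @return numeric vector of length \code{nFrames}.
#' @examples
#' m <- fluctuationModel("brownian_phase", amplitude = 100, rate = 2, seed = 3)
#' tr <- simulateTrace(m, nFrames = 512, frameRate = 100)
#' @export
simulateTrace <- function(model, nFrames, frameRate, background = 0) {
  stopifnot(is(model, "FluctuationModel"))
  validObject(model)
  if (nFrames < 2L) .err("nFrames must be >= 2", "dynoct_bad_args")
  if (frameRate <= 0) .err("frameRate must be > 0", "dynoct_bad_args")
  background + .simTraceCore(model@kind, model@amplitude, model@rate,
                             as.integer(nFrames), frameRate, model@seed)
}

#' Simulate an interferogram cube from a scene
#'
#' Every pixel's trace follows its region's fluctuation model (uncovered
#' pixels are frozen speckle); the per-frame exposure-drift factors multiply
#' each frame uniformly; optional shot noise adds Gaussian fluctuations with
#' variance equal to the mean counts.  Per-pixel random substreams are
#' derived from the scene seed by pixel counter, so editing the region layout
#' does not change the streams of unaffected pixels.
#'
#' @param scene a \linkS4class{MotilityScene}.
#' @return list with \code{cube} (an \linkS4class{InterferogramCube}) and
#'   \code{labels} (integer matrix mapping pixels to region indices, 0 for
#'   background).
#' @export
simulateCube <- function(scene) {
  stopifnot(is(scene, "MotilityScene"))
  validObject(scene)
  h <- scene@height; w <- scene@width; n <- scene@nFrames
  labels <- matrix(0L, h, w)
  for (i in seq_along(scene@regions))
    labels[scene@regions[[i]]$mask] <- i
  npix <- h * w
  mat <- matrix(0, n, npix)
  for (j in seq_len(npix)) {
    ri <- labels[j]
    if (ri == 0L) {
      kind <- "static"; amp <- scene@referenceLevel; rate <- 0; salt <- 0L
    } else {
      m <- scene@regions[[ri]]$model
      kind <- m@kind; amp <- m@amplitude; rate <- m@rate; salt <- m@seed
    }
    mat[, j] <- scene@backgroundLevel +
      .simTraceCore(kind, amp, rate, n, scene@frameRate,
                    .pixelSeed(scene@seed, j, salt))
  }
  mat <- mat * scene@exposureDrift  # recycles down columns: per-frame factor
  if (scene@shotNoise) {
    noise <- .withSeed(.pixelSeed(scene@seed, 0L, 104729L),
                       rnorm(n * npix, sd = sqrt(pmax(mat, 0))))
    mat <- mat + noise
  }
  mat <- pmax(mat, 0)
  cube <- new("InterferogramCube", frames = array(mat, dim = c(n, h, w)),
              frameRate = scene@frameRate,
              metadata = list(source = "dynoct simulator", seed = scene@seed))
  list(cube = cube, labels = labels)
}

#' Closed-form expected power spectral density of a fluctuation model
#'
#' Evaluates the analytic one-sided PSD on a frequency grid, for models with
#' a closed form: the relaxation model (small-modulation limit) gives a
#' Lorentzian with half-width \code{rate/(2*pi)} Hz; the white-intensity
#' model is flat up to Nyquist; a static model is a delta at zero frequency
#' (represented as \code{Inf} in the DC bin).  The curve integrates (over
#' [0, Nyquist], trapezoidal) to the trace's expected fluctuation power,
#' which is attached as attribute \code{"power"}.
#'
#' @param model a \linkS4class{FluctuationModel}.
#' @param frameRate sampling rate in Hz (sets the Nyquist limit).
#' @param f frequency grid (Hz) on which to evaluate; defaults to 512 points
#'   from 0 to Nyquist.
#' @return numeric vector of PSD values on \code{f}, with attribute
#'   \code{"power"}.  Brownian-phase models are rejected: their phase is
#'   non-stationary and no stationary closed form is provided; use an
#'   empirical (simulated) oracle instead.
#' @export
analyticPSD <- function(model, frameRate,
                        f = seq(0, frameRate / 2, length.out = 512L)) {
  stopifnot(is(model, "FluctuationModel"))
  validObject(model)
  if (any(f < 0) || any(f > frameRate / 2 + 1e-9))
    .err("frequency grid must lie in [0, Nyquist]", "dynoct_bad_args")
  A <- model@amplitude
  switch(model@kind,
    static = {
      out <- ifelse(f == 0, Inf, 0)
      attr(out, "power") <- 0
      out
    },
    white_intensity = {
      power <- A^2
      out <- rep(power / (frameRate / 2), length(f))
      attr(out, "power") <- power
      out
    },
    relaxation_phase = {
      r <- model@rate
      # E_phi0[ Var(A cos(phi0 + dphi)) ] ~= A^2 sigma^2 / 2, small modulation
      power <- A^2 * .PHASE_SIGMA^2 / 2
      out <- if (r == 0) ifelse(f == 0, Inf, 0)
             else power * 4 * r / (r^2 + (2 * pi * f)^2)
      attr(out, "power") <- power
      out
    },
    brownian_phase = .err(
      "brownian_phase has no stationary closed form; use an empirical oracle",
      "dynoct_no_closed_form"))
}
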