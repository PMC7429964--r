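---
title: "Quantifying subcellular motility with dynamic full-field OCT: models and methods"
author: "dynoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subcellular motility with dynamic full-field OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynoct)
```

## The measurement and the signal model

Dynamic full-field optical coherence tomography (D-FFOCT) records, at a fixed
depth, a movie of the interference between light backscattered by the sample
and light from a reference mirror. Organelle-scale motion displaces the
backscatterers by fractions of a wavelength, which modulates the optical
phase and therefore the intensity on each camera pixel. A pixel's trace is
modelled here as two-beam interference,

$$ I(t) = B + A\cos\phi(t) + \varepsilon(t), $$

where $B$ is an incoherent background, $A$ the interference amplitude, and
$\phi(t)$ the fluctuating phase. The pipeline never needs this model — it is
purely spectral — but the **simulator** uses it to produce cubes whose
statistics are known in closed form, so every processing stage can be tested
against ground truth without an instrument.

Four phase/intensity models are provided:

* `static`: constant phase — frozen speckle, no fluctuation;
* `brownian_phase`: Wiener phase with increment variance $2r\,\Delta t$ (free
  diffusion). The phase is non-stationary, but the intensity autocovariance
  is stationary; `analyticPSD()` still refuses this kind and directs the
  caller to an empirical oracle, because the closed form depends on the
  modulation regime;
* `relaxation_phase`: Ornstein–Uhlenbeck phase with correlation time $1/r$
  (confined motion). In the small-modulation limit the intensity spectrum is
  Lorentzian with half-width $r/(2\pi)$ Hz;
* `white_intensity`: i.i.d. additive intensity noise — a flat-spectrum null
  model.

The relaxation model's stationary phase standard deviation is an internal
constant, 0.4 rad. That value keeps the simulator in the small-modulation
regime where the intensity autocorrelation tracks the phase autocorrelation
$e^{-r|t|}$: the second-harmonic contamination scales as
$\sigma_\phi^2/2 = 8\%$ of the fundamental, small enough that the measured
correlation time agrees with $1/r$ to within a few percent. It is a fixed
numerical choice of the simulator, not a user parameter, because the model
type list carries one amplitude and one rate per region.

Two further acquisition artefacts are simulated because the pipeline exists
to remove or tolerate them: a per-frame multiplicative **exposure drift**
(the camera's frame-to-frame instability) and optional **shot noise**,
Gaussian with variance equal to the mean counts — the high-count limit
appropriate for a camera operated near saturation. Determinism is strict:
one root seed, with per-pixel substreams derived by pixel counter, so adding
a region does not perturb the streams of untouched pixels.

## From cube to colour

The processing chain mirrors the standard D-FFOCT post-processing:

1. **Exposure normalisation.** Every frame is rescaled so all frames share
   one spatial mean. The statistic is the full-frame mean (not the median,
   and not tile-wise): the instability being corrected is multiplicative and
   global, so the mean is sufficient and exactly inverts a multiplicative
   drift. The target is the cube's global mean by default (total intensity
   preserved); matching to the first frame is available via
   `reference = "first"` since either convention is defensible.
2. **Per-pixel Welch PSD.** Averaged modified periodograms over tapered,
   overlapping segments. The Welch parameters are not fixed by the method
   description, so the defaults follow common practice: segment length =
   trace length / 8 rounded down to a power of two (64 for the standard 512
   frames), 50% overlap, Hann taper; all exposed in `pipelineConfig()`.
   Each segment is detrended by its mean and the DC bin is discarded before
   anything else: the static backscatter level is FFOCT signal, not dynamic
   signal.
3. **L1 normalisation.** Each pixel's PSD is divided by its sum and treated
   as a probability distribution $P$ over the frequency grid $f$. The
   pre-normalisation power is kept separately. All-zero spectra are flagged
   *silent* instead of being divided by zero; silent pixels render black.
4. **Low-frequency trim.** The lowest 3% of frequency *bins* are removed and
   $P$ renormalised. The trim is interpreted in bins, not cumulative power,
   because the artefact it removes (sensor and mechanical instability) lives
   at the bottom of the grid regardless of how much power a given pixel has
   there. Trimming happens after the first normalisation and renormalises —
   the order is not observable downstream since every summary uses the
   renormalised $P$.
5. **Channels.**
   * *Hue* is the mean frequency $P \cdot f$, affinely inverted onto
     $[0, 0.66]$: the low end of the frequency range maps to $H = 0.66$
     (blue) and the high end to $H = 0$ (red). The reference range is fixed
     to [post-trim grid minimum, Nyquist] by default so a given frequency is
     always represented by the same colour across acquisitions; per-image
     autoscaling is available (`autoscale = TRUE`). The interval end 0.66 is
     taken as the HSV blue angle ($\approx 240^\circ/360^\circ$).
   * *Saturation* encodes the spectral bandwidth
     $S = P\cdot f^2 - (P\cdot f)^2$, inverted onto $[0, 0.8]$: narrow
     spectra vivid, broad noise-like spectra grey. As printed, $S$ is a
     variance (Hz²) although it is often described as a standard deviation;
     the variance is the default statistic and
     `saturation_statistic = "sd"` switches to its square root.
   * *Value* is the average running standard deviation of the trace, window
     50 samples, stride 1 frame, windows truncated at the trace end
     excluded. The brightest 0.1% of pixels are saturated at the
     nearest-rank 99.9th percentile of the pooled pixel population (ties
     broken by value, then index) and the map is divided by that threshold.
6. **RGB rendering** by the standard HSV conversion with $H$ on the
   $[0, 1]$ circle.

For 3D stacks (`processStack()`), the clip threshold — and, under
autoscaling, the hue/saturation ranges — is computed once from the pooled
stack and applied to every plane, so colour is comparable through depth.
When both the per-plane and per-stack options could apply, the pooled-stack
population wins.

## The real-time variant

The streaming mode trades quantitation for speed: per pixel, the DFT
magnitude is integrated in three bands (blue = low, green = mid, red =
high) and a new image is emitted every `hop` frames of a sliding window.
At the standard 100 Hz frame rate and hop 2 this yields an output every
20 ms (50 Hz). Band edges default to tertiles of the post-DC axis and the
window to 128 frames (a power of two, at least one Welch segment); both are
configurable. Display normalisation is per-output channel maxima by
default, so that non-overlapping streaming (`hop = window`) is bit-exactly
the batch computation on each block; a running-maximum mode with
exponential forgetting (0.99 per frame) is available for flicker-free live
display. This variant is documented as non-quantitative and noise-prone:
its tests assert band selectivity and output cadence, never spectral
summaries.

## Registration, plane locking, depth interpolation

* **Plane locking** scans candidate planes over a 10 µm axial extent at
  0.5 µm steps (interpreted as ±5 µm about the nominal plane) and picks the
  grid argmax of the zero-mean normalised cross-correlation (Pearson over
  pixels) with the target image. No sub-step refinement by default — the
  motor moves in discrete steps — with parabolic refinement behind a flag.
  The relock trigger compares the current correlation against a threshold
  (default 0.3, documented as a mid-range value of the typical 0.2–0.4
  band, not a constant); negative correlations are floored at zero so a
  zero threshold can never trigger.
* **Lateral registration** aligns each plane to the first by corner
  features: Harris responses with quadratic subpixel refinement, normalised
  17×17 patch descriptors, mutual-best matching, and a rigid fit by random
  sample consensus (500 seeded iterations, 1.5 px inlier tolerance)
  followed by a least-squares refit on the inliers. A scale-invariant
  detector is unnecessary here because inter-plane drift is a small, nearly
  rigid motion at constant magnification; the robust consensus step, which
  is what protects the fit from wrong matches, is retained in full.
  Reference choice is the first plane; planes with too few matches keep the
  identity and are flagged rather than failing the stack.
* **Depth interpolation** resamples z by a natural cubic spline (one
  tridiagonal solve shared by all pixels) to a default isotropic voxel edge
  of 0.22 µm; natural splines reproduce constants and linear ramps exactly,
  which is the correctness contract tested. Fewer than 4 planes fall back
  to linear interpolation with a warning.
* **Non-local means** is offered as an optional display filter (patch 5,
  search radius 5, strength relative to the image standard deviation);
  strength 0 is the identity and the mean is preserved.

## Fluorescence overlay

The two cameras are related by a projective transform calibrated from ≥ 4
point pairs via the normalised direct linear transform; degenerate (e.g.
collinear) layouts are rejected by a rank test, and the reprojection RMS is
reported. Overlays insert the (min–max normalised) value channel into all
three RGB channels and *add* the registered fluorescence to the red channel
only, clipped at 1 — additive rather than alpha-blended, since only
"added to R" is specified. Warping uses bilinear resampling: overlays are
display products, so sub-pixel smoothness is preferred over exactness.

## What the simulator does and does not emulate

The simulator is a statistical signal generator, not an optics model: no
point-spread function, no coherence gating, no multiple scattering, no 3D
speckle correlation between pixels. Consequently, passing tests demonstrate
that the *processing* is correct (spectral estimates, channel arithmetic,
clipping and trimming fractions, registration recovery) under known
statistics; they do not certify biological fidelity of any particular
colour, because the fluctuation statistics of real organelles are not
specified anywhere in the method. Simulator parameter ranges were chosen
once for test coverage: rates 0.5–30 Hz straddle the observable band at a
100 Hz frame rate, amplitudes put fluctuations well above double-precision
noise but below camera saturation, and background 10 000 counts with
reference amplitude 1 000 mimics a near-saturation 16-bit camera.

## Numerical choices and degenerate inputs

* Welch one-sided scaling satisfies Parseval (integral ≈ detrended
  variance, within 5% for the Hann default). The independent test oracle is
  a direct DFT sum, and single-segment untapered estimates agree with it to
  1e-9 relative.
* One caveat frozen into the tests: with the default segment length (n/8),
  a 2¹⁵-sample white-noise spectrum has a bin-to-bin coefficient of
  variation of ≈ 0.26 (15 averaged segments); the flatness assertion
  (CV < 0.2) is therefore made at segment length 1024, where averaging is
  sufficient. This is a property of Welch averaging, not of the
  implementation.
* Silent pixels (no retained fluctuation power) propagate as NA summaries
  and render black; all-zero value maps are returned unchanged with a
  warning rather than rescaled by zero.
* The clip threshold uses the nearest-rank quantile; with $m$ distinct
  values exactly $\lfloor 0.001\,m \rfloor$ pixels are clipped.
* Transforms act on 0-based $(x, y, 1)$ column vectors, origin top-left,
  x rightward, y downward; rigid matrices keep an orthonormal 2×2 block
  with determinant +1, homographies are normalised to $H_{33} = 1$.
* Cubes travel as multi-page 16-bit TIFF (time as pages, for universal
  reader support) with a JSON sidecar carrying the frame rate; integer
  count cubes round-trip bit-identically, and all JSON is written with
  sorted keys so identical runs produce identical bytes.

## Problem sizes used by the test-suite and acceptance runs

The shipped tests run the full chain on cubes of 24²–48² pixels × 256–512
frames, single traces up to 10⁵ samples for autocorrelation fits and 2¹⁴
samples for spectrum-shape checks, 128² images for registration, and
21-plane lock scans — sizes at which every statistical assertion has
comfortable margin while the whole suite completes in well under a minute.
These sizes are stated here so results can be reproduced exactly; they are
choices of the package, and all scale up linearly.

## Known limitations

* The relaxation-model spectrum match is asserted in the small-modulation
  regime; large phase excursions shift power into harmonics and the
  Lorentzian description degrades (as it would physically).
* Harris corners are not scale-invariant: lateral registration assumes
  constant magnification between planes, which holds for z-stacks from a
  single objective but would not survive a zoom change.
* Non-local means is implemented slice-wise for volumes; no 3D patch
  search.
* The streaming variant reproduces the computation, not the throughput, of
  a GPU implementation.
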