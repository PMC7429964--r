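# dynoct

Processing pipeline for **dynamic full-field optical coherence tomography
(D-FFOCT)** in R. D-FFOCT images living tissue without labels by recording a
movie of the interferogram at each depth: subcellular motion (organelle
transport, membrane fluctuations) modulates the optical phase of the
backscattered light, and the temporal fluctuation statistics of every camera
pixel become an endogenous contrast for cell state and type — for example in
live retinal organoids, where active cells glow and dying cells go dark.

`dynoct` is for researchers who have (or want to emulate) such
`(x, y, t)` interferogram cubes and need the quantitative colour rendering,
the supporting registration machinery, and a fully synthetic test bench.

## The method

For each pixel's intensity trace, after per-frame exposure normalisation,
the power spectral density is estimated by Welch's method, L1-normalised
into a distribution *P* over the frequency grid *f* (DC excluded, lowest 3%
of bins trimmed), and summarised into an HSV triplet:

* **Hue** — the mean frequency *P·f*, inverted and rescaled to [0, 0.66]:
  blue = slow, red = fast;
* **Saturation** — the spectral bandwidth
  **S = P·f² − (P·f)²**, inverted and rescaled to [0, 0.8]: narrow spectra
  vivid, noise-like spectra grey;
* **Value** — the average running standard deviation of the trace (window
  50 samples), with the top 0.1% of pixels saturated: fluctuation
  amplitude as brightness.

Around this core the package provides: a streaming three-band RGB variant
(one image every 2 frames → 20 ms temporal resolution at 100 Hz), axial
plane locking by cross-correlation, feature-based rigid registration of
z-stacks, depth interpolation to isotropic 220 nm voxels, non-local-means
denoising, projective calibration and red-channel fluorescence overlays,
multi-page TIFF I/O — and a seeded simulator (`motilityScene`,
`simulateCube`) that generates cubes from prescribed phase-fluctuation
models (Brownian, relaxation, white-intensity, static) with exposure drift
and shot noise, so every stage is testable against ground truth.

## Worked example

```r
library(dynoct)

scene <- sceneFromConfig(yaml::read_yaml(
  system.file("extdata/example_scene.yaml", package = "dynoct")))
sim <- simulateCube(scene)   # cube + ground-truth labels
sim$cube
#> InterferogramCube: 512 frames of 48 x 48 px at 100 Hz (5.12 s)

img <- processCube(sim$cube)
img
#> DynamicImage 48 x 48 px (HSV + RGB)
#>   hue in [0.300, 0.618], saturation in [0.471, 0.726], value in [0.006, 1.000]

spec <- cubeSpectra(normalizeFrames(sim$cube))
mf <- meanFrequency(spec)
lab <- sim$labels
for (r in 1:3)
  cat(sprintf("region %d: median mean frequency %.2f Hz, median hue %.3f\n",
              r, median(mf[lab == r]), median(hueMap(img)[lab == r])))
#> region 1: median mean frequency 8.00 Hz, median hue 0.591
#> region 2: median mean frequency 11.09 Hz, median hue 0.548
#> region 3: median mean frequency 26.05 Hz, median hue 0.337
```

The example scene has a slow relaxation region (rate 1 Hz), a fast one
(20 Hz) and a white-noise disc: the mean frequency rises with the
fluctuation rate and the hue falls accordingly (blue → green), exactly the
blue-slow/red-fast encoding. The static speckle background stays near
value 0 (black). Region 3 (white noise) sits at the centre of the retained
frequency band, as a flat spectrum must, and is the least saturated.

A thin command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/dynoct.R", package="dynoct"))') \
  simulate --scene scene.yaml --out cube.tif
# then: process --in cube.tif --out dyn.png
# also: stack / stream / lock / register / interp / calibrate / overlay
```

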