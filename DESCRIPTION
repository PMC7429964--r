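Package: dynoct
Title: Dynamic Full-Field Optical Coherence Tomography Image Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for dynamic full-field optical coherence
    tomography (D-FFOCT). Converts time series of interferometric camera
    frames into quantitative HSV colour maps of subcellular motility:
    per-pixel Welch power spectral density estimation, L1 normalisation,
    low-frequency trimming, mean-frequency (hue), spectral-bandwidth
    (saturation) and running-standard-deviation (value) channels, plus a
    fast three-band streaming variant. Includes axial plane locking by
    cross-correlation, feature-based rigid registration of z-stacks, depth
    interpolation to isotropic voxels, non-local-means denoising,
    projective calibration for fluorescence overlays, multi-page TIFF
    input/output, and a synthetic interferogram simulator with prescribed
    phase-fluctuation spectra that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
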