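Package: muellerpli
Title: Mueller-Matrix Polarimetry Analysis for Backscattering Polarized
    Light Imaging of Fiber Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing per-pixel Mueller-matrix image stacks from
    multi-wavelength backscattering polarized light imaging (PLI).  Provides
    Mueller-matrix algebra for elementary polarization elements, Lu-Chipman
    polar decomposition into retardance, diattenuation and depolarization
    maps, correction of the inverse-cosine phase-wrapping artifact, a
    tilted-uniaxial-crystal forward model for the retardance of inclined
    birefringent fibers, ROI analyses (axial angular histograms, path
    profiles with linear fits, rotation-series registration and fitting),
    an SVD-based Taubin circle fit for radius-of-curvature estimation, and
    a synthetic phantom generator that renders crossing, inclined,
    cylinder-wrapped, in-plane-looping and rotated fiber scenes to Mueller
    stacks with full per-pixel ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
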