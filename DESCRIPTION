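Package: mmphasor
Title: Phasor Analysis for Mueller-Matrix Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for polarization-resolved image analysis with Mueller-matrix
    (MM) scanning microscopy. Converts per-pixel 4x4 Mueller matrices into
    polarization-resolved intensity stacks, applies a single-frequency phasor
    transform, and reads out retardance and fast-axis orientation maps directly
    from the phasor coordinates of the circular- and linear-input channels. The
    Lu-Chipman polar decomposition is provided as the reference baseline, along
    with a forward instrument simulator (polarization state generator/analyzer
    projections, per-element Gaussian noise), synthetic birefringent phantoms
    (uniform retarder films, layered oriented fibre stacks, striped and rotated
    fibre scenes), phasor histograms, phasor-gated segmentation, float32 TIFF
    input/output and region-of-interest summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
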