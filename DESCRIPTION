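Package: evlfm
Title: Event-Camera Fourier Light Field Microscopy: Simulation and
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates dynamic 3D fluorescent scenes imaged through a
    Fourier light field microscope onto a contrast-threshold event sensor,
    and reconstructs them: asynchronous event streams are converted to
    temporally continuous frames with an exponential time-surface
    algorithm, cropped into sub-aperture views, and refocused into 3D
    volumes by shift-and-sum. Includes a full characterization suite
    (PSF/MTF, FWHM resolution, SNR gain, temporal traces, spike
    cross-correlation, 3D centroid tracking) and the loss functions used
    for learned volume enhancement.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
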