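Package: phantomqc
Title: Dose-Neutral Image Quality Analysis for CT and CBCT Phantom Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image-quality analysis for phantom-based quality
    assurance of computed tomography (CT) and cone-beam CT (CBCT) systems.
    Implements the standard region-of-interest metrics (uniformity, Hounsfield
    unit accuracy, contrast-to-noise ratio and its dose-normalized variant
    CNRD, low-contrast visibility), slanted-edge estimation of the modulation
    transfer function (edge spread function, line spread function, normalized
    Fourier transform, MTF50/MTF10 readout), and a synthetic phantom-image
    simulator (rasterization with partial-volume handling, Gaussian system
    blur, radial cupping bias, dose-scaled noise) so that every metric can be
    validated by parameter recovery against closed forms. Results are returned
    as tibbles with broom-style tidiers and ggplot2 autoplot methods; a small
    command-line front end drives simulation, analysis and dose-neutral
    comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    oro.nifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
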