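Package: rcaflow
Title: 3D Ultrafast Doppler Processing for Row-Column Ultrasound Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and processing toolchain for row-column-addressed (RCA)
    ultrasound sensors aimed at 3D microvascular Doppler imaging. Provides
    transmit-sequence design (synthetic aperture, Hadamard-encoded synthetic
    aperture, single-array and orthogonal plane waves), digital phantoms with
    pulsatile flow and stimulus-driven blood-volume dynamics, a linear
    time-of-flight radio-frequency simulator, 3D delay-and-sum beamforming
    with coherent compounding and XDoppler correlation, SVD clutter filtering
    and power/signed/spectral Doppler, Kasai tissue pulse-wave extraction with
    ECG synchronisation, vesselness-based rigid registration of repeated
    volumes, hemodynamic response fitting with gamma-difference kernels, and
    point-spread-function image-quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    generics,
    tibble,
    jsonlite,
    yaml,
    signal,
    minpack.lm,
    RNifti,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
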