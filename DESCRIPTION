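Package: contactdose
Title: Contact-Current Dosimetry on Voxel Body Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Electro-quasi-static dosimetry for electric contact currents
    (DC to 1 MHz) on labeled voxel body phantoms. Provides a parametric
    synthetic body phantom with a closed skin envelope, heart shell and
    blood-vessel channels, a frequency-dependent tissue dielectric table
    (Cole-Cole dispersion), the two-body-model contact framework (skin-slice
    impedance layer, regime classification by frequency and touch voltage,
    skin-property fitting against reference impedance curves), a complex
    finite-volume solver for the voltage-driven conduction problem, and
    dose post-processing: total body current, body impedance, the 99th
    percentile myocardial field, orthogonal trans-cardiac line integrals,
    and heart-current-factor tables over the 16 standard current paths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
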