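Package: luquant
Title: Quantitative SPECT/CT Commissioning and Dosimetry QA for Lu-177 Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of the physics-QA chain used to
    qualify a SPECT/CT system for Lu-177 radiopharmaceutical-therapy dosimetry:
    dose-calibrator constancy and linearity checks against decay-corrected
    activity, digital NEMA-style and uniform-cylinder phantoms, a triple-energy-
    window SPECT acquisition simulator with attenuation, resolution blur,
    scatter and Poisson noise, TEW scatter correction with MLEM/OSEM
    attenuation-corrected reconstruction, volume-sensitivity calibration
    (cps/MBq), NEMA sphere activity recovery with partial-volume margins,
    point-source hybrid-registration QA with centre-of-rotation analysis, and
    single-time-point local-deposition voxel dose maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
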