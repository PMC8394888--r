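Package: uvskin
Title: Quantitative Optical Assessment of UV-Induced Skin Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for assessing acute and chronic ultraviolet
    (UV) skin damage in a murine model. Implements fluorescence tissue-content
    indices (eta = If/(If+Ibs)) for collagen and porphyrins from laser
    fluorescence spectra, stepwise minimal-erythema-dose (MED) irradiation
    scheduling and dosimetry, linear-regression estimation of the collagen
    degradation rate with a slope-ratio criterion separating photoaging from
    chronoaging, CIELAB relative erythema index (delta a*) colorimetry of RGB
    dorsum photographs with white-phantom balance correction, and Masson's
    trichrome collagen morphometry by colour-threshold filtering. Ships
    synthetic-data generators (spectra, longitudinal cohorts with withdrawal
    and mortality, dorsum and trichrome image phantoms) with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
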