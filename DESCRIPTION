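Package: svdose
Title: Small-Volume-of-Interest Kidney Dosimetry for Lu-177 SPECT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital-phantom evaluation of small-volume-of-interest (SV) kidney
    dosimetry for Lu-177-DOTATATE SPECT/CT. Generates synthetic kidney
    parenchyma phantoms with mono-exponential washout, emulates reconstructed
    SPECT images with a Gaussian point-spread function, Poisson count noise and
    Gaussian post-filtering, computes recovery coefficients and their
    volume-response curve, estimates absorbed doses with the whole-kidney
    parenchyma (WKP) reference method and with spherical SV sampling, calibrates
    normalization factors for the SV methods, and summarises method agreement
    with bias, accuracy, Pearson correlation and Bland-Altman limits of
    agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
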