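Package: socspec
Title: Soil Organic Carbon Calibration from Vis-NIR Spectral Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometric workflow for predicting soil organic carbon (SOC)
    from visible and near-infrared (Vis-NIR) diffuse reflectance spectra of
    soil samples, at the scale of a continental spectral library. Provides a
    synthetic spectral-library generator with known property-to-spectrum
    structure; the full spectral pre-treatment chain (scan averaging with
    quality control, absorbance conversion, detector-splice correction,
    Savitzky-Golay smoothing and differentiation, standard normal variate,
    band decimation, continuum removal); Kennard-Stone maximin selection of
    calibration samples in normalized principal-component score space; partial
    least squares calibration implemented from first principles with
    repeated half-split cross-validation, one-standard-error model selection,
    recursive feature elimination and auxiliary-predictor fusion; and the
    standard suite of validation statistics (bias, SEP, RMSEP, RPD, R2, SEL).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Matrix,
    signal,
    yaml,
    data.table,
    withr
Suggests:
    testthat (>= 3.0.0),
    ranger,
    jsonlite
Config/testthat/edition: 3
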