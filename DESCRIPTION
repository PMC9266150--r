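Package: nirsize
Title: Fruit-Size Correction of NIR Transmission Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Corrects near-infrared transmission spectra of fruit for
    differences in fruit diameter by estimating an average per-wavelength
    extinction coefficient against a reference size group (Beer-Lambert
    attenuation) and transforming every spectrum to a common reference
    diameter. Includes a complete chemometrics pipeline around the
    correction: wide-CSV spectra I/O, wavelength restriction, SNV, MSC and
    Savitzky-Golay pretreatments, Kennard-Stone calibration/prediction
    splitting, NIPALS partial least squares regression with latent-variable
    selection, evaluation metrics, and a synthetic cohort generator that
    provides ground truth for testing soluble solids content models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'nirsize-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'kennard-stone.R'
    'spectra-ops.R'
    'preprocess.R'
    'pls.R'
    'size-correction.R'
    'pipeline.R'
    'spectra-io.R'
    'synthetic.R'
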