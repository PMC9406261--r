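Package: eosinQuant
Title: Quantification of Intravascular Blood in H&E Sections from Eosin
    Fluorescence Red-Shift
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and quantifies erythrocytes in eosin-stained
    histology sections from the red-shift of eosin Y fluorescence.
    Provides lambda-stack spectral analysis (per-pixel peak emission
    wavelength maps, red-shift classification), Huang fuzzy-entropy
    automatic thresholding, and a two-channel (FITC/TRITC) arithmetic
    pipeline reporting the blood-to-tissue area percentage, together
    with a seeded synthetic phantom generator with known ground truth
    for end-to-end validation, TIFF/CSV input and output, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
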