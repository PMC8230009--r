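Package: xgalvox
Title: Quantification of lacZ Reporter Activity in Micro-CT Volumes of
    X-gal-Stained Brains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify beta-galactosidase (lacZ) reporter gene
    activity from laboratory micro-CT scans of X-gal-stained,
    paraffin-embedded mouse brains. Provides TIFF stack volume input and
    output with geometry metadata, two-point Hounsfield-unit calibration
    against water and air references, Otsu-based paraffin exclusion,
    per-region grayscale statistics, wild-type background correction,
    standard-deviation-graded relative expression classification,
    line-profile densitometry across tissue layers, a synthetic phantom
    generator with ground truth for validation, and a reproducible
    pipeline front-end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
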