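Package: telophen
Title: Quantitative Phenotyping Pipeline for Telomere Dysfunction Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative machinery for phenotyping telomere dysfunction in
    progeria models: telomere dysfunction-induced focus (TIF) calling by
    per-section two-channel colocalization in 3D fluorescence stacks, nuclear
    circularity morphometry from the lamin A/C channel, delta-delta-Ct
    relative quantification of telomeric noncoding RNAs, composite
    semiquantitative histopathology damage scoring with automated nuclear IHC
    positivity, and the accompanying group-comparison and Kaplan-Meier
    survival statistics. Includes seeded synthetic-data generators with
    machine-readable ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    survival,
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
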