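Package: tagquant
Title: Quantitative Comparison of Anti-Tag Antibodies by Dual-Channel Immunofluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the relative efficiency with which anti-epitope-tag
    antibodies detect a tagged membrane protein in dual-channel
    immunofluorescence images. Anti-tag signal is regressed against a
    co-stained reference-antibody signal over sampled high-signal image
    regions; slopes are normalized to a reference antibody (set to 100),
    aggregated across independent experiments (mean plus or minus SEM),
    tested for specificity against an irrelevant-antibody control, and
    classified as good, fair, mediocre or nonspecific. Includes a synthetic
    two-channel image generator with Langmuir antibody-binding kinetics and
    known ground-truth efficiency for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
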