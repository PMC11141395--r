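Package: bitecount
Title: Rule-Based Bite Counting from Facial Landmark Video Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic counting of bites in meal video recordings from a
    468-point 3D face-mesh landmark stream. Computes a per-frame mouth
    ratio (lip separation over mouth width, mesh key points 0, 17, 61 and
    291), smooths it with a trailing moving average, removes per-participant
    outliers, and counts bites as maximal runs of frames exceeding a
    per-participant threshold. The threshold is tuned against manually
    annotated bite counts by grid, random or Bayesian search with
    cross-validation, and transferred to unannotated participants by
    leave-one-out averaging. Includes the pooled-count accuracy metric and
    report tables used in intake-monitoring evaluation, plus a synthetic
    generator of landmark series, mouth-ratio traces and whole annotated
    cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
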