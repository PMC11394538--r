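Package: herdtrack
Title: Multi-Object Tracking and Evaluation for Group-Housed Livestock Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracking-by-detection for fixed-count animal pens: a Deep
    SORT-style multi-object tracker with appearance cascade matching,
    Kalman motion prediction and Mahalanobis gating, extended with a
    secondary relaxed-IOU association pass and a dynamic "extreme ID"
    track-admission gate that exploits the closed-pen constraint of a
    fixed herd size.  Includes CLEAR-MOT/identity evaluation (MOTA, MOTP
    in its IoU form, IDF1, identity switches), readers and writers for
    MOT-16 detection/ground-truth/result files with appearance-feature
    sidecars, DarkLabel annotation conversion, Market-1501-style
    re-identification crop export, and a seeded synthetic herd simulator
    for desk-scale benchmarking of occlusion-heavy pen scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
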