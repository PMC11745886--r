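Package: tendonsfa
Title: Spatial Frequency Analysis of Tendon Ultrasound Speckle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of longitudinal B-mode ultrasound images of
    the Achilles tendon. Implements kernel-wise spatial frequency analysis
    (SFA) of the speckle pattern yielding the peak spatial frequency radius
    (PSFR), an index of collagen fiber bundle organization; tendon thickness
    measurement from traced borders at the calcaneal insertion and at
    mid-tendon sites; intra-rater reliability statistics (intraclass
    correlation and standard error of measurement); and group-comparison
    statistics including one-way ANOVA from raw data or published summary
    statistics, eta-squared effect sizes with noncentral-F confidence
    intervals, and exact noncentral-t sample-size calculations. A synthetic
    speckle-phantom generator with known band spacing, organization level and
    border geometry provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    tiff,
    pracma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
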