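Package: evidemr
Title: Multicriteria Decision Analysis and Test-Retest Reliability for
    Health Technology Assessment Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the EVIDEM healthcare decision framework: a
    multicriteria decision analysis (MCDA) linear additive value model over
    panelist weights and scores, the qualitative Extrinsic Value Tool, a
    Quality Matrix evidence layer, and a test-retest reliability suite with
    Shrout-Fleiss intraclass correlation coefficients ICC(1,1) and ICC(3,1),
    ordinal agreement proportions and a systematic-error outlier rule. A
    synthetic-panel simulator generates weight/score matrices with
    controllable dispersion and retest perturbation so every statistic is
    testable without external data. Ships the 15-component, 4-cluster value
    framework with 6 extrinsic components and an illustrative growth-hormone
    for Turner-syndrome evidence bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
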