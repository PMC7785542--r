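Package: brscore
Title: Quantitative Benefit-Risk Scoring for Regulatory Product Approvals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scoring engine that codifies a medical product's benefits, risks and
    risk mitigations into categorical scales and computes a Gross Benefit Score,
    per-risk Risk and Risk Mitigation Scores, a Residual Risk Score, a Net-Benefit
    Score and a Benefit-Risk Ratio, with interpretation bands. Includes portfolio
    aggregation into division-level summary tables, an indication/division scatter
    view, milestone trajectories, structured benefit-risk reports, a configuration
    calibration search against the approvability constraint (positive net benefit
    for approved products), a seeded synthetic-portfolio generator, JSON/CSV
    profile I/O and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
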