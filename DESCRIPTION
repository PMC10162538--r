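Package: agritrain
Title: Gender-Aware Planning of Agricultural Extension Training Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning village-level agricultural extension training
    events when both total turnout and female participation matter. Fits
    gender-specific overdispersed (quasi-Poisson) count models of event
    attendance, selects model inputs by grouped penalized regression (group
    Lasso, group MCP, group SCAD) with cross-validated regularization,
    attaches bootstrap percentile confidence intervals to predictions over
    the discrete grid of feasible event configurations, and simulates
    top-list mixing policies that trade off total attendance against female
    participation. Includes a calibrated synthetic event-record generator
    with known ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
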