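Package: csrdesign
Title: Combination Stopping Rules for Two-Stage Phase II Oncology Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of single-arm two-stage phase II oncology
    trials whose decision rules combine response rate (RR) with Kaplan-Meier
    median time to progression (TTP). The Combination Stopping Rule (CSR)
    rejects inactivity at stage II if either the cumulative response count or
    the estimated median TTP reaches its threshold, and stops early for
    futility at stage I when responses are few and early progressive disease
    (EPD) -- progression at the first post-baseline tumour measurement,
    linked to median TTP through an exponential progression model -- is
    common. Thresholds are derived by Monte-Carlo search over a grid of
    candidate rules under user-specified null and alternative hypotheses and
    error limits. Exact-binomial Simon optimal and Fleming two-stage designs
    are provided for comparison, along with a command-line interface and
    reproducible, seeded simulation throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
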