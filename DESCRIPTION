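Package: equitrial
Title: Sex/Gender Representation and Reporting in Cardiovascular Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the representation of women/females in
    cardiovascular clinical trial publications. Computes per-trial
    participation-prevalence ratios (PPR) against region- and year-specific
    disease prevalence shares, scores sex/gender-sensitive reporting (SGR)
    of article sections with a deterministic whole-word keyword scanner,
    designates author sex/gender by a pluggable name lookup, and links
    authorship, participation and reporting with trend, rank, chi-square and
    logistic-regression statistics. Ships a seeded synthetic-corpus generator
    with the statistical structure the analysis assumes, so the whole
    pipeline is testable without access to the underlying literature corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
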