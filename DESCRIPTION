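Package: edcrowd
Title: Queue-Based Analysis of Emergency Department Crowding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Describe and analyse emergency department (ED) crowding from
    patient-level arrival and departure timestamps. Builds a 30-minute
    interval aggregate, runs the queue-length recursion
    Q(t+1) = Q(t) + A(t) - D(t) with an independent census cross-check,
    extracts per-shift maximum queue lengths with burn-in, computes
    empirical-CDF capacity-exceedance risks and patient-to-nurse ratios
    from a duty roster, tests carry-over rank correlations between
    successive shifts, applies Fisher's index of dispersion to the
    Poisson assumption on arrival counts, and generates seeded synthetic
    ED visit records (non-homogeneous, optionally over-dispersed arrival
    process; log-normal length of stay; ordered in-visit surrogate
    timestamps; field-level missingness) so every stage of the pipeline
    is testable without hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
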