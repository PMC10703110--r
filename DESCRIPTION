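Package: emsrank
Title: Ranking Emergency-Care Server Location Configurations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to enumerate all allocations of emergency-service vehicles
    (basic and dedicated advanced units) to geographic zones, evaluate each
    allocation with an aggregated hypercube spatial queuing model under two
    call priorities (loss or finite priority-queue operation), and rank the
    allocations with a constrained output-oriented variable-returns DEA
    benefit-of-the-doubt composite index sharpened by an inverted frontier.
    Includes a discrete-event simulator used to validate the analytic queuing
    results, Spearman-based post-ranking pattern analysis, transcriptions of
    two published Brazilian mobile emergency service (SAMU) case systems, and
    a synthetic-system generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    boot,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
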