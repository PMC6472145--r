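Package: margex
Title: Mining Marginal-Significance Reporting from Scientific Article Text
Version: 0.1.0
Authors@R:
    person("Margex", "Developers", email = "margex@example.org", role = c("aut", "cre"))
Description: Extracts reported p-values from plain-text scientific articles
    with a configurable regular-expression grammar, applies a metadata and
    range filter cascade, classifies p-values in (.05, .10] as reported as
    marginally significant via a 200-character context-window stem search
    ("margin*", "approach*"), and summarises the practice per journal,
    discipline and year with binomial confidence intervals and least-squares
    trend slopes. Ships a synthetic-corpus generator with per-mention ground
    truth so every pipeline stage can be validated end to end without access
    to a real article corpus.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
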