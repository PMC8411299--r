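Package: egsnet
Title: Interhospital Transfer Network Analysis for Emergency General Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted directed interhospital transfer networks from
    encounter-level administrative claims, links temporally adjacent encounters
    into episodes of care, computes degree-centrality measures and the
    centrality ratio (incoming transfers per outgoing transfer) per hospital,
    derives risk-adjusted in-hospital mortality and failure to rescue by
    indirect standardization, and tests associations between centrality ratio
    and hospital characteristics with one-way ANOVA, Tukey post hoc contrasts,
    and multivariable regression with state-clustered robust errors. Includes
    a seeded synthetic claims generator with recorded ground truth for
    validation of the full pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    sandwich,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
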