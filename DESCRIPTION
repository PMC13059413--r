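Package: leadmap
Title: Mapping Informal Leadership from Advice-Seeking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies informal leaders in clinical teams from roster-based
    advice-seeking surveys. Builds the directed advice network, computes four
    centrality metrics used as proxies for transformational, relational,
    adaptive and resilient leadership styles, derives style importance weights
    from preceptor reciprocal-rank ratings, and combines them into a
    Leadership-as-Done (LAD) composite score. Self-perception Likert items
    yield a matching Leadership-as-Imagined (LAI) score. Actors are classified
    into four quadrants (established, humble, aspirational, latent) using
    sample-mean cut-offs, with a full-network versus residents-only boundary
    sensitivity analysis. Includes a synthetic sociometric cohort generator
    with planted leadership archetypes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
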