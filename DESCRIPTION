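Package: netflux
Title: Integrative Topological and Functional Analysis of Gene
    Co-Expression and Metabolic Networks
Version: 0.1.0
Authors@R:
    person("netflux", "developers", email = "netflux@example.org",
           role = c("aut", "cre"))
Description: Reconstructs gene co-expression networks from expression
    compendia by bootstrapped mutual-information scoring (CLR-style
    per-gene background Z-scores), computes degree, eigenvector,
    betweenness and harmonic-closeness centralities on the resulting
    (generally disconnected) graphs, estimates condition-specific
    metabolic flux distributions from expression by weighted flux
    minimization, simulates exhaustive single-gene knockouts with a
    linearized minimization-of-metabolic-adjustment objective, classifies
    genes into functional-importance tiers, and cross-classifies
    topological against functional importance with Fisher enrichment and
    Monte Carlo randomization statistics. Includes synthetic-data
    generators for expression compendia with planted co-expression
    modules and small metabolic models with known knockout phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    xml2
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
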