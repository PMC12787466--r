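Package: pcnet
Title: Partial-Correlation Network Analysis of Mixed-Type Health Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates Gaussian graphical (partial-correlation) networks over
    mixed sociodemographic, nutritional, metabolic and psychological variables,
    prunes edges by a p-value screen, and characterises the resulting weighted
    signed graph with Gephi-convention node statistics (closeness, harmonic
    closeness, betweenness, eigenvector, HITS authority/hub, local clustering)
    and Louvain community detection.  Ships a seeded latent-Gaussian copula
    generator for synthetic high-weight young-adult cohorts so the whole
    pipeline runs without access to restricted participant data, plus
    deterministic clinical derivations (HOMA-IR, BMI classification) and
    CSV/GEXF/GraphML/JSON exporters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
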