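Package: soilrisk
Title: Contamination Indices and Probabilistic Health Risk Assessment for
    Heavy Metals in Soil
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing heavy metal(loid) contamination of soils and
    the associated human health risks. Computes the standard geochemical
    pollution indices (enrichment factor, geo-accumulation index,
    contamination factor, pollution load index) against shale or crustal
    background values, deterministic USEPA-style exposure-dose and risk
    estimates (hazard quotients and indices, cancer risks) for child and
    adult receptors over the ingestion, inhalation and dermal pathways,
    Monte Carlo uncertainty propagation with percentile and exceedance
    summaries and convergence diagnostics, variance-based global
    sensitivity analysis (Sobol indices via Saltelli designs), and
    multivariate source apportionment (Ward hierarchical clustering and
    varimax-rotated principal component analysis). Includes a synthetic
    point-source site generator and packaged summary statistics for a
    smelter-impacted agricultural site so the full pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
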