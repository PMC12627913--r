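Package: ednacomp
Title: Community Comparison and Mapping for Geolocated eDNA Metabarcoding Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ingests geolocated environmental-DNA (eDNA) metabarcoding feature
    tables (a two-sheet Read/Location workbook or its CSV dialect), applies
    standard table-cleaning rules (per-sample low-count removal, negative-control
    exclusion, taxon-list exclusion, prevalence filtering), and compares
    community composition between sampling points: Jaccard and Bray-Curtis
    dissimilarities, nonmetric multidimensional scaling with Kruskal stress-1
    and pool-adjacent-violators monotone regression, one-way PERMANOVA with
    exact or sampled permutation p-values, agglomerative hierarchical
    clustering, analytic rarefaction, biogeographic-boundary hypothesis tests,
    species search and list matching, depth and batch diagnostics, GeoJSON map
    layers, and an ordered multi-section HTML report. A seeded synthetic-data
    generator with known regional, batch, and depth structure makes every
    analysis stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    readxl,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    withr
Config/testthat/edition: 3
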