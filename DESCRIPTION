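Package: rhizovec
Title: Vectorized Root System Architecture for Rhizotron Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with vectorized root systems traced from
    rhizotron-grown plants. Reads and writes Root System Markup Language
    (RSML), merges registered partial tracings from split-and-combine
    scanning into a single root system, computes architectural traits
    (length, surface and volume by root order, distal cumulative measures,
    depth profiles, diameter statistics with compact letter displays,
    orientation profiles, Fitter topological indices), and crosses root
    architecture with raster soil water content maps through nearest-segment
    distance maps and distance-binned time series. Includes seeded
    generators for maize-like synthetic root systems and water depletion
    map series so that every stage of the pipeline can be exercised without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    png,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
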