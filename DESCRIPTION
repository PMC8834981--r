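Package: agewalk
Title: Network-Based Walkability and Potential Accessibility for Older Adults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the potential accessibility of a neighbourhood for older-adult
    pedestrians. Builds a pedestrian network graph from line features, computes
    multi-source shortest-path distance fields to benches and to categorized
    services and facilities (service areas), derives percent slope from a digital
    terrain model, reclassifies every variable onto a common five-level ordinal
    scale, and combines the layers with profile-specific weights (healthy, chronic
    disease, reduced mobility) into a weighted-linear-combination accessibility
    surface on a 5 m analysis grid, with per-level area summaries. Includes a
    synthetic neighbourhood generator (street network, bench and facility
    inventories, terrain) so the full pipeline runs without external data, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
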