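Package: osteonet
Title: Topology of Osteogenic Protein-Protein Interaction Networks and
    Colony Morphometry for Stromal-Cell Differentiation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse scored protein-protein interaction (PPI)
    networks of the kind exported by the STRING database (confidence
    filtering, reduction to a connected seed-anchored core, per-node and
    global topological indices computed from first principles, and
    hub/bottleneck/backbone/upstream-signal role classification), together
    with colony-level morphometry for stromal-cell differentiation assays
    (segmentation of culture images, colony area and isoperimetric
    circularity, sparse/dense classification, colony-forming efficiency,
    grid-field proportions, ordinal staining scores) and the matching
    inferential layer (one-way ANOVA, Student-Newman-Keuls post hoc,
    chi-squared tests of proportions, noncentral-F sample-size helper).
    Seeded synthetic-data generators produce scored graphs with planted
    hubs and bottlenecks and culture images with known colony ground
    truth, so every analysis stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
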