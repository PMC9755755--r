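Package: edgetic
Title: Multi-Scale Analysis of Somatic Variants at Protein Interaction
    Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps somatic missense variants onto structure-derived
    protein interaction interfaces, extracts functional interactions and a
    reaction network from a Reactome-style knowledgebase, tests interfaces,
    reactions and pathways for mutation enrichment against a within-protein
    substitution-shuffling background model (binomial test with
    Benjamini-Hochberg correction), and screens perturbed units for
    association with overall survival using Cox proportional hazards.
    Includes a fully seeded synthetic-data generator so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    survival,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
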