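Package: bioexplore
Title: Taxonomy-Driven Exploration of Biodiversity Data for Bioinspired Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline toolkit for taxonomy-driven exploration of biodiversity
    data in support of bioinspired design. Loads a GBIF-style taxonomic
    backbone and serves ranked name suggestions for scientific and vernacular
    queries, extracts lineages and maintains a merged taxonomy tree with
    DOT/JSON/Newick export; summarises a taxon's climatic niche by overlaying
    hexagonal occurrence zones on monthly climate rasters; and ranks
    semantically related taxa, biological processes, habitats and measurements
    with a min-of-cosines compatibility score over entity-phrased skip-gram
    word embeddings. Includes seeded generators for synthetic backbones,
    occurrence points, climate rasters and corpora with planted entity
    co-occurrence, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
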