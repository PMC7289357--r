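Package: goslicer
Title: Keyword-Driven Extraction of Concept Subgraphs from the Gene Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds custom GO-slim-like category subgraphs from the Gene
    Ontology using user-supplied keywords or seed terms, with scope-aware
    traversal of mereological relations (is_a, part_of, and a reinterpreted
    has_part that is inverted into a part-of-some reading to keep the graph
    acyclic and congruent in semantic scope).  Parses OBO 1.2 flat files into
    a directed acyclic graph with lazily cached ancestor and descendant
    closures, elects a representative root term per category, maps
    fine-grained gene annotations in GAF 2.x files onto category roots with
    superset suppression, and compares category subgraphs and annotation
    sources via inclusion and Jaccard indices and a five-way per-gene
    agreement classification.  Includes a synthetic ontology and annotation
    generator with known ground truth for validation, a parser for the
    UniProt subcellular-location controlled vocabulary, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
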