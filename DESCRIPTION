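Package: corpuscle
Title: Tools for Cell-Population Literature Annotation Corpora
Version: 0.1.0
Authors@R:
    person("Corpuscle", "Developers", email = "corpuscle@example.org",
           role = c("aut", "cre"))
Description: A toolkit for building and evaluating annotated corpora of cell
    population mentions in the biomedical literature. Provides a data model for
    span-annotated passages with qualified ontology links (BioC XML I/O),
    directed-acyclic ontology handling with depth and ancestor queries, designed
    corpus sampling by greedy Kullback-Leibler divergence minimization,
    hill-climbing train/validation/test splitting, span-level inter-annotator
    agreement in several strictness regimes, named-entity-recognition and
    entity-linking evaluation harnesses (including top-k recall and
    novelty-detection ROC analysis), ontology coverage statistics, and analysis
    of compositional naming motifs with exact binomial and Fisher tests under
    Benjamini-Hochberg false-discovery-rate control. Ships a synthetic-data
    generator producing corpora, toy ontologies, dual-annotator variants and
    linker confidence scores with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
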