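Package: gorank
Title: Literature-Driven Retrieval and Reranking for Gene Ontology Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-stage information-retrieval pipeline for automated protein
    function annotation with the Gene Ontology (GO). Stage one retrieves
    candidate GO terms from annotated proteins whose UniProt-style textual
    descriptions (recommended name and species) are similar to the target
    protein under Okapi BM25, and scores them by a weighted nearest-neighbour
    vote; the same vote kernel supports BLAST bit-score and protein-network
    neighbour weights. Stage two reranks the candidates by semantic matching
    between a query built from the protein name plus informative literature
    sentences and each candidate term's GO definition, through a pluggable
    pair-scorer contract with a deterministic lexical backend and a trainable
    bag-of-words logistic backend. Includes OBO parsing with true-path
    propagation and information content, GAF and BLAST tabular readers,
    CAFA-style weighted-Fmax evaluation, a synthetic fixture generator with
    planted text-to-term signal, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
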