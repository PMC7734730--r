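Package: litkg
Title: Ontology-Linked Knowledge Graphs from Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ontology-linked RDF knowledge graphs from unstructured
    biomedical text through a semi-automatic, rule-based pipeline: sentence
    splitting, pronoun coreference substitution, Schwartz-Hearst abbreviation
    detection and expansion, constituency-parse sentence simplification,
    reified triple extraction from semantic role labeling frames with
    PropBank/VerbNet-style rolesets, secondary triple extraction from
    dependency parses (modifier subclass chains and prepositional
    modification), UMLS concept linking with mapping to a target ontology's
    CUI-annotated classes, and RDF graph assembly with Turtle and DOT output.
    Linguistic analyses are consumed through a pluggable provider contract
    with a deterministic replay-fixture backend, so every stage runs offline
    and byte-reproducibly. Includes triple-set comparison utilities (set
    differences and the Jaccard similarity coefficient) for evaluating
    extracted triples against manually curated sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
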