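Package: semdisc
Title: Semantic Annotation and Discovery of Biosimulation Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Encodes composite biological annotations (biophysical property,
    chemical species, anatomical locations, protein mediator) on variables of
    CellML models, indexes them as RDF triples in an in-memory store with
    basic-graph-pattern querying, discovers model entities from free-text
    queries via dictionary-based ontology-term mapping with ranked results,
    and recommends similar models from shared anatomical location plus
    protein percent-identity. Includes a deterministic synthetic-corpus
    generator emulating a cohort of annotated epithelial-transport models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
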