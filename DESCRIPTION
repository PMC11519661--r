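Package: phenoscribe
Title: Ontology-Anchored Semantic Species Descriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolchain for ontology-anchored (entity-quality) phenotype
    descriptions of taxa. Parses a Phenoscript-style domain-specific language
    into ordered semantic statements, resolves terms against a seeded ontology
    registry with identifier minting, compiles descriptions into typed RDF
    instance graphs (Turtle, N-Triples, TriG), renders deterministic
    natural-language clause text, computes statement-level diagnoses between
    species, evaluates dichotomous identification keys, ingests Darwin Core
    occurrence records, and assembles nanopublications for taxon names and
    habitat associations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
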