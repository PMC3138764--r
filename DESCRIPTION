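Package: ontoreason
Title: Relation Expansion and Description-Logic Reasoning over OBO Ontologies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts OBO Flatfile ontologies and their cross-product
    (logical) definitions into description-logic axioms using
    single-argument relation-expansion templates, aligns them to a minimal
    four-class upper-level ontology (Material object, Process, Quality,
    Function) with axiomatized relations, detects unsatisfiable classes
    with a built-in tableau reasoner supporting role hierarchies, inverse,
    transitive and functional roles, repairs ambiguous relation use via
    disjunctive disambiguation templates, and answers expressive
    cross-ontology class-expression queries.  Includes worked-example
    fixtures for the classic contradiction patterns (local disjointness
    clashes, global cross-ontology clashes, homonymy, improper relation
    use) and a seeded generator of random ontologies with planted,
    ground-truth contradictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
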