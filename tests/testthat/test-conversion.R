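test_that("the upper ontology declares the printed relation axioms", {
  o <- build_upper_ontology()
  u <- upper_classes()
  # one 4-way disjointness axiom, six pairwise after normalization
  disj <- Filter(function(a) a$type == "disjoint", o$axioms)
  expect_length(disj, 1L)
  expect_length(disj[[1L]]$members, 4L)
  n <- normalize_axioms(o)
  bottoms <- Filter(function(a) ce_equal(a$sup, ce_bottom()), n$axioms)
  expect_length(bottoms, 6L)
  # a quality can inhere in at most one thing
  expect_true(o$roles$inheres_in$functional)
  # the range of inheres-in is Thing: no range restriction is declared
  expect_null(o$roles$inheres_in$range)
  expect_true(ce_equal(o$roles$inheres_in$domain, ce_named(u[["quality"]])))
  expect_true(o$roles$part_of$transitive)
  expect_true(o$roles$part_of$reflexive)
  expect_identical(o$roles$part_of$inverse, "has_part")
  expect_identical(o$roles$proper_part_of$super_roles, "part_of")
  # Table-style domain/range entries
  expect_true(ce_equal(o$roles$has_participant$domain,
                       ce_named(u[["process"]])))
  expect_true(ce_equal(o$roles$has_participant$range,
                       ce_named(u[["material"]])))
  expect_true(ce_equal(o$roles$realized_by$domain, ce_named(u[["func"]])))
})

test_that("templates expand a single placeholder argument", {
  tpl <- default_templates()
  expect_true(ce_equal(expand_template(tpl$part_of, ce_named("Cell")),
                       parse_class_expression("part_of some Cell")))
  expect_true(ce_equal(
    expand_template(tpl$inheres_in_part_of, ce_named("Liver")),
    parse_class_expression("inheres_in some (part_of some Liver)")))
  expect_true(ce_equal(
    expand_template(tpl$capable_of, ce_named("P")),
    parse_class_expression("has_function some (realized_by only P)")))
  expect_error(relation_template("bad", "part_of some X"), "exactly once")
  expect_error(relation_template("bad", "?Y and part_of some ?Y"),
               "exactly once")
})

test_that("conversion expands relationship and intersection_of as specified", {
  doc <- obo_document(terms = list(
    obo_term("CL:Cell", "cell"),
    obo_term("GO:Nucleus", "nucleus", namespace = "cellular_component",
             relationship = list(c("part_of", "CL:Cell"))),
    obo_term("CL:Spore", "spore",
             intersection_of = list("CL:Fungal", "CL:Prok")),
    obo_term("CL:Fungal"), obo_term("CL:Prok"),
    obo_term("CL:Plain", "plain term")))
  o <- convert_obo(doc, conversion_config())
  keys <- vapply(o$axioms, format, "")
  expect_true("GO:Nucleus SubClassOf (part_of some CL:Cell)" %in% keys)
  expect_true("CL:Spore EquivalentTo (CL:Fungal and CL:Prok)" %in% keys)
  # a term with only id/name contributes no axiom beyond its root
  plain <- grep("CL:Plain", keys, value = TRUE)
  expect_identical(plain, "CL:Plain SubClassOf MaterialObject")
})

test_that("upper-root assignment follows prefixes and GO namespaces", {
  doc <- obo_document(terms = list(
    obo_term("PATO:0000001"),
    obo_term("GO:bp1", namespace = "biological_process"),
    obo_term("GO:cc1", namespace = "cellular_component"),
    obo_term("GO:mf1", namespace = "molecular_function"),
    obo_term("XX:nomatch")))
  keys_for <- function(mf_mode) {
    o <- convert_obo(doc, conversion_config(mf_mode = mf_mode))
    vapply(o$axioms, format, "")
  }
  kf <- keys_for("function")
  expect_true("PATO:0000001 SubClassOf Quality" %in% kf)
  expect_true("GO:bp1 SubClassOf Process" %in% kf)
  expect_true("GO:cc1 SubClassOf MaterialObject" %in% kf)
  expect_true("GO:mf1 SubClassOf Function" %in% kf)
  expect_false(any(grepl("^XX:nomatch SubClassOf", kf)))
  kp <- keys_for("process")
  expect_true("GO:mf1 SubClassOf Process" %in% kp)
  expect_error(assign_upper_roots(ontology(),
                                  c(A = "Quality", A = "Process")),
               "twice")
})

test_that("quality constraints add exactly two axioms, idempotently", {
  o <- build_upper_ontology()
  o <- add_class(o, c("PATO:PQ", "PATO:PhQ"))
  o1 <- add_quality_constraints(o, "PATO:PQ", "PATO:PhQ")
  expect_length(o1$axioms, length(o$axioms) + 2L)
  o2 <- add_quality_constraints(o1, "PATO:PQ", "PATO:PhQ")
  expect_length(o2$axioms, length(o1$axioms))
  expect_error(add_quality_constraints(o, "PATO:PQ", "PATO:Missing"),
               "not in signature")
})

test_that("relation spelling variants canonicalize to one role", {
  expect_identical(canonical_relation_id(c("has_part", "has-part",
                                           "has part", "Has Part")),
                   rep("has_part", 4L))
  doc1 <- obo_document(terms = list(
    obo_term("A:1", relationship = list(c("has_part", "A:2"))),
    obo_term("A:2")))
  doc2 <- obo_document(terms = list(
    obo_term("B:1", relationship = list(c("has-part", "B:2"))),
    obo_term("B:2")))
  o <- convert_obo(list(doc1, doc2), conversion_config())
  keys <- vapply(o$axioms, format, "")
  expect_true("A:1 SubClassOf (has_part some A:2)" %in% keys)
  expect_true("B:1 SubClassOf (has_part some B:2)" %in% keys)
})

test_that("results_in* relations stay primitive with domain Process", {
  doc <- obo_document(terms = list(
    obo_term("GO:X", namespace = "biological_process",
             relationship = list(c("results_in_release_of", "CHEBI:M"))),
    obo_term("CHEBI:M")))
  o <- convert_obo(doc, conversion_config())
  d <- o$roles$results_in_release_of
  expect_false(is.null(d))
  expect_true(ce_equal(d$domain, ce_named("Process")))
  keys <- vapply(o$axioms, format, "")
  expect_true("GO:X SubClassOf (results_in_release_of some CHEBI:M)" %in% keys)
})

test_that("strip_asserted_isa removes only is_a-derived axioms", {
  doc <- obo_document(terms = list(
    obo_term("A:1", is_a = "A:2",
             intersection_of = list("A:3", c("part_of", "A:2"))),
    obo_term("A:2"), obo_term("A:3")))
  keep <- convert_obo(doc, conversion_config())
  strip <- convert_obo(doc, conversion_config(strip_asserted_isa = TRUE))
  kk <- vapply(keep$axioms, format, "")
  ks <- vapply(strip$axioms, format, "")
  expect_true("A:1 SubClassOf A:2" %in% kk)
  expect_false("A:1 SubClassOf A:2" %in% ks)
  # the definition-derived equivalence survives
  expect_true(any(grepl("A:1 EquivalentTo", ks)))
  # only is_a provenance disappears
  expect_identical(setdiff(kk, ks), "A:1 SubClassOf A:2")
})

test_that("conversion is deterministic and provenance is total", {
  set.seed(17)
  doc <- random_obo_document()
  o1 <- convert_obo(doc, conversion_config())
  o2 <- convert_obo(doc, conversion_config())
  expect_identical(vapply(o1$axioms, format, ""),
                   vapply(o2$axioms, format, ""))
  expect_length(o1$provenance, length(o1$axioms))
  expect_false(any(is.na(o1$provenance) | o1$provenance == ""))
})

test_that("configuration round-trips through YAML", {
  cfg <- conversion_config(
    mf_mode = "process", strip_asserted_isa = TRUE,
    add_quality_constraints = TRUE,
    quality_roots = c(process = "PATO:PQ", physical = "PATO:PhQ"),
    disambiguate = "has_central_participant")
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_identical(cfg2$mf_mode, "process")
  expect_true(cfg2$strip_asserted_isa)
  expect_true(cfg2$add_quality_constraints)
  expect_identical(unname(cfg2$quality_roots[["process"]]), "PATO:PQ")
  expect_identical(cfg2$disambiguate, "has_central_participant")
})

test_that("OWL functional-syntax export emits every axiom", {
  b <- worked_example("spore")
  o <- convert_obo(b$document, b$config)
  lines <- write_owl_functional(o)
  expect_true(any(grepl("^Ontology\\(", lines)))
  expect_true(any(grepl("FunctionalObjectProperty\\(:inheres_in\\)", lines)))
  expect_true(any(grepl("DisjointClasses", lines)))
  n_axiom_lines <- sum(grepl("^(SubClassOf|EquivalentClasses|DisjointClasses)\\(",
                             lines))
  expect_identical(n_axiom_lines, length(o$axioms))
})
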