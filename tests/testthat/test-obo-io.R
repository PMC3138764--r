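spore_obo_text <- c(
  "format-version: 1.2",
  "",
  "[Term]",
  "id: CL:0000521",
  "name: fungal cell",
  "is_a: CL:0000255 ! eukaryotic cell",
  "",
  "[Term]",
  "id: GO:0042244",
  "name: spore wall assembly",
  "namespace: biological_process",
  "relationship: part_of GO:0070590 {source=\"curator\"}",
  "intersection_of: GO:0008150",
  "intersection_of: part_of GO:0070590",
  "",
  "[Typedef]",
  "id: part_of",
  "name: part of",
  "is_transitive: true")

test_that("parser maps stanzas to frames and preserves structure", {
  doc <- parse_obo(spore_obo_text)
  expect_length(doc$terms, 2L)
  expect_length(doc$typedefs, 1L)
  f <- doc$terms[["CL:0000521"]]
  expect_identical(f$is_a, "CL:0000255")   # trailing comment stripped
  g <- doc$terms[["GO:0042244"]]
  expect_identical(g$relationship[[1L]], c("part_of", "GO:0070590"))
  # a bare and a relational intersection_of entry
  expect_identical(g$intersection_of[[1L]], c(NA_character_, "GO:0008150"))
  expect_identical(g$intersection_of[[2L]], c("part_of", "GO:0070590"))
  expect_true(doc$typedefs$part_of$is_transitive)
  expect_identical(g$line, 8L)
})

test_that("parser reports malformed input and single-entry intersections", {
  expect_error(parse_obo(c("[Term", "id: X:1")), "malformed stanza")
  expect_error(parse_obo(c("[Term]", "no tag here")), "malformed tag")
  expect_error(parse_obo(c("[Term]", "id: X:1", "", "[Term]", "id: X:1")),
               "duplicate term")
  warn_doc <- parse_obo(c("[Term]", "id: X:1",
                          "intersection_of: Y:1"))
  expect_match(warn_doc$warnings, "single element")
})

test_that("write/parse round-trip is a structural identity", {
  doc <- parse_obo(spore_obo_text)
  doc2 <- parse_obo(write_obo(doc))
  # compare everything except recorded line numbers
  strip <- function(d) {
    d$terms <- lapply(d$terms, function(f) { f$line <- NULL; f })
    d$typedefs <- lapply(d$typedefs, function(f) { f$line <- NULL; f })
    d
  }
  expect_identical(strip(doc2), strip(doc))
  set.seed(31)
  for (i in 1:20) {
    d <- random_obo_document()
    d2 <- parse_obo(write_obo(d))
    expect_identical(strip(d2)$terms, strip(d)$terms)
  }
})

test_that("relation usage counts match a naive text-scan oracle", {
  set.seed(13)
  for (i in 1:10) {
    doc <- random_obo_document()
    text <- write_obo(doc)
    tab <- count_relation_usage(doc)
    for (rel in tab$relation) {
      n_rel <- sum(grepl(paste0("^relationship: ", rel, " "), text))
      n_def <- sum(grepl(paste0("^intersection_of: ", rel, " "), text))
      expect_identical(tab$n_relationship[tab$relation == rel], n_rel)
      expect_identical(tab$n_definition[tab$relation == rel], n_def)
    }
    # sorted by relationship count, invariant under stanza order
    expect_true(!is.unsorted(rev(tab$n_relationship)))
    shuffled <- doc
    shuffled$terms <- rev(doc$terms)
    expect_identical(count_relation_usage(shuffled), tab)
  }
  expect_identical(nrow(count_relation_usage(obo_document())), 0L)
})

test_that("defined-term count excludes obsolete and plain terms", {
  doc <- obo_document(terms = list(
    obo_term("X:1", intersection_of = list("X:2", c("part_of", "X:3"))),
    obo_term("X:2"),
    obo_term("X:3", intersection_of = list("X:1", "X:2"),
             is_obsolete = TRUE),
    obo_term("X:4", intersection_of = list("X:1", c("part_of", "X:2")))))
  expect_identical(count_defined_terms(doc), 2L)
  # planted ground truth on random documents
  set.seed(5)
  for (i in 1:10) {
    d <- random_obo_document()
    k <- sum(vapply(d$terms, function(f)
      !f$is_obsolete && length(f$intersection_of) > 0L, TRUE))
    expect_identical(count_defined_terms(d), as.integer(k))
    expect_lte(count_defined_terms(d), length(d$terms))
  }
})

test_that("dangling references are reported, never dropped", {
  doc <- obo_document(terms = list(
    obo_term("X:1", is_a = "X:404",
             relationship = list(c("part_of", "X:2")))))
  rep <- dangling_references(doc)
  expect_setequal(rep$id, c("X:404", "X:2"))
})
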