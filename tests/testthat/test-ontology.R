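test_that("normalize_axioms rewrites equivalence and disjointness", {
  A <- ce_named("A"); B <- ce_named("B")
  o <- ontology()
  o <- add_axiom(o, ax_equivalent(A, B), "src")
  n <- normalize_axioms(o)
  expect_length(n$axioms, 2L)
  expect_true(all(vapply(n$axioms, `[[`, "", "type") == "subclass"))
  expect_identical(unique(n$provenance), "src")

  o2 <- ontology()
  o2 <- add_axiom(o2, ax_disjoint(list(A, B)), "d")
  n2 <- normalize_axioms(o2)
  expect_length(n2$axioms, 1L)
  expect_true(ce_equal(n2$axioms[[1L]]$sup, ce_bottom()))
})

test_that("n-member disjointness yields choose(n, 2) pairwise axioms", {
  # independent oracle: enumerate the pairs directly
  for (n in 2:5) {
    members <- lapply(paste0("M", seq_len(n)), ce_named)
    expected <- nrow(utils::combn(n, 2L) |> t())
    o <- ontology()
    o <- add_axiom(o, ax_disjoint(members), "d")
    expect_length(normalize_axioms(o)$axioms, expected)
  }
})

test_that("super-role closure follows sub-role links and inverses", {
  o <- build_upper_ontology()
  cl <- super_roles_closure(o, "proper_part_of")
  expect_true(all(c("proper_part_of", "part_of") %in% cl))
  expect_identical(as.character(super_roles_closure(o, "derives_from")),
                   "derives_from")
  # closed under inverses: has_proper_part is below has_part because
  # proper_part_of is below part_of
  expect_true("has_part" %in% super_roles_closure(o, "has_proper_part"))
  # sub-roles of has_participant
  for (r in c("has_input", "has_output", "has_central_participant"))
    expect_true("has_participant" %in% super_roles_closure(o, r))
  expect_error(super_roles_closure(o, "no_such_role"), "unknown role")
})

test_that("cyclic sub-role declarations are closed and flagged equivalent", {
  o <- ontology()
  o <- add_role(o, role_declaration("r", super_roles = "s"))
  o <- add_role(o, role_declaration("s", super_roles = "r"))
  cr <- super_roles_closure(o, "r")
  cs <- super_roles_closure(o, "s")
  expect_setequal(as.character(cr), c("r", "s"))
  expect_setequal(as.character(cs), c("r", "s"))
  expect_identical(attr(cr, "equivalent_roles"), "s")
})

test_that("inverse declarations are kept symmetric", {
  o <- ontology()
  o <- add_role(o, role_declaration("part_of", inverse = "has_part"))
  expect_identical(o$roles$has_part$inverse, "part_of")
  expect_identical(o$roles$part_of$inverse, "has_part")
})
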