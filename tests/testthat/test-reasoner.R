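test_that("basic satisfiability verdicts", {
  o <- tiny_ontology()
  expect_false(is_satisfiable(o, ce_bottom()))
  expect_false(is_satisfiable(o, ce_and(ce_named("A"),
                                        ce_not(ce_named("A")))))
  expect_true(is_satisfiable(o, ce_named("A")))
  expect_true(is_satisfiable(o, "A and r some B"))
  # fresh names are unconstrained
  expect_true(is_satisfiable(o, ce_named("Z99")))
})

test_that("subsumption reduces to unsatisfiability of the difference", {
  o <- tiny_ontology()
  expect_true(subsumes(o, "C", "A"))
  expect_false(subsumes(o, "A", "C"))
  expect_true(subsumes(o, ce_top(), "A"))
  expect_true(subsumes(o, "r some C", "r some A"))
})

test_that("functional roles merge successors", {
  o <- ontology()
  o <- add_role(o, role_declaration("f", functional = TRUE))
  o <- add_axiom(o, ax_disjoint(list(ce_named("P"), ce_named("Q"))), "d")
  expect_false(is_satisfiable(o, "f some P and f some Q"))
  o2 <- ontology()
  o2 <- add_role(o2, role_declaration("g"))
  o2 <- add_axiom(o2, ax_disjoint(list(ce_named("P"), ce_named("Q"))), "d")
  expect_true(is_satisfiable(o2, "g some P and g some Q"))
})

test_that("transitive roles propagate universal restrictions", {
  o <- ontology()
  o <- add_role(o, role_declaration("t", transitive = TRUE))
  # x with only-t A and a t-chain of length 2: the far node gets A
  expect_false(is_satisfiable(o,
    "t only A and t some (t some (not A))"))
  o2 <- ontology()
  o2 <- add_role(o2, role_declaration("u"))
  expect_true(is_satisfiable(o2,
    "u only A and u some (u some (not A))"))
})

test_that("inverse roles propagate backwards", {
  o <- ontology()
  o <- add_role(o, role_declaration("p", inverse = "q"))
  expect_false(is_satisfiable(o, "A and p some (q only (not A))"))
})

test_that("blocking terminates cyclic existential chains", {
  o <- ontology()
  o <- add_role(o, role_declaration("r"))
  o <- add_axiom(o, ax_subclass(ce_named("A"), ce_some("r", ce_named("A"))),
                 "loop")
  expect_true(is_satisfiable(o, ce_named("A")))
  # with a transitive role too
  o2 <- ontology()
  o2 <- add_role(o2, role_declaration("r", transitive = TRUE))
  o2 <- add_axiom(o2, ax_subclass(ce_named("A"),
                                  ce_some("r", ce_named("A"))), "loop")
  expect_true(is_satisfiable(o2, "A and r only (A or B)"))
})

test_that("resource caps yield an explicit undecided verdict", {
  o <- ontology()
  o <- add_role(o, role_declaration("r"))
  o <- add_axiom(o, ax_subclass(ce_top(),
    ce_and(ce_some("r", ce_named("A")), ce_some("r", ce_named("B")))), "x")
  o <- add_axiom(o, ax_subclass(ce_named("A"), ce_some("r", ce_named("B"))),
                 "y")
  v <- is_satisfiable(o, ce_named("A"), max_nodes = 3)
  expect_true(is.na(v))
})

test_that("unsatisfiable classes on the spore fixture match the narrative", {
  b <- worked_example("spore")
  o <- convert_obo(b$document, b$config)
  u <- unsatisfiable_classes(o)
  expect_identical(as.character(u), b$expected$unsatisfiable)
  expect_length(attr(u, "undecided"), 0L)
  # the upper ontology alone has no clash
  expect_length(as.character(unsatisfiable_classes(build_upper_ontology())),
                0L)
})

test_that("classification groups equivalents and reduces to direct supers", {
  o <- tiny_ontology()
  o <- add_axiom(o, ax_equivalent(ce_named("B"), ce_named("B2")), "eq")
  idx <- classify(o)
  expect_true(all(idx$satisfiable[c("A", "B", "C")]))
  expect_setequal(idx$equivalents[["B"]], c("B", "B2"))
  expect_identical(idx$direct_super[["A"]], "B")
  expect_identical(idx$direct_super[["B"]], "C")
  # transitive closure of the index equals pairwise subsumes()
  M <- idx$subsumption
  for (i in rownames(M)) for (j in colnames(M))
    expect_identical(unname(M[i, j]),
                     isTRUE(subsumes(o, ce_named(j), ce_named(i))))
})

test_that("query_subclasses returns satisfiable subclasses only", {
  o <- tiny_ontology()
  o <- add_axiom(o, ax_subclass(ce_named("Dead"), ce_bottom()), "kill")
  ans <- query_subclasses(o, "C")
  expect_setequal(as.character(ans), c("A", "B", "C"))
  ans2 <- query_subclasses(o, "C", include_unsatisfiable = TRUE)
  expect_true("Dead" %in% ans2)
  expect_setequal(as.character(query_subclasses(o, ce_top())),
                  c("A", "B", "C"))
})

test_that("justifications are subset-minimal and reproduce the spore cause", {
  b <- worked_example("spore")
  o <- convert_obo(b$document, b$config)
  j <- justify(o, "CL:Spore")
  keys <- sort(vapply(j$axioms, format, ""))
  expect_identical(keys, sort(c(
    "CL:Spore EquivalentTo (CL:FungalCell and CL:ProkaryoticCell)",
    "CL:FungalCell SubClassOf CL:EukaryoticCell",
    "DisjointClasses(CL:EukaryoticCell, CL:ProkaryoticCell)")))
  # minimality: removing any member restores satisfiability
  all_keys <- vapply(o$axioms, format, "")
  member_idx <- match(vapply(j$axioms, format, ""), all_keys)
  for (drop in member_idx) {
    keep_idx <- setdiff(member_idx, drop)
    sub <- o
    sub$axioms <- o$axioms[keep_idx]
    sub$provenance <- o$provenance[keep_idx]
    expect_true(is_satisfiable(sub, ce_named("CL:Spore")))
  }
  # a direct bottom axiom justifies itself
  o2 <- ontology()
  o2 <- add_axiom(o2, ax_subclass(ce_named("X"), ce_bottom()), "only")
  j2 <- justify(o2, "X")
  expect_length(j2$axioms, 1L)
  expect_error(justify(o2, "Y"), "satisfiable")
})

test_that("tableau verdicts agree with finite-model search on random ontologies", {
  # a reduced sweep; the full 200-ontology sweep runs in the acceptance suite
  bad <- 0L
  for (s in 1:40) {
    rx <- random_alc_ontology(s)
    prep <- reasoner_prepare(rx$ontology)
    exprs <- c(lapply(sort(rx$ontology$classes), ce_named), list(rx$probe))
    for (e in exprs) {
      vt <- is_satisfiable(rx$ontology, e, prepared = prep)
      vo <- model_check_satisfiable(rx$ontology, e)
      if (is.na(vt) || vt != vo) bad <- bad + 1L
    }
  }
  expect_identical(bad, 0L)
})

test_that("adding axioms never shrinks the unsatisfiable set", {
  set.seed(23)
  for (i in 1:10) {
    b <- generate_planted(plant_spec(seed = 100L + i, n_classes = 16L,
                                     plants = c(disjoint_intersection = 1L,
                                                domain_violation = 1L)))
    o <- convert_obo(b$document, b$config)
    u1 <- as.character(unsatisfiable_classes(o))
    cls <- sample(setdiff(o$classes, unname(upper_classes())), 2L)
    o2 <- add_axiom(o, ax_subclass(ce_named(cls[1L]), ce_named(cls[2L])),
                    "extra")
    u2 <- as.character(unsatisfiable_classes(o2))
    expect_true(all(u1 %in% u2))
  }
})

test_that("existential dependence on an unsatisfiable filler propagates", {
  set.seed(29)
  for (i in 1:10) {
    o <- ontology()
    o <- add_role(o, role_declaration("r"))
    o <- add_axiom(o, ax_subclass(ce_named("D"), ce_bottom()), "kill")
    chain <- paste0("K", seq_len(sample(2:4, 1L)))
    prev <- "D"
    for (cl in chain) {
      o <- add_axiom(o, ax_subclass(ce_named(cl),
                                    ce_some("r", ce_named(prev))), "dep")
      prev <- cl
    }
    u <- as.character(unsatisfiable_classes(o))
    expect_setequal(u, c("D", chain))
  }
})
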