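test_that("disambiguated expansion is the disjunction of the alternatives", {
  rules <- disambiguation_rules()
  Y <- ce_named("Y")
  hcp <- disambiguated_expand(rules$has_central_participant, Y)
  expect_true(ce_equal(hcp, parse_class_expression(
    paste("has_central_participant some Y or",
          "inheres_in some (has_central_participant some Y)"))))
  hi <- disambiguated_expand(rules$has_input, Y)
  expect_true(ce_equal(hi, parse_class_expression(
    paste("has_input some Y or",
          "(Function and (realized_by only (has_input some Y)))"))))
  single <- disambiguation_rule("solo", list("part_of some ?Y"), "solo")
  expect_true(ce_equal(disambiguated_expand(single, Y),
                       parse_class_expression("part_of some Y")))
})

test_that("uses resolve to intended or unintended meanings on the fixture", {
  b <- worked_example("hcp_disambiguation")
  o <- convert_obo(b$document, b$config_disambiguated)
  rules <- disambiguation_rules()
  rep_hcp <- resolve_uses(o, rules$has_central_participant)
  got <- stats::setNames(rep_hcp$status, rep_hcp$class)
  expect_identical(got[names(b$expected$resolution$has_central_participant)],
                   b$expected$resolution$has_central_participant)
  expect_true(all(rep_hcp$meaning == "inheres_in_has_central_participant"))
  rep_hi <- resolve_uses(o, rules$has_input)
  expect_identical(stats::setNames(rep_hi$status, rep_hi$class),
                   b$expected$resolution$has_input)
})

test_that("a class closing both branches resolves to neither", {
  # a class asserted under both Quality and Process misuses hcp: the
  # process reading clashes with Quality, the quality-of-process reading
  # clashes with Process (inheres-in has domain Quality)
  doc <- obo_document(terms = list(
    obo_term("PATO:Abnormal"),
    obo_term("GO:SomeProcess", namespace = "biological_process"),
    obo_term("MA:Thing"),
    obo_term("MP:Broken",
             is_a = "GO:SomeProcess",
             intersection_of = list("PATO:Abnormal",
                                    c("has_central_participant",
                                      "MA:Thing")))))
  cfg <- conversion_config(root_map = c(default_root_map(),
                                        MP = "Quality"),
                           disambiguate = "has_central_participant")
  o <- convert_obo(doc, cfg)
  rep <- resolve_uses(o, disambiguation_rules()$has_central_participant)
  expect_identical(rep$status, "neither")
})

test_that("rewriting resolved uses repairs the document", {
  b <- worked_example("hcp_disambiguation")
  o_strict <- convert_obo(b$document, b$config)
  o_dis <- convert_obo(b$document, b$config_disambiguated)
  rules <- disambiguation_rules()
  rep <- resolve_uses(o_dis, rules$has_central_participant)
  doc_rw <- rewrite_resolved(b$document, rep, rules = rules,
                             cfg = b$config_disambiguated)
  # the rewritten lines now use the composite relation
  f <- doc_rw$terms[["MP:AbnormalEyeMovement"]]
  expect_identical(f$intersection_of[[2L]][1L],
                   "inheres_in_has_central_participant")
  o_after <- convert_obo(doc_rw, b$config)
  expect_identical(as.character(unsatisfiable_classes(o_after)),
                   b$expected$unsatisfiable_after_rewrite)
  # fixpoint: re-resolving the rewritten document reports nothing to fix
  o_dis2 <- convert_obo(doc_rw, b$config_disambiguated)
  rep2 <- resolve_uses(o_dis2, rules$has_central_participant)
  expect_identical(nrow(rep2), 0L)
  # a report with no unintended uses leaves the document unchanged
  doc_same <- rewrite_resolved(b$document, rep2,
                               cfg = b$config_disambiguated)
  expect_identical(doc_same$terms, b$document$terms)
})

test_that("disambiguation never enlarges the unsatisfiable set", {
  b <- worked_example("hcp_disambiguation")
  u_strict <- as.character(unsatisfiable_classes(
    convert_obo(b$document, b$config)))
  u_dis <- as.character(unsatisfiable_classes(
    convert_obo(b$document, b$config_disambiguated)))
  expect_true(all(u_dis %in% u_strict))
  set.seed(3)
  for (s in 1:5) {
    pb <- generate_planted(plant_spec(seed = 200L + s))
    cfg_dis <- pb$config
    cfg_dis$disambiguate <- "has_central_participant"
    us <- as.character(unsatisfiable_classes(convert_obo(pb$document,
                                                         pb$config)))
    ud <- as.character(unsatisfiable_classes(convert_obo(pb$document,
                                                         cfg_dis)))
    expect_true(all(ud %in% us))
    expect_identical(ud, pb$expected$unsatisfiable_disambiguated)
  }
})

test_that("before/after comparison separates removed from remaining", {
  b <- worked_example("hcp_disambiguation")
  o_strict <- convert_obo(b$document, b$config)
  cmp_same <- compare_unsat(o_strict, o_strict)
  expect_length(cmp_same$removed, 0L)
  r <- cmd_disambiguate(list(b$document), config = b$config_disambiguated)
  expect_setequal(r$removed, b$misuse_classes)
  expect_identical(r$remaining, "MP:HeartMixup")
})
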