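test_that("negation normal form pushes negation to named classes", {
  A <- ce_named("A"); B <- ce_named("B")
  # De Morgan
  expect_true(ce_equal(nnf(ce_not(ce_and(A, B))),
                       ce_or(ce_not(A), ce_not(B))))
  expect_true(ce_equal(nnf(ce_not(ce_or(A, B))),
                       ce_and(ce_not(A), ce_not(B))))
  # duality of restrictions
  expect_true(ce_equal(nnf(ce_not(ce_some("r", A))),
                       ce_only("r", ce_not(A))))
  expect_true(ce_equal(nnf(ce_not(ce_only("r", A))),
                       ce_some("r", ce_not(A))))
  # complements of Thing / Nothing
  expect_true(ce_equal(ce_not(ce_top()), ce_bottom()))
  expect_true(ce_equal(ce_not(ce_bottom()), ce_top()))
})

test_that("nnf is idempotent and negation-free below Not on random expressions", {
  no_complex_not <- function(e) {
    switch(e$op,
      named = , top = , bottom = TRUE,
      not = e$arg$op == "named",
      and = , or = all(vapply(e$args, no_complex_not, TRUE)),
      some = , only = no_complex_not(e$filler))
  }
  set.seed(11)
  for (i in 1:80) {
    e <- random_expression(depth = 3L)
    n1 <- nnf(e)
    expect_true(no_complex_not(n1))
    expect_true(ce_equal(nnf(n1), n1))
  }
})

test_that("And/Or are flattened, deduplicated and order-insensitive", {
  A <- ce_named("A"); B <- ce_named("B"); C <- ce_named("C")
  expect_true(ce_equal(ce_and(A, ce_and(B, C)), ce_and(ce_and(A, B), C)))
  expect_true(ce_equal(ce_and(A, B), ce_and(B, A)))
  expect_true(ce_equal(ce_and(A, A), A))
  expect_true(ce_equal(ce_or(A, ce_bottom()), A))
  expect_true(ce_equal(ce_and(A, ce_bottom()), ce_bottom()))
  expect_true(ce_equal(ce_or(A, ce_top()), ce_top()))
  # n-ary arguments survive flattening with >= 2 members
  e <- ce_and(A, ce_and(B, C))
  expect_identical(e$op, "and")
  expect_length(e$args, 3L)
})

test_that("Manchester-style serialization round-trips structurally", {
  cases <- c("A", "Thing", "Nothing", "not A", "A and B", "A or B and C",
             "r some A", "r only (A or B)",
             "Quality and inheres_in some (part_of some MA:Liver)",
             "inheres_in some (has_central_participant some Thing)")
  for (s in cases) {
    e <- parse_class_expression(s)
    expect_true(ce_equal(parse_class_expression(format_class_expression(e)),
                         e), info = s)
  }
  set.seed(7)
  for (i in 1:60) {
    e <- random_expression(depth = 3L)
    expect_true(ce_equal(parse_class_expression(format_class_expression(e)),
                         e))
  }
})

test_that("parser respects precedence and reports syntax errors", {
  # and binds tighter than or; restrictions tighter than and
  e <- parse_class_expression("A or B and C")
  expect_identical(e$op, "or")
  e2 <- parse_class_expression("r some A and B")
  expect_identical(e2$op, "and")
  expect_error(parse_class_expression("A and"), "end of expression")
  expect_error(parse_class_expression("(A or B"), "expected")
  expect_error(parse_class_expression("A B"), "trailing")
})

test_that("placeholder substitution replaces every occurrence", {
  t <- parse_class_expression("inheres_in some (part_of some ?Y)")
  out <- ce_substitute(t, "?Y", ce_named("Liver"))
  expect_true(ce_equal(out,
    parse_class_expression("inheres_in some (part_of some Liver)")))
  expect_identical(ce_signature(out), "Liver")
})
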