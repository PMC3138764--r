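test_that("every worked example reproduces its expected unsatisfiable set", {
  for (nm in c("spore", "leukocyte_activation", "mucus_secretion",
               "liver_inflammation", "host_cell_cytoplasm_part",
               "vasculature_query")) {
    b <- worked_example(nm)
    o <- convert_obo(b$document, b$config)
    expect_identical(as.character(unsatisfiable_classes(o)),
                     b$expected$unsatisfiable, info = nm)
  }
  expect_error(worked_example("no_such_fixture"))
})

test_that("the homonymy clash disappears with the process-rooted genus", {
  b <- worked_example("mucus_secretion")
  o_var <- convert_obo(b$variant_document, b$config)
  expect_identical(as.character(unsatisfiable_classes(o_var)),
                   b$expected$variant_unsatisfiable)
})

test_that("the liver clash has two independent causes", {
  b <- worked_example("liver_inflammation")
  run <- function(functional, constraints) {
    cfg <- b$config
    cfg$functional_inheres_in <- functional
    cfg$add_quality_constraints <- constraints
    as.character(unsatisfiable_classes(convert_obo(b$document, cfg)))
  }
  expect_identical(run(TRUE, TRUE), b$expected$unsatisfiable)
  expect_identical(run(FALSE, TRUE), b$expected$unsat_without_functionality)
  expect_identical(run(TRUE, FALSE),
                   b$expected$unsat_without_quality_constraints)
  expect_identical(run(FALSE, FALSE), b$expected$unsat_without_both)
})

test_that("planted generation is seed-deterministic and respects zero plants", {
  b1 <- generate_planted(plant_spec(seed = 42L))
  b2 <- generate_planted(plant_spec(seed = 42L))
  expect_identical(write_obo(b1$document), write_obo(b2$document))
  b3 <- generate_planted(plant_spec(seed = 43L))
  expect_false(identical(write_obo(b1$document), write_obo(b3$document)))
  clean <- generate_planted(plant_spec(seed = 1L, plants = c()))
  expect_length(clean$expected$unsatisfiable, 0L)
  expect_length(as.character(unsatisfiable_classes(
    convert_obo(clean$document, clean$config))), 0L)
  expect_error(generate_planted(plant_spec(seed = 1L, n_classes = 6L)),
               "infeasible")
})

test_that("generator ground truth matches the reasoner across seeds", {
  # a reduced sweep; the 100-seed sweep runs in the acceptance suite
  for (s in 1:15) {
    b <- generate_planted(plant_spec(seed = 300L + s))
    o <- convert_obo(b$document, b$config)
    u <- unsatisfiable_classes(o)
    expect_identical(as.character(u), b$expected$unsatisfiable,
                     info = paste("seed", 300L + s))
    expect_length(attr(u, "undecided"), 0L)
    expect_true(all(b$expected$planted %in% b$expected$unsatisfiable))
  }
})

test_that("fixture bundles round-trip through files and the cli path", {
  dir <- tempfile("fx")
  r <- cmd_fixture("spore", dir)
  expect_true(file.exists(r$paths[["obo"]]))
  expect_true(file.exists(r$paths[["config"]]))
  chk <- cmd_check(r$paths[["obo"]], config = r$paths[["config"]])
  expected <- jsonlite::read_json(r$paths[["expected"]],
                                  simplifyVector = TRUE)
  expect_identical(chk$unsatisfiable, expected$unsatisfiable)
  expect_identical(chk$status, 1L)
})
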