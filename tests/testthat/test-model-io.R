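test_that("matrix assembly has one row per metabolite, one column per reaction", {
  m <- toy_chain_model()
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(nrow(m$metabolites), length(m$reactions)))
  # boundary columns have exactly one nonzero entry
  for (id in reaction_ids(m, c("exchange", "demand"))) {
    expect_equal(sum(S[, id] != 0), 1, info = id)
  }
  expect_equal(unname(S["a_c", "AB"]), -1)
})

test_that("structural invariants are enforced at construction", {
  m <- new_model("t", c(c = "cytosol"))
  m <- add_metabolite(m, "a_c", formula = "C", charge = 0L)
  expect_error(add_metabolite(m, "a_c"), "duplicate")
  expect_error(add_metabolite(m, "b_q"), "compartment")
  expect_error(add_reaction(m, "R1", c(zz_c = -1)), "undeclared")
  m <- add_reaction(m, "R1", c(a_c = -1), kind = "demand")
  expect_error(add_reaction(m, "R1", c(a_c = -1)), "duplicate")
  expect_error(add_reaction(m, "R2", c(a_c = -1), lower_bound = 5,
                            upper_bound = 1), "lower_bound")
  expect_error(set_objective(m, "nope"), "not in model")
  expect_true(validate_model(set_objective(m, "R1")))
})

test_that("JSON write/read is identity on id-level content", {
  m <- demo_cached()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path, "json")
  m2 <- read_model(path, "json")
  expect_setequal(m2$metabolites$id, m$metabolites$id)
  expect_setequal(names(m2$reactions), names(m$reactions))
  for (id in names(m$reactions)) {
    r1 <- m$reactions[[id]]; r2 <- m2$reactions[[id]]
    expect_equal(sort(names(r1$stoichiometry)), sort(names(r2$stoichiometry)))
    expect_equal(r2$stoichiometry[names(r1$stoichiometry)],
                 r1$stoichiometry)
    expect_equal(c(r2$lower_bound, r2$upper_bound),
                 c(r1$lower_bound, r1$upper_bound))
    expect_identical(gpr_to_string(r2$gpr), gpr_to_string(r1$gpr))
    expect_identical(r2$kind, r1$kind)
  }
  expect_identical(m2$objective, m$objective)
})

test_that("JSON referential integrity violations fail the load", {
  path <- withr::local_tempfile(fileext = ".json")
  doc <- list(id = "bad", compartments = list(c = "cytosol"),
              metabolites = list(list(id = "a_c", compartment = "c")),
              reactions = list(list(id = "R1",
                                    metabolites = list(ghost_c = -1),
                                    lower_bound = 0, upper_bound = 10)),
              genes = list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_model(path, "json"), "undeclared metabolite")
})

test_that("SBML-FBC export re-imports with an identical stoichiometric matrix", {
  m <- demo_cached()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path, "sbml")
  m2 <- read_model(path, "sbml")
  S1 <- stoichiometric_matrix(m)
  S2 <- stoichiometric_matrix(m2)
  expect_equal(S2[rownames(S1), colnames(S1)], S1)
  for (id in names(m$reactions)) {
    expect_identical(gpr_to_string(m2$reactions[[id]]$gpr),
                     gpr_to_string(m$reactions[[id]]$gpr), info = id)
    expect_equal(m2$reactions[[id]]$lower_bound, m$reactions[[id]]$lower_bound)
  }
  expect_identical(m2$objective$reaction, m$objective$reaction)
  # formulas and charges survive the fbc attributes
  expect_identical(
    m2$metabolites$formula[m2$metabolites$id == "q9_m"],
    m$metabolites$formula[m$metabolites$id == "q9_m"])
})

test_that("reading a missing file or unknown dialect errors cleanly", {
  expect_error(read_model("no/such/file.json", "json"), "no such file")
  expect_error(read_model("x", "gms"))
})
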