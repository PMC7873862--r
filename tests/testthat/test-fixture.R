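test_that("the demo fixture is balanced, massed, and audit-clean", {
  m <- demo_cached()
  rep <- check_balance(m)
  expect_length(rep$unbalanced, 0)
  expect_length(rep$unauditable, 0)
  expect_gt(rep$n_checked, 80)
  expect_equal(biomass_mass(m), 1, tolerance = 1e-4)
  expect_true(validate_model(m))
})

test_that("the fixture grows on all packaged carbon sources", {
  m <- demo_cached()
  for (nm in names(demo_media())) {
    res <- fba(m, demo_media()[[nm]])
    expect_equal(res$status, "optimal", info = nm)
    expect_gt(res$objective, 1e-3)
  }
})

test_that("ubiquinone in the fixture carries nine isoprenyl units", {
  m <- demo_cached()
  for (id in c("q9_m", "q9h2_m")) {
    f <- parse_formula(m$metabolites$formula[m$metabolites$id == id])
    # quinone head contributes 9 carbons; each isoprenyl unit 5
    expect_equal((f[["C"]] - 9) / 5, 9, info = id)
    expect_match(m$metabolites$name[m$metabolites$id == id], "9 isoprenyl")
  }
})

test_that("pentose flux passes through the arabinitol loop, not xylulokinase", {
  m <- demo_cached()
  res <- fba(m, demo_media()$xylose)
  expect_gt(res$fluxes[["RBK"]], 1e-6)          # D-ribulose kinase active
  expect_lt(abs(res$fluxes[["XYLK"]]), 1e-9)    # xylulokinase silent
})

test_that("deletion phenotypes reproduce the fitness-data biology", {
  m <- demo_cached()
  media <- demo_media()
  calls <- function(gene) {
    vapply(names(media), function(nm) {
      delete_genes(m, gene, media[[nm]])$growth > 1e-6
    }, logical(1))
  }
  wt <- vapply(names(media), function(nm) fba(m, media[[nm]])$objective > 1e-6,
               logical(1))
  expect_true(all(wt))
  # ribulose kinase: pentose sugars and alcohols only
  expect_identical(unname(calls("14368")),
                   c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # xylulokinase: no call changes anywhere
  expect_identical(unname(calls("16850")), unname(wt))
  # protocatechuate dioxygenase: p-coumarate only
  expect_identical(unname(calls("12623")),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("the fixture has no energy-generating cycles", {
  m <- demo_cached()
  expect_length(find_egc(m), 0)
})

test_that("deletion screen and growth agree with an independent COBRA implementation", {
  m <- demo_cached()
  json <- withr::local_tempfile(fileext = ".json")
  write_model(m, json, "json")
  script <- withr::local_tempfile(fileext = ".py")
  genes <- c("14368", "16850", "12623", "10021", "9990", "10051")
  writeLines(sprintf("
import json, cobra
m = cobra.io.load_json_model('%s')
m.reactions.EX_glc__D_e.lower_bound = -10
out = {'growth': m.slim_optimize()}
for g in %s:
    with m as mm:
        mm.genes.get_by_id(g).knock_out()
        out[g] = mm.slim_optimize(error_value=0.0)
print(json.dumps(out))
", json, paste0("['", paste(genes, collapse = "','"), "']")), script)
  res <- tryCatch(system2("python", script, stdout = TRUE, stderr = FALSE),
                  error = function(e) NULL)
  expect_false(is.null(res))
  vals <- jsonlite::fromJSON(res[length(res)])
  med <- demo_media()$glucose
  ours <- fba(m, med)
  expect_equal(ours$objective, vals$growth, tolerance = 1e-5)
  ref <- fba(apply_medium(m, med))
  for (g in genes) {
    d <- delete_genes(apply_medium(m, med), g, reference = ref)
    expect_equal(d$growth, vals[[g]], tolerance = 1e-5, info = g)
  }
})
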