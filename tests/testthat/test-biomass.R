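test_that("noise-free segmented fit recovers the generating line exactly", {
  # three fatty acids, samples at total contents {5, 10, 20, 40} wt%
  fit <- fit_segmented(demo_fame_data())
  expect_equal(fit$x0, 5, tolerance = 1e-6)
  expect_equal(unname(fit$m), c(0.7, 0.2, 0.1), tolerance = 1e-6)
  expect_equal(unname(fit$b), c(3, 1, 1), tolerance = 1e-6)
  expect_equal(unname(fit$lipid_body_composition), c(0.7, 0.2, 0.1),
               tolerance = 1e-6)
  expect_equal(sum(fit$m), 1, tolerance = 1e-6)
  expect_equal(sum(fit$b), fit$x0, tolerance = 1e-6)
})

test_that("constant fatty acids are pinned to slope zero and closure is restored", {
  x <- c(6, 12, 24, 36)
  y <- cbind(inc = 1 * (x - 6) + 2, flat = 4 + 0 * x)
  fit <- fit_segmented(fame_dataset(y))
  expect_false(fit$increasing[["flat"]])
  expect_true(fit$increasing[["inc"]])
  expect_equal(unname(fit$m), c(1, 0), tolerance = 1e-6)
  expect_equal(sum(fit$b), fit$x0, tolerance = 1e-9)
  # closure property: predicted totals equal x for all x >= x0
  pred_total <- sum(fit$b) + sum(fit$m) * (30 - fit$x0)
  expect_equal(pred_total, 30, tolerance = 1e-9)
})

test_that("degenerate single-fatty-acid data y = x collapses to the pure lipid line", {
  y <- matrix(c(0, 1, 2, 5), ncol = 1, dimnames = list(NULL, "only"))
  fit <- fit_segmented(fame_dataset(y))
  expect_equal(fit$x0, 0, tolerance = 1e-9)
  expect_equal(unname(fit$m), 1, tolerance = 1e-9)
  expect_equal(unname(fit$b), 0, tolerance = 1e-9)
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(fit_segmented(fame_dataset(matrix(1, 2, 2))), "3 samples")
  same_x <- matrix(c(1, 1, 1, 2, 2, 2), 3, 2)
  expect_error(fit_segmented(fame_dataset(same_x)), "distinct")
  # scatter with no credible trend in any fatty acid (slope t below 2)
  scatter <- cbind(a = c(5, 6, 4.8, 5.1), b = c(5.2, 4.4, 6.0, 5.4))
  expect_error(fit_segmented(fame_dataset(scatter)), "no lipid-body signal")
  expect_error(fame_dataset(matrix(-1, 3, 2)), "nonnegative")
})

test_that("recovery under noise improves with sample count (Monte-Carlo)", {
  err_at_n <- function(n) {
    mean(vapply(1:8, function(s) {
      fit <- fit_segmented(make_fame(700 + s, sigma = 0.5, n_samples = n))
      mean(abs(fit$b - c(3, 1, 1)))
    }, numeric(1)))
  }
  expect_lt(err_at_n(24), err_at_n(6) + 0.05)
})

test_that("abundance-weighted composition equals the direct dot product", {
  ents <- list(p1 = c(ala = 1, gly = 0), p2 = c(ala = 0, gly = 1))
  expect_equal(composition_from_weights(ents, c(p1 = 1, p2 = 1)),
               c(ala = 0.5, gly = 0.5))
  expect_equal(composition_from_weights(ents["p1"], c(p1 = 3)),
               c(ala = 1, gly = 0))
  set.seed(5)
  monomers <- paste0("m", 1:6)
  ents2 <- lapply(1:100, function(i) {
    v <- runif(6); setNames(v / sum(v), monomers)
  })
  names(ents2) <- paste0("e", 1:100)
  w <- setNames(runif(100), names(ents2))
  direct <- Reduce(`+`, Map(function(e, wi) e * wi, ents2, w)) / sum(w)
  expect_equal(composition_from_weights(ents2, w), direct, tolerance = 1e-12)
  expect_error(composition_from_weights(ents, c(p1 = 1, p3 = 1)),
               "without composition")
  expect_error(composition_from_weights(ents, c(p1 = 0, p2 = 0)),
               "all zero")
})

test_that("biomass coefficients are mass_fraction * mol_fraction / residue_mass", {
  m <- new_model("bm", c(c = "cytosol"))
  m <- add_metabolite(m, "aa_c", formula = "C3H7NO2", charge = 0L)
  m <- add_metabolite(m, "atp_c", formula = "C10H12N5O13P3", charge = -4L)
  m <- add_metabolite(m, "adp_c", formula = "C10H12N5O10P2", charge = -3L)
  m <- add_metabolite(m, "pi_c", formula = "HO4P", charge = -2L)
  m <- add_metabolite(m, "h2o_c", formula = "H2O", charge = 0L)
  m <- add_metabolite(m, "h_c", formula = "H", charge = 1L)
  m <- add_reaction(m, "SRC", c(aa_c = 1), kind = "sink")
  spec <- biomass_spec(
    macromolecules = c(protein = 1),
    monomers = list(protein = data.frame(metabolite = "aa_c",
                                         mol_fraction = 1,
                                         residue_mass = 0.1)),
    gam = 0)
  m2 <- assemble_biomass(m, spec)
  expect_equal(unname(m2$reactions$BIOMASS$stoichiometry[["aa_c"]]), -10)
  expect_error(assemble_biomass(m, biomass_spec(
    macromolecules = c(protein = 1),
    monomers = list(protein = data.frame(metabolite = "ghost_c",
                                         mol_fraction = 1,
                                         residue_mass = 0.1)),
    gam = 0)), "missing from model")
  expect_error(biomass_spec(c(protein = 0.7), list()), "sum")
})

test_that("assembled demo biomass drains 1 g/gDW and demands mirror the fit", {
  m <- demo_cached()
  expect_equal(biomass_mass(m), 1, tolerance = 1e-4)
  fit <- fit_segmented(demo_fame_data())
  dm <- m$reactions$DM_tag_lipid_body$stoichiometry
  tags <- c(C18_1 = "tag_ocdcea_l", C16_0 = "tag_hdca_l",
            C18_2 = "tag_lnlc_l")
  coefs <- -dm[tags[names(fit$lipid_body_composition)]]
  ratio <- coefs / fit$lipid_body_composition
  expect_lt(diff(range(ratio)), 1e-6 * mean(ratio))
  # sinks exist, closed by default
  expect_equal(m$reactions$SK_tag_lipid_body$upper_bound, 0)
})

test_that("opening the lipid-body demand shifts fatty-acid output toward slopes", {
  m <- demo_cached()
  med <- demo_media()$glucose
  ref <- fba(m, med)
  m2 <- apply_medium(m, med)
  m2 <- set_bounds(m2, "BIOMASS", lower_bound = 0.5 * ref$objective)
  res <- fba(m2, objective = "DM_tag_lipid_body", direction = "max")
  expect_gt(res$objective, 1e-3)
  # with the demand running, oleate flux rises relative to the lean ratio
  expect_gt(res$fluxes[["TAGS181"]], res$fluxes[["TAGS182"]])
})
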