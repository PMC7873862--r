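two_comp_model <- function() {
  m <- new_model("cur", c(c = "cytosol", m = "mitochondrion"))
  add <- function(m, id, f, ch, nm = id) add_metabolite(m, id, name = nm,
                                                        formula = f,
                                                        charge = ch)
  m <- add(m, "ficytc_m", "C42H44FeN8O8S2", 2L, "ferricytochrome c")
  m <- add(m, "ficytC_m", "C42H44FeN8O8S2", 2L, "Ferricytochrome-C")
  m <- add(m, "focytc_m", "C42H45FeN8O8S2", 1L, "ferrocytochrome c")
  m <- add(m, "a_c", "C3H6O3", 0L)
  m <- add(m, "b_c", "C3H6O3", 0L)
  m <- add(m, "d_c", "C3H4O3", -1L)
  m
}

test_that("signature is direction- and permutation-invariant", {
  st <- c(a_c = -1, b_c = 2, d_c = -3)
  s1 <- reaction_signature(st)
  s2 <- reaction_signature(st[c(3, 1, 2)])
  s3 <- reaction_signature(-st)          # written in the reverse direction
  s4 <- reaction_signature(2.5 * st)     # arbitrary rescaling
  expect_identical(s1$key, s2$key)
  expect_identical(s1$key, s3$key)
  expect_identical(s1$key, s4$key)
  # pure-production reactions anchor at +1 instead of -1
  expect_match(reaction_signature(c(a_c = 2))$key, "a_c:1")
})

test_that("duplicate metabolites are found by key and via the alias table", {
  m <- two_comp_model()
  pairs <- find_duplicate_metabolites(m)
  expect_true(any(pairs$a == "a_c" & pairs$b == "b_c"))          # same key
  expect_false(any(pairs$a == "d_c" | pairs$b == "d_c"))         # distinct
  # the classic cytochrome-c case-variant pair shares the key too, and an
  # alias table can add pairs the keys cannot see
  expect_true(any(pairs$a == "ficytC_m" & pairs$b == "ficytc_m"))
  aliases <- data.frame(keep_id = "ficytc_m", drop_id = "focytc_m",
                        stringsAsFactors = FALSE)
  pairs2 <- find_duplicate_metabolites(m, aliases)
  expect_true(any(pairs2$basis == "alias" &
                    pairs2$a == "ficytc_m" & pairs2$b == "focytc_m"))
  # a model with all-distinct keys reports nothing
  m2 <- new_model("d", c(c = "cytosol"))
  m2 <- add_metabolite(m2, "x_c", formula = "C2H4", charge = 0L)
  m2 <- add_metabolite(m2, "y_c", formula = "C2H6", charge = 0L)
  expect_equal(nrow(find_duplicate_metabolites(m2)), 0)
})

test_that("merging rewrites stoichiometry, cancels zero sums, flags collisions", {
  m <- two_comp_model()
  m <- add_reaction(m, "R1", c(a_c = -1, b_c = 1))     # cancels to nothing
  m <- add_reaction(m, "R2", c(a_c = -1, d_c = 1))
  m <- add_reaction(m, "R3", c(b_c = -1, d_c = 1))     # becomes duplicate of R2
  res <- merge_metabolites(m, "a_c", "b_c")
  expect_identical(res$removed_reactions, "R1")
  expect_setequal(res$flagged_duplicates, c("R2", "R3"))
  expect_false("b_c" %in% res$model$metabolites$id)
  expect_error(merge_metabolites(m, "a_c", "ficytc_m"), "cross-compartment")
  expect_error(merge_metabolites(m, "a_c", "ghost_c"), "not in model")
})

test_that("duplicate reactions group across direction and scale; dedup merges policy-wise", {
  m <- two_comp_model()
  m <- add_reaction(m, "FWD", c(a_c = -1, d_c = 1), -1000, 1000, gpr = "g1")
  m <- add_reaction(m, "REV", c(a_c = 1, d_c = -1), -1000, 500, gpr = "g2")
  m <- add_reaction(m, "OTHER", c(b_c = -1, d_c = 1))
  groups <- find_duplicate_reactions(m)
  expect_length(groups, 1)
  expect_setequal(groups[[1]], c("FWD", "REV"))
  dd <- dedup_reactions(m)
  expect_false("REV" %in% names(dd$model$reactions))
  kept <- dd$model$reactions$FWD
  expect_identical(gpr_to_string(kept$gpr), "g1 or g2")
  # REV's [-1000, 500] maps to [-500, 1000] in FWD orientation; widest wins
  expect_equal(c(kept$lower_bound, kept$upper_bound), c(-1000, 1000))
  # idempotence
  dd2 <- dedup_reactions(dd$model)
  expect_equal(nrow(dd2$log), 0)
})

test_that("dedup leaves the feasible flux cone unchanged (FVA equality)", {
  m <- toy_chain_model()
  m <- add_reaction(m, "AB_copy", c(a_c = -1, b_c = 1), 0, 400, gpr = "g9")
  dd <- dedup_reactions(m)
  ids <- c("EX_a_e", "DM_b")
  fv1 <- flux_variability(m, ids)
  fv2 <- flux_variability(dd$model, ids)
  expect_equal(fv2$min, fv1$min, tolerance = 1e-6)
  expect_equal(fv2$max, fv1$max, tolerance = 1e-6)
})

test_that("50-reaction model with 5 injected duplicates yields exactly 5 groups", {
  set.seed(11)
  m <- new_model("big", c(c = "cytosol"))
  for (i in 1:20) {
    m <- add_metabolite(m, sprintf("m%02d_c", i),
                        formula = sprintf("C%dH%d", i, 2 * i), charge = 0L)
  }
  for (i in 1:45) {
    mets <- sample(20, sample(2:4, 1))
    st <- setNames(sample(c(-2, -1, 1, 2), length(mets), replace = TRUE),
                   sprintf("m%02d_c", mets))
    if (all(st > 0) || all(st < 0)) st[1] <- -st[1]
    m <- tryCatch(add_reaction(m, sprintf("R%02d", i), st), error = function(e) m)
  }
  base_ids <- sample(names(m$reactions), 5)
  for (k in seq_along(base_ids)) {
    st <- m$reactions[[base_ids[k]]]$stoichiometry
    m <- add_reaction(m, sprintf("DUP%d", k), -2 * st)  # scaled + reversed
  }
  groups <- find_duplicate_reactions(m)
  expect_length(groups, 5)
  expect_setequal(vapply(groups, function(g) sum(grepl("^DUP", g)), integer(1)),
                  rep(1L, 5))
})

test_that("dead-end classification matches a reachability view of the network", {
  m <- new_model("de", c(c = "cytosol", e = "extracellular"))
  for (id in c("a", "b", "lone")) {
    m <- add_metabolite(m, paste0(id, "_c"), formula = "C", charge = 0L)
  }
  m <- add_metabolite(m, "a_e", formula = "C", charge = 0L)
  m <- add_reaction(m, "EX_a", c(a_e = -1), -10, 10, kind = "exchange")
  m <- add_reaction(m, "At", c(a_e = -1, a_c = 1))
  m <- add_reaction(m, "AB", c(a_c = -1, b_c = 1))
  rep <- dead_end_report(m)
  expect_identical(rep$role[rep$metabolite == "b_c"], "only-produced")
  expect_identical(rep$role[rep$metabolite == "lone_c"], "disconnected")
  expect_false("a_c" %in% rep$metabolite)
  # a fully exchanged toy reports nothing
  m2 <- add_reaction(m, "DM_b", c(b_c = -1), kind = "demand")
  m2 <- remove_reactions(m2, character(0))
  rep2 <- dead_end_report(m2)
  expect_false("b_c" %in% rep2$metabolite)
  # reversibility is honored: a reversible consumer is also a producer
  m3 <- new_model("rev", c(c = "cytosol"))
  m3 <- add_metabolite(m3, "p_c", formula = "C", charge = 0L)
  m3 <- add_metabolite(m3, "q_c", formula = "C", charge = 0L)
  m3 <- add_reaction(m3, "PQ", c(p_c = -1, q_c = 1), -1000, 1000)
  rep3 <- dead_end_report(m3)
  # both metabolites have a producer and a consumer through reversibility
  expect_equal(nrow(rep3), 0)
})
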