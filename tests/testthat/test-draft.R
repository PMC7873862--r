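donor_pair <- function() {
  d <- new_model("don", c(c = "cytosol", e = "extracellular"))
  d <- add_metabolite(d, "a_c", formula = "C2H4O2", charge = 0L)
  d <- add_metabolite(d, "b_c", formula = "C2H4O2", charge = 0L)
  d <- add_metabolite(d, "c_c", formula = "C2H4O2", charge = 0L)
  d <- add_reaction(d, "R1", c(a_c = -1, b_c = 1), gpr = "ga")
  d <- add_reaction(d, "R2", c(b_c = -1, c_c = 1), gpr = "gb")
  d <- add_reaction(d, "R3", c(a_c = -1, c_c = 1))            # orphan
  d
}

omap_for <- function(rows) {
  ortholog_map(do.call(rbind, lapply(rows, function(r) {
    data.frame(group_id = r[1], organism = r[2], gene_id = r[3],
               stringsAsFactors = FALSE)
  })), target_organism = "RT")
}

test_that("reactions transfer iff a GPR gene maps; GPRs are rewritten", {
  omap <- omap_for(list(c("G1", "don", "ga"), c("G1", "RT", "t1")))
  tr <- transfer_reactions(list(don = donor_pair()), omap)
  expect_setequal(names(tr$draft$reactions), "R1")
  expect_identical(gpr_to_string(tr$draft$reactions$R1$gpr), "t1")
  log_r2 <- tr$log[tr$log$donor_reaction_id == "R2", ]
  expect_identical(log_r2$action, "skipped_no_ortholog")
  # orphans (empty GPR) surface in the candidate list, never auto-transfer
  expect_true("R3" %in% tr$orphans$reaction_id)
  # provenance: every draft reaction has a transfer record
  expect_true(all(names(tr$draft$reactions) %in%
                    tr$log$donor_reaction_id[tr$log$action == "transferred"]))
})

test_that("one-to-many ortholog groups expand to OR (isozyme semantics)", {
  omap <- omap_for(list(c("G1", "don", "ga"), c("G1", "RT", "t1"),
                        c("G1", "RT", "t2")))
  tr <- transfer_reactions(list(don = donor_pair()), omap)
  expect_identical(gpr_to_string(tr$draft$reactions$R1$gpr), "t1 or t2")
})

test_that("a donor organism missing from the map is an error", {
  omap <- omap_for(list(c("G1", "other", "ga"), c("G1", "RT", "t1")))
  expect_error(transfer_reactions(list(don = donor_pair()), omap),
               "absent from ortholog map")
})

test_that("unmapped-gene resolution implements the isozyme/complex rule", {
  d <- new_model("don", c(c = "cytosol"))
  d <- add_metabolite(d, "a_c", formula = "C", charge = 0L)
  d <- add_metabolite(d, "b_c", formula = "C", charge = 0L)
  d <- add_metabolite(d, "c_c", formula = "C", charge = 0L)
  d <- add_reaction(d, "KEEP", c(a_c = -1, b_c = 1), gpr = "(ga and gu) or gb")
  d <- add_reaction(d, "DROP", c(b_c = -1, c_c = 1), gpr = "ga and gu")
  omap <- omap_for(list(c("G1", "don", "ga"), c("G1", "RT", "t1"),
                        c("G2", "don", "gb"), c("G2", "RT", "t2")))
  tr <- transfer_reactions(list(don = d), omap)
  res <- resolve_unmapped(tr$draft, tr$log)
  expect_true("KEEP" %in% names(res$model$reactions))
  expect_identical(gpr_to_string(res$model$reactions$KEEP$gpr), "t2")
  expect_false("DROP" %in% names(res$model$reactions))
  expect_true(any(res$log$action == "removed_complex"))
  # namespace purity: no donor-namespaced genes survive
  left <- unlist(lapply(res$model$reactions, function(r) gpr_genes(r$gpr)))
  expect_false(any(grepl(":", left)))
  # idempotence
  res2 <- resolve_unmapped(res$model)
  expect_identical(names(res2$model$reactions), names(res$model$reactions))
})

test_that("keep/remove equals mapped-genes-only satisfiability (truth-table)", {
  genes <- paste0("g", 1:4)
  for (seed in 301:330) {
    text <- random_gpr_text(seed, genes)
    g <- parse_gpr(text)
    used <- gpr_genes(g)
    set.seed(seed)
    mapped <- used[runif(length(used)) < 0.5]
    unmapped <- setdiff(used, mapped)
    # oracle: satisfiable with every unmapped gene forced FALSE?
    oracle_keep <- evaluate_gpr(g, knocked_out = unmapped)
    d <- new_model("don", c(c = "cytosol"))
    d <- add_metabolite(d, "a_c", formula = "C", charge = 0L)
    d <- add_metabolite(d, "b_c", formula = "C", charge = 0L)
    d <- add_reaction(d, "R", c(a_c = -1, b_c = 1), gpr = text)
    rows <- list()
    for (gg in used) rows <- c(rows, list(c(paste0("G", gg), "don", gg)))
    for (gg in mapped) rows <- c(rows, list(c(paste0("G", gg), "RT",
                                              paste0("t_", gg))))
    omap <- omap_for(rows)
    tr <- transfer_reactions(list(don = d), omap)
    if (length(mapped) == 0L) {
      expect_false("R" %in% names(tr$draft$reactions), info = text)
      next
    }
    res <- resolve_unmapped(tr$draft, tr$log)
    expect_identical("R" %in% names(res$model$reactions), oracle_keep,
                     info = sprintf("'%s' mapped {%s}", text,
                                    paste(mapped, collapse = ",")))
  }
})

test_that("transfer is monotone in the ortholog map", {
  d <- donor_pair()
  rows1 <- list(c("G1", "don", "ga"), c("G1", "RT", "t1"))
  rows2 <- c(rows1, list(c("G2", "don", "gb"), c("G2", "RT", "t2")))
  tr1 <- transfer_reactions(list(don = d), omap_for(rows1))
  tr2 <- transfer_reactions(list(don = d), omap_for(rows2))
  expect_true(all(names(tr1$draft$reactions) %in% names(tr2$draft$reactions)))
})

test_that("compartment rules rewrite suffixes; undeclared compartments resolve", {
  m <- new_model("d", c(c = "cytosol", m = "mitochondrion", h = "chloroplast"))
  m <- add_metabolite(m, "a_h", formula = "C2H4O2", charge = 0L)
  m <- add_metabolite(m, "b_h", formula = "C2H4O2", charge = 0L)
  m <- add_metabolite(m, "a_c", formula = "C2H4O2", charge = 0L)
  m <- add_metabolite(m, "b_c", formula = "C2H4O2", charge = 0L)
  m <- add_reaction(m, "RH", c(a_h = -1, b_h = 1), gpr = "t1")
  m <- add_reaction(m, "RC", c(a_c = -1, b_c = 1), gpr = "t1")
  m <- add_reaction(m, "RH2", c(b_h = -1, a_h = 1), gpr = "t9")
  rules <- data.frame(selector = "RH", from = "h", to = "c",
                      stringsAsFactors = FALSE)
  res <- assign_compartments(m, rules = rules,
                             target_compartments = c("c", "m"))
  # RH relocated onto existing c species and collapsed into RC (duplicate)
  expect_false("h" %in% unique(res$model$metabolites$compartment))
  expect_true("RC" %in% names(res$model$reactions))
  expect_false("RH2" %in% names(res$model$reactions))  # removed: no rule
  expect_true(any(grepl("undeclared", res$log$detail)))
  # localization can rescue instead of removal
  loc <- data.frame(gene_id = "t9", compartments = "m",
                    stringsAsFactors = FALSE)
  res2 <- assign_compartments(m, localization = loc, rules = rules,
                              target_compartments = c("c", "m"))
  expect_true("RH2" %in% names(res2$model$reactions))
  comps2 <- unique(sub("^.*_", "",
                       names(res2$model$reactions$RH2$stoichiometry)))
  expect_identical(comps2, "m")
  # relocation to an undeclared compartment is an error
  bad <- data.frame(selector = "RH", from = "h", to = "zz",
                    stringsAsFactors = FALSE)
  expect_error(assign_compartments(m, rules = bad,
                                   target_compartments = c("c", "m")),
               "undeclared")
})
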