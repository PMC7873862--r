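test_that("generators are pure functions of seed and spec", {
  u1 <- make_universe(universe_spec(seed = 3, n_genes = 12, n_reactions = 15,
                                    dup_rate = 0.1, imbalance_rate = 0.1,
                                    coverage = 0.8, spurious_rate = 0.1))
  u2 <- make_universe(universe_spec(seed = 3, n_genes = 12, n_reactions = 15,
                                    dup_rate = 0.1, imbalance_rate = 0.1,
                                    coverage = 0.8, spurious_rate = 0.1))
  expect_identical(u1, u2)
  f1 <- make_fame(9); f2 <- make_fame(9)
  expect_identical(f1, f2)
  # the global RNG stream is left untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_fame(4)); after <- runif(1)
  expect_identical(before, after)
})

test_that("the generated truth model is feasible with positive product flux", {
  u <- make_universe(universe_spec(seed = 5, n_genes = 10, n_reactions = 12))
  res <- fba(u$truth)
  expect_equal(res$status, "optimal")
  expect_gt(res$objective, 1e-6)
})

test_that("full-coverage noiseless universes reconstruct exactly", {
  u <- make_universe(universe_spec(seed = 21, n_genes = 25, n_reactions = 30,
                                   n_donors = 3, coverage = 1))
  tr <- transfer_reactions(u$donors, u$omap)
  res <- resolve_unmapped(tr$draft, tr$log)
  expect_setequal(names(res$model$reactions), u$ledger$transferable)
})

test_that("partial coverage recovers the expected fraction and never more", {
  u <- make_universe(universe_spec(seed = 22, n_genes = 30, n_reactions = 40,
                                   coverage = 0.6))
  tr <- transfer_reactions(u$donors, u$omap)
  res <- resolve_unmapped(tr$draft, tr$log)
  got <- names(res$model$reactions)
  expect_true(all(got %in% u$ledger$transferable))
  # reactions whose every GPR branch needs an uncovered gene cannot appear
  frac <- length(got) / length(u$ledger$transferable)
  expect_lt(frac, 1)
  expect_gt(frac, 0.2)
})

test_that("injected duplicates and imbalances are ledgered and found exactly", {
  u <- make_universe(universe_spec(seed = 23, n_genes = 20, n_reactions = 50,
                                   dup_rate = 0.1, imbalance_rate = 0.08))
  tr <- transfer_reactions(u$donors, u$omap)
  res <- resolve_unmapped(tr$draft, tr$log)
  pairs <- find_duplicate_metabolites(res$model)
  found <- apply(pairs[, c("a", "b")], 1, function(z) paste(sort(z), collapse = "|"))
  truth <- apply(u$ledger$duplicate_pairs, 1,
                 function(z) paste(sort(z), collapse = "|"))
  expect_setequal(found, truth)
  bal <- check_balance(res$model)
  expect_setequal(names(bal$unbalanced), u$ledger$imbalanced)
})

test_that("fame generator validates its compositional preconditions", {
  expect_error(make_fame(1, m = c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(make_fame(1, b = c(C18_1 = 1, C16_0 = 1, C18_2 = 1)), "x0")
  expect_error(make_fame(1, n_samples = 2), "3 samples")
  # closure is exact even under noise
  f <- make_fame(2, sigma = 1)
  expect_equal(rowSums(f$y), f$x, tolerance = 1e-12)
})

test_that("phenotype/fitness generator flips exactly what it ledgers", {
  m <- toy_chain_model(gpr_ab = "g1 or g2")
  media <- list(grow = c(EX_a_e = -10), starve = c(EX_a_e = 0))
  pf <- make_phenotype_and_fitness(31, m, media, flip_rate = 0.5)
  # observed growth = truth XOR flip, verifiable from the ledger
  expect_identical(unname(xor(pf$ledger$true_growth,
                              names(media) %in% pf$ledger$flipped_wells)),
                   pf$phenotypes$observed_growth)
  # scores land on the intended side of the midpoint cutoff
  obs <- pf$fitness$score < -2
  truth <- xor(pf$ledger$true_essential,
               seq_len(nrow(pf$fitness)) %in% pf$ledger$flipped_pairs)
  expect_identical(obs, unname(truth))
})
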