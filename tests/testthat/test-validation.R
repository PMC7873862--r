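test_that("confusion statistics reproduce the printed-count arithmetic", {
  # the published pre-refinement Biolog screen: 76 TP, 12 TN, 6 FP, 22 FN
  cs <- confusion(c(rep(TRUE, 76), rep(FALSE, 12), rep(TRUE, 6), rep(FALSE, 22)),
                  c(rep(TRUE, 76), rep(FALSE, 12), rep(FALSE, 6), rep(TRUE, 22)))
  expect_equal(cs$n, 116)
  expect_equal(cs$accuracy, 100 * 88 / 116, tolerance = 1e-12)
  expect_equal(round(cs$accuracy, 1), 75.9)
  perfect <- confusion(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)
  expect_error(confusion(TRUE, c(TRUE, FALSE)), "length mismatch")
  expect_error(confusion(logical(0), logical(0)), "at least one")
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    pred <- runif(n) < 0.5
    obs <- runif(n) < 0.5
    cs <- confusion(pred, obs)
    r <- suppressWarnings(cor(as.numeric(pred), as.numeric(obs)))
    if (is.na(r)) {
      expect_equal(cs$mcc, 0)
    } else {
      expect_equal(cs$mcc, r, tolerance = 1e-12)
    }
    # symmetry
    expect_equal(confusion(obs, pred)$mcc, cs$mcc, tolerance = 1e-12)
  }
})

test_that("phenotype simulation swaps element sources and tracks coverage", {
  m <- demo_cached()
  wells <- data.frame(
    plate = "PM1", well = c("A01", "A02", "A03", "A04"),
    substrate = c("glucose", "D-xylose", "L-arabinose", "Tween 40"),
    element_class = "C", a590 = c(1.2, 1.2, 1.2, 0.2), a750 = 0.2,
    observed_growth = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  sim <- simulate_phenotypes(m, wells, demo_substrate_map(),
                             demo_media()$glucose)
  expect_equal(unname(sim$coverage[c("simulable", "excluded")]), c(3, 1))
  expect_true(all(sim$wells$predicted_growth[1:3]))
  cs <- phenotype_concordance(sim)
  expect_equal(cs$n, 3)
  expect_equal(cs$accuracy, 100)
  # predictions are invariant to well ordering
  perm <- sample(nrow(wells))
  sim2 <- simulate_phenotypes(m, wells[perm, ], demo_substrate_map(),
                              demo_media()$glucose)
  expect_identical(sim2$wells$predicted_growth[order(perm)],
                   sim$wells$predicted_growth)
})

test_that("a well mapped to a dead-end metabolite predicts no growth", {
  m <- demo_cached()
  wells <- data.frame(plate = "P", well = "A01", substrate = "orphanose",
                      element_class = "C", a590 = 1, a750 = 0.2,
                      observed_growth = TRUE, stringsAsFactors = FALSE)
  map <- data.frame(substrate = "orphanose", metabolite_id = "xu5p__D_c",
                    stringsAsFactors = FALSE)
  sim <- simulate_phenotypes(m, wells, map, demo_media()$glucose)
  expect_true(sim$wells$simulable[1])
  expect_false(sim$wells$predicted_growth[1])
  expect_true("EX_xu5p__D_c" %in% sim$created_exchanges)
})

test_that("absorbance binarization uses the negative-control floor", {
  wells <- data.frame(
    substrate = c("negative control", "negative control", "sub1", "sub2"),
    a590 = c(0.21, 0.22, 1.4, 0.22), a750 = 0.2, stringsAsFactors = FALSE)
  out <- binarize_phenotypes(wells)
  expect_true(out$observed_growth[3])
  expect_false(out$observed_growth[4])
  expect_error(binarize_phenotypes(data.frame(substrate = "s", a590 = 1,
                                              a750 = 0.2)),
               "no negative-control")
})

test_that("essentiality concordance partitions genes and scores the conditional subset", {
  m <- toy_chain_model(gpr_ab = "g1 or g2")
  m <- add_metabolite(m, "c_c", formula = "C2H4O2", charge = 0L)
  m <- add_reaction(m, "BC", c(b_c = -1, c_c = 1), gpr = "g3")
  m <- add_reaction(m, "DM_c", c(c_c = -1), kind = "demand")
  # condition 1 objective: DM_b (g3 irrelevant); condition 2: DM_c (g3 needed)
  m1 <- set_objective(m, "DM_b"); m2 <- set_objective(m, "DM_c")
  media <- list(b_cond = c(EX_a_e = -10), c_cond = c(EX_a_e = -10))
  pred <- rbind(
    data.frame(gene = c("g1", "g2", "g3"), condition = "b_cond",
               essential = c(FALSE, FALSE, FALSE), growth_ratio = 1),
    data.frame(gene = c("g1", "g2", "g3"), condition = "c_cond",
               essential = c(FALSE, FALSE, TRUE), growth_ratio = c(1, 1, 0)))
  fitness <- data.frame(
    gene = rep(c("g1", "g2", "g3"), 2),
    condition = rep(c("b_cond", "c_cond"), each = 3),
    score = c(0, 0, 0, 0, 0, -5),
    global_essential = FALSE, stringsAsFactors = FALSE)
  conc <- essentiality_concordance(m1, fitness, media, predictions = pred)
  expect_equal(conc$pooled$accuracy, 100)
  expect_equal(conc$pooled$mcc, 1)
  sizes <- partition_sizes(conc)
  expect_equal(unname(sizes), c(0L, 2L, 1L))
  expect_equal(sum(sizes), conc$n_genes)
  # classes are disjoint and exhaustive by construction of the partition
  expect_setequal(conc$partition$gene, c("g1", "g2", "g3"))
  # conditional-subset accuracy equals pooled accuracy restricted to them
  cond_genes <- conc$partition$gene[conc$partition$class == "conditional"]
  sub <- conc$pairs[conc$pairs$gene %in% cond_genes, ]
  expect_equal(conc$conditional$accuracy,
               100 * mean(sub$predicted == sub$observed))
  # global_essential overrides the score rule
  fitness2 <- fitness
  fitness2$global_essential <- fitness2$gene == "g1"
  conc2 <- essentiality_concordance(m1, fitness2, media, predictions = pred)
  expect_equal(partition_sizes(conc2)[["always"]], 1L)
  expect_error(essentiality_concordance(m1, fitness, media["b_cond"],
                                        predictions = pred),
               "without a medium")
})

test_that("identical inputs give byte-identical concordance reports", {
  m <- toy_chain_model(gpr_ab = "g1 or g2")
  media <- list(cond = c(EX_a_e = -10))
  fitness <- data.frame(gene = c("g1", "g2"), condition = "cond",
                        score = c(-5, 0), global_essential = FALSE,
                        stringsAsFactors = FALSE)
  c1 <- essentiality_concordance(m, fitness, media)
  c2 <- essentiality_concordance(m, fitness, media)
  expect_identical(c1, c2)
})
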