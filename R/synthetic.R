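## Seed-deterministic generators for every input the pipeline consumes,
## each carrying a ground-truth ledger so tests can score recovery exactly.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification for a synthetic reconstruction universe
#'
#' @param seed integer seed; generation is a pure function of the spec.
#' @param n_genes number of target-organism genes in the ground truth.
#' @param n_reactions length of the ground-truth pathway chain.
#' @param n_donors number of donor models.
#' @param coverage fraction of truth genes present in the ortholog map
#'   with a target-organism member.
#' @param spurious_rate fraction of donor genes assigned to the wrong
#'   ortholog group (erroneous ortholog calls).
#' @param dup_rate fraction of internal metabolites for which donors carry
#'   a duplicate identifier (alias) used by an extra reaction copy.
#' @param imbalance_rate fraction of donor reactions perturbed to be mass
#'   imbalanced (a water molecule dropped).
#' @return a `universe_spec` list.
#' @export
universe_spec <- function(seed = 1, n_genes = 30, n_reactions = 40,
                          n_donors = 2, coverage = 1, spurious_rate = 0,
                          dup_rate = 0, imbalance_rate = 0) {
  stopifnot(coverage >= 0, coverage <= 1, spurious_rate >= 0,
            spurious_rate <= 1, dup_rate >= 0, dup_rate <= 1,
            imbalance_rate >= 0, imbalance_rate <= 1, n_donors >= 1)
  structure(list(seed = seed, n_genes = n_genes, n_reactions = n_reactions,
                 n_donors = n_donors, coverage = coverage,
                 spurious_rate = spurious_rate, dup_rate = dup_rate,
                 imbalance_rate = imbalance_rate), class = "universe_spec")
}

#' Generate a synthetic reconstruction universe with known ground truth
#'
#' Builds a feasible ground-truth model (a hydration chain from an
#' exchanged substrate to a demanded product, so every metabolite has a
#' distinct formula and every reaction is balanced), projects it into
#' `n_donors` donor models with donor-namespaced genes, and derives an
#' ortholog map with controlled coverage and spurious-link rate.
#' Duplicate-metabolite aliases and mass-imbalanced copies are injected
#' into the donors at the requested rates.  Everything injected is
#' recorded in the truth ledger.
#'
#' @param spec a `universe_spec`.
#' @return list with `truth` (model), `donors` (named list of models),
#'   `omap` (an `ortholog_map`), and `ledger` (list: `transferable`
#'   reaction ids, `duplicate_pairs` data.frame, `imbalanced` reaction
#'   ids, `spurious` data.frame, `unmapped_genes`).
#' @export
make_universe <- function(spec) {
  stopifnot(inherits(spec, "universe_spec"))
  with_seed(spec$seed, make_universe_impl(spec))
}

make_universe_impl <- function(spec) {
  p <- spec$n_reactions
  genes <- sprintf("TG%03d", seq_len(spec$n_genes))
  truth <- new_model("truth", c(c = "cytosol", e = "extracellular"))
  met_id <- function(i) sprintf("mx%02d_c", i)
  # chain metabolite i: C6 H(12+2i) O(6+i); hydration steps keep balance
  for (i in seq_len(p + 1)) {
    truth <- add_metabolite(truth, met_id(i), formula =
                              sprintf("C6H%dO%d", 12 + 2 * i, 6 + i),
                            charge = 0L, compartment = "c")
  }
  truth <- add_metabolite(truth, "sub_e", formula = "C6H14O7", charge = 0L,
                          compartment = "e")
  truth <- add_metabolite(truth, "h2o_c", formula = "H2O", charge = 0L,
                          compartment = "c")
  truth <- add_metabolite(truth, "h2o_e", formula = "H2O", charge = 0L,
                          compartment = "e")
  truth <- add_reaction(truth, "EX_sub_e", c(sub_e = -1), -10, 1000,
                        kind = "exchange")
  truth <- add_reaction(truth, "EX_h2o_e", c(h2o_e = -1), -1000, 1000,
                        kind = "exchange")
  truth <- add_reaction(truth, "H2Ot", c(h2o_e = -1, h2o_c = 1), -1000, 1000,
                        gpr = sample(genes, 1), kind = "transport")
  truth <- add_reaction(truth, "SUBt", c(sub_e = -1, mx01_c = 1), 0, 1000,
                        gpr = sample(genes, 1), kind = "transport")
  # random GPR shapes: single gene, isozyme pair, two-subunit complex
  rxn_ids <- sprintf("R%03d", seq_len(p))
  for (i in seq_len(p)) {
    shape <- sample(c("single", "iso", "complex"), 1,
                    prob = c(0.5, 0.25, 0.25))
    gs <- sample(genes, if (shape == "single") 1 else 2)
    gpr <- switch(shape, single = gs, iso = paste(gs, collapse = " or "),
                  complex = paste(gs, collapse = " and "))
    truth <- add_reaction(truth, rxn_ids[i],
                          stats::setNames(c(-1, -1, 1),
                                          c(met_id(i), "h2o_c", met_id(i + 1))),
                          0, 1000, gpr = gpr, kind = "metabolic",
                          subsystem = "chain")
    }
  truth <- add_reaction(truth, "DM_product",
                        stats::setNames(-1, met_id(p + 1)), 0, 1000,
                        kind = "demand")
  truth <- set_objective(truth, "DM_product")
  ref <- fba(truth)
  if (ref$status != "optimal" || ref$objective <= 1e-6) {
    stop("generated truth model is infeasible")   # not reachable by design
  }
  # donors: projections with namespaced genes; each carries ~90% of the
  # chain (all of it when there is a single donor), union covering all
  donor_names <- sprintf("D%d", seq_len(spec$n_donors))
  donors <- list()
  dup_pairs <- data.frame(keep_id = character(0), drop_id = character(0),
                          stringsAsFactors = FALSE)
  imbalanced <- character(0)
  transferable <- character(0)
  for (d in seq_len(spec$n_donors)) {
    org <- donor_names[d]
    keep <- if (spec$n_donors == 1) rxn_ids else {
      sel <- stats::runif(p) < 0.9
      # round-robin assignment guarantees the union covers the whole chain
      rxn_ids[sel | seq_len(p) %% spec$n_donors == (d - 1)]
    }
    donor <- truth
    donor$id <- org
    donor <- remove_reactions(donor, setdiff(rxn_ids, keep))
    # namespace genes
    ns <- stats::setNames(as.list(paste0(org, "_", truth$genes)), truth$genes)
    for (rid in names(donor$reactions)) {
      donor$reactions[[rid]]$gpr <- gpr_substitute(donor$reactions[[rid]]$gpr, ns)
    }
    donor$genes <- paste0(org, "_", truth$genes)
    donors[[org]] <- donor
    transferable <- union(transferable, keep)
  }
  transferable <- sort(union(transferable, c("H2Ot", "SUBt")))
  # inject duplicate metabolite aliases into donor 1
  if (spec$dup_rate > 0) {
    d1 <- donors[[1]]
    # only metabolites whose consuming reaction the donor actually carries
    eligible <- which(rxn_ids %in% names(d1$reactions))
    n_dup <- min(length(eligible), max(1L, round(spec$dup_rate * p)))
    targets <- sample(eligible, n_dup)
    for (i in targets) {
      orig <- met_id(i)
      alias <- sub("_c$", "_alt_c", orig)
      mrow <- d1$metabolites[d1$metabolites$id == orig, ]
      d1 <- add_metabolite(d1, alias, name = paste0(mrow$name, " (alias)"),
                           formula = mrow$formula, charge = mrow$charge,
                           compartment = "c")
      rid <- rxn_ids[i]
      if (rid %in% names(d1$reactions)) {
        st <- d1$reactions[[rid]]$stoichiometry
        names(st)[names(st) == orig] <- alias
        d1 <- add_reaction(d1, paste0(rid, "_alt"), st, 0, 1000,
                           gpr = d1$reactions[[rid]]$gpr, kind = "metabolic",
                           subsystem = "chain")
        transferable <- sort(union(transferable, paste0(rid, "_alt")))
      }
      dup_pairs <- rbind(dup_pairs, data.frame(keep_id = orig,
                                               drop_id = alias,
                                               stringsAsFactors = FALSE))
    }
    donors[[1]] <- d1
  }
  # inject mass imbalance: drop the water reactant from some donor-1 copies
  if (spec$imbalance_rate > 0) {
    d1 <- donors[[1]]
    avail <- intersect(rxn_ids, names(d1$reactions))
    n_imb <- max(1L, round(spec$imbalance_rate * length(avail)))
    for (rid in sample(avail, n_imb)) {
      st <- d1$reactions[[rid]]$stoichiometry
      d1$reactions[[rid]]$stoichiometry <- st[names(st) != "h2o_c"]
      imbalanced <- c(imbalanced, rid)
    }
    donors[[1]] <- d1
  }
  # ortholog map: one group per truth gene; coverage and spurious links
  n_cov <- round(spec$coverage * spec$n_genes)
  covered <- sample(genes, n_cov)
  rows <- data.frame(group_id = paste0("OG_", genes), organism = "target",
                     gene_id = genes, stringsAsFactors = FALSE)
  rows <- rows[rows$gene_id %in% covered, , drop = FALSE]
  spurious <- data.frame(organism = character(0), gene_id = character(0),
                         wrong_group = character(0), stringsAsFactors = FALSE)
  for (org in donor_names) {
    for (g in genes) {
      grp <- paste0("OG_", g)
      if (spec$spurious_rate > 0 && stats::runif(1) < spec$spurious_rate) {
        wrong <- paste0("OG_", sample(setdiff(genes, g), 1))
        spurious <- rbind(spurious, data.frame(
          organism = org, gene_id = paste0(org, "_", g), wrong_group = wrong,
          stringsAsFactors = FALSE))
        grp <- wrong
      }
      rows <- rbind(rows, data.frame(group_id = grp, organism = org,
                                     gene_id = paste0(org, "_", g),
                                     stringsAsFactors = FALSE))
    }
  }
  omap <- ortholog_map(rows, target_organism = "target")
  list(truth = truth, donors = donors, omap = omap,
       ledger = list(transferable = transferable,
                     duplicate_pairs = dup_pairs,
                     imbalanced = sort(imbalanced),
                     spurious = spurious,
                     unmapped_genes = sort(setdiff(genes, covered))))
}

#' Generate synthetic fatty-acid composition data
#'
#' Inverts the lean/lipid-body line: places total fatty-acid contents `x`
#' uniformly over `[x0, x0 + 35]` wt% CDW (evenly spaced conditions from
#' a low-lipid rich medium at the lean point to a high-lipid
#' nitrogen-limited medium, emulating a designed media panel), sets
#' `y_k = m_k (x - x0) + b_k` plus Gaussian noise truncated at 0, then
#' rescales each sample so that compositional closure `sum(y) = x` holds
#' exactly.  The `x` design is deterministic; the seed drives only the
#' measurement noise.
#'
#' @param seed integer seed.
#' @param b lean fatty-acid contents (wt% CDW), named; `sum(b)` must
#'   equal `x0`.
#' @param m lipid-body mass-fraction composition, same names; must sum
#'   to 1.
#' @param x0 lean total fatty-acid content (wt% CDW).
#' @param sigma Gaussian noise standard deviation (wt% CDW).
#' @param n_samples number of samples (>= 3).
#' @return a `fame_dataset`.
#' @export
make_fame <- function(seed, b = c(C18_1 = 3, C16_0 = 1, C18_2 = 1),
                      m = c(C18_1 = 0.7, C16_0 = 0.2, C18_2 = 0.1),
                      x0 = 5, sigma = 0.5, n_samples = 12) {
  if (abs(sum(m) - 1) > 1e-8) stop("lipid-body composition m must sum to 1")
  if (abs(sum(b) - x0) > 1e-8) stop("lean contents b must sum to x0")
  if (any(m < 0) || any(b < 0)) stop("m and b must be nonnegative")
  if (n_samples < 3) stop("need at least 3 samples")
  if (!identical(names(b), names(m))) stop("b and m must share names")
  with_seed(seed, {
    x <- seq(x0, x0 + 35, length.out = n_samples)
    y <- t(vapply(x, function(xi) m * (xi - x0) + b, numeric(length(m))))
    if (sigma > 0) {
      y <- pmax(y + matrix(stats::rnorm(length(y), 0, sigma), nrow(y)), 0)
      y <- y * (x / rowSums(y))
    }
    rownames(y) <- sprintf("S%02d", seq_len(n_samples))
    fame_dataset(y)
  })
}

#' Generate synthetic phenotype-array and gene-fitness data from a model
#'
#' Observed growth per condition is the model's own FBA growth call
#' flipped by independent Bernoulli(`flip_rate`) label noise.  Fitness
#' scores are drawn from N(0, 0.5) for (gene, condition) pairs the
#' model's deletions call non-essential and N(-4, 1) for essential pairs
#' (distributions chosen to straddle any reasonable cutoff), with labels
#' flipped at the same rate before drawing.  Draws are resampled onto the
#' intended side of the distribution midpoint (-2), so the Bernoulli
#' flips are the only label noise: scoring the table at a cutoff of -2
#' recovers the flipped pairs exactly.  The truth ledger records the
#' model's own calls and every flip.
#'
#' @param seed integer seed.
#' @param model a `metabolic_model` with an objective.
#' @param media named list of media (see [apply_medium()]); names are the
#'   condition labels.
#' @param flip_rate label-noise probability `q`.
#' @param genes genes to include in the fitness table (default: all model
#'   genes).
#' @param deletions optional precomputed deletion calls: data.frame with
#'   columns `gene`, `condition`, `essential` (saves re-solving when
#'   generating many noise replicates of one model).
#' @param growth_threshold flux threshold for the growth call.
#' @return list with `phenotypes` (data.frame: plate, well, substrate,
#'   element_class, a590, a750, observed_growth), `fitness` (data.frame:
#'   gene, condition, score, global_essential), and `ledger` (list:
#'   `true_growth`, `flipped_wells`, `true_essential`, `flipped_pairs`,
#'   `deletions`).
#' @export
make_phenotype_and_fitness <- function(seed, model, media, flip_rate = 0,
                                       genes = NULL, deletions = NULL,
                                       growth_threshold = 1e-6) {
  stopifnot(flip_rate >= 0, flip_rate <= 1)
  if (is.null(genes)) genes <- model$genes
  if (is.null(deletions)) {
    deletions <- model_deletion_calls(model, media, genes)
  }
  true_growth <- vapply(names(media), function(nm) {
    r <- fba(model, media[[nm]])
    r$status == "optimal" && r$objective > growth_threshold
  }, logical(1))
  with_seed(seed, {
    flip_w <- stats::runif(length(media)) < flip_rate
    obs_growth <- xor(true_growth, flip_w)
    phenotypes <- data.frame(
      plate = "SYN1",
      well = sprintf("A%02d", seq_along(media)),
      substrate = names(media),
      element_class = "C",
      a590 = round(0.20 + ifelse(obs_growth, 1.0, 0.02) +
                     stats::runif(length(media), 0, 0.01), 4),
      a750 = 0.20,
      observed_growth = obs_growth,
      stringsAsFactors = FALSE)
    flip_f <- stats::runif(nrow(deletions)) < flip_rate
    obs_ess <- xor(deletions$essential, flip_f)
    score <- ifelse(obs_ess, stats::rnorm(nrow(deletions), -4, 1),
                    stats::rnorm(nrow(deletions), 0, 0.5))
    # resample tail-crossers so the intended label survives a -2 cutoff
    bad <- (obs_ess & score >= -2) | (!obs_ess & score < -2)
    while (any(bad)) {
      score[bad] <- ifelse(obs_ess[bad], stats::rnorm(sum(bad), -4, 1),
                           stats::rnorm(sum(bad), 0, 0.5))
      bad <- (obs_ess & score >= -2) | (!obs_ess & score < -2)
    }
    fitness <- data.frame(
      gene = deletions$gene, condition = deletions$condition,
      score = score,
      global_essential = FALSE,
      stringsAsFactors = FALSE)
    list(phenotypes = phenotypes, fitness = fitness,
         ledger = list(true_growth = true_growth,
                       flipped_wells = names(media)[flip_w],
                       true_essential = deletions$essential,
                       flipped_pairs = which(flip_f),
                       deletions = deletions))
  })
}

#' Model deletion calls across conditions
#'
#' Single-gene deletion essentiality calls for each condition, the shared
#' input of the fitness generator and the concordance scorer.
#'
#' @param model a `metabolic_model`.
#' @param media named list of media.
#' @param genes genes to screen (default: all).
#' @param essentiality_threshold growth-ratio cutoff.
#' @return data.frame with columns `gene`, `condition`, `essential`,
#'   `growth_ratio`.
#' @export
model_deletion_calls <- function(model, media, genes = NULL,
                                 essentiality_threshold = 0.1) {
  if (is.null(genes)) genes <- model$genes
  rows <- lapply(names(media), function(nm) {
    scr <- single_deletions(model, genes, media[[nm]],
                            essentiality_threshold = essentiality_threshold)
    data.frame(gene = scr$gene, condition = nm, essential = scr$essential,
               growth_ratio = scr$growth_ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
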