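#' Apply a growth medium to a model
#'
#' A medium is a named numeric vector giving the lower (uptake) bound for
#' each listed exchange reaction, in mmol/gDW/h (negative = uptake
#' allowed).  All exchange reactions not listed are closed for uptake
#' (lower bound 0); secretion (upper) bounds are left untouched.
#'
#' @param model a `metabolic_model`.
#' @param medium named numeric vector of exchange lower bounds.
#' @return the bounded model.
#' @export
apply_medium <- function(model, medium) {
  ex <- reaction_ids(model, "exchange")
  unknown <- setdiff(names(medium), ex)
  if (length(unknown) > 0L) {
    stop("medium keys are not exchange reactions: ",
         paste(unknown, collapse = ", "))
  }
  for (id in ex) model$reactions[[id]]$lower_bound <- 0
  for (id in names(medium)) model$reactions[[id]]$lower_bound <- medium[[id]]
  model
}

#' Flux balance analysis
#'
#' Solves the LP `sense(v_obj)` subject to `S v = 0` and the model's flux
#' bounds, optionally after applying a medium.  Shadow prices are the dual
#' values of the metabolite mass-balance rows: the marginal change of the
#' objective per unit of external supply of the metabolite.
#'
#' @param model a `metabolic_model` with an objective (or see `objective`).
#' @param medium optional medium (see [apply_medium()]).
#' @param objective optional reaction id overriding the model objective.
#' @param direction `"max"` (default) or `"min"` when `objective` is given.
#' @return a `flux_result`: list with `status`, `objective` (value),
#'   `fluxes` (named), `shadow_prices` (named by metabolite).
#' @export
fba <- function(model, medium = NULL, objective = NULL, direction = "max") {
  stopifnot(inherits(model, "metabolic_model"))
  if (!is.null(medium)) model <- apply_medium(model, medium)
  if (is.null(objective)) {
    if (is.null(model$objective)) stop("model has no objective")
    objective <- model$objective$reaction
    direction <- model$objective$direction
  }
  if (!objective %in% names(model$reactions)) {
    stop(sprintf("objective reaction '%s' not in model", objective))
  }
  S <- stoichiometric_matrix(model)
  n <- ncol(S)
  lbs <- vapply(model$reactions, function(r) r$lower_bound, numeric(1))
  ubs <- vapply(model$reactions, function(r) r$upper_bound, numeric(1))
  cvec <- as.numeric(colnames(S) == objective)
  res <- solve_lp(cvec, S, rep(0, nrow(S)), lb = lbs, ub = ubs,
                  sense = direction)
  structure(list(
    status = res$status,
    objective = res$objective,
    fluxes = if (res$status == "optimal") stats::setNames(res$x, colnames(S)) else NULL,
    shadow_prices = if (res$status == "optimal") stats::setNames(res$duals_eq, rownames(S)) else NULL,
    objective_reaction = objective, direction = direction
  ), class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> %s: %s = %s (%s)\n", x$status,
              x$objective_reaction, format(x$objective), x$direction))
  invisible(x)
}

#' Flux variability analysis
#'
#' Minimum and maximum attainable flux for each requested reaction at a
#' given fraction of the optimal objective.
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids (default: all).
#' @param medium optional medium.
#' @param fraction_of_optimum fix the objective at this fraction of its
#'   optimum before scanning (0 = no growth constraint).
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, reactions = NULL, medium = NULL,
                             fraction_of_optimum = 0) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  if (is.null(reactions)) reactions <- reaction_ids(model)
  if (fraction_of_optimum > 0) {
    ref <- fba(model)
    if (ref$status != "optimal") stop("reference FBA not optimal")
    model <- set_bounds(model, model$objective$reaction,
                        lower_bound = fraction_of_optimum * ref$objective)
  }
  S <- stoichiometric_matrix(model)
  lbs <- vapply(model$reactions, function(r) r$lower_bound, numeric(1))
  ubs <- vapply(model$reactions, function(r) r$upper_bound, numeric(1))
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reactions)) {
    cvec <- as.numeric(colnames(S) == reactions[i])
    lo <- solve_lp(cvec, S, rep(0, nrow(S)), lb = lbs, ub = ubs, sense = "min")
    hi <- solve_lp(cvec, S, rep(0, nrow(S)), lb = lbs, ub = ubs, sense = "max")
    out$min[i] <- lo$objective
    out$max[i] <- hi$objective
  }
  out
}

#' Diagnose producibility of biomass precursors
#'
#' For every metabolite consumed by the biomass reaction, maximizes a
#' temporary demand for it and reports whether it can be synthesized in
#' the given medium.  Metabolites the biomass reaction produces (the ADP,
#' phosphate and proton returned by the maintenance hydrolysis) are
#' supplied back during each test, so conserved-moiety currency
#' precursors such as ATP are judged by regeneration capacity rather than
#' impossible net synthesis.  For non-producible precursors, the upstream
#' dead-end metabolites (reachable backwards through the network) are
#' listed as blocking evidence, mirroring the shadow-price diagnosis used
#' when repairing a draft model.
#'
#' @param model a `metabolic_model`.
#' @param medium optional medium.
#' @param biomass biomass reaction id (default: the model objective).
#' @param flux_tol producibility threshold on the maximal synthesis flux.
#' @return data.frame with columns `precursor`, `producible`, `max_flux`,
#'   and list-column `blocking` (character vectors of upstream dead ends).
#' @export
diagnose_precursors <- function(model, medium = NULL, biomass = NULL,
                                flux_tol = 1e-6) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  if (is.null(biomass)) {
    if (is.null(model$objective)) stop("model has no objective")
    biomass <- model$objective$reaction
  }
  st <- model$reactions[[biomass]]$stoichiometry
  precursors <- names(st)[st < 0]
  byproducts <- names(st)[st > 0]
  dead <- dead_end_report(model)
  dead_ids <- dead$metabolite[dead$role != "ok"]
  out <- data.frame(precursor = precursors, producible = NA,
                    max_flux = NA_real_, stringsAsFactors = FALSE)
  out$blocking <- vector("list", length(precursors))
  for (i in seq_along(precursors)) {
    m2 <- model
    m2$reactions[[biomass]]$lower_bound <- 0
    m2$reactions[[biomass]]$upper_bound <- 0
    for (bp in setdiff(byproducts, precursors[i])) {
      m2 <- add_reaction(m2, paste0(".SK_", bp), stats::setNames(1, bp),
                         lower_bound = 0, upper_bound = 1000, kind = "sink")
    }
    dm_id <- ".DM_diag"
    m2 <- add_reaction(m2, dm_id, stats::setNames(-1, precursors[i]),
                       lower_bound = 0, upper_bound = 1000, kind = "demand")
    res <- fba(m2, objective = dm_id, direction = "max")
    mx <- if (res$status == "optimal") res$objective else 0
    out$producible[i] <- mx > flux_tol
    out$max_flux[i] <- mx
    if (!out$producible[i]) {
      upstream <- upstream_metabolites(model, precursors[i])
      out$blocking[[i]] <- intersect(upstream, dead_ids)
    }
  }
  out
}

# metabolites reachable backwards from `target` through reactions that can
# (given their bounds) produce the metabolite being traced
upstream_metabolites <- function(model, target) {
  seen <- character(0)
  frontier <- target
  while (length(frontier) > 0L) {
    seen <- union(seen, frontier)
    nxt <- character(0)
    for (r in model$reactions) {
      st <- r$stoichiometry
      fwd <- r$upper_bound > 1e-12   # can run left->right
      rev <- r$lower_bound < -1e-12  # can run right->left
      prod_fwd <- names(st)[st > 0]; cons_fwd <- names(st)[st < 0]
      if (fwd && any(prod_fwd %in% frontier)) nxt <- union(nxt, cons_fwd)
      if (rev && any(cons_fwd %in% frontier)) nxt <- union(nxt, prod_fwd)
    }
    frontier <- setdiff(nxt, seen)
  }
  setdiff(seen, target)
}

#' Reactions disabled by a gene knockout
#'
#' @param model a `metabolic_model`.
#' @param genes gene ids knocked out.
#' @return character vector of reaction ids whose GPR is unsatisfied.
#' @export
knockout_reactions <- function(model, genes) {
  unknown <- setdiff(genes, model$genes)
  if (length(unknown) > 0L) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  }
  ids <- names(model$reactions)
  ids[!vapply(model$reactions, function(r) evaluate_gpr(r$gpr, genes),
              logical(1))]
}

#' Simulate a gene deletion (single or set)
#'
#' Reactions whose GPR is unsatisfied with the genes removed are closed
#' (bounds 0,0) and FBA is re-solved.  A gene (set) is called essential
#' when the growth ratio falls below `essentiality_threshold`.
#'
#' @param model a `metabolic_model` with an objective.
#' @param genes gene ids to delete together.
#' @param medium optional medium.
#' @param reference optional precomputed reference `flux_result` for the
#'   same model+medium (saves re-solving in deletion screens).
#' @param essentiality_threshold growth-ratio cutoff for the essential call.
#' @return a `deletion_result`: list with `genes`, `disabled_reactions`,
#'   `growth`, `reference_growth`, `growth_ratio`, `essential`.
#' @export
delete_genes <- function(model, genes, medium = NULL, reference = NULL,
                         essentiality_threshold = 0.1) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  if (is.null(reference)) reference <- fba(model)
  if (reference$status != "optimal") stop("reference FBA is not optimal")
  disabled <- knockout_reactions(model, genes)
  growth <- NA_real_
  if (length(disabled) == 0L) {
    growth <- reference$objective
  } else {
    for (id in disabled) {
      model$reactions[[id]]$lower_bound <- 0
      model$reactions[[id]]$upper_bound <- 0
    }
    res <- fba(model)
    growth <- if (res$status == "optimal") res$objective else 0
  }
  ratio <- if (abs(reference$objective) > 1e-12) growth / reference$objective else 0
  structure(list(genes = genes, disabled_reactions = disabled,
                 growth = growth, reference_growth = reference$objective,
                 growth_ratio = ratio,
                 essential = ratio < essentiality_threshold,
                 essentiality_threshold = essentiality_threshold),
            class = "deletion_result")
}

#' Single-gene deletion screen
#'
#' @param model a `metabolic_model`.
#' @param genes gene ids (default: all model genes).
#' @param medium optional medium.
#' @inheritParams delete_genes
#' @return data.frame with columns `gene`, `growth`, `growth_ratio`,
#'   `essential`, `n_disabled`.
#' @export
single_deletions <- function(model, genes = NULL, medium = NULL,
                             essentiality_threshold = 0.1) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  if (is.null(genes)) genes <- model$genes
  ref <- fba(model)
  if (ref$status != "optimal") stop("reference FBA is not optimal")
  rows <- lapply(genes, function(g) {
    d <- delete_genes(model, g, reference = ref,
                      essentiality_threshold = essentiality_threshold)
    data.frame(gene = g, growth = d$growth, growth_ratio = d$growth_ratio,
               essential = d$essential,
               n_disabled = length(d$disabled_reactions),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default energy-dissipation currency specifications
#'
#' Builds dissipation pseudo-reactions for the classical energy currencies
#' (ATP, GTP, NADH, NADPH, FADH2 hydrolysis/oxidation in each compartment
#' where the species exist) and for the trans-mitochondrial proton
#' gradient (`h_c -> h_m`), keeping only those whose metabolites are all
#' present in the model.
#'
#' @param model a `metabolic_model`.
#' @return named list of stoichiometry vectors (metabolite id ->
#'   coefficient), one per currency.
#' @export
default_currencies <- function(model) {
  mets <- model$metabolites$id
  comps <- unique(model$metabolites$compartment)
  specs <- list()
  templates <- list(
    atp  = c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1),
    gtp  = c(gtp = -1, h2o = -1, gdp = 1, pi = 1, h = 1),
    nadh = c(nadh = -1, nad = 1, h = 1),
    nadph = c(nadph = -1, nadp = 1, h = 1),
    fadh2 = c(fadh2 = -1, fad = 1, h = 2)
  )
  for (comp in comps) {
    for (nm in names(templates)) {
      tm <- templates[[nm]]
      ids <- paste0(names(tm), "_", comp)
      if (all(ids %in% mets)) {
        specs[[paste0(nm, "_", comp)]] <- stats::setNames(as.numeric(tm), ids)
      }
    }
  }
  if (all(c("h_c", "h_m") %in% mets)) {
    specs[["proton_gradient_m"]] <- c(h_c = -1, h_m = 1)
  }
  specs
}

#' Detect energy-generating cycles by mixed-integer programming
#'
#' With every boundary reaction (exchange, demand, sink) closed, a sound
#' model can dissipate no energy currency at steady state.  For each
#' currency, the audit maximizes a dissipation pseudo-flux; if it exceeds
#' `flux_tol`, a thermodynamically impossible internal loop exists, and a
#' MIP minimizes the number of reactions with `|v| > eps` subject to
#' dissipation >= 1 (big-M linking), returning the minimal active set.
#' The network is first reduced by iterative connectivity pruning (with
#' boundaries closed, any metabolite lacking a possible producer or
#' consumer blocks its reactions), which leaves only reactions that can
#' participate in internal cycles and keeps the MIP small.
#'
#' @param model a `metabolic_model`.
#' @param currencies named list of dissipation stoichiometries; defaults
#'   to [default_currencies()].
#' @param eps activity threshold in the MIP linking constraints.
#' @param flux_tol dissipation considered zero below this.
#' @param time_limit MIP time limit per currency, seconds; on expiry the
#'   finding carries `proven = FALSE` ("minimality unproven").
#' @return list of `egc_finding`s: `currency`, `dissipation_flux`,
#'   `reactions` (minimal active set), `proven`.  Empty list if the model
#'   is clean.
#' @export
find_egc <- function(model, currencies = NULL, eps = 1e-4, flux_tol = 1e-6,
                     time_limit = 60) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.null(currencies)) currencies <- default_currencies(model)
  closed <- model
  for (id in reaction_ids(model, boundary_kinds())) {
    closed$reactions[[id]]$lower_bound <- 0
    closed$reactions[[id]]$upper_bound <- 0
  }
  findings <- list()
  for (nm in names(currencies)) {
    spec <- currencies[[nm]]
    if (!all(names(spec) %in% model$metabolites$id)) next
    m2 <- closed
    diss_id <- ".DISS"
    m2 <- add_reaction(m2, diss_id, spec, lower_bound = 0,
                       upper_bound = 1000, kind = "demand")
    red <- prune_blocked(m2, keep = diss_id)
    if (!diss_id %in% names(red$reactions)) next  # dissipation blocked: clean
    res <- fba(red, objective = diss_id, direction = "max")
    if (res$status != "optimal" || res$objective <= flux_tol) next
    # cardinality MIP on the reduced network; reactions that cannot carry
    # flux with dissipation >= 1 are dropped first (cheap FVA)
    red$reactions[[diss_id]]$lower_bound <- 1
    fv <- flux_variability(red, setdiff(names(red$reactions), diss_id))
    fixed0 <- fv$reaction[pmax(abs(fv$min), abs(fv$max)) < eps / 2]
    if (length(fixed0) > 0L) {
      red <- remove_reactions(red, fixed0, prune_metabolites = TRUE)
    }
    S <- stoichiometric_matrix(red)
    rxns <- colnames(S)
    cand <- setdiff(rxns, diss_id)
    n <- length(rxns); k <- length(cand)
    lbs <- vapply(red$reactions, function(r) r$lower_bound, numeric(1))[rxns]
    ubs <- vapply(red$reactions, function(r) r$upper_bound, numeric(1))[rxns]
    # variables: v (n), y (k binaries)
    nv <- n + k
    Aeq <- cbind(S, matrix(0, nrow(S), k))
    beq <- rep(0, nrow(S))
    ci <- match(cand, rxns)
    Ale <- matrix(0, 2 * k, nv); ble <- numeric(2 * k)
    for (j in seq_len(k)) {
      i <- ci[j]
      Ale[2 * j - 1, i] <- 1;  Ale[2 * j - 1, n + j] <- -ubs[i]  # v <= u y
      Ale[2 * j, i] <- -1;     Ale[2 * j, n + j] <- lbs[i]       # v >= l y
    }
    cvec <- c(rep(0, n), rep(1, k))
    lo <- c(lbs, rep(0, k)); hi <- c(ubs, rep(1, k))
    mip <- solve_milp(cvec, Aeq, beq, Ale, ble, lo, hi,
                      int_idx = n + seq_len(k), sense = "min",
                      time_limit = time_limit)
    if (mip$status != "optimal") next
    active <- cand[mip$x[n + seq_len(k)] > 0.5 &
                     abs(mip$x[ci]) > eps / 2]
    findings[[nm]] <- structure(list(
      currency = nm, dissipation_flux = res$objective,
      reactions = sort(active), proven = mip$proven), class = "egc_finding")
  }
  unname(findings)
}

# iteratively drop reactions blocked by connectivity: a metabolite with no
# possible producer or no possible consumer (honoring bound directions)
# blocks every reaction it touches
prune_blocked <- function(model, keep = character(0)) {
  repeat {
    rxns <- model$reactions
    if (length(rxns) == 0L) return(model)
    produced <- character(0); consumed <- character(0)
    for (r in rxns) {
      st <- r$stoichiometry
      fwd <- r$upper_bound > 1e-12; rev <- r$lower_bound < -1e-12
      if (fwd) {
        produced <- c(produced, names(st)[st > 0])
        consumed <- c(consumed, names(st)[st < 0])
      }
      if (rev) {
        produced <- c(produced, names(st)[st < 0])
        consumed <- c(consumed, names(st)[st > 0])
      }
    }
    used <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
    bad_mets <- used[!(used %in% produced) | !(used %in% consumed)]
    drop <- names(rxns)[vapply(rxns, function(r) {
      any(names(r$stoichiometry) %in% bad_mets) ||
        (r$upper_bound <= 1e-12 && r$lower_bound >= -1e-12)
    }, logical(1))]
    drop <- setdiff(drop, keep)
    if (length(drop) == 0L) return(model)
    model <- remove_reactions(model, drop, prune_metabolites = TRUE)
    if (!all(keep %in% names(model$reactions))) return(model)
  }
}
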