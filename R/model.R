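#' Construct an empty constraint-based metabolic model
#'
#' The model is the central object of the package: a set of
#' compartmentalized metabolites, reactions with bounds and GPR rules, a
#' gene list, and an objective.  Metabolite ids follow the BiGG-style
#' convention of a base id plus `"_"` plus a compartment token
#' (e.g. `"glc__D_c"`).
#'
#' @param id model identifier.
#' @param compartments named character vector, token -> descriptive name
#'   (e.g. `c(c = "cytosol", m = "mitochondrion")`).
#' @return an object of class `metabolic_model`.
#' @export
new_model <- function(id, compartments = c(c = "cytosol")) {
  stopifnot(is.character(id), length(id) == 1L)
  if (is.null(names(compartments)) || any(!nzchar(names(compartments)))) {
    stop("compartments must be a named character vector (token -> name)")
  }
  structure(list(
    id = id,
    compartments = compartments,
    metabolites = data.frame(id = character(0), name = character(0),
                             formula = character(0), charge = integer(0),
                             compartment = character(0),
                             stringsAsFactors = FALSE),
    reactions = list(),
    genes = character(0),
    objective = NULL
  ), class = "metabolic_model")
}

#' Add a metabolite to a model
#'
#' @param model a `metabolic_model`.
#' @param id metabolite id (compartment-suffixed token).
#' @param name free-text name.
#' @param formula empirical formula string (may use pseudo-elements R/X);
#'   `NA` if unknown.
#' @param charge integer charge; `NA` if unknown.
#' @param compartment compartment token; must be declared in the model.
#'   Defaults to the suffix after the last `"_"` of `id`.
#' @return the updated model.
#' @export
add_metabolite <- function(model, id, name = id, formula = NA_character_,
                           charge = NA_integer_, compartment = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.null(compartment)) compartment <- sub("^.*_", "", id)
  if (!compartment %in% names(model$compartments)) {
    stop(sprintf("metabolite '%s': compartment '%s' not declared in model '%s'",
                 id, compartment, model$id))
  }
  if (id %in% model$metabolites$id) {
    stop(sprintf("duplicate metabolite id '%s'", id))
  }
  if (!is.na(formula)) parse_formula(formula)  # validate grammar eagerly
  model$metabolites <- rbind(model$metabolites, data.frame(
    id = id, name = name, formula = formula,
    charge = as.integer(charge), compartment = compartment,
    stringsAsFactors = FALSE))
  model
}

#' Add a reaction to a model
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param stoichiometry named numeric vector, metabolite id -> coefficient
#'   (negative = consumed).  Must be nonempty except for declared
#'   `exchange`/`demand`/`sink` reactions (which have exactly one entry) --
#'   empty stoichiometry is rejected for every kind.
#' @param lower_bound,upper_bound flux bounds in mmol/gDW/h.
#' @param gpr a GPR string (parsed with [parse_gpr()]) or a `gpr` object.
#' @param name free-text name.
#' @param subsystem free-text subsystem label.
#' @param kind one of `"metabolic"`, `"exchange"`, `"transport"`,
#'   `"demand"`, `"sink"`, `"biomass"`.
#' @return the updated model.  Genes named in the GPR are added to the
#'   model gene list.
#' @export
add_reaction <- function(model, id, stoichiometry,
                         lower_bound = 0, upper_bound = 1000,
                         gpr = NULL, name = id, subsystem = "",
                         kind = c("metabolic", "exchange", "transport",
                                  "demand", "sink", "biomass")) {
  stopifnot(inherits(model, "metabolic_model"))
  kind <- match.arg(kind)
  if (id %in% names(model$reactions)) {
    stop(sprintf("duplicate reaction id '%s'", id))
  }
  if (lower_bound > upper_bound) {
    stop(sprintf("reaction '%s': lower_bound > upper_bound", id))
  }
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (length(stoichiometry) == 0L) {
    stop(sprintf("reaction '%s': empty stoichiometry", id))
  }
  missing <- setdiff(names(stoichiometry), model$metabolites$id)
  if (length(missing) > 0L) {
    stop(sprintf("reaction '%s' cites undeclared metabolite(s): %s",
                 id, paste(missing, collapse = ", ")))
  }
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  model$genes <- union(model$genes, gpr_genes(gpr))
  model$reactions[[id]] <- list(
    id = id, name = name, stoichiometry = stoichiometry,
    lower_bound = lower_bound, upper_bound = upper_bound,
    gpr = gpr, subsystem = subsystem, kind = kind)
  model
}

#' Remove reactions (and optionally orphaned metabolites) from a model
#' @param model a `metabolic_model`.
#' @param ids reaction ids to remove.
#' @param prune_metabolites drop metabolites no longer used by any reaction.
#' @return the updated model.
#' @export
remove_reactions <- function(model, ids, prune_metabolites = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  unknown <- setdiff(ids, names(model$reactions))
  if (length(unknown) > 0L) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  }
  model$reactions[ids] <- NULL
  if (!is.null(model$objective) && model$objective$reaction %in% ids) {
    model$objective <- NULL
  }
  if (prune_metabolites) {
    used <- unique(unlist(lapply(model$reactions, function(r) names(r$stoichiometry))))
    model$metabolites <- model$metabolites[model$metabolites$id %in% used, ,
                                           drop = FALSE]
  }
  model
}

#' Set the model objective
#' @param model a `metabolic_model`.
#' @param reaction objective reaction id (must exist).
#' @param direction `"max"` or `"min"`.
#' @return the updated model.
#' @export
set_objective <- function(model, reaction, direction = c("max", "min")) {
  stopifnot(inherits(model, "metabolic_model"))
  direction <- match.arg(direction)
  if (!reaction %in% names(model$reactions)) {
    stop(sprintf("objective reaction '%s' not in model", reaction))
  }
  model$objective <- list(reaction = reaction, direction = direction)
  model
}

#' Set flux bounds on a reaction
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lower_bound,upper_bound new bounds; `NULL` leaves a bound as is.
#' @return the updated model.
#' @export
set_bounds <- function(model, id, lower_bound = NULL, upper_bound = NULL) {
  if (!id %in% names(model$reactions)) stop(sprintf("unknown reaction '%s'", id))
  if (!is.null(lower_bound)) model$reactions[[id]]$lower_bound <- lower_bound
  if (!is.null(upper_bound)) model$reactions[[id]]$upper_bound <- upper_bound
  r <- model$reactions[[id]]
  if (r$lower_bound > r$upper_bound) stop(sprintf("reaction '%s': lower_bound > upper_bound", id))
  model
}

#' Reaction ids of a model, optionally filtered by kind
#' @param model a `metabolic_model`.
#' @param kind optional kind filter (see [add_reaction()]).
#' @return character vector of reaction ids.
#' @export
reaction_ids <- function(model, kind = NULL) {
  ids <- names(model$reactions)
  if (is.null(kind)) return(ids)
  ids[vapply(model$reactions, function(r) r$kind %in% kind, logical(1))]
}

# boundary reactions are exempt from mass/charge balance and are the ones
# closed during an energy-generating-cycle audit
boundary_kinds <- function() c("exchange", "demand", "sink")

#' Assemble the stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @return a dense numeric matrix with one row per metabolite (rownames =
#'   metabolite ids) and one column per reaction (colnames = reaction ids).
#' @export
stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites$id
  rxns <- names(model$reactions)
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

#' Validate a model's structural invariants
#'
#' Checks id uniqueness, referential integrity of stoichiometries and GPR
#' genes, declared compartments, bound ordering, and that the objective
#' reaction exists.
#'
#' @param model a `metabolic_model`.
#' @return invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (anyDuplicated(model$metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(model$metabolites$id[duplicated(model$metabolites$id)]),
               collapse = ", "))
  }
  if (anyDuplicated(names(model$reactions))) stop("duplicate reaction ids")
  bad_comp <- setdiff(unique(model$metabolites$compartment),
                      names(model$compartments))
  if (length(bad_comp) > 0L) {
    stop("undeclared compartment(s): ", paste(bad_comp, collapse = ", "))
  }
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoichiometry), model$metabolites$id)
    if (length(missing) > 0L) {
      stop(sprintf("reaction '%s' cites undeclared metabolite(s): %s",
                   r$id, paste(missing, collapse = ", ")))
    }
    if (r$lower_bound > r$upper_bound) {
      stop(sprintf("reaction '%s': lower_bound > upper_bound", r$id))
    }
    gg <- gpr_genes(r$gpr)
    if (!all(gg %in% model$genes)) {
      stop(sprintf("reaction '%s': GPR gene(s) missing from gene list", r$id))
    }
  }
  if (!is.null(model$objective) &&
      !model$objective$reaction %in% names(model$reactions)) {
    stop("objective reaction not in model")
  }
  invisible(TRUE)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions, %d genes, %d compartments\n",
              x$id, nrow(x$metabolites), length(x$reactions),
              length(x$genes), length(x$compartments)))
  if (!is.null(x$objective)) {
    cat(sprintf("  objective: %s (%s)\n", x$objective$reaction, x$objective$direction))
  }
  invisible(x)
}
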