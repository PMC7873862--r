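#' Read or write a model in the BiGG-like JSON dialect
#'
#' The dialect has top-level entries `metabolites`, `reactions`, `genes`,
#' `compartments` and `objective`; GPR rules are stored as strings under
#' `gene_reaction_rule`.  Files written here carry per-reaction
#' `objective_coefficient` fields as well, so they load unchanged into
#' other constraint-based modeling toolchains that expect them.  Reaction
#' kinds are kept under `notes$kind`; on read, missing kinds are inferred
#' from id conventions (`EX_`/`DM_`/`SK_` prefixes, single-metabolite
#' boundary columns, `biomass` in the id).
#'
#' `read_model()`/`write_model()` dispatch on `dialect`.
#'
#' @param path file path.
#' @param dialect `"json"` or `"sbml"`.
#' @return `read_model()` returns a `metabolic_model`; `write_model()`
#'   returns the path invisibly.
#' @seealso [write_model_sbml()] for the SBML L3/FBC subset.
#' @export
read_model <- function(path, dialect = c("json", "sbml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(dialect, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' @rdname read_model
#' @param model a `metabolic_model`.
#' @export
write_model <- function(model, path, dialect = c("json", "sbml")) {
  dialect <- match.arg(dialect)
  switch(dialect, json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

infer_reaction_kind <- function(id, stoich) {
  if (length(stoich) == 1L) {
    if (grepl("^EX_", id)) return("exchange")
    if (grepl("^DM_", id)) return("demand")
    if (grepl("^(SK_|sink_)", id)) return("sink")
    return("exchange")
  }
  if (grepl("biomass", id, ignore.case = TRUE)) return("biomass")
  "metabolic"
}

read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  comps <- unlist(doc$compartments)
  if (is.null(comps)) stop("model JSON: missing 'compartments'")
  model <- new_model(id = doc$id %||% "model", compartments = comps)
  for (m in doc$metabolites) {
    if (is.null(m$id)) stop("model JSON: metabolite record without id")
    model <- add_metabolite(model, id = m$id, name = m$name %||% m$id,
                            formula = m$formula %||% NA_character_,
                            charge = m$charge %||% NA_integer_,
                            compartment = m$compartment %||% NULL)
  }
  obj_rxn <- NULL
  for (r in doc$reactions) {
    if (is.null(r$id)) stop("model JSON: reaction record without id")
    st <- unlist(r$metabolites)
    if (is.null(st)) {
      stop(sprintf("model JSON: reaction '%s' has no stoichiometry", r$id))
    }
    kind <- r$notes$kind %||% infer_reaction_kind(r$id, st)
    model <- add_reaction(model, id = r$id, stoichiometry = st,
                          lower_bound = r$lower_bound %||% 0,
                          upper_bound = r$upper_bound %||% 1000,
                          gpr = r$gene_reaction_rule %||% NULL,
                          name = r$name %||% r$id,
                          subsystem = r$subsystem %||% "",
                          kind = kind)
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0) {
      obj_rxn <- r$id
    }
  }
  for (g in doc$genes) model$genes <- union(model$genes, g$id)
  if (!is.null(doc$objective)) {
    model <- set_objective(model, doc$objective$reaction,
                           doc$objective$direction %||% "max")
  } else if (!is.null(obj_rxn)) {
    model <- set_objective(model, obj_rxn)
  }
  validate_model(model)
  model
}

write_model_json <- function(model, path) {
  validate_model(model)
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  obj_id <- if (is.null(model$objective)) NA_character_ else model$objective$reaction
  rxns <- lapply(model$reactions, function(r) {
    list(id = r$id, name = r$name,
         metabolites = as.list(r$stoichiometry),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gene_reaction_rule = gpr_to_string(r$gpr),
         subsystem = r$subsystem,
         objective_coefficient = if (!is.na(obj_id) && r$id == obj_id) 1 else 0,
         notes = list(kind = r$kind))
  })
  genes <- lapply(model$genes, function(g) list(id = g, name = g))
  doc <- list(id = model$id, version = "1",
              compartments = as.list(model$compartments),
              metabolites = mets,
              reactions = unname(rxns),
              genes = genes)
  if (!is.null(model$objective)) doc$objective <- model$objective
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
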