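#' Ortholog map between donor organisms and the target organism
#'
#' An ortholog map is a set of groups, each linking genes across
#' organisms; within the reconstruction it drives reaction transfer: a
#' donor gene maps to the set of target-organism genes sharing its group.
#' A (organism, gene) pair may appear in at most one group.
#'
#' @param groups data.frame with columns `group_id`, `organism`, `gene_id`.
#' @param target_organism organism token identifying the target.
#' @return an `ortholog_map` object.
#' @export
ortholog_map <- function(groups, target_organism) {
  stopifnot(all(c("group_id", "organism", "gene_id") %in% names(groups)))
  key <- paste(groups$organism, groups$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- groups[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("(organism, gene) pair in more than one group: %s/%s",
                 dup$organism, dup$gene_id))
  }
  structure(list(groups = groups, target_organism = target_organism),
            class = "ortholog_map")
}

#' Read an ortholog map from TSV
#' @param path TSV with columns `group_id`, `organism`, `gene_id`.
#' @param target_organism organism token identifying the target.
#' @return an `ortholog_map`.
#' @export
read_ortholog_map <- function(path, target_organism) {
  ortholog_map(utils::read.delim(path, stringsAsFactors = FALSE),
               target_organism)
}

#' Target-organism orthologs of a donor gene
#' @param omap an `ortholog_map`.
#' @param organism donor organism token.
#' @param gene donor gene id.
#' @return character vector of target gene ids (possibly empty).
#' @export
ortholog_lookup <- function(omap, organism, gene) {
  g <- omap$groups
  grp <- g$group_id[g$organism == organism & g$gene_id == gene]
  if (length(grp) == 0L) return(character(0))
  sort(unique(g$gene_id[g$group_id %in% grp &
                          g$organism == omap$target_organism]))
}

new_transfer_log <- function() {
  data.frame(donor_model = character(0), donor_reaction_id = character(0),
             action = character(0), detail = character(0),
             stringsAsFactors = FALSE)
}

log_row <- function(log, donor, rid, action, detail = "") {
  rbind(log, data.frame(donor_model = donor, donor_reaction_id = rid,
                        action = action, detail = detail,
                        stringsAsFactors = FALSE))
}

#' Transfer reactions from donor models through an ortholog map
#'
#' A donor reaction is carried into the draft iff at least one gene in its
#' GPR maps to at least one target gene.  Mappable GPR leaves are replaced
#' by the OR of their target co-orthologs (isozyme semantics: ortholog
#' groups mix orthologs and recent paralogs); unmapped leaves are kept,
#' namespaced `"organism:gene"`, for [resolve_unmapped()] to settle.
#' Metabolites come along with formula, charge and compartment.
#' Reactions with an empty donor GPR (spontaneous/orphan) are never
#' auto-transferred; they are logged `skipped_no_ortholog` and surface in
#' the candidate-orphan list for manual opt-in.  Structural duplicates
#' across donors collapse onto the first-transferred copy (first donor in
#' the given order wins metadata conflicts; the collapse is logged).
#'
#' @param donors named list of donor `metabolic_model`s; names are the
#'   donor organism tokens used in the ortholog map.
#' @param omap an `ortholog_map` covering the donor organisms.
#' @param draft_id id for the draft model.
#' @return list with `draft` (a `metabolic_model`), `log` (the transfer
#'   log data.frame), and `orphans` (data.frame of donor reactions with
#'   empty GPRs, for manual opt-in).
#' @export
transfer_reactions <- function(donors, omap, draft_id = "draft") {
  stopifnot(inherits(omap, "ortholog_map"))
  if (is.null(names(donors)) || any(!nzchar(names(donors)))) {
    stop("donors must be a named list (organism -> model)")
  }
  absent <- setdiff(names(donors), unique(omap$groups$organism))
  if (length(absent) > 0L) {
    stop("donor organism(s) absent from ortholog map: ",
         paste(absent, collapse = ", "))
  }
  comp_union <- list()
  for (d in donors) for (i in seq_along(d$compartments)) {
    comp_union[[names(d$compartments)[i]]] <- d$compartments[[i]]
  }
  draft <- new_model(draft_id, unlist(comp_union))
  log <- new_transfer_log()
  orphans <- data.frame(donor_model = character(0), reaction_id = character(0),
                        stringsAsFactors = FALSE)
  seen_sig <- character(0)
  for (org in names(donors)) {
    donor <- donors[[org]]
    # per-donor cache of ortholog lookups
    lookup <- new.env(parent = emptyenv())
    map_gene <- function(g) {
      if (is.null(lookup[[g]])) lookup[[g]] <- ortholog_lookup(omap, org, g)
      lookup[[g]]
    }
    for (r in donor$reactions) {
      if (r$kind %in% c(boundary_kinds(), "biomass")) {
        log <- log_row(log, org, r$id, "skipped_no_ortholog", "boundary/biomass")
        next
      }
      genes <- gpr_genes(r$gpr)
      if (length(genes) == 0L) {
        log <- log_row(log, org, r$id, "skipped_no_ortholog", "empty GPR")
        orphans <- rbind(orphans, data.frame(donor_model = org,
                                             reaction_id = r$id,
                                             stringsAsFactors = FALSE))
        next
      }
      maps <- lapply(genes, map_gene)
      names(maps) <- genes
      if (all(vapply(maps, length, integer(1)) == 0L)) {
        log <- log_row(log, org, r$id, "skipped_no_ortholog", "no mapped gene")
        next
      }
      subst <- lapply(maps, function(tg) if (length(tg) == 0L) NULL else tg)
      new_gpr <- gpr_substitute(r$gpr, subst)
      # leaves that stayed unmapped get donor namespacing
      unmapped <- genes[vapply(maps, length, integer(1)) == 0L]
      if (length(unmapped) > 0L) {
        ns <- stats::setNames(as.list(paste0(org, ":", unmapped)), unmapped)
        new_gpr <- gpr_substitute(new_gpr, ns)
      }
      sig <- reaction_signature(r$stoichiometry)$key
      if (sig %in% seen_sig) {
        # structural duplicate of an already-transferred reaction: merge GPR
        existing <- names(which(vapply(draft$reactions, function(x) {
          reaction_signature(x$stoichiometry)$key == sig
        }, logical(1))))[1]
        merged <- gpr_from_dnf(c(gpr_dnf(draft$reactions[[existing]]$gpr),
                                 gpr_dnf(new_gpr)))
        draft$genes <- union(draft$genes, gpr_genes(merged))
        draft$reactions[[existing]]$gpr <- merged
        log <- log_row(log, org, r$id, "transferred",
                       sprintf("collapsed into %s (duplicate)", existing))
        next
      }
      for (mid in names(r$stoichiometry)) {
        if (!mid %in% draft$metabolites$id) {
          m <- donor$metabolites[donor$metabolites$id == mid, ]
          draft <- add_metabolite(draft, mid, m$name, m$formula, m$charge,
                                  m$compartment)
        }
      }
      rid <- r$id
      if (rid %in% names(draft$reactions)) {
        # same id, different structure: first donor won; log the conflict
        log <- log_row(log, org, r$id, "skipped_no_ortholog",
                       "id conflict with earlier donor (first donor wins)")
        next
      }
      draft <- add_reaction(draft, rid, r$stoichiometry,
                            lower_bound = r$lower_bound,
                            upper_bound = r$upper_bound,
                            gpr = new_gpr, name = r$name,
                            subsystem = r$subsystem, kind = r$kind)
      seen_sig <- c(seen_sig, sig)
      log <- log_row(log, org, r$id, "transferred",
                     if (length(unmapped) > 0L)
                       paste("unmapped:", paste(unmapped, collapse = ","))
                     else "")
    }
  }
  list(draft = draft, log = log, orphans = orphans)
}

#' Resolve donor genes with no target ortholog
#'
#' Applies the isozyme/complex rule on the disjunctive normal form of each
#' GPR: an AND-clause containing an unmapped (donor-namespaced) gene is an
#' enzyme complex missing a subunit and is dropped; if at least one fully
#' mapped clause survives (an isozyme exists) the reaction is kept with
#' the pruned rule, otherwise the reaction is removed.  Equivalently, a
#' reaction survives iff its GPR has a satisfying assignment using mapped
#' genes only.  Idempotent; the result contains no donor-namespaced genes.
#'
#' @param draft a draft `metabolic_model` from [transfer_reactions()].
#' @param log the transfer log to append to.
#' @return list with `model` and `log`.
#' @export
resolve_unmapped <- function(draft, log = new_transfer_log()) {
  is_unmapped <- function(g) grepl(":", g, fixed = TRUE)
  to_remove <- character(0)
  for (rid in names(draft$reactions)) {
    gpr <- draft$reactions[[rid]]$gpr
    genes <- gpr_genes(gpr)
    if (!any(is_unmapped(genes))) next
    clauses <- gpr_dnf(gpr)
    keepable <- clauses[!vapply(clauses, function(cl) any(is_unmapped(cl)),
                                logical(1))]
    if (length(keepable) > 0L) {
      draft$reactions[[rid]]$gpr <- gpr_from_dnf(keepable)
      log <- log_row(log, draft$id, rid, "gpr_pruned",
                     sprintf("dropped %d complex branch(es) with unmapped subunits",
                             length(clauses) - length(keepable)))
    } else {
      to_remove <- c(to_remove, rid)
      log <- log_row(log, draft$id, rid, "removed_complex",
                     "all branches require an unmapped subunit")
    }
  }
  if (length(to_remove) > 0L) {
    draft <- remove_reactions(draft, to_remove, prune_metabolites = TRUE)
  }
  draft$genes <- sort(setdiff(
    unique(unlist(lapply(draft$reactions, function(r) gpr_genes(r$gpr)))),
    character(0)))
  list(model = draft, log = log)
}

#' Assign or relocate reactions to target-organism compartments
#'
#' Applies a relocation rule table (selector = reaction id or subsystem,
#' `from` compartment, `to` compartment): matched reactions have every
#' metabolite's compartment suffix rewritten.  Reactions left in
#' compartments the target organism does not declare are then relocated
#' via the localization table (first allowed declared compartment of any
#' associated gene) or removed.  Relocations that create a structural
#' duplicate collapse onto the existing copy.
#'
#' @param model a `metabolic_model`.
#' @param localization optional data.frame with columns `gene_id`,
#'   `compartments` (comma-separated tokens).
#' @param rules optional data.frame with columns `selector`, `from`, `to`.
#' @param target_compartments compartment tokens of the target organism;
#'   defaults to all compartments declared on `model`.
#' @return list with `model` and `log` (data.frame of actions).
#' @export
assign_compartments <- function(model, localization = NULL, rules = NULL,
                                target_compartments = NULL) {
  log <- new_transfer_log()
  declared <- target_compartments %||% names(model$compartments)
  relocate <- function(model, rid, from, to) {
    if (!to %in% declared) {
      stop(sprintf("relocation of '%s' to undeclared compartment '%s'", rid, to))
    }
    r <- model$reactions[[rid]]
    st <- r$stoichiometry
    new_ids <- names(st)
    suffix <- paste0("_", from)
    hit <- endsWith(new_ids, suffix)
    new_ids[hit] <- paste0(substr(new_ids[hit], 1,
                                  nchar(new_ids[hit]) - nchar(suffix)),
                           "_", to)
    for (i in which(hit)) {
      if (!new_ids[i] %in% model$metabolites$id) {
        old <- model$metabolites[model$metabolites$id == names(st)[i], ]
        model <- add_metabolite(model, new_ids[i], old$name, old$formula,
                                old$charge, to)
      }
    }
    names(st) <- new_ids
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))
    st <- st[abs(st) > 1e-12]
    model$reactions[[rid]]$stoichiometry <- st
    model
  }
  if (!is.null(rules) && nrow(rules) > 0L) {
    for (rid in names(model$reactions)) {
      r <- model$reactions[[rid]]
      comps <- unique(sub("^.*_", "", names(r$stoichiometry)))
      for (i in seq_len(nrow(rules))) {
        sel <- rules$selector[i]
        if ((sel == rid || sel == r$subsystem) && rules$from[i] %in% comps) {
          model <- relocate(model, rid, rules$from[i], rules$to[i])
          log <- log_row(log, model$id, rid, "transferred",
                         sprintf("relocated %s -> %s", rules$from[i], rules$to[i]))
          break
        }
      }
    }
  }
  # reactions still in undeclared compartments: localization or removal
  loc_lookup <- NULL
  if (!is.null(localization) && nrow(localization) > 0L) {
    loc_lookup <- stats::setNames(
      lapply(strsplit(localization$compartments, ","), trimws),
      localization$gene_id)
  }
  to_remove <- character(0)
  for (rid in names(model$reactions)) {
    comps <- unique(sub("^.*_", "", names(model$reactions[[rid]]$stoichiometry)))
    bad <- setdiff(comps, declared)
    if (length(bad) == 0L) next
    moved <- FALSE
    if (!is.null(loc_lookup)) {
      genes <- gpr_genes(model$reactions[[rid]]$gpr)
      allowed <- intersect(unique(unlist(loc_lookup[genes])), declared)
      if (length(allowed) > 0L) {
        for (b in bad) model <- relocate(model, rid, b, allowed[1])
        log <- log_row(log, model$id, rid, "transferred",
                       sprintf("localization-relocated %s -> %s",
                               paste(bad, collapse = ","), allowed[1]))
        moved <- TRUE
      }
    }
    if (!moved) {
      to_remove <- c(to_remove, rid)
      log <- log_row(log, model$id, rid, "removed_complex",
                     sprintf("undeclared compartment(s): %s",
                             paste(bad, collapse = ",")))
    }
  }
  if (length(to_remove) > 0L) {
    model <- remove_reactions(model, to_remove, prune_metabolites = TRUE)
  }
  # collapse duplicates created by relocation
  dd <- dedup_reactions(model)
  if (nrow(dd$log) > 0L) {
    for (i in seq_len(nrow(dd$log))) {
      log <- log_row(log, model$id, dd$log$dropped[i], "transferred",
                     sprintf("relocation duplicate collapsed into %s",
                             dd$log$kept[i]))
    }
  }
  # drop metabolites in undeclared compartments that no reaction uses
  used <- unique(unlist(lapply(dd$model$reactions,
                               function(r) names(r$stoichiometry))))
  keep <- dd$model$metabolites$id %in% used |
    dd$model$metabolites$compartment %in% declared
  dd$model$metabolites <- dd$model$metabolites[keep, , drop = FALSE]
  dd$model$compartments <-
    dd$model$compartments[names(dd$model$compartments) %in%
                            union(declared,
                                  unique(dd$model$metabolites$compartment))]
  list(model = dd$model, log = log)
}
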