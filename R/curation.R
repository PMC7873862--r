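#' Canonical stoichiometry signature of a reaction
#'
#' Two reactions are structural duplicates iff they share this signature:
#' metabolite ids sorted, coefficients scaled so that the
#' lexicographically-smallest participating id has coefficient -1
#' (direction-normalized, so a reversible reaction written in either
#' direction gets the same signature).  In a pure-production or
#' pure-consumption reaction, where all coefficients share one sign, the
#' anchor takes +1 instead so the signature stays sign-deterministic.
#'
#' @param stoichiometry named numeric vector (metabolite id -> coefficient).
#' @return list with `key` (a signature string) and `scale` (the factor by
#'   which the input was multiplied to reach canonical form).
#' @export
reaction_signature <- function(stoichiometry) {
  st <- stoichiometry[stoichiometry != 0]
  if (length(st) == 0L) return(list(key = "", scale = 1))
  st <- st[order(names(st))]
  anchor <- st[[1]]
  one_sign <- all(st > 0) || all(st < 0)
  scale <- if (one_sign) 1 / abs(anchor) else -1 / anchor
  st <- st * scale
  key <- paste(sprintf("%s:%.10g", names(st), st), collapse = ";")
  list(key = key, scale = scale)
}

normalize_name_token <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Find candidate duplicate metabolites
#'
#' Candidates share the dedup key (canonical formula, charge, compartment)
#' or are listed in an alias table of known synonym id pairs (the
#' ficytc/ficytC situation in public reaction databases).  Exact-key
#' matches are ranked first, with pairs also sharing a normalized name
#' token at the top; name similarity is never used to match on its own.
#' Metabolites lacking a formula or charge are only matched via the alias
#' table.
#'
#' @param model a `metabolic_model`.
#' @param alias_table optional data.frame with columns `keep_id`,
#'   `drop_id` (and optionally `evidence`).
#' @return data.frame with columns `a`, `b`, `basis` (`"key"` or
#'   `"alias"`), `same_name_token`; zero rows if nothing is suspect.
#' @export
find_duplicate_metabolites <- function(model, alias_table = NULL) {
  met <- model$metabolites
  out <- data.frame(a = character(0), b = character(0), basis = character(0),
                    same_name_token = logical(0), stringsAsFactors = FALSE)
  keyed <- met[!is.na(met$formula) & !is.na(met$charge), , drop = FALSE]
  if (nrow(keyed) > 1L) {
    key <- paste(vapply(keyed$formula, function(f) format_formula(parse_formula(f)),
                        character(1)),
                 keyed$charge, keyed$compartment, sep = "|")
    for (k in unique(key[duplicated(key)])) {
      ids <- keyed$id[key == k]
      pairs <- utils::combn(sort(ids), 2)
      for (p in seq_len(ncol(pairs))) {
        a <- pairs[1, p]; b <- pairs[2, p]
        tok <- normalize_name_token(met$name[met$id == a]) ==
               normalize_name_token(met$name[met$id == b])
        out <- rbind(out, data.frame(a = a, b = b, basis = "key",
                                     same_name_token = tok,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(alias_table) && nrow(alias_table) > 0L) {
    for (i in seq_len(nrow(alias_table))) {
      a <- alias_table$keep_id[i]; b <- alias_table$drop_id[i]
      if (!all(c(a, b) %in% met$id)) next
      already <- any(out$a == min(a, b) & out$b == max(a, b))
      if (already) next
      tok <- normalize_name_token(met$name[met$id == a]) ==
             normalize_name_token(met$name[met$id == b])
      out <- rbind(out, data.frame(a = min(a, b), b = max(a, b),
                                   basis = "alias", same_name_token = tok,
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$basis != "key", !out$same_name_token), , drop = FALSE]
}

#' Merge two duplicate metabolites
#'
#' Rewrites every stoichiometric reference to `drop_id` as `keep_id`
#' (coefficients on the same metabolite summed; zero-sum entries deleted),
#' removes `drop_id`, and flags any reaction whose canonical signature now
#' duplicates another's.  Reactions whose stoichiometry cancels away
#' entirely are removed.
#'
#' @param model a `metabolic_model`.
#' @param keep_id,drop_id metabolite ids in the same compartment.
#' @return list with `model`, `flagged_duplicates` (reaction ids whose
#'   signature now collides), `removed_reactions`.
#' @export
merge_metabolites <- function(model, keep_id, drop_id) {
  met <- model$metabolites
  for (id in c(keep_id, drop_id)) {
    if (!id %in% met$id) stop(sprintf("metabolite '%s' not in model", id))
  }
  ck <- met$compartment[met$id == keep_id]
  cd <- met$compartment[met$id == drop_id]
  if (ck != cd) {
    stop(sprintf("cross-compartment merge %s (%s) <- %s (%s): relocate first",
                 keep_id, ck, drop_id, cd))
  }
  removed <- character(0)
  for (rid in names(model$reactions)) {
    st <- model$reactions[[rid]]$stoichiometry
    if (!drop_id %in% names(st)) next
    add <- st[[drop_id]]
    st <- st[names(st) != drop_id]
    st[keep_id] <- (if (keep_id %in% names(st)) st[[keep_id]] else 0) + add
    st <- st[abs(st) > 1e-12]
    if (length(st) == 0L) {
      removed <- c(removed, rid)
    } else {
      model$reactions[[rid]]$stoichiometry <- st
    }
  }
  if (length(removed) > 0L) model <- remove_reactions(model, removed)
  model$metabolites <- met[met$id != drop_id, , drop = FALSE]
  keys <- vapply(model$reactions,
                 function(r) reaction_signature(r$stoichiometry)$key,
                 character(1))
  flagged <- names(keys)[keys %in% keys[duplicated(keys)]]
  list(model = model, flagged_duplicates = sort(flagged),
       removed_reactions = removed)
}

#' Find groups of duplicate reactions
#'
#' Groups reactions sharing the canonical stoichiometry signature
#' (see [reaction_signature()]).  Boundary reactions (exchange, demand,
#' sink) are grouped separately from internal reactions so an accumulation
#' demand never collides with a mobilization sink.
#'
#' @param model a `metabolic_model`.
#' @return list of character vectors (reaction ids), one per duplicate
#'   group; empty list if all signatures are distinct.
#' @export
find_duplicate_reactions <- function(model) {
  rxns <- model$reactions
  if (length(rxns) == 0L) return(list())
  keys <- vapply(rxns, function(r) {
    paste0(if (r$kind %in% boundary_kinds()) paste0(r$kind, "|") else "",
           reaction_signature(r$stoichiometry)$key)
  }, character(1))
  dup_keys <- unique(keys[duplicated(keys)])
  lapply(dup_keys, function(k) sort(names(keys)[keys == k]))
}

#' Collapse duplicate reactions
#'
#' For every duplicate group, keeps the lexicographically-smallest id,
#' unions the GPRs with OR (conservative retention of capability), and
#' takes the widest bounds after aligning each duplicate's orientation and
#' scale to the kept reaction.
#'
#' @param model a `metabolic_model`.
#' @return list with `model` and `log`, a data.frame recording each drop
#'   (`operation`, `kept`, `dropped`, `detail`).
#' @export
dedup_reactions <- function(model) {
  groups <- find_duplicate_reactions(model)
  log <- data.frame(operation = character(0), kept = character(0),
                    dropped = character(0), detail = character(0),
                    stringsAsFactors = FALSE)
  for (grp in groups) {
    keep <- grp[1]
    rk <- model$reactions[[keep]]
    sk <- reaction_signature(rk$stoichiometry)
    lb <- rk$lower_bound; ub <- rk$upper_bound
    gprs <- list(rk$gpr)
    for (dup in grp[-1]) {
      rd <- model$reactions[[dup]]
      sd <- reaction_signature(rd$stoichiometry)
      # v_keep-equivalent of dup's bounds: stoich_dup = stoich_keep*(sk/sd)
      alpha <- sk$scale / sd$scale
      bd <- sort(c(rd$lower_bound / alpha, rd$upper_bound / alpha))
      lb <- min(lb, bd[1]); ub <- max(ub, bd[2])
      gprs <- c(gprs, list(rd$gpr))
      log <- rbind(log, data.frame(operation = "dedup_reaction", kept = keep,
                                   dropped = dup,
                                   detail = sprintf("scale %.6g", alpha),
                                   stringsAsFactors = FALSE))
    }
    gprs <- gprs[!vapply(gprs, is.null, logical(1))]
    merged_gpr <- if (length(gprs) == 0L) NULL else {
      gpr_from_dnf(do.call(c, lapply(gprs, gpr_dnf)))
    }
    model$reactions[[keep]]$lower_bound <- lb
    model$reactions[[keep]]$upper_bound <- ub
    model$reactions[[keep]]$gpr <- merged_gpr
    model <- remove_reactions(model, grp[-1])
  }
  list(model = model, log = log)
}

#' Dead-end metabolite report
#'
#' Classifies metabolites from the stoichiometric sparsity pattern with
#' reversibility honored: a metabolite some reaction can produce but none
#' can consume is `only-produced`; the converse is `only-consumed`; a
#' metabolite no open reaction touches is `disconnected`.  Boundary
#' reactions count as producers/consumers, so a fully exchanged model
#' reports nothing.
#'
#' @param model a `metabolic_model`.
#' @return data.frame with columns `metabolite`, `role`; zero rows when
#'   the network has no dead ends.
#' @export
dead_end_report <- function(model) {
  mets <- model$metabolites$id
  produced <- character(0); consumed <- character(0); touched <- character(0)
  for (r in model$reactions) {
    st <- r$stoichiometry
    fwd <- r$upper_bound > 1e-12; rev <- r$lower_bound < -1e-12
    if (fwd || rev) touched <- c(touched, names(st))
    if (fwd) {
      produced <- c(produced, names(st)[st > 0])
      consumed <- c(consumed, names(st)[st < 0])
    }
    if (rev) {
      produced <- c(produced, names(st)[st < 0])
      consumed <- c(consumed, names(st)[st > 0])
    }
  }
  role <- ifelse(!mets %in% touched, "disconnected",
          ifelse(mets %in% produced & !mets %in% consumed, "only-produced",
          ifelse(mets %in% consumed & !mets %in% produced, "only-consumed",
                 "ok")))
  out <- data.frame(metabolite = mets, role = role, stringsAsFactors = FALSE)
  out[out$role != "ok", , drop = FALSE]
}
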