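#' SBML Level 3 + FBC import/export (subset)
#'
#' Writes and reads the subset of SBML L3v1 with the FBC v2 extension that
#' constraint-based models need: compartments, species with
#' `fbc:chemicalFormula`/`fbc:charge`, reactions with flux bounds stored as
#' parameters, GPR rules as `fbc:geneProductAssociation`, gene products,
#' and the active objective.  Ids are prefixed `M_`/`R_`/`G_` on export
#' (SBML SIds cannot start with a digit) and stripped on import.  Reaction
#' kinds are not part of SBML; on import they are re-inferred from id
#' conventions, so the stoichiometric content, bounds, GPR strings and
#' objective round-trip exactly.
#'
#' @param model a `metabolic_model`.
#' @param path file path.
#' @return `write_model_sbml()` the path, invisibly; `read_model_sbml()` a
#'   `metabolic_model`.
#' @keywords internal
write_model_sbml <- function(model, path) {
  validate_model(model)
  sid <- function(x) gsub("[^A-Za-z0-9_]", "__", x)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  lines <- character(0)
  push <- function(...) lines <<- c(lines, sprintf(...))
  push('<?xml version="1.0" encoding="UTF-8"?>')
  push(paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
              'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
              'level="3" version="1" fbc:required="false">'))
  push('  <model id="%s" fbc:strict="true">', sid(model$id))
  push('    <listOfCompartments>')
  for (i in seq_along(model$compartments)) {
    push('      <compartment id="%s" name="%s" constant="true"/>',
         sid(names(model$compartments)[i]), esc(model$compartments[[i]]))
  }
  push('    </listOfCompartments>')
  push('    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    extra <- ""
    if (!is.na(m$charge)) extra <- paste0(extra, sprintf(' fbc:charge="%d"', m$charge))
    if (!is.na(m$formula)) extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"', m$formula))
    push(paste0('      <species id="M_%s" name="%s" compartment="%s" ',
                'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                'constant="false"%s/>'),
         sid(m$id), esc(m$name), sid(m$compartment), extra)
  }
  push('    </listOfSpecies>')
  # bounds as shared parameters, one per distinct value
  bvals <- sort(unique(unlist(lapply(model$reactions,
                                     function(r) c(r$lower_bound, r$upper_bound)))))
  pname <- function(v) sprintf("B_%s", gsub("[^0-9A-Za-z]", "_", format(v, digits = 17)))
  push('    <listOfParameters>')
  for (v in bvals) {
    push('      <parameter id="%s" value="%s" constant="true"/>',
         pname(v), format(v, digits = 17))
  }
  push('    </listOfParameters>')
  push('    <listOfReactions>')
  gpa_xml <- function(node, indent) {
    pad <- strrep(" ", indent)
    if (node$op == "leaf") {
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                     pad, sid(node$gene)))
    }
    tag <- if (node$op == "and") "fbc:and" else "fbc:or"
    inner <- unlist(lapply(node$args, gpa_xml, indent = indent + 2L))
    c(sprintf("%s<%s>", pad, tag), inner, sprintf("%s</%s>", pad, tag))
  }
  for (r in model$reactions) {
    push(paste0('      <reaction id="R_%s" name="%s" reversible="%s" fast="false" ',
                'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
         sid(r$id), esc(r$name), if (r$lower_bound < 0) "true" else "false",
         pname(r$lower_bound), pname(r$upper_bound))
    st <- r$stoichiometry
    for (side in c("Reactants", "Products")) {
      sel <- if (side == "Reactants") st < 0 else st > 0
      if (!any(sel)) next
      push('        <listOf%s>', side)
      for (mid in names(st)[sel]) {
        push('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
             sid(mid), format(abs(st[[mid]]), digits = 17))
      }
      push('        </listOf%s>', side)
    }
    if (!is.null(r$gpr)) {
      push('        <fbc:geneProductAssociation>')
      lines <- c(lines, gpa_xml(r$gpr, 10L))
      push('        </fbc:geneProductAssociation>')
    }
    push('      </reaction>')
  }
  push('    </listOfReactions>')
  if (!is.null(model$objective)) {
    push('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    push('      <fbc:objective fbc:id="obj" fbc:type="%s">',
         if (model$objective$direction == "max") "maximize" else "minimize")
    push('        <fbc:listOfFluxObjectives>')
    push('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
         sid(model$objective$reaction))
    push('        </fbc:listOfFluxObjectives>')
    push('      </fbc:objective>')
    push('    </fbc:listOfObjectives>')
  }
  if (length(model$genes) > 0L) {
    push('    <fbc:listOfGeneProducts>')
    for (g in model$genes) {
      push('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>', sid(g), esc(g))
    }
    push('    </fbc:listOfGeneProducts>')
  }
  push('  </model>')
  push('</sbml>')
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_sbml
#' @keywords internal
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ln <- function(node, name) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  }
  attr1 <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    v
  }
  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)
  model_node <- ln(doc, "model")[[1]]
  comps <- ln(model_node, "compartment")
  compartments <- stats::setNames(
    vapply(comps, function(n) attr1(n, "name"), character(1)),
    vapply(comps, function(n) attr1(n, "id"), character(1)))
  model <- new_model(id = attr1(model_node, "id") %||% "model",
                     compartments = compartments)
  # gene products: SId -> label
  gps <- ln(model_node, "geneProduct")
  gp_label <- stats::setNames(
    vapply(gps, function(n) attr1(n, "label"), character(1)),
    vapply(gps, function(n) attr1(n, "id"), character(1)))
  for (sp in ln(model_node, "species")) {
    ch <- attr1(sp, "charge")
    model <- add_metabolite(
      model, id = strip(attr1(sp, "id"), "M_"),
      name = attr1(sp, "name") %||% strip(attr1(sp, "id"), "M_"),
      formula = attr1(sp, "chemicalFormula") %||% NA_character_,
      charge = if (is.na(ch)) NA_integer_ else as.integer(ch),
      compartment = attr1(sp, "compartment"))
  }
  params <- ln(model_node, "parameter")
  pval <- stats::setNames(
    vapply(params, function(n) as.numeric(attr1(n, "value")), numeric(1)),
    vapply(params, function(n) attr1(n, "id"), character(1)))
  parse_gpa <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- attr1(node, "geneProduct")
      lab <- gp_label[[gid]]
      return(gpr_leaf(if (is.null(lab) || is.na(lab)) strip(gid, "G_") else lab))
    }
    kids <- xml2::xml_children(node)
    args <- lapply(kids, parse_gpa)
    if (nm == "and") return(gpr_node("and", args))
    if (nm == "or") return(gpr_node("or", args))
    if (length(args) == 1L) return(args[[1]])
    stop("SBML: unexpected element in geneProductAssociation: ", nm)
  }
  for (rx in ln(model_node, "reaction")) {
    rid <- strip(attr1(rx, "id"), "R_")
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      for (sr in ln(rx, "speciesReference")) {
        parent <- xml2::xml_name(xml2::xml_parent(sr))
        if (parent != side) next
        mid <- strip(attr1(sr, "species"), "M_")
        st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) +
          sgn * as.numeric(attr1(sr, "stoichiometry"))
      }
    }
    lb <- pval[[attr1(rx, "lowerFluxBound")]]
    ub <- pval[[attr1(rx, "upperFluxBound")]]
    gpa <- ln(rx, "geneProductAssociation")
    gpr <- NULL
    if (length(gpa) > 0L) {
      kids <- xml2::xml_children(gpa[[1]])
      if (length(kids) > 0L) gpr <- parse_gpa(kids[[1]])
    }
    model <- add_reaction(model, id = rid, stoichiometry = st,
                          lower_bound = lb, upper_bound = ub, gpr = gpr,
                          name = attr1(rx, "name") %||% rid,
                          kind = infer_reaction_kind(rid, st))
  }
  fo <- ln(model_node, "fluxObjective")
  if (length(fo) > 0L) {
    obj_node <- ln(model_node, "objective")[[1]]
    dir <- attr1(obj_node, "type")
    model <- set_objective(model, strip(attr1(fo[[1]], "reaction"), "R_"),
                           if (identical(dir, "minimize")) "min" else "max")
  }
  validate_model(model)
  model
}
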