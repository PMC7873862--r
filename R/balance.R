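#' Mass and charge balance audit
#'
#' Computes the net element and charge balance of every non-boundary
#' reaction (exchange, demand, sink and biomass pseudo-reactions are
#' exempt).  A reaction is balanced iff every element net and the charge
#' net are zero: exactly zero when all coefficients are integral, within
#' `tol` when any coefficient is fractional (biomass-style
#' stoichiometries).  Reactions touching a metabolite with no formula or
#' charge are reported as unauditable rather than silently skipped.
#' Pseudo-elements `R`/`X` participate like ordinary elements.
#'
#' @param model a `metabolic_model`.
#' @param tol absolute tolerance for fractional-coefficient reactions.
#' @return a `balance_report`: list with `unbalanced` (named list per
#'   reaction: `elements` net map, `charge` net, `has_pseudo`),
#'   `unauditable` (reaction id -> offending metabolite ids), and
#'   `n_checked`.
#' @export
check_balance <- function(model, tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  met <- model$metabolites
  formulas <- stats::setNames(as.list(met$formula), met$id)
  charges <- stats::setNames(met$charge, met$id)
  exempt <- c(boundary_kinds(), "biomass")
  unbalanced <- list()
  unauditable <- list()
  n_checked <- 0L
  for (r in model$reactions) {
    if (r$kind %in% exempt) next
    ids <- names(r$stoichiometry)
    no_info <- ids[vapply(ids, function(m) is.na(formulas[[m]]) || is.na(charges[[m]]),
                          logical(1))]
    if (length(no_info) > 0L) {
      unauditable[[r$id]] <- no_info
      next
    }
    n_checked <- n_checked + 1L
    parsed <- lapply(formulas[ids], parse_formula)
    net <- combine_formulas(parsed, as.numeric(r$stoichiometry))
    net_charge <- sum(charges[ids] * r$stoichiometry)
    integral <- all(abs(r$stoichiometry - round(r$stoichiometry)) < 1e-12)
    this_tol <- if (integral) 0 else tol
    if (any(abs(net) > this_tol) || abs(net_charge) > this_tol) {
      net <- net[abs(net) > this_tol]
      unbalanced[[r$id]] <- list(
        elements = net,
        charge = if (abs(net_charge) > this_tol) net_charge else 0,
        has_pseudo = any(c("R", "X") %in% unlist(lapply(parsed, names))))
    }
  }
  structure(list(unbalanced = unbalanced, unauditable = unauditable,
                 n_checked = n_checked),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> %d reactions audited, %d unbalanced, %d unauditable\n",
              x$n_checked, length(x$unbalanced), length(x$unauditable)))
  for (id in names(x$unbalanced)) {
    u <- x$unbalanced[[id]]
    cat(sprintf("  %s: %s charge %+g\n", id,
                paste(sprintf("%s%+g", names(u$elements), u$elements), collapse = " "),
                u$charge))
  }
  invisible(x)
}
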