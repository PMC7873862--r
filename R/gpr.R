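#' Gene-protein-reaction (GPR) boolean expressions
#'
#' A GPR rule states which gene combinations enable a reaction: `or` joins
#' isozymes (any suffices), `and` joins complex subunits (all required).
#' Internally an expression is a tree of nodes `list(op = "and"/"or",
#' args = list(...))` with leaves `list(op = "leaf", gene = "g1")`.  The
#' empty expression (`NULL`) means "no gene requirement" and is always
#' satisfied.
#'
#' The grammar is case-insensitive; `and` binds tighter than `or`;
#' parentheses group.  This matches the common model-JSON dialect.
#'
#' @param text GPR string, e.g. `"(g1 and g2) or g3"`; `""` and `NA` give
#'   the empty expression.
#' @return a `gpr` object (or `NULL` for the empty expression).
#' @examples
#' g <- parse_gpr("(g1 and g2) or g3")
#' evaluate_gpr(g, knocked_out = "g1")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L) return(NULL)
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st, text)
  if (st$pos <= length(st$toks)) {
    stop(sprintf("GPR parse error in '%s': unexpected token '%s' at token %d",
                 text, st$toks[st$pos], st$pos))
  }
  expr
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st, text) {
  args <- list(gpr_parse_and(st, text))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st, text)))
  }
  if (length(args) == 1L) args[[1]] else gpr_node("or", args)
}

gpr_parse_and <- function(st, text) {
  args <- list(gpr_parse_atom(st, text))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st, text)))
  }
  if (length(args) == 1L) args[[1]] else gpr_node("and", args)
}

gpr_parse_atom <- function(st, text) {
  tok <- gpr_peek(st)
  if (is.na(tok)) {
    stop(sprintf("GPR parse error in '%s': unexpected end of expression", text))
  }
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st, text)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop(sprintf("GPR parse error in '%s': unbalanced parentheses at token %d",
                   text, st$pos))
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop(sprintf("GPR parse error in '%s': stray token '%s' at token %d",
                 text, tok, st$pos))
  }
  st$pos <- st$pos + 1L
  gpr_leaf(tok)
}

gpr_node <- function(op, args) {
  # flatten nested same-op nodes so and/or always have >= 2 children
  flat <- list()
  for (a in args) {
    if (!is.null(a$op) && a$op == op) flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  structure(list(op = op, args = flat), class = "gpr")
}

gpr_leaf <- function(gene) structure(list(op = "leaf", gene = gene), class = "gpr")

#' Serialize a GPR expression to its infix string
#'
#' Round-trips with [parse_gpr()] up to whitespace and redundant
#' parentheses.  The empty expression serializes to `""`.
#'
#' @param gpr a `gpr` object or `NULL`.
#' @return a single string.
#' @export
gpr_to_string <- function(gpr) {
  if (is.null(gpr)) return("")
  walk <- function(node, parent_op) {
    if (node$op == "leaf") return(node$gene)
    parts <- vapply(node$args, walk, character(1), parent_op = node$op)
    s <- paste(parts, collapse = paste0(" ", node$op, " "))
    # parenthesize an 'or' under an 'and' (and any nested mixed case)
    if (!is.na(parent_op) && parent_op == "and" && node$op == "or") {
      s <- paste0("(", s, ")")
    }
    s
  }
  walk(gpr, NA_character_)
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}

#' Genes appearing in a GPR expression
#' @param gpr a `gpr` object or `NULL`.
#' @return character vector of distinct gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (gpr$op == "leaf") return(gpr$gene)
  unique(unlist(lapply(gpr$args, gpr_genes)))
}

#' Evaluate a GPR under a gene knockout
#'
#' @param gpr a `gpr` object or `NULL` (always satisfied).
#' @param knocked_out character vector of gene ids set to FALSE.
#' @return `TRUE` if the boolean expression is satisfied.
#' @export
evaluate_gpr <- function(gpr, knocked_out = character(0)) {
  if (is.null(gpr)) return(TRUE)
  if (gpr$op == "leaf") return(!(gpr$gene %in% knocked_out))
  vals <- vapply(gpr$args, evaluate_gpr, logical(1), knocked_out = knocked_out)
  if (gpr$op == "and") all(vals) else any(vals)
}

#' Disjunctive normal form of a GPR
#'
#' Expands a GPR into a list of AND-clauses (character vectors of gene
#' ids); the rule is satisfied iff at least one clause has all its genes
#' present.  Used by the isozyme/complex pruning rule, which is defined on
#' DNF so that "top-level OR sibling" is well-defined for nested rules.
#'
#' @param gpr a `gpr` object or `NULL`.
#' @return list of character vectors; `list()` for the empty rule.
#' @export
gpr_dnf <- function(gpr) {
  if (is.null(gpr)) return(list())
  if (gpr$op == "leaf") return(list(gpr$gene))
  parts <- lapply(gpr$args, gpr_dnf)
  if (gpr$op == "or") {
    clauses <- do.call(c, parts)
  } else {
    clauses <- list(character(0))
    for (p in parts) {
      clauses <- unlist(lapply(clauses, function(cl) {
        lapply(p, function(q) unique(c(cl, q)))
      }), recursive = FALSE)
    }
  }
  # drop duplicate clauses (order-insensitive)
  keys <- vapply(clauses, function(cl) paste(sort(cl), collapse = "\r"), character(1))
  clauses[!duplicated(keys)]
}

#' Rebuild a GPR from DNF clauses
#' @param clauses list of character vectors of gene ids.
#' @return a `gpr` object, or `NULL` for an empty clause list.
#' @export
gpr_from_dnf <- function(clauses) {
  clauses <- clauses[vapply(clauses, length, integer(1)) > 0L]
  if (length(clauses) == 0L) return(NULL)
  ands <- lapply(clauses, function(cl) {
    if (length(cl) == 1L) gpr_leaf(cl) else gpr_node("and", lapply(cl, gpr_leaf))
  })
  if (length(ands) == 1L) ands[[1]] else gpr_node("or", ands)
}

# Substitute leaves: map is a named list gene -> character vector of
# replacement genes (OR-expanded), or NULL/absent to leave untouched.
gpr_substitute <- function(gpr, map) {
  if (is.null(gpr)) return(NULL)
  if (gpr$op == "leaf") {
    repl <- map[[gpr$gene]]
    if (is.null(repl)) return(gpr)
    if (length(repl) == 1L) return(gpr_leaf(repl))
    return(gpr_node("or", lapply(repl, gpr_leaf)))
  }
  gpr_node(gpr$op, lapply(gpr$args, gpr_substitute, map = map))
}
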