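# Independent oracles and tiny generators shared across the suite.
# Each oracle is deliberately written with a different algorithm than the
# implementation it checks.

# Brute-force LP oracle: maximize c'v over {S v = 0, lb <= v <= ub} by
# enumerating candidate vertices (every choice of n - rank(S) variables
# pinned to a bound), solving for the rest, and keeping feasible points.
brute_force_lp_max <- function(S, lb, ub, cvec) {
  n <- ncol(S)
  r <- qr(S)$rank
  nfix <- n - r
  best <- -Inf
  check_point <- function(v) {
    if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) return()
    if (max(abs(S %*% v)) > 1e-7) return()
    best <<- max(best, sum(cvec * v))
  }
  check_point(rep(0, n))
  for (size in max(nfix, 1):n) {
    combos <- utils::combn(n, size)
    for (ci in seq_len(ncol(combos))) {
      F <- combos[, ci]
      free <- setdiff(seq_len(n), F)
      for (mask in 0:(2^size - 1)) {
        side <- bitwAnd(bitwShiftR(mask, seq_len(size) - 1), 1) == 1
        vF <- ifelse(side, ub[F], lb[F])
        v <- numeric(n)
        v[F] <- vF
        if (length(free) > 0L) {
          A <- S[, free, drop = FALSE]
          rhs <- -S[, F, drop = FALSE] %*% vF
          sol <- tryCatch(qr.solve(A, rhs, tol = 1e-10),
                          error = function(e) NULL)
          if (is.null(sol)) next
          v[free] <- sol
        }
        check_point(v)
      }
    }
  }
  best
}

# Random small flux network: S (m x n), finite bounds, one objective column.
random_lp_network <- function(seed) {
  set.seed(seed)
  n <- sample(3:6, 1)
  m <- sample(2:4, 1)
  repeat {
    S <- matrix(sample(c(-2, -1, 0, 0, 1, 2), m * n, replace = TRUE), m, n)
    if (all(colSums(abs(S)) > 0)) break
  }
  lb <- sample(c(0, 0, -10), n, replace = TRUE)
  ub <- sample(c(5, 10), n, replace = TRUE)
  list(S = S, lb = lb, ub = ub,
       cvec = as.numeric(seq_len(n) == sample(n, 1)))
}

# GPR truth-table oracle: translate the rule text into an R logical
# expression and evaluate it with substitution -- a different path than
# the package's tree walk.
oracle_gpr_eval <- function(text, genes, knocked_out) {
  if (!nzchar(trimws(text))) return(TRUE)
  expr_text <- text
  for (g in genes) {
    expr_text <- gsub(paste0("\\b", g, "\\b"),
                      if (g %in% knocked_out) "FALSE" else "TRUE", expr_text)
  }
  expr_text <- gsub("\\band\\b", "&&", expr_text, ignore.case = TRUE)
  expr_text <- gsub("\\bor\\b", "||", expr_text, ignore.case = TRUE)
  eval(parse(text = expr_text))
}

random_gpr_text <- function(seed, genes = paste0("g", 1:4)) {
  set.seed(seed)
  k <- sample(seq_along(genes), 1)
  gs <- sample(genes, k)
  if (k == 1) return(gs)
  ops <- sample(c("and", "or"), k - 1, replace = TRUE)
  out <- gs[1]
  for (i in seq_len(k - 1)) {
    grouped <- sample(c(TRUE, FALSE), 1)
    nxt <- gs[i + 1]
    out <- if (grouped) sprintf("(%s) %s %s", out, ops[i], nxt)
           else sprintf("%s %s %s", out, ops[i], nxt)
  }
  out
}

# Minimal three-step toy model: EX_A -> A -> B -> demand, with optional
# tweaks, used across modules.
toy_chain_model <- function(ub_uptake = 10, gpr_ab = NULL) {
  m <- new_model("toy", c(c = "cytosol", e = "extracellular"))
  m <- add_metabolite(m, "a_e", formula = "C2H4O2", charge = 0L)
  m <- add_metabolite(m, "a_c", formula = "C2H4O2", charge = 0L)
  m <- add_metabolite(m, "b_c", formula = "C2H4O2", charge = 0L)
  m <- add_reaction(m, "EX_a_e", c(a_e = -1), -ub_uptake, 1000,
                    kind = "exchange")
  m <- add_reaction(m, "At", c(a_e = -1, a_c = 1), 0, 1000, kind = "transport")
  m <- add_reaction(m, "AB", c(a_c = -1, b_c = 1), 0, 1000, gpr = gpr_ab)
  m <- add_reaction(m, "DM_b", c(b_c = -1), 0, 1000, kind = "demand")
  set_objective(m, "DM_b")
}

# The injected trans-mitochondrial proton leak used by the EGC tests:
# a synthetic carrier cycle returning matrix protons to the cytosolic
# face for free.
inject_proton_loop <- function(model) {
  for (id in c("crr_c", "crr_m", "crx_m")) {
    model <- add_metabolite(model, id, name = "synthetic carrier",
                            formula = "X", charge = 0L)
  }
  model <- add_reaction(model, "EGCA", c(crr_c = -1, crr_m = 1))
  model <- add_reaction(model, "EGCB", c(crr_m = -1, h_m = -2, crx_m = 1,
                                         h_c = 2))
  add_reaction(model, "EGCC", c(crx_m = -1, crr_c = 1))
}

# cached demo fixture (built once per test run)
demo_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- demo_model()
    m
  }
})
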