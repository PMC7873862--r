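## Dense bounded-variable primal simplex with phase-1/phase-2 and duals.
## Exact desk-scale solver for the package's flux balance LPs and the
## branch-and-bound used by the energy-generating-cycle audit.  Written for
## robustness over speed: Bland's anti-cycling pivot rule throughout, full
## basis refactorization every iteration.  Models in this package have at
## most a few hundred columns, where this is more than fast enough.

.LP_BIG <- 1e9   # stand-in for an infinite bound
.LP_TOL <- 1e-9

#' Solve a linear program with two-sided variable bounds
#'
#' Solves `sense(c'x)` subject to `Aeq x = beq`, `Ale x <= ble`,
#' `lb <= x <= ub`.  Infinite bounds are allowed.  Returns the dual values
#' of the equality rows, signed so that `duals_eq[i]` is the marginal
#' change of the reported objective per unit increase of `beq[i]` (the
#' shadow-price convention used by [fba()]).
#'
#' @param cvec objective coefficients.
#' @param Aeq,beq equality constraints (matrix may have 0 rows).
#' @param Ale,ble optional inequality constraints.
#' @param lb,ub variable bounds (recycled).
#' @param sense `"max"` or `"min"`.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective`, `x`, and `duals_eq`.
#' @keywords internal
#' @export
solve_lp <- function(cvec, Aeq, beq, Ale = NULL, ble = NULL,
                     lb = -Inf, ub = Inf, sense = c("max", "min")) {
  sense <- match.arg(sense)
  n <- length(cvec)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  if (is.null(Ale)) { Ale <- matrix(0, 0, n); ble <- numeric(0) }
  n_sl <- nrow(Ale)
  A <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), n_sl)),
             cbind(Ale, diag(1, n_sl)))
  b <- c(beq, ble)
  cc <- c(cvec, rep(0, n_sl))
  lb <- c(lb, rep(0, n_sl)); ub <- c(ub, rep(Inf, n_sl))
  res <- simplex_bounded(if (sense == "max") -cc else cc, A, b, lb, ub)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_,
                x = rep(NA_real_, n), duals_eq = rep(NA_real_, nrow(Aeq))))
  }
  obj <- sum(cvec * res$x[seq_len(n)])
  # unbounded detection: a capped-infinite variable parked at the cap
  at_cap <- abs(res$x[seq_len(n)]) >= .LP_BIG * (1 - 1e-6)
  inf_orig <- !is.finite(ub[seq_len(n)]) | !is.finite(lb[seq_len(n)])
  if (any(at_cap & inf_orig)) {
    return(list(status = "unbounded", objective = obj,
                x = res$x[seq_len(n)], duals_eq = rep(NA_real_, nrow(Aeq))))
  }
  duals <- res$y[seq_len(nrow(Aeq))]
  if (sense == "max") duals <- -duals
  list(status = "optimal", objective = obj, x = res$x[seq_len(n)],
       duals_eq = duals)
}

# minimize c'x s.t. A x = b, lb <= x <= ub (Inf allowed; capped internally)
simplex_bounded <- function(cc, A, b, lb, ub, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  lb <- pmax(lb, -.LP_BIG); ub <- pmin(ub, .LP_BIG)
  if (any(lb > ub + .LP_TOL)) return(list(status = "infeasible"))
  ub <- pmax(ub, lb)
  if (m == 0L) {
    x <- ifelse(cc > 0, lb, ifelse(cc < 0, ub, lb))
    return(list(status = "optimal", x = x, y = numeric(0)))
  }
  # start: structurals nonbasic at the bound of smaller magnitude
  at_upper <- abs(ub) < abs(lb)
  x_struct <- ifelse(at_upper, ub, lb)
  r <- b - as.vector(A %*% x_struct)
  sgn <- ifelse(r >= 0, 1, -1)
  Aall <- cbind(A, diag(sgn, m))
  lball <- c(lb, rep(0, m)); uball <- c(ub, rep(Inf, m))
  uball <- pmin(uball, .LP_BIG)
  basis <- n + seq_len(m)
  nb_at_upper <- c(at_upper, rep(FALSE, m))  # meaningful for nonbasic only
  run_phase <- function(cost, basis, nb_at_upper) {
    for (iter in seq_len(max_iter)) {
      Bmat <- Aall[, basis, drop = FALSE]
      Binv <- tryCatch(solve(Bmat), error = function(e) NULL)
      if (is.null(Binv)) return(list(status = "singular"))
      nonbasic <- setdiff(seq_len(n + m), basis)
      xN <- ifelse(nb_at_upper[nonbasic], uball[nonbasic], lball[nonbasic])
      xB <- as.vector(Binv %*% (b - Aall[, nonbasic, drop = FALSE] %*% xN))
      y <- as.vector(crossprod(Binv, cost[basis]))
      d <- cost[nonbasic] - as.vector(crossprod(Aall[, nonbasic, drop = FALSE], y))
      improving <- (!nb_at_upper[nonbasic] & d < -.LP_TOL) |
                   (nb_at_upper[nonbasic] & d > .LP_TOL)
      if (!any(improving)) {
        x <- numeric(n + m)
        x[nonbasic] <- xN; x[basis] <- xB
        return(list(status = "optimal", x = x, y = y, basis = basis,
                    nb_at_upper = nb_at_upper))
      }
      j_rel <- which(improving)[1]            # Bland: smallest index
      j <- nonbasic[j_rel]
      dir <- if (nb_at_upper[nonbasic][j_rel]) -1 else 1
      w <- as.vector(Binv %*% Aall[, j]) * dir
      # entering moves by t >= 0 in direction dir; basics move by -t*w
      ti <- rep(Inf, m); to_upper <- logical(m)
      pos <- w > .LP_TOL; neg <- w < -.LP_TOL
      ti[pos] <- (xB[pos] - lball[basis[pos]]) / w[pos]
      ti[neg] <- (uball[basis[neg]] - xB[neg]) / (-w[neg])
      to_upper[neg] <- TRUE
      ti <- pmax(ti, 0)
      t_bound <- uball[j] - lball[j]
      t_min <- min(ti, t_bound)
      if (!is.finite(t_min)) return(list(status = "unbounded"))
      if (t_bound <= t_min + 1e-12) {
        # entering runs to its opposite bound; basis unchanged
        nb_at_upper[j] <- !nb_at_upper[j]
      } else {
        cand <- which(ti <= t_min + 1e-9)
        leave <- cand[which.min(basis[cand])]   # Bland tie-break
        lv <- basis[leave]
        nb_at_upper[lv] <- to_upper[leave]
        basis[leave] <- j
      }
    }
    list(status = "iteration_limit")
  }
  # phase 1: minimize sum of artificials
  cost1 <- c(rep(0, n), rep(1, m))
  p1 <- run_phase(cost1, basis, nb_at_upper)
  if (p1$status != "optimal") return(list(status = "infeasible"))
  if (sum(p1$x[n + seq_len(m)]) > 1e-6) return(list(status = "infeasible"))
  # phase 2: artificials pinned to zero
  uball[n + seq_len(m)] <- 0
  cost2 <- c(cc, rep(0, m))
  p2 <- run_phase(cost2, p1$basis, p1$nb_at_upper)
  if (p2$status != "optimal") {
    return(list(status = if (p2$status == "unbounded") "unbounded" else "infeasible"))
  }
  list(status = "optimal", x = p2$x[seq_len(n)], y = p2$y)
}

#' Solve a small mixed-integer LP by branch and bound
#'
#' Depth-first branch and bound over variables restricted to {0,1},
#' solving the LP relaxation with [solve_lp()] at each node.  Intended for
#' the cardinality-minimization problems of the energy-generating-cycle
#' audit (tens of binaries).
#'
#' @inheritParams solve_lp
#' @param int_idx indices of variables restricted to integers in `[lb,ub]`
#'   (in practice binaries in `[0,1]`).
#' @param time_limit seconds; on expiry the incumbent is returned with
#'   `proven = FALSE`.
#' @return list with `status`, `objective`, `x`, `proven`.
#' @keywords internal
#' @export
solve_milp <- function(cvec, Aeq, beq, Ale = NULL, ble = NULL,
                       lb = -Inf, ub = Inf, int_idx = integer(0),
                       sense = c("max", "min"), time_limit = 60) {
  sense <- match.arg(sense)
  n <- length(cvec)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  t0 <- Sys.time()
  best <- list(objective = if (sense == "max") -Inf else Inf, x = NULL)
  proven <- TRUE
  int_tol <- 1e-6
  better <- function(a, b) if (sense == "max") a > b + 1e-9 else a < b - 1e-9
  # rounding heuristic on the root relaxation for an initial incumbent
  root <- solve_lp(cvec, Aeq, beq, Ale, ble, lb, ub, sense)
  if (root$status == "optimal" && length(int_idx) > 0L) {
    rlb <- lb; rub <- ub
    up <- abs(root$x[int_idx]) > int_tol
    rlb[int_idx] <- ifelse(up, pmax(lb[int_idx], ceiling(root$x[int_idx] - int_tol)), lb[int_idx])
    rub[int_idx] <- ifelse(up, rub[int_idx], pmin(ub[int_idx], 0))
    rlb[int_idx] <- pmax(rlb[int_idx], lb[int_idx])
    cand <- solve_lp(cvec, Aeq, beq, Ale, ble, rlb, rub, sense)
    if (cand$status == "optimal" &&
        all(abs(cand$x[int_idx] - round(cand$x[int_idx])) <= int_tol)) {
      best <- list(objective = cand$objective, x = cand$x)
    }
  }
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack) > 0L) {
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_limit) {
      proven <- FALSE
      break
    }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- solve_lp(cvec, Aeq, beq, Ale, ble, node$lb, node$ub, sense)
    if (rel$status != "optimal") next
    if (!better(rel$objective, best$objective)) next   # bound
    frac <- int_idx[abs(rel$x[int_idx] - round(rel$x[int_idx])) > int_tol]
    if (length(frac) == 0L) {
      best <- list(objective = rel$objective, x = rel$x)
      next
    }
    jb <- frac[1]
    v <- rel$x[jb]
    lo <- node; lo$ub[jb] <- floor(v)
    hi <- node; hi$lb[jb] <- ceiling(v)
    # explore the down-branch first: for cardinality minimization it is the
    # branch most likely to carry the optimum
    stack <- c(stack, list(hi), list(lo))
  }
  if (is.null(best$x)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL,
                proven = proven))
  }
  list(status = "optimal", objective = best$objective, x = best$x,
       proven = proven)
}
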