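# Dense two-phase primal simplex with Bland's anti-cycling rule.
# Deliberately simple: the models this package optimises are small
# (tens of reactions), where a dense tableau is exact and fast.

# Core: min c'x s.t. Ax = b, x >= 0, starting from the given feasible basis.
simplex_core <- function(A, b, c, basis, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  Tb <- cbind(A, b)
  cost <- c(c, 0)
  for (r in seq_len(m)) {
    j <- basis[r]
    if (abs(cost[j]) > 0) cost <- cost - cost[j] * Tb[r, ]
  }
  repeat {
    entering <- which(cost[seq_len(n)] < -tol)
    if (!length(entering)) break
    j <- entering[1L]                       # Bland: lowest index
    col <- Tb[seq_len(m), j]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(status = "unbounded", basis = basis, tableau = Tb))
    }
    ratios <- Tb[pos, n + 1L] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    r <- cand[which.min(basis[cand])]       # Bland: lowest basic index on ties
    piv <- Tb[r, j]
    Tb[r, ] <- Tb[r, ] / piv
    upd <- which(abs(Tb[seq_len(m), j]) > 0 & seq_len(m) != r)
    for (k in upd) Tb[k, ] <- Tb[k, ] - Tb[k, j] * Tb[r, ]
    cost <- cost - cost[j] * Tb[r, ]
    basis[r] <- j
  }
  x <- numeric(n)
  x[basis] <- Tb[seq_len(m), n + 1L]
  list(status = "optimal", x = x, objective = -cost[n + 1L],
       basis = basis, tableau = Tb, cost = cost)
}

#' Solve a bounded linear program
#'
#' Optimise `obj' x` subject to row constraints `mat x (dir) rhs` and box
#' bounds `lb <= x <= ub`, by two-phase dense simplex. All bounds must be
#' finite (constraint-based models use finite default bounds such as +/-1000).
#'
#' @param obj objective coefficient vector.
#' @param mat constraint matrix (may have zero rows).
#' @param dir character vector over rows: `"="`, `"<="` or `">="`.
#' @param rhs right-hand sides.
#' @param lb,ub variable bounds (finite).
#' @param maximize logical; default `TRUE`.
#' @param tol pivot/feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective`, and the primal solution `x` on the original scale.
#' @export
solve_lp <- function(obj, mat, dir, rhs, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(ncol(mat) == n || nrow(mat) == 0, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("solve_lp requires finite variable bounds")
  }
  if (any(lb > ub + tol)) return(list(status = "infeasible"))

  # shift x = y + lb so y >= 0; add explicit rows y_i <= ub_i - lb_i
  nr <- nrow(mat)
  rhs_shift <- if (nr) rhs - as.numeric(mat %*% lb) else numeric(0)
  span <- ub - lb
  A <- rbind(mat, diag(n))
  d <- c(dir, rep("<=", n))
  bvec <- c(rhs_shift, span)

  # slacks for inequality rows
  ineq <- which(d != "=")
  ns <- length(ineq)
  S <- matrix(0, nrow(A), ns)
  for (k in seq_along(ineq)) S[ineq[k], k] <- if (d[ineq[k]] == "<=") 1 else -1
  A2 <- cbind(A, S)

  # make rhs non-negative
  neg <- which(bvec < 0)
  if (length(neg)) {
    A2[neg, ] <- -A2[neg, ]
    bvec[neg] <- -bvec[neg]
  }

  m <- nrow(A2)
  ntot <- ncol(A2)

  # phase 1: artificial basis
  A1 <- cbind(A2, diag(m))
  c1 <- c(rep(0, ntot), rep(1, m))
  p1 <- simplex_core(A1, bvec, c1, basis = ntot + seq_len(m), tol = tol)
  if (p1$status != "optimal" || p1$objective > 1e-7) {
    return(list(status = "infeasible"))
  }

  # drive remaining artificials out of the basis; drop redundant rows
  basis <- p1$basis
  Tb <- p1$tableau
  keep <- rep(TRUE, m)
  for (r in seq_len(m)) {
    if (basis[r] > ntot) {
      piv_cols <- which(abs(Tb[r, seq_len(ntot)]) > tol)
      if (length(piv_cols)) {
        j <- piv_cols[1L]
        piv <- Tb[r, j]
        Tb[r, ] <- Tb[r, ] / piv
        for (k in seq_len(m)) {
          if (k != r && abs(Tb[k, j]) > 0) Tb[k, ] <- Tb[k, ] - Tb[k, j] * Tb[r, ]
        }
        basis[r] <- j
      } else {
        keep[r] <- FALSE  # redundant constraint row
      }
    }
  }
  A3 <- Tb[keep, seq_len(ntot), drop = FALSE]
  b3 <- Tb[keep, ncol(Tb)]
  basis3 <- basis[keep]

  c2 <- c(if (maximize) -obj else obj, rep(0, ns))
  p2 <- simplex_core(A3, b3, c2, basis = basis3, tol = tol)
  if (p2$status != "optimal") return(list(status = p2$status))

  y <- p2$x[seq_len(n)]
  list(status = "optimal",
       objective = unname(if (maximize) -p2$objective + sum(obj * lb)
                          else p2$objective + sum(obj * lb)),
       x = unname(y + lb))
}
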