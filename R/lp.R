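# Dense two-phase primal simplex for small linear programs.
#
#   minimize    c'x
#   subject to  A_eq x  = b_eq
#               A_ub x <= b_ub
#               lb <= x <= ub        (finite bounds)
#
# The problem is reduced to standard form (shift by lb, slack out the
# inequalities and upper bounds, flip rows until b >= 0) and solved with a
# full-tableau two-phase simplex under Bland's anti-cycling rule.  The
# tableau is carried from phase 1 into phase 2 (artificials retained at a
# large cost so they never re-enter; redundant rows keep their artificial
# basic at zero harmlessly).  Problem sizes in this package are tiny (tens
# of variables), so robustness and determinism win over speed; the basic
# solution is re-solved from the final basis for accuracy.

# Pivot a canonical tableau T = [A | b] (basis columns = identity) to
# optimality for `cost` under Bland's rule. Returns updated T and basis.
simplex_run <- function(T, basis, cost, tol = 1e-9, max_iter = 50000L) {
  m <- nrow(T); n <- ncol(T) - 1L
  for (it in seq_len(max_iter)) {
    red <- cost - drop(cost[basis] %*% T[, seq_len(n), drop = FALSE])
    red[basis] <- 0
    enter <- which(red < -tol)
    if (!length(enter))
      return(list(status = "optimal", T = T, basis = basis))
    j <- min(enter)                         # Bland: smallest entering index
    col <- T[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratio <- T[pos, n + 1L] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    r <- cand[which.min(basis[cand])]       # Bland: smallest leaving index
    T[r, ] <- T[r, ] / T[r, j]
    other <- setdiff(seq_len(m), r)
    T[other, ] <- T[other, , drop = FALSE] - outer(T[other, j], T[r, ])
    T[abs(T) < 1e-11] <- 0
    T[other, n + 1L] <- pmax(T[other, n + 1L], 0)
    basis[r] <- j
  }
  list(status = "iteration_limit")
}

# Solve min c'y, A y = b, y >= 0 by the two-phase method.
simplex_standard <- function(A, b, cost, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }
  T <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  p1 <- simplex_run(T, basis, c(numeric(n), rep(1, m)), tol = tol)
  if (p1$status != "optimal") return(list(status = p1$status))
  x1 <- numeric(n + m)
  x1[p1$basis] <- p1$T[, n + m + 1L]
  if (sum(x1[n + seq_len(m)]) > 1e-7) return(list(status = "infeasible"))
  big <- 1e8 * (1 + max(abs(cost)))
  p2 <- simplex_run(p1$T, p1$basis, c(cost, rep(big, m)), tol = tol)
  if (p2$status != "optimal") return(list(status = p2$status))
  x_full <- numeric(n + m)
  x_full[p2$basis] <- p2$T[, n + m + 1L]
  if (sum(x_full[n + seq_len(m)]) > 1e-7) return(list(status = "infeasible"))
  list(status = "optimal", x = x_full[seq_len(n)], basis = p2$basis,
       A = A, b = b)
}

#' Solve a small dense linear program
#'
#' Minimizes `obj %*% x` subject to `A_eq x = b_eq`, `A_ub x <= b_ub` and
#' finite bounds `lb <= x <= ub`, by a dense two-phase simplex. Intended
#' for the small flux-balance problems built by this package; determinism
#' (Bland's rule) is favored over speed.
#'
#' @param obj objective coefficients (minimized).
#' @param A_eq,b_eq equality constraints (may be NULL).
#' @param A_ub,b_ub inequality constraints `A_ub x <= b_ub` (may be NULL).
#' @param lb,ub finite variable bounds (recycled to length of `obj`).
#' @param tol pivot tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`,
#'   `"iteration_limit"`), and for optimal solutions `x` and `objective`.
#' @export
lp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     lb, ub, tol = 1e-9) {
  obj <- as.numeric(obj)
  n <- length(obj)
  lb <- rep_len(as.numeric(lb), n); ub <- rep_len(as.numeric(ub), n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop_nf("lp_solve requires finite variable bounds")
  if (any(lb > ub)) return(list(status = "infeasible"))
  Aeq <- if (is.null(A_eq)) matrix(0, 0, n) else as.matrix(A_eq)
  beq <- if (is.null(b_eq)) numeric(0) else as.numeric(b_eq)
  Aub <- if (is.null(A_ub)) matrix(0, 0, n) else as.matrix(A_ub)
  bub <- if (is.null(b_ub)) numeric(0) else as.numeric(b_ub)

  # shift x = lb + y with 0 <= y <= span
  span <- ub - lb
  beq2 <- beq - drop(Aeq %*% lb)
  bub2 <- bub - drop(Aub %*% lb)
  n_ineq <- nrow(Aub)
  ntot <- n + n_ineq + n            # y, ineq slacks, upper-bound slacks
  rows <- nrow(Aeq) + n_ineq + n
  A <- matrix(0, rows, ntot)
  b <- numeric(rows)
  if (nrow(Aeq)) {
    A[seq_len(nrow(Aeq)), seq_len(n)] <- Aeq
    b[seq_len(nrow(Aeq))] <- beq2
  }
  if (n_ineq) {
    r0 <- nrow(Aeq)
    A[r0 + seq_len(n_ineq), seq_len(n)] <- Aub
    A[cbind(r0 + seq_len(n_ineq), n + seq_len(n_ineq))] <- 1
    b[r0 + seq_len(n_ineq)] <- bub2
  }
  r0 <- nrow(Aeq) + n_ineq
  for (i in seq_len(n)) {
    A[r0 + i, i] <- 1
    A[r0 + i, n + n_ineq + i] <- 1
    b[r0 + i] <- span[i]
  }
  cost <- c(obj, numeric(n_ineq + n))
  res <- simplex_standard(A, b, cost, tol = tol)
  if (res$status != "optimal") return(list(status = res$status))
  # refine the basic solution by solving the basis system directly
  x_std <- res$x
  xb <- tryCatch(solve(res$A[, res$basis, drop = FALSE], res$b),
                 error = function(e) NULL)
  if (!is.null(xb) && all(xb > -1e-7)) {
    x_full <- numeric(ncol(res$A))
    x_full[res$basis] <- pmax(xb, 0)
    real <- x_full[seq_len(ntot)]
    if (max(abs(real - c(x_std, numeric(0)))) < 1e-4) x_std <- real
  }
  x <- lb + pmin(x_std[seq_len(n)], span)
  list(status = "optimal", x = x, objective = sum(obj * x))
}
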