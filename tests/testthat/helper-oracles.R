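# Independent oracles used to cross-check the package implementations.
# Each one is written against a different algorithm than the code it
# checks (dense eigendecomposition vs power iteration, Floyd-Warshall vs
# BFS, path-count dynamic programming vs Brandes accumulation, scipy's
# interior-point/HiGHS LP vs the package's simplex).

# -- graphs ------------------------------------------------------------------

random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  if (n > 1) {
    up <- which(upper.tri(A))
    A[up] <- stats::rbinom(length(up), 1, p)
    A <- A + t(A)
  }
  dimnames(A) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  A
}

# all-pairs shortest-path distances (Floyd-Warshall)
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  D
}

oracle_degree <- function(A) as.integer(colSums(A))

oracle_closeness <- function(A) {
  D <- oracle_distances(A)
  diag(D) <- Inf
  rowSums(1 / D)
}

oracle_eigenvector <- function(A) {
  if (sum(A) == 0) return(list(values = 0, vector = numeric(nrow(A))))
  es <- eigen(A, symmetric = TRUE)
  v <- es$vectors[, 1]
  v <- abs(v)  # Perron vector of the dominant component, sign-fixed
  v[v < 1e-10] <- 0
  v <- v / sqrt(sum(v^2))
  list(values = es$values, vector = v)
}

# geodesic path counts by dynamic programming on distances
oracle_sigma <- function(A) {
  D <- oracle_distances(A)
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  maxd <- max(D[is.finite(D)])
  if (maxd >= 1) for (d in seq_len(maxd)) {
    idx <- which(D == d, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      j <- idx[r, 1]; k <- idx[r, 2]
      nb <- which(A[, k] > 0 & D[j, ] == d - 1)
      sigma[j, k] <- sum(sigma[j, nb])
    }
  }
  sigma
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  sigma <- oracle_sigma(A)
  b <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    if (i == j || i == k || j == k) next
    if (!is.finite(D[j, k]) || sigma[j, k] == 0) next
    if (D[j, i] + D[i, k] == D[j, k])
      b[i] <- b[i] + sigma[j, i] * sigma[i, k] / sigma[j, k]
  }
  b
}

# exhaustive / sampled centrality comparison used by several tests
expect_centralities_match_oracles <- function(A, tol = 1e-8) {
  expect_equal(unname(degree_centrality(A)), oracle_degree(A))
  expect_equal(unname(betweenness_centrality(A)), oracle_betweenness(A),
               tolerance = tol)
  expect_equal(unname(closeness_centrality(A)), oracle_closeness(A),
               tolerance = tol)
  e <- eigenvector_centrality(A)
  or <- oracle_eigenvector(A)
  lam <- attr(e, "lambda")
  # residual is the defining property; the vector itself is only unique
  # when the dominant eigenvalue is simple (gap above numerical noise)
  if (sum(A) > 0) {
    expect_lt(max(abs(lam * e - drop(A %*% e))), 1e-7)
    gap <- or$values[1] - max(c(abs(or$values[-1]), 0))
    if (gap > 1e-3)
      expect_equal(as.vector(e), or$vector, tolerance = 1e-5)
  } else {
    expect_true(all(e == 0))
  }
  invisible(TRUE)
}

# -- mutual information -------------------------------------------------------

# brute-force contingency-table MI (bits) on pre-binned integer rows
oracle_mi_binned <- function(bi, bj) {
  m <- length(bi)
  tab <- table(bi, bj) / m
  pi_ <- rowSums(tab); pj <- colSums(tab)
  s <- 0
  for (a in seq_len(nrow(tab))) for (b in seq_len(ncol(tab))) {
    p <- tab[a, b]
    if (p > 0) s <- s + p * log2(p / (pi_[a] * pj[b]))
  }
  unname(s)
}

# -- linear programming -------------------------------------------------------

# scipy.optimize.linprog as an independent dense solver (the python stack
# is part of the runtime image). Solves min c'x st A_eq x = b_eq within
# bounds; returns list(status, objective).
scipy_linprog <- function(obj, A_eq = NULL, b_eq = NULL, lb, ub) {
  req <- list(c = as.numeric(obj),
              lb = as.numeric(rep_len(lb, length(obj))),
              ub = as.numeric(rep_len(ub, length(obj))))
  if (!is.null(A_eq)) {
    req$A_eq <- as.matrix(A_eq)
    req$b_eq <- as.numeric(b_eq)
  }
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  fpy <- tempfile(fileext = ".py")
  jsonlite::write_json(req, fin, digits = NA, matrix = "rowmajor")
  writeLines(c(
    "import json",
    "import numpy as np",
    "from scipy.optimize import linprog",
    sprintf("req = json.load(open('%s'))", fin),
    "kw = dict(c=req['c'], bounds=list(zip(req['lb'], req['ub'])), method='highs')",
    "if 'A_eq' in req:",
    "    kw.update(A_eq=np.array(req['A_eq'], dtype=float), b_eq=req['b_eq'])",
    "r = linprog(**kw)",
    "out = {'status': 'optimal' if r.status == 0 else ('infeasible' if r.status == 2 else 'other'),",
    "       'objective': float(r.fun) if r.status == 0 else None}",
    sprintf("json.dump(out, open('%s', 'w'))", fout)), fpy)
  rc <- system2("python", fpy, stdout = FALSE, stderr = FALSE)
  if (rc != 0) stop("scipy oracle call failed")
  jsonlite::read_json(fout)
}

# brute-force LP oracle: enumerate vertices of {A x <= b, lb <= x <= ub}
oracle_lp_vertex <- function(obj, A_ub = NULL, b_ub = NULL, lb, ub) {
  n <- length(obj)
  Aall <- rbind(if (is.null(A_ub)) NULL else as.matrix(A_ub), diag(n), -diag(n))
  ball <- c(b_ub, rep_len(ub, n), -rep_len(lb, n))
  best <- Inf
  for (idx in utils::combn(nrow(Aall), n, simplify = FALSE)) {
    M <- Aall[idx, , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    x <- solve(M, ball[idx])
    if (all(Aall %*% x <= ball + 1e-8)) best <- min(best, sum(obj * x))
  }
  best
}

# -- metabolic models ---------------------------------------------------------

# independent reachability oracle: breadth-first closure written against
# the reaction list rather than the stoichiometric matrix scan used in the
# package (recursive formulation, different traversal order)
oracle_biomass_reachable <- function(model, disabled = character()) {
  lb <- model$lb; ub <- model$ub
  lb[disabled] <- 0; ub[disabled] <- 0
  avail <- names(which(model$external))
  fired <- rep(FALSE, length(model$rxn_ids))
  repeat {
    progressed <- FALSE
    for (j in seq_along(model$rxn_ids)) {
      s <- model$S[, j]
      fwd_in <- rownames(model$S)[s < 0]
      rev_in <- rownames(model$S)[s > 0]
      can_f <- ub[j] > 1e-12 && all(fwd_in %in% avail)
      can_r <- lb[j] < -1e-12 && all(rev_in %in% avail)
      new_mets <- character()
      if (can_f) new_mets <- c(new_mets, rev_in)
      if (can_r) new_mets <- c(new_mets, fwd_in)
      new_mets <- setdiff(new_mets, avail)
      if (length(new_mets)) { avail <- c(avail, new_mets); progressed <- TRUE }
    }
    if (!progressed) break
  }
  j <- match(model$biomass, model$rxn_ids)
  ub[j] > 1e-12 && all(rownames(model$S)[model$S[, j] < 0] %in% avail)
}

# hand-rolled 2x2-margin enumeration for the Fisher oracle
oracle_fisher_upper <- function(k, K, n, M) {
  kk <- max(0, n + K - M):min(n, K)
  probs <- vapply(kk, function(x)
    choose(K, x) * choose(M - K, n - x) / choose(M, n), numeric(1))
  sum(probs[kk >= k])
}

# tiny helper for planted-module evaluation
module_recovery <- function(net, module_idx) {
  A <- net$adjacency
  inn <- A[module_idx, module_idx][upper.tri(A[module_idx, module_idx])]
  n_all <- sum(A[upper.tri(A)])
  n_in <- sum(inn)
  n_pairs <- length(net$genes) * (length(net$genes) - 1) / 2
  in_pairs <- length(module_idx) * (length(module_idx) - 1) / 2
  list(recall = n_in / in_pairs,
       fpr = (n_all - n_in) / (n_pairs - in_pairs))
}
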