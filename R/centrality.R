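# Centrality measures on undirected, unweighted, possibly disconnected
# graphs.
#
# Conventions (chosen to reproduce the mock-graph worked examples):
#   degree       d_i = sum_j A_ij
#   eigenvector  dominant eigenpair of A by power iteration; e >= 0,
#                ||e||_2 = 1.  On a disconnected graph the dominant
#                eigenvector lives on the component with the largest
#                spectral radius; entries elsewhere are zero.
#   betweenness  sum over unordered pairs {j,k} (j,k != i) of
#                sigma(j,k | through i) / sigma(j,k); unreachable pairs
#                contribute zero; no endpoint contribution; unnormalized.
#   closeness    harmonic form c_i = sum_{j != i} 1 / g_ij with 1/Inf = 0,
#                finite and informative on disconnected graphs.

# Accept a coexpression_network, mock_graph, igraph, or plain symmetric
# 0/1 adjacency matrix.
as_adjacency <- function(x) {
  if (inherits(x, "coexpression_network")) return(x$adjacency)
  if (inherits(x, "mock_graph")) return(x$adjacency)
  if (inherits(x, "igraph")) {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop_nf("igraph object supplied but igraph is not installed")
    A <- as.matrix(igraph::as_adjacency_matrix(x))
    A[A > 1] <- 1
    return(A)
  }
  if (is.matrix(x) && is.numeric(x)) {
    if (nrow(x) != ncol(x) || !isTRUE(all.equal(x, t(x))))
      stop_nf("adjacency matrix must be square and symmetric")
    A <- x
    diag(A) <- 0
    A[A != 0] <- 1
    if (is.null(rownames(A)))
      dimnames(A) <- list(as.character(seq_len(nrow(A))),
                          as.character(seq_len(nrow(A))))
    return(A)
  }
  stop_nf("cannot interpret object of class '%s' as a graph", class(x)[1])
}

# Adjacency list (integer neighbor indices) from adjacency matrix.
adj_list <- function(A) apply(A > 0, 1, which, simplify = FALSE)

#' Degree centrality
#' @param net a network (adjacency matrix, `coexpression_network`,
#'   [mock_graph()], or igraph object).
#' @return named integer vector of node degrees.
#' @export
degree_centrality <- function(net) {
  A <- as_adjacency(net)
  stats::setNames(as.integer(rowSums(A)), rownames(A))
}

#' Eigenvector centrality
#'
#' Dominant eigenvector of the adjacency matrix by power iteration,
#' normalized to unit Euclidean length with non-negative entries. An
#' edgeless graph yields all zeros.
#'
#' @inheritParams degree_centrality
#' @param tol convergence tolerance on the iterate (sup-norm).
#' @param max_iter iteration cap.
#' @return named numeric vector; attribute `lambda` holds the dominant
#'   eigenvalue.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 100000L) {
  A <- as_adjacency(net)
  n <- nrow(A)
  if (sum(A) == 0) {
    e <- stats::setNames(numeric(n), rownames(A))
    attr(e, "lambda") <- 0
    return(e)
  }
  # Power-iterate on A + I: for a bipartite component the adjacency
  # spectrum is symmetric (lambda_min = -lambda_max) and plain iteration
  # oscillates; the unit shift makes the Perron root strictly dominant in
  # modulus without changing eigenvectors. The positive start vector puts
  # weight on every component; the component with the largest spectral
  # radius wins in the limit.
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    w <- drop(A %*% v) + v
    nw <- sqrt(sum(w * w))
    if (nw == 0) break
    w <- w / nw
    if (max(abs(w - v)) < tol) { v <- w; break }
    v <- w
  }
  v[v < 0] <- 0
  v[v < 1e-12] <- 0
  if (any(v > 0)) v <- v / sqrt(sum(v * v))
  lambda <- drop(v %*% A %*% v)  # Rayleigh quotient
  e <- stats::setNames(v, rownames(A))
  attr(e, "lambda") <- lambda
  e
}

#' Betweenness centrality
#'
#' Brandes' accumulation on the unweighted graph; pair convention:
#' unordered pairs, endpoints excluded, unreachable pairs contribute zero,
#' no normalization.
#'
#' @inheritParams degree_centrality
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(net) {
  A <- as_adjacency(net)
  n <- nrow(A)
  nb <- adj_list(A)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_vis <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_vis <- c(order_vis, v)
      for (w in nb[[v]]) {
        if (dist[w] < 0L) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_vis)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  stats::setNames(bc / 2, rownames(A))  # ordered -> unordered pairs
}

# All-pairs BFS geodesic distances (Inf when unreachable).
bfs_distances <- function(A) {
  n <- nrow(A)
  nb <- adj_list(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    D[s, ] <- dist
  }
  D
}

#' Harmonic closeness centrality
#'
#' `c_i = sum_{j != i} 1 / g_ij`, with unreachable pairs contributing zero,
#' so the measure stays finite and strictly positive for every non-isolated
#' node of a disconnected graph.
#'
#' @inheritParams degree_centrality
#' @return named numeric vector.
#' @export
closeness_centrality <- function(net) {
  A <- as_adjacency(net)
  D <- bfs_distances(A)
  diag(D) <- Inf
  stats::setNames(rowSums(1 / D), rownames(A))
}
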