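test_that("components handle degenerate and standard graphs", {
  # empty graph: all singletons
  empty <- matrix(0, 5, 5)
  expect_equal(graph_components(empty)$sizes, rep(1L, 5))
  # complete graph: one component
  comp <- matrix(1, 6, 6); diag(comp) <- 0
  expect_equal(graph_components(comp)$sizes, 6L)
  expect_equal(graph_components(mock_graph())$sizes, c(4, 2, 1, 1))
})

test_that("degree centrality satisfies the handshake lemma", {
  set.seed(31)
  for (i in 1:20) {
    A <- random_adjacency(sample(2:12, 1), stats::runif(1, 0.1, 0.9))
    expect_equal(sum(degree_centrality(A)), sum(A))
  }
})

test_that("eigenvector centrality: symmetry, zeros off the dominant component", {
  k <- 5
  K <- matrix(1, k, k); diag(K) <- 0
  e <- eigenvector_centrality(K)
  expect_equal(as.vector(e), rep(1 / sqrt(k), k), tolerance = 1e-8)
  g <- mock_graph()
  e <- eigenvector_centrality(g)
  expect_gt(e[["4"]], e[["5"]])            # quality of neighbors matters
  expect_equal(unname(e[5:8]), rep(0, 4))  # dominant eigenpair lives in
                                           # the largest component
  edgeless <- matrix(0, 4, 4)
  expect_true(all(eigenvector_centrality(edgeless) == 0))
})

test_that("betweenness and closeness match textbook small cases", {
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))
  b <- betweenness_centrality(mock_graph())
  expect_equal(unname(b), c(0, 2, 0, 0, 0, 0, 0, 0))  # pairs {1,4}, {3,4}
  # star: hub closeness = number of leaves
  k <- 6
  star <- matrix(0, k + 1, k + 1)
  star[1, 2:(k + 1)] <- star[2:(k + 1), 1] <- 1
  expect_equal(unname(closeness_centrality(star))[1], k)
  cl <- closeness_centrality(mock_graph())
  expect_equal(unname(cl[c("4", "5", "7")]), c(2, 1, 0))
})

test_that("all four centralities match independent oracles on random graphs", {
  set.seed(77)
  for (i in 1:40) {
    A <- random_adjacency(sample(2:8, 1), stats::runif(1, 0.15, 0.9))
    expect_centralities_match_oracles(A)
  }
})

test_that("node relabeling permutes centralities conformably; isolated nodes are inert", {
  set.seed(13)
  A <- random_adjacency(9, 0.35)
  perm <- sample(9)
  Ap <- A[perm, perm]
  tab <- centrality_table(A)
  tabp <- centrality_table(Ap)
  for (mcol in c("degree", "betweenness", "closeness"))
    expect_equal(tabp[[mcol]], tab[[mcol]][perm])
  # adding an isolated node leaves every other node untouched
  A2 <- rbind(cbind(A, 0), 0)
  dimnames(A2) <- list(c(rownames(A), "iso"), c(rownames(A), "iso"))
  tab2 <- centrality_table(A2)
  for (mcol in c("degree", "eigenvector", "betweenness", "closeness"))
    expect_equal(tab2[[mcol]][1:9], tab[[mcol]], tolerance = 1e-8)
  expect_equal(tab2$degree[10], 0)
})

test_that("combined centrality normalizes per measure and flags TI correctly", {
  tab <- centrality_table(mock_graph())
  # node 2 attains the maximum of all four measures -> combined exactly 1
  expect_equal(tab$combined[tab$gene == "2"], 1)
  expect_true(all(tab$combined[tab$gene %in% c("7", "8")] == 0))
  # isolated genes are never TI, at any fraction
  for (f in c(0.1, 0.5, 1)) {
    ti <- classify_ti(tab, top_fraction = f)
    expect_false(any(ti[tab$is_isolated]))
  }
  expect_error(classify_ti(tab, top_fraction = 0), "top_fraction")
  expect_error(classify_ti(tab, top_fraction = 1.2), "top_fraction")
  # all-tied combined scores: every non-isolated gene is TI
  tied <- data.frame(combined = c(rep(0.4, 6), 0, 0),
                     is_isolated = c(rep(FALSE, 6), TRUE, TRUE))
  expect_equal(sum(classify_ti(tied, 0.5)), 6)
  # distinct scores: exactly the top half
  dist10 <- data.frame(combined = seq(0.1, 1, by = 0.1),
                       is_isolated = rep(FALSE, 10))
  expect_equal(which(classify_ti(dist10, 0.5)), 6:10)
  # a measure that is identically zero is dropped from the average
  tri <- matrix(0, 3, 3); tri[upper.tri(tri)] <- 1; tri <- tri + t(tri)
  tt <- centrality_table(tri)   # triangle: betweenness all zero
  expect_equal(tt$combined, rep(1, 3))
  # per-measure TI mode adds one flag column per measure
  pm <- centrality_table(mock_graph(), per_measure = TRUE)
  expect_true(all(c("TI_degree", "TI_eigenvector", "TI_betweenness",
                    "TI_closeness") %in% names(pm)))
  expect_false(any(pm$TI_degree[pm$is_isolated]))
})

test_that("degree-distribution fit recovers exact and generated power laws", {
  # exact histogram count(k) = C k^-2: slope -2, R^2 = 1
  d <- rep(c(1, 2, 4, 8), times = c(64, 16, 4, 1))
  fit <- degree_distribution_fit(d)
  expect_true(fit$available)
  expect_equal(fit$exponent, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # a regular graph has one distinct degree: diagnostic refused
  ring <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; ring[i, j] <- ring[j, i] <- 1 }
  expect_false(degree_distribution_fit(ring)$available)
  # preferential-attachment graphs fit in the scale-free exponent band
  ex <- vapply(1:10, function(seed) {
    set.seed(seed)
    g <- igraph::sample_pa(2000, directed = FALSE)
    degree_distribution_fit(as.numeric(igraph::degree(g)))$exponent
  }, numeric(1))
  expect_true(all(ex >= 1.5 & ex <= 3.5))
})
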