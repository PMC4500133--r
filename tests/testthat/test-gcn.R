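make_expr <- function(values) {
  x <- do.call(rbind, values)
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  colnames(x) <- paste0("c", seq_len(ncol(x)))
  x
}

test_that("plug-in MI reproduces closed-form contingency results", {
  # identical rows with >= n_bins distinct values: MI(X, X) = H(X), the
  # maximum over that row's pairs
  r <- 2^(1:10) - 1
  x <- make_expr(list(r, r, rev(r)))
  mi <- mutual_information_matrix(x, n_bins = 2, estimator = "plugin")
  expect_equal(mi["g1", "g2"], 1)           # H = 1 bit for 2 balanced bins
  expect_equal(mi["g1", "g2"], max(mi[1, -1]))
  # perfect association with uniform marginals: counts [[5,0],[0,5]]
  a <- c(rep(1, 5), rep(9, 5)); b <- c(rep(4, 5), rep(7, 5))
  mi2 <- mutual_information_matrix(make_expr(list(a, b)), n_bins = 2,
                                   estimator = "plugin")
  expect_equal(mi2["g1", "g2"], 1)
  # independent rows at large m: MI within estimator bias of 0, and equal
  # to the brute-force contingency-table computation
  set.seed(99)
  m <- 10000
  x3 <- make_expr(list(stats::rexp(m, 0.01), stats::rexp(m, 0.01)))
  mi3 <- mutual_information_matrix(x3, n_bins = 2, estimator = "plugin")
  expect_lt(mi3["g1", "g2"], 0.01)
  b1 <- netflux:::bin_row(log2(x3[1, ] + 1), 2)
  b2 <- netflux:::bin_row(log2(x3[2, ] + 1), 2)
  expect_lt(abs(mi3["g1", "g2"] - oracle_mi_binned(b1, b2)), 1e-12)
})

test_that("both MI estimators satisfy the shared contract", {
  set.seed(4)
  x <- make_expr(lapply(1:6, function(i) stats::runif(30, 0, 100)))
  x[3, ] <- 50  # constant row
  for (est in c("plugin", "bspline")) {
    mi <- mutual_information_matrix(x, estimator = est)
    expect_true(all(mi >= 0))
    expect_equal(mi, t(mi))
    expect_true(all(mi[3, -3] == 0))  # constant row: MI 0 vs everything
  }
  # the B-spline estimator ranks a dependent pair well above the
  # independent-pair bias floor (~0.65 bits at m = 30 with 10 bins)
  y <- make_expr(list(x[1, ], x[1, ] * 1.3 + 2, stats::runif(30, 0, 100)))
  mib <- mutual_information_matrix(y, estimator = "bspline")
  expect_gt(mib["g1", "g2"], 2 * mib["g1", "g3"])
})

test_that("CLR z-scores match a hand-computed 3-gene oracle", {
  mi <- matrix(c(0, 0.9, 0.1,
                 0.9, 0, 0.1,
                 0.1, 0.1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  diag(mi) <- 1
  # row a background (off-diagonal): {0.9, 0.1}, mean 0.5, sample sd
  # 0.4*sqrt(2); z_a(b) = 0.4/(0.4*sqrt(2)) = 1/sqrt(2), symmetric for b
  Zmin <- clr_zscores(mi, combine = "min")
  expect_equal(Zmin["a", "b"], 1 / sqrt(2), tolerance = 1e-12)
  # row c has zero background sd -> its z-scores are all 0, so the pair
  # score of (a, c) under min is a's view, negative
  expect_equal(Zmin["a", "c"], -1 / sqrt(2), tolerance = 1e-12)
  Zclr <- clr_zscores(mi, combine = "clr")
  expect_equal(Zclr["a", "b"], 1, tolerance = 1e-12)  # sqrt(1/2 + 1/2)
  expect_equal(Zclr["a", "c"], 0)                     # negatives clipped
})

test_that("CLR z-scores are symmetric and flat backgrounds give zero", {
  flat <- matrix(0.3, 4, 4); diag(flat) <- 1
  expect_true(all(clr_zscores(flat) == 0))
  set.seed(8)
  mi <- abs(matrix(stats::rnorm(49), 7, 7)); mi <- (mi + t(mi)) / 2
  for (comb in c("min", "clr")) {
    Z <- clr_zscores(mi, combine = comb)
    expect_equal(Z, t(Z))
    expect_true(all(diag(Z) == 0))
  }
})

test_that("bootstrap network respects thresholds, seeds and gene order", {
  x <- generate_expression(
    expression_spec(20, 15, modules = list(list(size = 6, cor = 0.9)),
                    seed = 21))
  expect_error(bootstrap_network(x, n_boot = 10, support_min = 11),
               "cannot exceed")
  expect_error(bootstrap_network(x[, 1:4], drop_per_iter = 2), "conditions")
  # unreachable threshold: empty edge set even at support_min = 0...
  net_inf <- bootstrap_network(x, z_threshold = Inf, n_boot = 5,
                               support_min = 0, seed = 1)
  expect_equal(sum(net_inf$adjacency), 0)
  # ...because support_min = 0 would otherwise connect everything
  expect_true(all(net_inf$support == 0))

  net <- bootstrap_network(x, n_boot = 40, support_min = 20, seed = 5)
  # identical rerun: identical support counts
  net_b <- bootstrap_network(x, n_boot = 40, support_min = 20, seed = 5)
  expect_identical(net$support, net_b$support)
  # raising support_min keeps a subset of edges
  net_hi <- bootstrap_network(x, n_boot = 40, support_min = 35, seed = 5)
  expect_true(all(net_hi$adjacency <= net$adjacency))
  # permuting genes permutes the adjacency conformably
  perm <- sample(rownames(x))
  net_p <- bootstrap_network(x[perm, ], n_boot = 40, support_min = 20,
                             seed = 5)
  expect_identical(net_p$adjacency, net$adjacency[perm, perm])
  # gene filter subsets the matrix before inference
  sub <- rownames(x)[1:8]
  net_s <- bootstrap_network(x, n_boot = 40, support_min = 20, seed = 5,
                             genes = sub)
  expect_identical(net_s$genes, sub)
  expect_error(bootstrap_network(x, genes = c("nope", sub)), "absent")
})

test_that("no planted signal leaks from a correlation-0 module", {
  # with the module parameter at 0 the module's edge rate matches the
  # background false-positive rate (both essentially zero here)
  rates <- vapply(1:3, function(seed) {
    x <- generate_expression(
      expression_spec(40, 20, modules = list(list(size = 8, cor = 0)),
                      seed = seed))
    net <- bootstrap_network(x, n_boot = 60, support_min = 45, seed = seed)
    rec <- module_recovery(net, 1:8)
    c(rec$recall, rec$fpr)
  }, numeric(2))
  expect_lt(max(abs(rates[1, ] - rates[2, ])), 0.05)
})
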