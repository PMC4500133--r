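test_that("cross-classification follows the TF/Tf/Ft rules and conserves counts", {
  genes <- paste0("g", 1:8)
  ti <- stats::setNames(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
                        genes)
  grp <- stats::setNames(c(3L, 1L, 2L, 1L, 2L, 3L, 1L, 1L), genes)
  iso <- stats::setNames(c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
                         genes)
  cls <- cross_classify(ti, grp, iso)
  expect_equal(cls$category[cls$gene == "g1"], "TF")   # TI and group 3
  expect_equal(cls$category[cls$gene == "g2"], "Tf")   # TI and group 1
  expect_equal(cls$category[cls$gene == "g3"], "Ft")   # FI, isolated
  expect_equal(cls$category[cls$gene == "g4"], "neither")
  cnt <- attr(cls, "counts")
  expect_equal(unname(cnt["TF"] + cnt["Tf"]), unname(cnt["TI"]))
  expect_equal(unname(cnt["TF"] + cnt["Ft"]), unname(cnt["FI"]))
  # all-isolated input: nothing can be TI, so no TF or Tf
  iso_all <- stats::setNames(rep(TRUE, 8), genes)
  cls2 <- cross_classify(stats::setNames(rep(FALSE, 8), genes), grp, iso_all)
  expect_equal(unname(attr(cls2, "counts")[c("TF", "Tf")]), c(0L, 0L))
  # violations are rejected
  expect_error(cross_classify(ti, grp[1:7], iso), "universes")
  expect_error(cross_classify(stats::setNames(TRUE, "g3")[
    rep("g3", 8)], grp, iso), "universes")
  bad_ti <- ti; bad_ti["g3"] <- TRUE  # isolated gene flagged TI
  expect_error(cross_classify(bad_ti, grp, iso), "isolated")
})

test_that("cross-classification counts are conserved on random inputs", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    genes <- paste0("g", seq_len(n))
    iso <- stats::setNames(stats::runif(n) < 0.3, genes)
    ti <- stats::setNames(stats::runif(n) < 0.5 & !iso, genes)
    grp <- stats::setNames(sample(1:3, n, replace = TRUE), genes)
    cnt <- attr(cross_classify(ti, grp, iso), "counts")
    expect_equal(unname(cnt["TF"] + cnt["Tf"]), sum(ti))
    expect_equal(unname(cnt["TF"] + cnt["Ft"]), sum(grp >= 2))
    expect_equal(sum(cnt[c("TF", "Tf", "Ft", "neither")]), n)
  }
})

test_that("Fisher enrichment equals the hypergeometric closed form", {
  # M = 10, K = n = k = 5: p = 1 / C(10, 5) = 1/252
  universe <- paste0("g", 1:10)
  cats <- stats::setNames(rep(c("hit", "other"), each = 5), universe)
  enr <- fisher_enrichment(universe[1:5], cats, universe)
  expect_equal(enr$p_value[enr$category == "hit"], 1 / 252,
               tolerance = 1e-12)
  # k = 0 for the other category in a disjoint set: p = 1, never flagged
  expect_equal(enr$p_value[enr$category == "other"], 1)
  expect_false(enr$significant[enr$category == "other"])
  expect_error(fisher_enrichment(character(), cats, universe), "empty")
  expect_error(fisher_enrichment("zzz", cats, universe), "subset")
})

test_that("Fisher enrichment matches margin enumeration and fisher.test", {
  set.seed(77)
  for (i in 1:25) {
    M <- sample(8:20, 1)
    universe <- paste0("u", seq_len(M))
    K <- sample(2:(M - 2), 1)
    n <- sample(2:(M - 2), 1)
    cats <- stats::setNames(c(rep("c1", K), rep("bg", M - K)), universe)
    set <- sample(universe, n)
    enr <- fisher_enrichment(set, cats, universe)
    k <- enr$k[enr$category == "c1"]
    p <- enr$p_value[enr$category == "c1"]
    expect_equal(p, oracle_fisher_upper(k, K, n, M), tolerance = 1e-10)
    ft <- stats::fisher.test(matrix(c(k, n - k, K - k, M - n - K + k), 2),
                             alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-8)
  }
})

test_that("Fisher significance is calibrated under random draws", {
  # a uniformly drawn set should be flagged in ~5% of categories
  set.seed(11)
  M <- 60
  universe <- paste0("u", 1:M)
  cats <- stats::setNames(rep(paste0("c", 1:6), each = 10), universe)
  hits <- vapply(1:400, function(i) {
    enr <- fisher_enrichment(sample(universe, 20), cats, universe)
    mean(enr$p_value < 0.05)
  }, numeric(1))
  # conservative check: the discrete hypergeometric makes the test
  # under-reject, so the rate must be at or below nominal (and not zero)
  expect_lt(mean(hits), 0.07)
  expect_gt(mean(hits), 0.005)
})

test_that("centrality randomization: degenerate, extreme and reproducible cases", {
  universe <- stats::setNames(rep(1, 50), paste0("g", 1:50))
  r <- centrality_randomization(paste0("g", 1:10), universe, n_draws = 200,
                                seed = 3)
  expect_equal(r$p_upper, 1)  # constant centrality: null always >= observed
  # group = top genes with distinct values: minimal attainable p
  vals <- stats::setNames(seq_len(200), paste0("g", 1:200))
  top <- paste0("g", 191:200)
  r2 <- centrality_randomization(top, vals, n_draws = 300, seed = 4)
  expect_equal(r2$p_upper, 1 / 301)
  # reproducibility and add-one bounds
  r3 <- centrality_randomization(top, vals, n_draws = 300, seed = 4)
  expect_identical(r2$null, r3$null)
  expect_gte(r2$p_lower, 1 / 301)
  expect_error(centrality_randomization(character(), vals), "empty")
  expect_error(centrality_randomization("nope", vals), "outside")
  # median statistic is exposed
  r4 <- centrality_randomization(top, vals, n_draws = 50, seed = 1,
                                 statistic = "median")
  expect_equal(r4$observed, stats::median(vals[top]))
})

test_that("randomization p-values are approximately uniform under the null", {
  set.seed(31)
  vals <- stats::setNames(stats::rnorm(150), paste0("g", 1:150))
  ps <- vapply(1:300, function(i) {
    grp <- sample(names(vals), 12)
    centrality_randomization(grp, vals, n_draws = 99, seed = 1000 + i)$p_upper
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))  # discrete p: ties
  expect_gt(ks$p.value, 0.01)
})
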