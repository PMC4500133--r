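# Shared toy models built in code.
toy_parallel <- function() {
  # S_ext -> A; A -> B by two gene-backed routes; B -> biomass
  S <- matrix(0, 4, 4,
              dimnames = list(c("S_ext", "A", "B", "BM_ext"),
                              c("R_upt", "R1", "R2", "R_bio")))
  S["S_ext", "R_upt"] <- -1; S["A", "R_upt"] <- 1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["A", "R2"] <- -1; S["B", "R2"] <- 1
  S["B", "R_bio"] <- -1; S["BM_ext", "R_bio"] <- 1
  metabolic_model(S, external = c(TRUE, FALSE, FALSE, TRUE),
                  lb = rep(0, 4), ub = rep(10, 4),
                  gpr = c("", "g1", "g2", ""), biomass = "R_bio")
}

test_that("GPR parsing and evaluation follow the AND-min / OR-max rules", {
  expect_equal(eval_gpr_numeric(parse_gpr("(g1 AND g2)"),
                                c(g1 = 10, g2 = 4)), 4)
  expect_equal(eval_gpr_numeric(parse_gpr("(g1 OR g2)"),
                                c(g1 = 10, g2 = 4)), 10)
  expect_equal(eval_gpr_numeric(parse_gpr("((g1 AND g2) OR g3)"),
                                c(g1 = 10, g2 = 4, g3 = 7)), 7)
  # boolean semantics for knockouts are distinct from the numeric mapping
  ast <- parse_gpr("(g1 AND g2) OR g3")
  expect_true(eval_gpr_boolean(ast, c(g1 = FALSE, g2 = TRUE, g3 = TRUE)))
  expect_false(eval_gpr_boolean(ast, c(g1 = FALSE, g2 = TRUE, g3 = FALSE)))
  # round-trip through the deparser preserves semantics
  expect_equal(deparse_gpr(parse_gpr(deparse_gpr(ast))), deparse_gpr(ast))
  expect_error(parse_gpr("g1 AND (g2"), "parenthes")
  expect_error(parse_gpr("AND g1"), "malformed")
  expect_null(parse_gpr(""))
})

test_that("expression maps onto reactions with median imputation", {
  m <- toy_parallel()
  expr <- matrix(c(10, 4), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  rx <- map_expression_to_reactions(expr, m, "c1")
  expect_equal(unname(rx[c("R1", "R2")]), c(10, 4))
  expect_true(all(is.na(rx[c("R_upt", "R_bio")])))
  expr1 <- expr["g1", , drop = FALSE]
  expect_warning(rx2 <- map_expression_to_reactions(expr1, m, "c1"),
                 "imputing")
  expect_equal(unname(rx2[["R2"]]), 10)  # median of the single value
})

test_that("E-Fmin: forced paths, weighted route choice, parsimonious limit", {
  # single linear path: stoichiometry forces every flux to the biomass
  # demand regardless of weights
  sm <- generate_model(model_spec("linear", 3, seed = 2))
  for (rx in list(NULL, stats::setNames(c(5, 1, 9, 2, 7),
                                        sm$model$rxn_ids))) {
    fs <- efmin_fluxes(sm$model, rx, growth_floor = 1)
    expect_equal(fs$status, "optimal")
    expect_equal(unname(fs$fluxes), rep(1, 5), tolerance = 1e-9)
  }
  # two parallel routes: all flux goes to the highly expressed one
  m <- toy_parallel()
  expr <- matrix(c(100, 1), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  fs <- efmin_fluxes(m, map_expression_to_reactions(expr, m, "c1"))
  expect_equal(unname(fs$fluxes["R1"]), 1, tolerance = 1e-9)
  expect_equal(unname(fs$fluxes["R2"]), 0, tolerance = 1e-9)
  # swap expression, route choice follows
  expr2 <- matrix(c(1, 100), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  fs2 <- efmin_fluxes(m, map_expression_to_reactions(expr2, m, "c1"))
  expect_equal(unname(fs2$fluxes["R2"]), 1, tolerance = 1e-9)
  # uniform expression: objective equals the unweighted (parsimonious)
  # flux minimum
  expr3 <- matrix(c(7, 7), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  fs3 <- efmin_fluxes(m, map_expression_to_reactions(expr3, m, "c1"))
  fs4 <- efmin_fluxes(m, NULL)
  expect_equal(fs3$objective, fs4$objective, tolerance = 1e-9)
  # infeasible growth floor is reported, not silently zeroed
  fs5 <- efmin_fluxes(m, NULL, growth_floor = 99)
  expect_equal(fs5$status, "infeasible")
  expect_null(fs5$fluxes)
})

test_that("flux states satisfy steady state and bounds", {
  for (seed in 1:6) {
    topo <- c("linear", "parallel", "branched")[(seed %% 3) + 1]
    sm <- generate_model(model_spec(topo, 4, seed = seed))
    ex <- generate_model_expression(sm, 3, seed = seed)
    for (cond in colnames(ex)) {
      fs <- efmin_fluxes(sm$model,
                         map_expression_to_reactions(ex, sm$model, cond))
      v <- fs$fluxes
      expect_lt(max(abs(netflux:::internal_S(sm$model) %*% v)), 1e-9)
      expect_true(all(v >= sm$model$lb - 1e-9 & v <= sm$model$ub + 1e-9))
    }
  }
})

test_that("MOMA knockouts: inert genes, lethal paths, rerouting", {
  m <- toy_parallel()
  # gene in no GPR: nothing disabled
  m2 <- metabolic_model(m$S, external = m$external, lb = m$lb, ub = m$ub,
                        gpr = m$gpr, biomass = "R_bio",
                        genes = c("g1", "g2", "g_orphan"))
  fs <- efmin_fluxes(m2, NULL)
  ko <- moma_knockout(m2, fs, "g_orphan")
  expect_false(ko$lethal); expect_false(ko$flux_changed)
  expect_equal(ko$moma_distance, 0, tolerance = 1e-9)
  # single-path model: any pathway gene is lethal
  sm <- generate_model(model_spec("linear", 3, seed = 5))
  fsl <- efmin_fluxes(sm$model, NULL)
  for (g in sm$model$genes) {
    ko <- moma_knockout(sm$model, fsl, g)
    expect_true(ko$lethal)
    expect_true(ko$flux_changed)
  }
  # parallel routes: knocking out the active route reroutes flux
  expr <- matrix(c(100, 1), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  fsp <- efmin_fluxes(m, map_expression_to_reactions(expr, m, "c1"),
                      condition = "c1")
  expect_equal(unname(fsp$fluxes["R1"]), 1, tolerance = 1e-9)
  ko <- moma_knockout(m, fsp, "g1")
  expect_false(ko$lethal)
  expect_true(ko$flux_changed)
  # the backup route must now carry the parent biomass demand
  expect_equal(unname(ko$mutant_fluxes["R2"]), fsp$biomass_flux,
               tolerance = 1e-9)
  expect_equal(ko$moma_distance, 2, tolerance = 1e-9)  # R1: 1->0, R2: 0->1
  expect_error(moma_knockout(m, fsp, "gX"), "not in the model")
})

test_that("knockout objective is monotone under added constraints", {
  # closing reactions can only increase the weighted flux minimum
  for (seed in 1:4) {
    sm <- generate_model(model_spec("parallel", 4, seed = seed))
    ex <- generate_model_expression(sm, 3, seed = seed)
    rx <- map_expression_to_reactions(ex, sm$model, "cond_1")
    parent <- efmin_fluxes(sm$model, rx)
    for (g in sm$model$genes) {
      off <- netflux:::ko_disabled_reactions(sm$model, g)
      mko <- sm$model
      mko$lb[off] <- 0; mko$ub[off] <- 0
      child <- efmin_fluxes(mko, rx)
      if (child$status == "optimal")
        expect_gte(child$objective, parent$objective - 1e-9)
    }
  }
})

test_that("group classification matches the knockout grid rules", {
  sm <- generate_model(model_spec("parallel", 4, seed = 7))
  ex <- generate_model_expression(sm, 4, seed = 7)
  scr <- knockout_screen(sm$model, ex)
  cls <- classify_groups(scr)
  truth <- c(lethal = 3L, flux_altering = 2L, silent = 1L)
  expect_equal(cls$group[match(names(sm$labels), cls$gene)],
               unname(truth[sm$labels]))
  expect_true(all(cls$is_FI == (cls$group >= 2)))
  # group 3 genes here are lethal everywhere
  expect_equal(attr(cls, "n_lethal_all"), sum(cls$group == 3))
  # incomplete grids are rejected
  expect_error(classify_groups(scr$outcomes[-1, ]), "incomplete")
})

test_that("flux PCA separates regimes and degrades gracefully", {
  mk_state <- function(v, cond) structure(
    list(condition = cond, fluxes = v, objective = sum(abs(v)),
         weights = NULL, status = "optimal", biomass_flux = v[["R_bio"]]),
    class = "flux_state")
  base <- c(R_upt = 1, R1 = 1, R2 = 0, R_bio = 1)
  alt <- c(R_upt = 1, R1 = 0, R2 = 1, R_bio = 1)
  # all identical: one profile, degenerate variance
  same <- lapply(1:4, function(i) mk_state(base, paste0("c", i)))
  p1 <- flux_pca(same)
  expect_equal(p1$n_profiles, 1)
  expect_true(p1$degenerate)
  # two well-separated regimes: 2 profiles, PC1 carries everything
  mixed <- c(lapply(1:3, function(i) mk_state(base, paste0("a", i))),
             lapply(1:3, function(i) mk_state(alt, paste0("b", i))))
  p2 <- flux_pca(mixed)
  expect_equal(p2$n_profiles, 2)
  expect_gt(p2$explained[1], 0.99)
  # variance ratios sum to one on noisy input
  set.seed(55)
  noisy <- lapply(1:5, function(i)
    mk_state(base + c(stats::runif(3, 0, 0.3), 0), paste0("n", i)))
  p3 <- flux_pca(noisy, cluster_tol = 1e-9)
  expect_equal(sum(p3$explained), 1, tolerance = 1e-12)
  expect_error(flux_pca(same[1]), "at least 2")
})
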