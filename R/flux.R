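# Expression-guided flux estimation and in-silico knockouts.
#
# Parent fluxes: weighted flux minimization.  Each reaction receives a
# weight w_r = 1 - e_hat_r, where e_hat_r is the GPR-mapped expression of
# the reaction min-max scaled to [0, 1] across mapped reactions of the
# condition (reactions without a GPR get w_r = 1).  The LP
#
#   min sum_r w_r |v_r|   s.t.  S_int v = 0, lb <= v <= ub,
#                               v_biomass >= growth_floor
#
# is linearized by splitting each flux into non-negative forward/reverse
# parts.  Knockouts: reactions whose GPR evaluates FALSE with the gene
# absent are closed to zero; the mutant flux re-routes minimally around
# the parent state (L1 minimization-of-adjustment), and lethality is
# decided by a separate biomass-maximization LP on the mutant.

#' Map expression onto reactions through GPR rules
#'
#' AND combines by `min` (limiting subunit), OR by `max` (isozymes).
#' GPR genes missing from the expression vector are imputed at the
#' condition median (with a warning); reactions without a GPR get `NA`
#' ("unmapped").
#'
#' @param expr genes x conditions expression matrix.
#' @param model a [metabolic_model()].
#' @param condition condition ID or column index.
#' @return named numeric vector over reactions (`NA` = unmapped).
#' @export
map_expression_to_reactions <- function(expr, model, condition) {
  if (is.character(condition) && !condition %in% colnames(expr))
    stop_nf("condition '%s' not in expression matrix", condition)
  vals <- expr[, condition]
  names(vals) <- rownames(expr)
  need <- setdiff(unlist(lapply(model$gpr_ast, gpr_genes)), names(vals))
  if (length(need)) {
    warning(sprintf("imputing condition-median expression for %d GPR gene(s): %s",
                    length(need), paste(utils::head(need, 5), collapse = ", ")),
            call. = FALSE)
    vals <- c(vals, stats::setNames(rep(stats::median(vals), length(need)), need))
  }
  out <- vapply(model$gpr_ast, function(ast)
    if (is.null(ast)) NA_real_ else eval_gpr_numeric(ast, vals), numeric(1))
  stats::setNames(out, model$rxn_ids)
}

# Weights from mapped reaction expression: min-max scale over mapped
# reactions, w = 1 - e_hat; unmapped reactions and flat expression get w = 1
# (the latter reduces to unweighted, parsimonious flux minimization).
efmin_weights <- function(reaction_expression) {
  w <- rep(1, length(reaction_expression))
  names(w) <- names(reaction_expression)
  mapped <- !is.na(reaction_expression)
  if (any(mapped)) {
    e <- reaction_expression[mapped]
    rng <- range(e)
    ehat <- if (diff(rng) > 0) (e - rng[1]) / diff(rng) else rep(0, length(e))
    w[mapped] <- pmax(1 - ehat, 0)
  }
  w
}

# Split-variable LP skeleton shared by efmin and MOMA: v = f - r with
# f in [max(0, lb), max(0, ub)], r in [max(0, -ub), max(0, -lb)].
split_bounds <- function(lb, ub) {
  list(f_lb = pmax(lb, 0), f_ub = pmax(ub, 0),
       r_lb = pmax(-ub, 0), r_ub = pmax(-lb, 0))
}

#' Expression-guided flux minimization
#'
#' @param model a [metabolic_model()].
#' @param reaction_expression per-reaction expression from
#'   [map_expression_to_reactions()] (`NA` = unmapped), or NULL for
#'   uniform weights (parsimonious minimization).
#' @param growth_floor minimum biomass flux anchoring the solution scale
#'   (arbitrary units; downstream comparisons are biomass-normalized).
#' @param condition optional condition label carried into the result.
#' @return an object of class `flux_state`: list with `condition`,
#'   `fluxes` (named net fluxes), `objective`, `weights`, `status`,
#'   `biomass_flux`.
#' @export
efmin_fluxes <- function(model, reaction_expression = NULL, growth_floor = 1,
                         condition = NA_character_) {
  growth_floor <- check_number(growth_floor, "growth_floor", min = 0)
  if (is.null(reaction_expression))
    reaction_expression <- stats::setNames(
      rep(NA_real_, length(model$rxn_ids)), model$rxn_ids)
  w <- efmin_weights(reaction_expression)
  lb <- model$lb; ub <- model$ub
  bio <- match(model$biomass, model$rxn_ids)
  lb[bio] <- max(lb[bio], growth_floor)
  if (lb[bio] > ub[bio])
    return(structure(list(condition = condition, fluxes = NULL,
                          objective = NA_real_, weights = w,
                          status = "infeasible",
                          biomass_flux = NA_real_), class = "flux_state"))
  nr <- length(model$rxn_ids)
  sb <- split_bounds(lb, ub)
  Sint <- internal_S(model)
  A_eq <- cbind(Sint, -Sint)
  res <- lp_solve(obj = c(w, w), A_eq = A_eq, b_eq = numeric(nrow(Sint)),
                  lb = c(sb$f_lb, sb$r_lb), ub = c(sb$f_ub, sb$r_ub))
  if (res$status != "optimal")
    return(structure(list(condition = condition, fluxes = NULL,
                          objective = NA_real_, weights = w,
                          status = res$status, biomass_flux = NA_real_),
                     class = "flux_state"))
  v <- res$x[seq_len(nr)] - res$x[nr + seq_len(nr)]
  names(v) <- model$rxn_ids
  structure(list(condition = condition, fluxes = v,
                 objective = res$objective, weights = w, status = "optimal",
                 biomass_flux = unname(v[model$biomass])),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("flux_state [%s]: status %s, biomass %.4g, objective %.4g\n",
              x$condition, x$status, x$biomass_flux, x$objective))
  invisible(x)
}

# Maximum attainable biomass flux under the given (possibly knocked-out)
# bounds; -Inf if infeasible.
max_biomass <- function(model, lb = model$lb, ub = model$ub) {
  nr <- length(model$rxn_ids)
  bio <- match(model$biomass, model$rxn_ids)
  sb <- split_bounds(lb, ub)
  Sint <- internal_S(model)
  obj <- numeric(2 * nr)
  obj[bio] <- -1; obj[nr + bio] <- 1
  res <- lp_solve(obj, A_eq = cbind(Sint, -Sint), b_eq = numeric(nrow(Sint)),
                  lb = c(sb$f_lb, sb$r_lb), ub = c(sb$f_ub, sb$r_ub))
  if (res$status != "optimal") return(-Inf)
  -res$objective
}

#' Single-gene knockout by linearized metabolic adjustment
#'
#' Closes all reactions whose GPR turns FALSE without the gene, then finds
#' the mutant flux vector minimizing the L1 distance to the parent state
#' (the linear recast of metabolic-adjustment minimization). Lethality is
#' decided separately by maximizing mutant biomass: a knockout is lethal
#' when the mutant cannot reach `growth_tol` times the parent biomass
#' flux. Flux change is judged on biomass-normalized (relative) flux
#' vectors at tolerance `flux_tol`.
#'
#' @param model a [metabolic_model()].
#' @param parent a `flux_state` from [efmin_fluxes()] (status "optimal").
#' @param gene gene ID to delete.
#' @param growth_tol relative growth threshold for lethality.
#' @param flux_tol sup-norm tolerance on relative flux change.
#' @return an object of class `knockout_outcome`: list with `gene`,
#'   `condition`, `lethal`, `flux_changed`, `moma_distance`,
#'   `mutant_fluxes`, `disabled_reactions`, `mutant_biomass_max`.
#' @export
moma_knockout <- function(model, parent, gene, growth_tol = 1e-6,
                          flux_tol = 1e-6) {
  if (!inherits(parent, "flux_state") || parent$status != "optimal")
    stop_nf("'parent' must be an optimal flux_state")
  off <- ko_disabled_reactions(model, gene)
  lb <- model$lb; ub <- model$ub
  lb[off] <- 0; ub[off] <- 0
  p <- parent$fluxes
  nr <- length(model$rxn_ids)

  mb <- max_biomass(model, lb, ub)
  lethal <- mb < growth_tol * parent$biomass_flux

  # MOMA LP: variables f, r (flux split) and d+ ,d- with v - d+ + d- = p
  sb <- split_bounds(lb, ub)
  Sint <- internal_S(model)
  nm <- nrow(Sint)
  dcap <- (model$ub - model$lb) + abs(p) + 1
  A_eq <- rbind(
    cbind(Sint, -Sint, matrix(0, nm, 2 * nr)),
    cbind(diag(nr), -diag(nr), -diag(nr), diag(nr)))
  b_eq <- c(numeric(nm), p)
  res <- lp_solve(obj = c(numeric(2 * nr), rep(1, 2 * nr)),
                  A_eq = A_eq, b_eq = b_eq,
                  lb = c(sb$f_lb, sb$r_lb, numeric(2 * nr)),
                  ub = c(sb$f_ub, sb$r_ub, dcap, dcap))
  if (res$status != "optimal") {
    # a knocked-out network with no feasible steady state at all
    return(structure(list(gene = gene, condition = parent$condition,
                          lethal = TRUE, flux_changed = TRUE,
                          moma_distance = NA_real_, mutant_fluxes = NULL,
                          disabled_reactions = off,
                          mutant_biomass_max = mb),
                     class = "knockout_outcome"))
  }
  v <- res$x[seq_len(nr)] - res$x[nr + seq_len(nr)]
  names(v) <- model$rxn_ids
  dist <- sum(abs(v - p))
  vb <- unname(v[model$biomass])
  if (!lethal && vb > growth_tol * parent$biomass_flux) {
    rel_change <- max(abs(v / vb - p / parent$biomass_flux))
    flux_changed <- rel_change > flux_tol
  } else {
    # no growth: the relative distribution is not comparable; any nonzero
    # adjustment counts as a change
    flux_changed <- dist > flux_tol
  }
  structure(list(gene = gene, condition = parent$condition, lethal = lethal,
                 flux_changed = flux_changed, moma_distance = dist,
                 mutant_fluxes = v, disabled_reactions = off,
                 mutant_biomass_max = mb),
            class = "knockout_outcome")
}

#' Exhaustive knockout screen over genes and conditions
#'
#' Runs [efmin_fluxes()] per condition and [moma_knockout()] for every
#' gene under every condition.
#'
#' @param model a [metabolic_model()].
#' @param expr genes x conditions expression matrix covering the model's
#'   GPR genes (missing genes are median-imputed); NULL for uniform
#'   weights in every condition.
#' @param conditions condition IDs to simulate (default: all columns of
#'   `expr`).
#' @param genes genes to delete (default: all model genes).
#' @param growth_floor,growth_tol,flux_tol see [efmin_fluxes()] and
#'   [moma_knockout()].
#' @return list of class `knockout_screen`: `outcomes` (data.frame gene x
#'   condition with lethal, flux_changed, moma_distance), `parents` (list
#'   of per-condition `flux_state`s), `params`.
#' @export
knockout_screen <- function(model, expr = NULL, conditions = NULL,
                            genes = model$genes, growth_floor = 1,
                            growth_tol = 1e-6, flux_tol = 1e-6) {
  if (is.null(conditions))
    conditions <- if (is.null(expr)) "uniform" else colnames(expr)
  parents <- list()
  rows <- list()
  for (cond in conditions) {
    rx <- if (is.null(expr)) NULL else
      map_expression_to_reactions(expr, model, cond)
    ps <- efmin_fluxes(model, rx, growth_floor = growth_floor,
                       condition = cond)
    if (ps$status != "optimal")
      stop_nf("parent flux estimation failed for condition '%s': %s",
              cond, ps$status)
    parents[[cond]] <- ps
    for (g in genes) {
      ko <- moma_knockout(model, ps, g, growth_tol = growth_tol,
                          flux_tol = flux_tol)
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, condition = cond, lethal = ko$lethal,
                   flux_changed = ko$flux_changed,
                   moma_distance = ko$moma_distance,
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(outcomes = do.call(rbind, rows), parents = parents,
                 params = list(growth_floor = growth_floor,
                               growth_tol = growth_tol,
                               flux_tol = flux_tol)),
            class = "knockout_screen")
}

#' Functional-importance groups from a knockout grid
#'
#' Group 3: lethal in at least one condition. Group 2: not Group 3 but
#' flux-changing in at least one condition. Group 1: neither. FI genes are
#' Groups 2 and 3.
#'
#' @param outcomes data.frame with columns gene, condition, lethal,
#'   flux_changed covering the complete gene x condition grid (e.g.,
#'   `knockout_screen(...)$outcomes`, or the `knockout_screen` object
#'   itself).
#' @return data.frame of class `fi_classification`: gene, group (1/2/3),
#'   lethal_conditions, is_FI; attribute `n_lethal_all` counts genes
#'   lethal under every condition.
#' @export
classify_groups <- function(outcomes) {
  if (inherits(outcomes, "knockout_screen")) outcomes <- outcomes$outcomes
  need <- c("gene", "condition", "lethal", "flux_changed")
  if (!all(need %in% names(outcomes)))
    stop_nf("'outcomes' must have columns %s", paste(need, collapse = ", "))
  grid <- table(outcomes$gene, outcomes$condition)
  if (any(grid != 1L))
    stop_nf("incomplete knockout grid: every gene x condition pair must appear exactly once")
  genes <- sort(unique(outcomes$gene))
  n_cond <- length(unique(outcomes$condition))
  agg <- lapply(genes, function(g) {
    o <- outcomes[outcomes$gene == g, ]
    nl <- sum(o$lethal)
    group <- if (nl > 0) 3L else if (any(o$flux_changed)) 2L else 1L
    data.frame(gene = g, group = group, lethal_conditions = nl,
               is_FI = group >= 2L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  attr(out, "n_lethal_all") <- sum(out$lethal_conditions == n_cond &
                                     out$group == 3L)
  class(out) <- c("fi_classification", "data.frame")
  out
}

#' Principal-component summary of condition flux vectors
#'
#' Mean-centered PCA of the condition x reaction matrix of
#' biomass-normalized fluxes, plus the number of distinct flux profiles:
#' conditions whose normalized flux vectors differ by less than
#' `cluster_tol` (Euclidean) are merged transitively into one profile.
#'
#' @param states list of `flux_state`s (one per condition) or a
#'   `knockout_screen` (its parents are used).
#' @param cluster_tol distance below which two conditions share a profile.
#' @return list with `explained` (variance ratios, summing to 1),
#'   `scores` (condition x PC matrix), `n_profiles`, `profile` (condition
#'   to profile ID), `degenerate` (TRUE when fluxes carry no variance).
#' @export
flux_pca <- function(states, cluster_tol = 1e-4) {
  if (inherits(states, "knockout_screen")) states <- states$parents
  if (length(states) < 2) stop_nf("flux_pca needs at least 2 conditions")
  V <- t(vapply(states, function(s) {
    if (s$status != "optimal") stop_nf("non-optimal flux state in flux_pca")
    s$fluxes / s$biomass_flux
  }, numeric(length(states[[1]]$fluxes))))
  rownames(V) <- vapply(states, function(s) as.character(s$condition),
                        character(1))
  D <- as.matrix(stats::dist(V))
  merged <- graph_components((D < cluster_tol) * 1)
  pc <- stats::prcomp(V, center = TRUE, scale. = FALSE)
  var_tot <- sum(pc$sdev^2)
  degenerate <- var_tot < 1e-24
  explained <- if (degenerate) rep(NA_real_, length(pc$sdev)) else
    pc$sdev^2 / var_tot
  list(explained = explained, scores = pc$x,
       n_profiles = length(merged$sizes),
       profile = merged$membership, degenerate = degenerate)
}
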