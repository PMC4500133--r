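# Synthetic metabolic models with known knockout phenotypes.
#
# Three pathway topologies are generated around a common skeleton
# (substrate uptake -> internal conversions -> biomass drain):
#
#   linear    uptake followed by a single chain; every chain gene is
#             essential (one route only).
#   parallel  the first internal conversion is duplicated into redundant
#             routes, each behind its own gene; route genes are
#             flux-altering (knockouts reroute, growth persists).
#   branched  a linear backbone plus an appendix branch whose bounds are
#             fixed to zero; the appendix gene is silent.
#
# Ground-truth phenotype labels (lethal / flux_altering / silent) are
# assigned at generation time by *stoichiometric reachability*, not by
# linear programming, so the flux-simulation module can be validated
# against an independent oracle.

#' Specification for a synthetic metabolic model
#'
#' @param topology one of `"linear"`, `"parallel"`, `"branched"`.
#' @param n_reactions number of gene-associated interior reactions
#'   (>= 2; >= 3 for `"parallel"`). Uptake and the biomass drain are added
#'   on top and carry no genes.
#' @param n_parallel number of redundant routes for the parallel topology.
#' @param gpr optional named character vector overriding the generated GPR
#'   rules (names = reaction IDs).
#' @param seed integer seed.
#' @return an object of class `synthetic_model_spec`.
#' @export
model_spec <- function(topology = c("linear", "parallel", "branched"),
                       n_reactions = 4, n_parallel = 2, gpr = NULL,
                       seed = 1L) {
  topology <- match.arg(topology)
  n_reactions <- check_count(n_reactions, "n_reactions", min = 2L)
  n_parallel <- check_count(n_parallel, "n_parallel", min = 2L)
  if (topology == "parallel" && n_reactions < 3L)
    stop_nf("parallel topology needs n_reactions >= 3")
  structure(list(topology = topology, n_reactions = n_reactions,
                 n_parallel = n_parallel, gpr = gpr,
                 seed = as.integer(seed)),
            class = "synthetic_model_spec")
}

#' Generate a small metabolic model with known knockout phenotypes
#'
#' @param spec a [model_spec()].
#' @return a list of class `synthetic_model` with elements `model`
#'   (a [metabolic_model()]), `labels` (named character,
#'   lethal/flux_altering/silent per gene), `route_genes` (list of
#'   redundant-route gene groups) and `spec`.
#' @export
generate_model <- function(spec) {
  if (!inherits(spec, "synthetic_model_spec"))
    stop_nf("'spec' must come from model_spec()")
  n <- spec$n_reactions
  topo <- spec$topology

  rxn <- list()  # each: id, eq (named stoich over metabolites), lb, ub, gpr
  add <- function(id, stoich, lb, ub, gpr = "")
    rxn[[length(rxn) + 1L]] <<- list(id = id, stoich = stoich, lb = lb,
                                     ub = ub, gpr = gpr)
  cap <- 10
  route_genes <- list()

  if (topo == "parallel") {
    n_chain <- n - 1L  # one slot is consumed by the duplicated step
    mets <- paste0("M", seq_len(n_chain + 1L))
    add("R_upt", c(S_ext = -1, M1 = 1), 0, cap)
    # duplicated step M1 -> M2, one gene per route
    for (p in seq_len(spec$n_parallel))
      add(paste0("R_par", p), c(M1 = -1, M2 = 1), 0, cap, paste0("g_par", p))
    route_genes <- list(paste0("g_par", seq_len(spec$n_parallel)))
    for (i in seq_len(n_chain - 1L) + 1L)
      add(paste0("R_chain", i), stats::setNames(c(-1, 1), mets[c(i, i + 1L)]),
          0, cap, paste0("g_chain", i))
    add("R_bio", stats::setNames(c(-1, 1), c(mets[n_chain + 1L], "BM_ext")),
        0, cap)
  } else {
    n_chain <- if (topo == "branched") n - 1L else n
    mets <- paste0("M", seq_len(n_chain + 1L))
    add("R_upt", c(S_ext = -1, M1 = 1), 0, cap)
    for (i in seq_len(n_chain)) {
      # one mid-chain reaction is written reversibly in the branched
      # topology to exercise forward/reverse flux splitting
      lb <- if (topo == "branched" && i == max(2L, n_chain %/% 2L)) -cap else 0
      add(paste0("R_chain", i), stats::setNames(c(-1, 1), mets[c(i, i + 1L)]),
          lb, cap, paste0("g_chain", i))
    }
    if (topo == "branched")
      add("R_appendix", stats::setNames(c(-1, 1), c(mets[2L], "W_ext")),
          0, 0, "g_appendix")
    add("R_bio", stats::setNames(c(-1, 1), c(mets[n_chain + 1L], "BM_ext")),
        0, cap)
  }

  gpr <- vapply(rxn, `[[`, character(1), "gpr")
  names(gpr) <- vapply(rxn, `[[`, character(1), "id")
  if (!is.null(spec$gpr)) {
    unknown <- setdiff(names(spec$gpr), names(gpr))
    if (length(unknown))
      stop_nf("GPR override names unknown reactions: %s",
              paste(unknown, collapse = ", "))
    gpr[names(spec$gpr)] <- spec$gpr
  }

  met_ids <- unique(unlist(lapply(rxn, function(r) names(r$stoich))))
  S <- matrix(0, length(met_ids), length(rxn),
              dimnames = list(met_ids, names(gpr)))
  for (j in seq_along(rxn)) S[names(rxn[[j]]$stoich), j] <- rxn[[j]]$stoich
  external <- grepl("_ext$", met_ids)
  genes <- unique(unlist(lapply(lapply(gpr, parse_gpr), gpr_genes)))
  category <- stats::setNames(sub("^g_", "", sub("[0-9]+$", "", genes)), genes)
  model <- metabolic_model(S, external = external,
                           lb = vapply(rxn, `[[`, numeric(1), "lb"),
                           ub = vapply(rxn, `[[`, numeric(1), "ub"),
                           gpr = gpr, biomass = "R_bio", genes = genes,
                           gene_category = category)

  if (!biomass_reachable(model))
    stop_nf("spec rejected: biomass is unreachable in the wild type")
  labels <- vapply(model$genes, function(g) phenotype_by_reachability(model, g),
                   character(1))
  structure(list(model = model, labels = labels, route_genes = route_genes,
                 spec = spec),
            class = "synthetic_model")
}

# -- stoichiometric reachability ---------------------------------------------
# A reaction can fire in a direction if it has capacity there and every
# metabolite it consumes in that direction is available (external species
# are always available). Closure: iterate until no new metabolite appears.
# Biomass is reachable iff the biomass reaction can fire forward.
reachable_metabolites <- function(model, disabled = character()) {
  S <- model$S
  lb <- model$lb; ub <- model$ub
  lb[disabled] <- 0; ub[disabled] <- 0
  avail <- model$external
  repeat {
    new <- FALSE
    for (j in seq_along(model$rxn_ids)) {
      cons_f <- S[, j] < 0; prod_f <- S[, j] > 0
      if (ub[j] > 1e-12 && all(avail[cons_f]) && any(prod_f & !avail)) {
        avail[prod_f] <- TRUE; new <- TRUE
      }
      if (lb[j] < -1e-12 && all(avail[prod_f]) && any(cons_f & !avail)) {
        avail[cons_f] <- TRUE; new <- TRUE
      }
    }
    if (!new) break
  }
  avail
}

biomass_reachable <- function(model, disabled = character()) {
  lb <- model$lb; ub <- model$ub
  lb[disabled] <- 0; ub[disabled] <- 0
  if (ub[model$biomass] <= 1e-12) return(FALSE)
  avail <- reachable_metabolites(model, disabled)
  cons <- model$S[, model$biomass] < 0
  all(avail[cons])
}

# Can reaction j carry any flux in the wild-type closure?
reaction_usable <- function(model, j) {
  if (model$ub[j] <= 1e-12 && model$lb[j] >= -1e-12) return(FALSE)
  avail <- reachable_metabolites(model)
  cons_f <- model$S[, j] < 0; prod_f <- model$S[, j] > 0
  (model$ub[j] > 1e-12 && all(avail[cons_f])) ||
    (model$lb[j] < -1e-12 && all(avail[prod_f]))
}

phenotype_by_reachability <- function(model, gene) {
  off <- ko_disabled_reactions(model, gene)
  if (!biomass_reachable(model, disabled = off)) return("lethal")
  usable <- vapply(match(off, model$rxn_ids), reaction_usable,
                   logical(1), model = model)
  if (length(off) == 0L || !any(usable)) "silent" else "flux_altering"
}

#' Condition-wise expression for a synthetic model's genes
#'
#' Produces a small gene x condition expression matrix matched to a
#' [generate_model()] output, in which each redundant route dominates in at
#' least one condition (expression-weighted flux estimation then prefers a
#' different route per condition, as pathway usage shifts with environment
#' in real compendia).
#'
#' @param sm a `synthetic_model` object.
#' @param n_conditions number of conditions (>= 3).
#' @param seed integer seed.
#' @return numeric genes x conditions matrix.
#' @export
generate_model_expression <- function(sm, n_conditions = 4, seed = 1L) {
  if (!inherits(sm, "synthetic_model")) stop_nf("'sm' must be a synthetic_model")
  n_conditions <- check_count(n_conditions, "n_conditions", min = 3L)
  genes <- sm$model$genes
  with_seed(seed, {
    x <- matrix(100 * exp(stats::rnorm(length(genes) * n_conditions, sd = 0.2)),
                length(genes), n_conditions,
                dimnames = list(genes, paste0("cond_", seq_len(n_conditions))))
    for (grp in sm$route_genes) {
      for (c in seq_len(n_conditions)) {
        dom <- grp[(c - 1L) %% length(grp) + 1L]
        x[grp, c] <- 20 * exp(stats::rnorm(length(grp), sd = 0.1))
        x[dom, c] <- 500 * exp(stats::rnorm(1, sd = 0.1))
      }
    }
    x
  })
}
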