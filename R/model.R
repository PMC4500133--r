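# Constraint-based metabolic model container.
#
# A metabolic_model is a plain list (S3) holding the stoichiometric matrix,
# reaction bounds, GPR rules and the designated biomass reaction.  External
# metabolites are excluded from the steady-state balance, which makes
# explicit exchange reactions unnecessary: a reaction consuming an external
# species acts as an uptake.

#' Construct a constraint-based metabolic model
#'
#' @param S stoichiometric matrix, metabolites x reactions (negative =
#'   consumed). Dimnames may be absent if `met_ids`/`rxn_ids` are given.
#' @param met_ids,rxn_ids metabolite and reaction identifiers.
#' @param external logical per metabolite; external species are not
#'   balanced.
#' @param lb,ub numeric reaction bounds, `lb <= ub`, finite.
#' @param gpr character GPR rules per reaction (`""` = no gene association).
#' @param biomass ID of the biomass reaction (must exist, `ub > 0`).
#' @param genes gene universe; defaults to the union of GPR genes.
#' @param gene_category optional named character vector mapping genes to
#'   functional categories.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(S, met_ids = rownames(S), rxn_ids = colnames(S),
                            external = rep(FALSE, nrow(S)),
                            lb, ub, gpr = rep("", ncol(S)), biomass,
                            genes = NULL, gene_category = NULL) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  if (is.null(met_ids) || is.null(rxn_ids))
    stop_nf("metabolite and reaction IDs are required")
  if (length(met_ids) != nrow(S) || length(rxn_ids) != ncol(S))
    stop_nf("ID lengths do not match the stoichiometric matrix")
  if (anyDuplicated(met_ids) || anyDuplicated(rxn_ids))
    stop_nf("metabolite and reaction IDs must be unique")
  dimnames(S) <- list(met_ids, rxn_ids)
  external <- as.logical(external)
  if (length(external) != nrow(S) || anyNA(external))
    stop_nf("'external' must be one flag per metabolite")
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  if (length(lb) != ncol(S) || length(ub) != ncol(S))
    stop_nf("bounds must have one entry per reaction")
  if (anyNA(lb) || anyNA(ub) || any(!is.finite(lb)) || any(!is.finite(ub)))
    stop_nf("reaction bounds must be finite")
  if (any(lb > ub)) stop_nf("every reaction needs lb <= ub")
  gpr <- as.character(gpr)
  if (length(gpr) != ncol(S)) stop_nf("one GPR rule per reaction required")
  gpr[is.na(gpr)] <- ""
  ast <- lapply(gpr, parse_gpr)
  gpr_gene_set <- unique(unlist(lapply(ast, gpr_genes)))
  genes <- unique(c(if (is.null(genes)) character() else as.character(genes),
                    gpr_gene_set))
  if (!biomass %in% rxn_ids) stop_nf("biomass reaction '%s' not in model", biomass)
  if (ub[match(biomass, rxn_ids)] <= 0)
    stop_nf("biomass reaction must admit positive flux (ub > 0)")
  structure(list(S = S, met_ids = met_ids, rxn_ids = rxn_ids,
                 external = stats::setNames(external, met_ids),
                 lb = stats::setNames(lb, rxn_ids),
                 ub = stats::setNames(ub, rxn_ids),
                 gpr = stats::setNames(gpr, rxn_ids), gpr_ast = ast,
                 biomass = biomass, genes = genes,
                 gene_category = gene_category),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites (%d external), %d reactions, %d genes\n",
              length(x$met_ids), sum(x$external), length(x$rxn_ids),
              length(x$genes)))
  cat(sprintf("biomass reaction: %s\n", x$biomass))
  invisible(x)
}

# Reactions disabled when `gene` is knocked out (all other genes active).
ko_disabled_reactions <- function(model, gene) {
  if (!gene %in% model$genes)
    stop_nf("gene '%s' is not in the model", gene)
  active <- stats::setNames(rep(TRUE, length(model$genes)), model$genes)
  active[gene] <- FALSE
  off <- !vapply(model$gpr_ast, eval_gpr_boolean, logical(1), active = active)
  model$rxn_ids[off]
}

# Internal (balanced) part of S.
internal_S <- function(model) model$S[!model$external, , drop = FALSE]
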