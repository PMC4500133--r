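# Cross-classification of topological vs functional importance, Fisher
# (hypergeometric) functional enrichment, and Monte Carlo gene-set
# randomization of centrality.

#' Cross-classify genes by topological and functional importance
#'
#' TF: TI and FI (Group 2 or 3). Tf: TI but Group 1. Ft: FI but not TI.
#' Everything else is "neither". Isolated genes are never TI by
#' construction upstream; the flags are validated here.
#'
#' @param ti_flags named logical vector (TI per gene).
#' @param fi_groups named integer vector of groups 1/2/3 per gene.
#' @param isolated_flags named logical vector per gene.
#' @return data.frame of class `gene_classification`: gene, group, is_TI,
#'   is_isolated, category (`"TF"`, `"Tf"`, `"Ft"`, `"neither"`);
#'   attribute `counts` holds the set sizes.
#' @export
cross_classify <- function(ti_flags, fi_groups, isolated_flags) {
  genes <- names(ti_flags)
  if (is.null(genes) || is.null(names(fi_groups)) ||
      is.null(names(isolated_flags)))
    stop_nf("all inputs must be named by gene")
  if (!setequal(genes, names(fi_groups)) ||
      !setequal(genes, names(isolated_flags)))
    stop_nf("gene universes of the three inputs differ")
  fi_groups <- fi_groups[genes]
  isolated_flags <- isolated_flags[genes]
  if (!all(fi_groups %in% 1:3)) stop_nf("groups must be 1, 2 or 3")
  if (any(ti_flags & isolated_flags))
    stop_nf("an isolated gene cannot be TI")
  fi <- fi_groups >= 2L
  category <- ifelse(ti_flags & fi, "TF",
                     ifelse(ti_flags, "Tf",
                            ifelse(fi, "Ft", "neither")))
  out <- data.frame(gene = genes, group = as.integer(fi_groups),
                    is_TI = as.logical(ti_flags),
                    is_isolated = as.logical(isolated_flags),
                    category = category, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(TI = sum(ti_flags), FI = sum(fi),
                           TF = sum(category == "TF"),
                           Tf = sum(category == "Tf"),
                           Ft = sum(category == "Ft"),
                           neither = sum(category == "neither"))
  class(out) <- c("gene_classification", "data.frame")
  out
}

#' Functional-category enrichment by Fisher's exact test
#'
#' One-sided (enrichment) hypergeometric upper-tail p-value per category:
#' with `k` set members in the category, set size `n`, `K` category
#' members in the universe of size `M`, `p = P(X >= k)` for
#' `X ~ Hypergeom(M, K, n)`.
#'
#' @param gene_set character vector of genes (subset of `universe`).
#' @param categories gene-to-category map: either a named character vector
#'   or a two-column data.frame (gene, category); a gene may carry several
#'   categories.
#' @param universe character vector of all genes.
#' @param alpha significance level for the `significant` flag.
#' @param bh if TRUE, add Benjamini-Hochberg adjusted p-values (off by
#'   default; raw Fisher p-values are the primary output).
#' @return data.frame of class `enrichment_result`, sorted by p:
#'   category, k, n, K, M, odds_ratio, p_value, significant.
#' @export
fisher_enrichment <- function(gene_set, categories, universe, alpha = 0.05,
                              bh = FALSE) {
  if (!length(gene_set)) stop_nf("'gene_set' must not be empty")
  gene_set <- unique(as.character(gene_set))
  universe <- unique(as.character(universe))
  if (!all(gene_set %in% universe))
    stop_nf("'gene_set' must be a subset of 'universe'")
  if (is.data.frame(categories)) {
    cat_map <- data.frame(gene = as.character(categories[[1]]),
                          category = as.character(categories[[2]]),
                          stringsAsFactors = FALSE)
  } else {
    cat_map <- data.frame(gene = names(categories),
                          category = as.character(categories),
                          stringsAsFactors = FALSE)
  }
  cat_map <- unique(cat_map[cat_map$gene %in% universe, ])
  M <- length(universe)
  n <- length(gene_set)
  res <- lapply(split(cat_map$gene, cat_map$category), function(members) {
    K <- length(members)
    k <- length(intersect(members, gene_set))
    p <- stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    orr <- (k * (M - n - K + k)) / ((n - k) * (K - k))
    data.frame(k = k, n = n, K = K, M = M,
               odds_ratio = orr, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(category = names(res), out)
  rownames(out) <- NULL
  out$significant <- out$p_value < alpha & out$k > 0
  if (bh) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$category), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Monte Carlo randomization of group centrality
#'
#' Compares the observed mean (or median) centrality of a gene group with
#' the null distribution of the same statistic over `n_draws` uniform
#' same-size draws (without replacement) from the universe. Empirical
#' p-values use the add-one correction
#' `p = (1 + #(null >= obs)) / (n_draws + 1)`.
#'
#' @param group character vector of gene IDs (non-empty subset of the
#'   universe).
#' @param centrality named numeric vector of centrality over the whole
#'   universe (isolated genes included with value 0).
#' @param n_draws number of random sets.
#' @param seed integer seed.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return list of class `randomization_result`: `observed`, `null`
#'   (length `n_draws`), `p_upper` (enrichment), `p_lower` (depletion),
#'   `statistic`, `group_size`, `n_draws`, `seed`.
#' @export
centrality_randomization <- function(group, centrality, n_draws = 5000L,
                                     seed = 1L,
                                     statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  n_draws <- check_count(n_draws, "n_draws")
  if (is.null(names(centrality))) stop_nf("'centrality' must be named by gene")
  group <- unique(as.character(group))
  if (!length(group)) stop_nf("'group' must not be empty")
  if (!all(group %in% names(centrality)))
    stop_nf("'group' contains genes outside the centrality universe")
  if (length(group) > length(centrality))
    stop_nf("'group' is larger than the universe")
  stat_fun <- if (statistic == "mean") mean else stats::median
  observed <- stat_fun(centrality[group])
  g <- length(group)
  null <- with_seed(seed, vapply(seq_len(n_draws), function(i)
    stat_fun(sample(centrality, g)), numeric(1)))
  structure(list(observed = observed, null = null,
                 p_upper = (1 + sum(null >= observed)) / (n_draws + 1),
                 p_lower = (1 + sum(null <= observed)) / (n_draws + 1),
                 statistic = statistic, group_size = g,
                 n_draws = n_draws, seed = seed),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("randomization (%s of %d genes, %d draws): observed %.4g, p_upper %.4g, p_lower %.4g\n",
              x$statistic, x$group_size, x$n_draws, x$observed, x$p_upper,
              x$p_lower))
  invisible(x)
}
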