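# Component decomposition, the combined centrality score, topological
# importance (TI) classification, and the log-log degree-distribution fit.

#' Connected components of a network
#'
#' @inheritParams degree_centrality
#' @return a list of class `component_decomposition` with `membership`
#'   (named integer, components numbered 1.. by decreasing size, ties by
#'   first node) and `sizes` (integer vector).
#' @export
graph_components <- function(net) {
  A <- as_adjacency(net)
  n <- nrow(A)
  nb <- adj_list(A)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  sizes <- tabulate(comp, cid)
  ord <- order(-sizes, seq_len(cid))
  relabel <- integer(cid); relabel[ord] <- seq_len(cid)
  comp <- relabel[comp]
  structure(list(membership = stats::setNames(comp, rownames(A)),
                 sizes = sort(sizes, decreasing = TRUE)),
            class = "component_decomposition")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf("%d components; sizes: %s\n", length(x$sizes),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Per-gene centrality table
#'
#' Computes the four centrality measures, the combined (overall) score and
#' the TI flag in one pass. The combined score divides each measure by its
#' maximum over genes (a measure that is identically zero is dropped) and
#' averages the normalized values; isolated genes score zero on every
#' measure and are never topologically important.
#'
#' @inheritParams degree_centrality
#' @param top_fraction fraction of non-isolated genes flagged TI
#'   (default 0.5, i.e., the top half of the combined score).
#' @param per_measure if TRUE, additionally flag the top fraction per
#'   individual measure (columns `TI_degree`, ..).
#' @return a `data.frame` of class `centrality_table`: gene, degree,
#'   eigenvector, betweenness, closeness, combined, is_isolated, is_TI.
#' @export
centrality_table <- function(net, top_fraction = 0.5, per_measure = FALSE) {
  A <- as_adjacency(net)
  d <- degree_centrality(A)
  e <- eigenvector_centrality(A)
  b <- betweenness_centrality(A)
  cl <- closeness_centrality(A)
  tab <- data.frame(gene = rownames(A), degree = as.numeric(d),
                    eigenvector = as.numeric(e), betweenness = as.numeric(b),
                    closeness = as.numeric(cl),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$is_isolated <- tab$degree == 0
  tab$combined <- combined_centrality(tab)
  tab$is_TI <- classify_ti(tab, top_fraction = top_fraction)
  if (per_measure) {
    for (mcol in c("degree", "eigenvector", "betweenness", "closeness"))
      tab[[paste0("TI_", mcol)]] <-
        ti_flag(tab[[mcol]], tab$is_isolated, top_fraction)
  }
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

#' Combined (overall) centrality
#'
#' Each of the four measures is divided by its maximum across genes and the
#' normalized measures are averaged. A measure that is identically zero
#' (e.g., betweenness on a union of cliques) carries no information and is
#' dropped from the average; isolated genes have all measures zero, hence
#' combined 0.
#'
#' @param table a data.frame with columns degree, eigenvector, betweenness,
#'   closeness (e.g., from [centrality_table()]).
#' @return numeric vector in \[0, 1\].
#' @export
combined_centrality <- function(table) {
  meas <- c("degree", "eigenvector", "betweenness", "closeness")
  if (!all(meas %in% names(table)))
    stop_nf("'table' must contain columns %s", paste(meas, collapse = ", "))
  cols <- lapply(meas, function(m) {
    v <- as.numeric(table[[m]])
    mx <- max(v)
    if (mx > 0) v / mx else NULL
  })
  cols <- Filter(Negate(is.null), cols)
  if (!length(cols)) return(numeric(nrow(table)))
  rowMeans(do.call(cbind, cols))
}

ti_flag <- function(score, isolated, top_fraction) {
  top_fraction <- check_number(top_fraction, "top_fraction")
  if (top_fraction <= 0 || top_fraction > 1)
    stop_nf("'top_fraction' must be in (0, 1]")
  flag <- rep(FALSE, length(score))
  cand <- !isolated
  if (!any(cand)) return(flag)
  # closed upper boundary at the interpolated quantile: ties included
  thr <- stats::quantile(score[cand], probs = 1 - top_fraction,
                         type = 7, names = FALSE)
  flag[cand] <- score[cand] >= thr
  flag
}

#' Topologically-important (TI) gene flags
#'
#' Isolated genes are never TI. Among non-isolated genes, those at or above
#' the `1 - top_fraction` quantile of the combined centrality are TI (ties
#' at the threshold are included).
#'
#' @param table data.frame with columns `combined` and `is_isolated`.
#' @param top_fraction fraction in (0, 1].
#' @return logical vector.
#' @export
classify_ti <- function(table, top_fraction = 0.5) {
  if (!all(c("combined", "is_isolated") %in% names(table)))
    stop_nf("'table' must contain 'combined' and 'is_isolated'")
  ti_flag(table$combined, table$is_isolated, top_fraction)
}

#' Power-law fit of the degree distribution
#'
#' Least-squares line of `log10(count of degree k)` against `log10(k)` over
#' observed degrees `k >= 1`. On a scale-free network the points fall on a
#' line with slope `-gamma`.
#'
#' @param net a network as in [degree_centrality()], or directly a numeric
#'   vector of node degrees.
#' @return a list with `available` (flag), and when available `exponent`
#'   (the fitted gamma, i.e., minus the slope), `r_squared`, `n_degrees`;
#'   otherwise `reason`.
#' @export
degree_distribution_fit <- function(net) {
  d <- if (is.numeric(net) && is.null(dim(net))) net else
    degree_centrality(net)
  tabd <- table(d[d > 0])
  k <- as.numeric(names(tabd))
  if (length(k) < 3)
    return(list(available = FALSE,
                reason = sprintf("need >= 3 distinct positive degrees, got %d",
                                 length(k))))
  fit <- stats::lm(log10(as.numeric(tabd)) ~ log10(k))
  # suppress the "essentially perfect fit" warning: exact power-law
  # histograms are a legitimate input here
  sm <- suppressWarnings(summary(fit))
  list(available = TRUE,
       exponent = -unname(stats::coef(fit)[2]),
       r_squared = sm$r.squared,
       n_degrees = length(k))
}
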