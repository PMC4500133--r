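# Synthetic expression compendia with planted co-expression modules.
#
# The generative model mirrors what a multi-condition RPKM compendium looks
# like after normalization: every gene fluctuates around a baseline
# abundance, genes inside a regulon share a latent per-condition activity
# factor, and measurement noise is additive.  Values are truncated at zero
# to respect RPKM semantics.
#
# For gene g in module M under condition c:
#   x[g,c] = max(0, b + a_g * (sqrt(w') * f[M,c] + sqrt(1-w') * eta[g,c])
#                   + noise_sd * eps[g,c])
# with f, eta, eps iid standard normal, b = baseline_mean, and gene-specific
# amplitude a_g = 0.25 * baseline_mean * u_g (u_g ~ U(0.7, 1.3)).  The
# factor share w' is calibrated so that the *realized* pairwise correlation
# of module genes (additive noise included) equals the module's correlation
# parameter w:  w' = w * (a^2 + noise_sd^2) / a^2 at the mean amplitude,
# capped at 1.  Background genes use the eta term only.

#' Specification for a synthetic expression compendium
#'
#' @param n_genes number of genes (rows).
#' @param n_conditions number of conditions (columns).
#' @param modules list of planted co-expression modules; each element is a
#'   list or vector with elements `size` (positive integer) and `cor`
#'   (within-module correlation in \[0, 1\]).
#' @param noise_sd standard deviation of the additive measurement noise, in
#'   expression units. Defaults to 5% of `baseline_mean`.
#' @param baseline_mean baseline expression level (RPKM-like scale).
#' @param seed integer seed; the generator is a pure function of the spec.
#'
#' @return an object of class `synthetic_expression_spec`.
#' @export
expression_spec <- function(n_genes, n_conditions, modules = list(),
                            noise_sd = NULL, baseline_mean = 100,
                            seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_conditions <- check_count(n_conditions, "n_conditions")
  baseline_mean <- check_number(baseline_mean, "baseline_mean", min = 0)
  noise_sd <- if (is.null(noise_sd)) 0.05 * baseline_mean else
    check_number(noise_sd, "noise_sd", min = 0)
  if (!is.list(modules)) stop_nf("'modules' must be a list")
  modules <- lapply(modules, function(m) {
    m <- as.list(m)
    list(size = check_count(m$size, "module size"),
         cor = check_number(m$cor, "module correlation", min = 0, max = 1))
  })
  if (length(modules) && sum(vapply(modules, `[[`, 1L, "size")) > n_genes)
    stop_nf("sum of module sizes (%d) exceeds n_genes (%d)",
            sum(vapply(modules, `[[`, 1L, "size")), n_genes)
  structure(list(n_genes = n_genes, n_conditions = n_conditions,
                 modules = modules, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, seed = as.integer(seed)),
            class = "synthetic_expression_spec")
}

#' Generate a synthetic expression matrix with planted modules
#'
#' Genes belonging to the same planted module share a latent per-condition
#' factor; the module's correlation parameter sets their pairwise
#' pre-truncation correlation. Background genes are mutually independent.
#' Regenerating with the same spec (including seed) is bit-identical.
#'
#' @param spec a [expression_spec()].
#' @return a numeric genes x conditions matrix with `gene_1..n` rownames and
#'   `cond_1..m` colnames; attribute `module` gives each gene's module index
#'   (0 for background).
#' @export
generate_expression <- function(spec) {
  if (!inherits(spec, "synthetic_expression_spec"))
    stop_nf("'spec' must come from expression_spec()")
  n <- spec$n_genes; m <- spec$n_conditions
  sizes <- vapply(spec$modules, `[[`, 1L, "size")
  module_of <- integer(n)
  if (length(sizes)) {
    idx <- seq_len(sum(sizes))
    module_of[idx] <- rep(seq_along(sizes), sizes)
  }
  x <- with_seed(spec$seed, {
    amp <- 0.25 * spec$baseline_mean * stats::runif(n, 0.7, 1.3)
    f <- matrix(stats::rnorm(length(sizes) * m), length(sizes), m)
    eta <- matrix(stats::rnorm(n * m), n, m)
    eps <- matrix(stats::rnorm(n * m), n, m)
    z <- eta
    abar2 <- (0.25 * spec$baseline_mean)^2
    for (k in seq_along(sizes)) {
      rows <- which(module_of == k)
      w <- spec$modules[[k]]$cor
      # calibrate the factor share for the additive noise so the realized
      # pairwise correlation matches w (capped at the attainable maximum)
      wp <- if (abar2 > 0) min(1, w * (abar2 + spec$noise_sd^2) / abar2) else w
      z[rows, ] <- sqrt(wp) * matrix(f[k, ], length(rows), m, byrow = TRUE) +
        sqrt(1 - wp) * eta[rows, , drop = FALSE]
    }
    pmax(spec$baseline_mean + amp * z + spec$noise_sd * eps, 0)
  })
  dimnames(x) <- list(paste0("gene_", seq_len(n)), paste0("cond_", seq_len(m)))
  attr(x, "module") <- stats::setNames(module_of, rownames(x))
  x
}

#' Validate an expression matrix
#'
#' Checks the contract shared by all downstream consumers: a numeric
#' genes x conditions matrix, unique gene IDs, at least 3 conditions, all
#' values non-negative.
#'
#' @param expr numeric matrix with gene rownames and condition colnames.
#' @param min_conditions minimum number of columns required.
#' @return `expr`, invisibly, after validation.
#' @export
validate_expression <- function(expr, min_conditions = 3L) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop_nf("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr)))
    stop_nf("expression matrix needs unique gene rownames")
  if (ncol(expr) < min_conditions)
    stop_nf("expression matrix needs at least %d conditions, got %d",
            min_conditions, ncol(expr))
  if (anyNA(expr) || any(expr < 0))
    stop_nf("expression values must be non-negative and non-missing")
  invisible(expr)
}
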