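# End-to-end orchestration: expression + model + categories in,
# co-expression network -> centrality -> knockout screen -> integration
# out, with every artifact written to disk and a manifest that is
# sufficient to reproduce the run.

run_config_defaults <- function() {
  list(expression = NULL, model = NULL, categories = NULL,
       output_dir = "netflux_out",
       z_threshold = 4.5, n_boot = 500L, support_min = 375L,
       drop_per_iter = 2L, combine = "clr",
       top_fraction = 0.5,
       growth_floor = 1, growth_tol = 1e-6, flux_tol = 1e-6,
       n_draws = 5000L, seed = 1L)
}

#' Build or load a run configuration
#'
#' `run_config()` assembles a validated configuration from arguments;
#' `read_run_config()` loads one from a JSON file. Unknown keys are
#' rejected.
#'
#' @param ... configuration values overriding the defaults (see
#'   [run_config_defaults names][run_all()]): `expression`, `model`,
#'   `categories` (paths), `output_dir`, `z_threshold`, `n_boot`,
#'   `support_min`, `drop_per_iter`, `combine`, `top_fraction`,
#'   `growth_floor`, `growth_tol`, `flux_tol`, `n_draws`, `seed`.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  override <- list(...)
  if (length(override) == 1L && is.list(override[[1]]) &&
      is.null(names(override)))
    override <- override[[1]]
  cfg <- run_config_defaults()
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop_nf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  cfg$n_boot <- check_count(cfg$n_boot, "n_boot")
  cfg$support_min <- check_count(cfg$support_min, "support_min", min = 0L)
  if (cfg$support_min > cfg$n_boot)
    stop_nf("support_min (%d) cannot exceed n_boot (%d)",
            cfg$support_min, cfg$n_boot)
  cfg$drop_per_iter <- check_count(cfg$drop_per_iter, "drop_per_iter", min = 0L)
  cfg$n_draws <- check_count(cfg$n_draws, "n_draws")
  cfg$seed <- check_count(cfg$seed, "seed", min = 0L)
  cfg$z_threshold <- check_number(cfg$z_threshold, "z_threshold")
  cfg$top_fraction <- check_number(cfg$top_fraction, "top_fraction")
  cfg$growth_floor <- check_number(cfg$growth_floor, "growth_floor", min = 0)
  cfg$growth_tol <- check_number(cfg$growth_tol, "growth_tol", min = 0)
  cfg$flux_tol <- check_number(cfg$flux_tol, "flux_tol", min = 0)
  if (!cfg$combine %in% c("min", "clr"))
    stop_nf("'combine' must be \"min\" or \"clr\"")
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON configuration file.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) load expression, model and category inputs; (2) infer the
#' bootstrapped co-expression network on the intersection of expression
#' and model genes (the "reduced" network); (3) centrality + TI
#' classification; (4) expression-guided fluxes, exhaustive knockouts and
#' FI groups; (5) cross-classification, enrichment and centrality
#' randomization. All artifacts are TSV/JSON files under
#' `config$output_dir`; a `manifest.json` records parameters, seeds,
#' versions and file checksums. Any stage failure aborts with the stage
#' name; artifacts written before the failure are left in place.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly.
#' @export
run_all <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "input"
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  tryCatch({
    if (is.null(config$expression) || is.null(config$model))
      stop_nf("config must name 'expression' and 'model' inputs")
    expr <- read_expression_tsv(config$expression)
    model <- read_model(config$model)
    categories <- NULL
    if (!is.null(config$categories)) {
      categories <- utils::read.table(config$categories, sep = "\t",
                                      header = TRUE,
                                      stringsAsFactors = FALSE,
                                      colClasses = "character")
    } else if (!is.null(model$gene_category)) {
      categories <- data.frame(gene = names(model$gene_category),
                               category = unname(model$gene_category),
                               stringsAsFactors = FALSE)
    }
    shared <- intersect(rownames(expr), model$genes)
    dropped_expr <- setdiff(model$genes, rownames(expr))
    say("universe: %d shared genes (%d model genes without expression)",
        length(shared), length(dropped_expr))
    if (length(shared) < 3)
      stop_nf("fewer than 3 genes shared between expression and model")

    stage <- "gcn"
    say("stage gcn: bootstrap network (%d iterations)", config$n_boot)
    net <- bootstrap_network(expr, z_threshold = config$z_threshold,
                             n_boot = config$n_boot,
                             support_min = config$support_min,
                             drop_per_iter = config$drop_per_iter,
                             seed = config$seed, genes = shared,
                             combine = config$combine)
    write_network_tsv(net, file.path(out, "network_edges.tsv"))
    write_network_graphml(net, file.path(out, "network.graphml"))

    stage <- "topology"
    say("stage topology: centralities and TI")
    ctab <- centrality_table(net, top_fraction = config$top_fraction)
    comp <- graph_components(net)
    utils::write.table(ctab, file.path(out, "centrality.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene = names(comp$membership),
                 component = comp$membership),
      file.path(out, "components.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    fit <- degree_distribution_fit(net)
    write_json_sidecar(fit, file.path(out, "degree_fit.json"))

    stage <- "flux"
    say("stage flux: E-Fmin + %d x %d knockouts", length(model$genes),
        ncol(expr))
    screen <- knockout_screen(model, expr,
                              growth_floor = config$growth_floor,
                              growth_tol = config$growth_tol,
                              flux_tol = config$flux_tol)
    utils::write.table(screen$outcomes, file.path(out, "knockouts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (cond in names(screen$parents)) {
      fs <- screen$parents[[cond]]
      utils::write.table(
        data.frame(reaction = names(fs$fluxes), flux = fs$fluxes),
        file.path(out, sprintf("flux_%s.tsv", cond)), sep = "\t",
        quote = FALSE, row.names = FALSE)
    }
    groups <- classify_groups(screen)
    utils::write.table(groups, file.path(out, "fi_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pca <- flux_pca(screen)
    write_json_sidecar(list(explained = pca$explained,
                            n_profiles = pca$n_profiles,
                            degenerate = pca$degenerate),
                       file.path(out, "flux_pca.json"))

    stage <- "integrate"
    say("stage integrate: cross-classification and statistics")
    common <- intersect(ctab$gene, groups$gene)
    ti <- stats::setNames(ctab$is_TI, ctab$gene)[common]
    iso <- stats::setNames(ctab$is_isolated, ctab$gene)[common]
    fg <- stats::setNames(groups$group, groups$gene)[common]
    cls <- cross_classify(ti, fg, iso)
    utils::write.table(cls, file.path(out, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_sidecar(as.list(attr(cls, "counts")),
                       file.path(out, "classification_summary.json"))
    if (!is.null(categories)) {
      for (set in c("TF", "Tf", "Ft")) {
        gs <- cls$gene[cls$category == set]
        if (length(gs)) {
          enr <- fisher_enrichment(gs, categories, universe = cls$gene)
          utils::write.table(enr,
                             file.path(out, sprintf("enrichment_%s.tsv", set)),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
    comb <- stats::setNames(ctab$combined, ctab$gene)[common]
    rand_rows <- lapply(sort(unique(cls$group)), function(gr) {
      gs <- cls$gene[cls$group == gr]
      rr <- centrality_randomization(gs, comb, n_draws = config$n_draws,
                                     seed = config$seed + gr)
      data.frame(group = gr, size = rr$group_size, observed = rr$observed,
                 null_mean = mean(rr$null), p_upper = rr$p_upper,
                 p_lower = rr$p_lower)
    })
    utils::write.table(do.call(rbind, rand_rows),
                       file.path(out, "randomization.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    stage <- "manifest"
    files <- list.files(out, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest <- list(
      package = "netflux",
      version = as.character(utils::packageVersion("netflux")),
      r_version = R.version.string,
      created = "see checksums; timestamps omitted for reproducibility",
      config = unclass(config),
      n_shared_genes = length(shared),
      dropped_model_genes = dropped_expr,
      checksums = as.list(tools::md5sum(sort(files))))
    names(manifest$checksums) <- basename(sort(files))
    write_json_sidecar(manifest, file.path(out, "manifest.json"))
    say("done: %d artifacts in %s", length(files) + 1L, out)
    invisible(manifest)
  }, error = function(e) {
    stop_nf("pipeline failed in stage '%s': %s", stage, conditionMessage(e))
  })
}
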