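# Plain-text interchange formats.
#
#  - expression: TSV, first column "gene", header row of condition IDs
#  - co-expression network: edge-list TSV (gene_a, gene_b, support,
#    mean_z) and GraphML
#  - metabolic model: three-file TSV dialect (reactions.tsv with
#    "2 A + B -> C" equations, metabolites.tsv, genes.tsv) and a minimal
#    SBML Level 3 + fbc subset
#  - parameters: JSON sidecars

#' Write / read an expression matrix as TSV
#' @param expr genes x conditions numeric matrix.
#' @param path output file.
#' @return `read_expression_tsv` returns the numeric matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  storage.mode(x) <- "double"
  validate_expression(x, min_conditions = 1L)
  x
}

#' Write a co-expression network
#'
#' `write_network_tsv` writes the edge list (gene_a, gene_b, support,
#' mean_z); `write_network_graphml` writes GraphML with the support and
#' mean Z as edge attributes.
#'
#' @param net a `coexpression_network`.
#' @param path output file.
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(network_edges(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(net, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  xml2::xml_add_child(doc, "key", id = "support", `for` = "edge",
                      attr.name = "support", attr.type = "int")
  xml2::xml_add_child(doc, "key", id = "mean_z", `for` = "edge",
                      attr.name = "mean_z", attr.type = "double")
  g <- xml2::xml_add_child(doc, "graph", id = "gcn", edgedefault = "undirected")
  for (gene in net$genes) xml2::xml_add_child(g, "node", id = gene)
  ed <- network_edges(net)
  for (i in seq_len(nrow(ed))) {
    e <- xml2::xml_add_child(g, "edge", source = ed$gene_a[i],
                             target = ed$gene_b[i])
    xml2::xml_add_child(e, "data", key = "support",
                        as.character(ed$support[i]))
    xml2::xml_add_child(e, "data", key = "mean_z",
                        format(ed$mean_z[i], digits = 10))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a graph from GraphML or an edge-list TSV
#'
#' @param path a `.graphml` file written by [write_network_graphml()] (or
#'   any GraphML with node `id`s), or an edge-list TSV whose first two
#'   columns are node IDs.
#' @return symmetric 0/1 adjacency matrix with node dimnames.
#' @export
read_graph <- function(path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    doc <- xml2::read_xml(path)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
    nodes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//g:node", ns), "id")
    edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
    ea <- cbind(xml2::xml_attr(edges, "source"),
                xml2::xml_attr(edges, "target"))
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    ea <- cbind(as.character(df[[1]]), as.character(df[[2]]))
    nodes <- sort(unique(c(ea)))
  }
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (length(ea)) for (i in seq_len(nrow(ea))) {
    A[ea[i, 1], ea[i, 2]] <- 1
    A[ea[i, 2], ea[i, 1]] <- 1
  }
  diag(A) <- 0
  A
}

# ---- metabolic model: TSV dialect ------------------------------------------

format_equation <- function(model, j) {
  s <- model$S[, j]
  side <- function(idx) {
    if (!length(idx)) return("")
    paste(vapply(idx, function(i) {
      coef <- abs(s[i])
      if (coef == 1) model$met_ids[i] else
        paste(format(coef, digits = 12), model$met_ids[i])
    }, character(1)), collapse = " + ")
  }
  paste(side(which(s < 0)), "->", side(which(s > 0)))
}

parse_equation <- function(eq) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) stop_nf("equation must contain '->': '%s'", eq)
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1) { coef <- 1; met <- parts }
      else if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stop_nf("bad stoichiometric coefficient in '%s'", tm)
        met <- parts[2]
      } else stop_nf("cannot parse term '%s'", tm)
      out[met] <- (if (met %in% names(out)) out[met] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  all_mets <- union(names(lhs), names(rhs))
  st <- stats::setNames(numeric(length(all_mets)), all_mets)
  st[names(lhs)] <- st[names(lhs)] + lhs
  st[names(rhs)] <- st[names(rhs)] + rhs
  st[st != 0]
}

#' Write / read a metabolic model in the three-file TSV dialect
#'
#' `reactions.tsv`: id, equation ("2 A + B -> C"), lb, ub, gpr, biomass
#' flag. `metabolites.tsv`: id, external flag. `genes.tsv`: id, category.
#'
#' @param model a [metabolic_model()].
#' @param dir directory for the three files (created if needed).
#' @return `read_model_tsv` returns a [metabolic_model()].
#' @export
write_model_tsv <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rx <- data.frame(
    id = model$rxn_ids,
    equation = vapply(seq_along(model$rxn_ids), function(j)
      format_equation(model, j), character(1)),
    lb = model$lb, ub = model$ub, gpr = model$gpr,
    biomass = as.integer(model$rxn_ids == model$biomass),
    stringsAsFactors = FALSE)
  utils::write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mets <- data.frame(id = model$met_ids,
                     external = as.integer(model$external),
                     stringsAsFactors = FALSE)
  utils::write.table(mets, file.path(dir, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cat_of <- function(g) {
    if (is.null(model$gene_category)) return("")
    v <- model$gene_category[g]
    ifelse(is.na(v), "", v)
  }
  genes <- data.frame(id = model$genes, category = cat_of(model$genes),
                      stringsAsFactors = FALSE)
  utils::write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_model_tsv
#' @export
read_model_tsv <- function(dir) {
  rx <- utils::read.table(file.path(dir, "reactions.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(id = "character", gpr = "character"))
  mets <- utils::read.table(file.path(dir, "metabolites.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            colClasses = c(id = "character"))
  genes_path <- file.path(dir, "genes.tsv")
  genes_df <- if (file.exists(genes_path))
    utils::read.table(genes_path, sep = "\t", header = TRUE, fill = TRUE,
                      stringsAsFactors = FALSE,
                      colClasses = "character") else NULL
  stoich <- lapply(rx$equation, parse_equation)
  met_ids <- mets$id
  extra <- setdiff(unique(unlist(lapply(stoich, names))), met_ids)
  if (length(extra))
    stop_nf("equation references metabolites missing from metabolites.tsv: %s",
            paste(extra, collapse = ", "))
  S <- matrix(0, length(met_ids), nrow(rx),
              dimnames = list(met_ids, rx$id))
  for (j in seq_along(stoich)) S[names(stoich[[j]]), j] <- stoich[[j]]
  biomass <- rx$id[rx$biomass == 1]
  if (length(biomass) != 1)
    stop_nf("exactly one reaction must be flagged as biomass (found %d)",
            length(biomass))
  gpr <- rx$gpr
  gpr[is.na(gpr)] <- ""
  category <- NULL
  genes <- NULL
  if (!is.null(genes_df)) {
    genes <- genes_df$id
    if ("category" %in% names(genes_df))
      category <- stats::setNames(genes_df$category, genes_df$id)
  }
  metabolic_model(S, external = mets$external == 1, lb = rx$lb, ub = rx$ub,
                  gpr = gpr, biomass = biomass, genes = genes,
                  gene_category = category)
}

# ---- metabolic model: minimal SBML L3 + fbc subset -------------------------

sbml_ns <- c(sbml = "http://www.sbml.org/sbml/level3/version1/core",
             fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

gpr_to_fbc <- function(node, ast) {
  if (is.character(ast)) {
    xml2::xml_add_child(node, "fbc:geneProductRef", `fbc:geneProduct` = ast)
  } else {
    tag <- if (ast$op == "and") "fbc:and" else "fbc:or"
    sub <- xml2::xml_add_child(node, tag)
    for (a in ast$args) gpr_to_fbc(sub, a)
  }
}

#' Write / read a metabolic model as minimal SBML Level 3 with fbc
#'
#' Covers the subset this package produces: species with
#' `boundaryCondition` for external metabolites, reactions with integer or
#' real stoichiometries, flux bounds as parameters referenced by
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound`, GPRs as
#' `fbc:geneProductAssociation`, and the biomass reaction as the single
#' `fbc:listOfObjectives` target. Not a general-purpose SBML parser.
#'
#' @param model a [metabolic_model()].
#' @param path `.xml` file path.
#' @return `read_sbml` returns a [metabolic_model()].
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = sbml_ns[["sbml"]],
                            `xmlns:fbc` = sbml_ns[["fbc"]],
                            level = "3", version = "1",
                            `fbc:required` = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             `fbc:strict` = "true")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")
  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_along(model$met_ids))
    xml2::xml_add_child(sp, "species", id = model$met_ids[i],
                        compartment = "c",
                        boundaryCondition = tolower(model$external[i]),
                        hasOnlySubstanceUnits = "false", constant = "false")
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  for (j in seq_along(model$rxn_ids)) {
    xml2::xml_add_child(pars, "parameter", id = paste0("lb_", j),
                        value = format(model$lb[j], digits = 15),
                        constant = "true")
    xml2::xml_add_child(pars, "parameter", id = paste0("ub_", j),
                        value = format(model$ub[j], digits = 15),
                        constant = "true")
  }
  gps <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model$genes)
    xml2::xml_add_child(gps, "fbc:geneProduct", `fbc:id` = g,
                        `fbc:label` = g)
  rxns <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_along(model$rxn_ids)) {
    r <- xml2::xml_add_child(rxns, "reaction", id = model$rxn_ids[j],
                             reversible = tolower(model$lb[j] < 0),
                             fast = "false",
                             `fbc:lowerFluxBound` = paste0("lb_", j),
                             `fbc:upperFluxBound` = paste0("ub_", j))
    s <- model$S[, j]
    if (any(s < 0)) {
      lr <- xml2::xml_add_child(r, "listOfReactants")
      for (i in which(s < 0))
        xml2::xml_add_child(lr, "speciesReference", species = model$met_ids[i],
                            stoichiometry = format(-s[i], digits = 15),
                            constant = "true")
    }
    if (any(s > 0)) {
      lp <- xml2::xml_add_child(r, "listOfProducts")
      for (i in which(s > 0))
        xml2::xml_add_child(lp, "speciesReference", species = model$met_ids[i],
                            stoichiometry = format(s[i], digits = 15),
                            constant = "true")
    }
    ast <- model$gpr_ast[[j]]
    if (!is.null(ast)) {
      gpa <- xml2::xml_add_child(r, "fbc:geneProductAssociation")
      gpr_to_fbc(gpa, ast)
    }
  }
  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              `fbc:activeObjective` = "obj")
  ob <- xml2::xml_add_child(objs, "fbc:objective", `fbc:id` = "obj",
                            `fbc:type` = "maximize")
  fl <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fl, "fbc:fluxObjective",
                      `fbc:reaction` = model$biomass,
                      `fbc:coefficient` = "1")
  xml2::write_xml(doc, path)
  invisible(path)
}

# namespace-agnostic helpers: SBML in the wild may or may not carry the
# fbc prefix through xml_ns_strip, so match on local names only
xfind_all <- function(node, name)
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
xfind_first <- function(node, name)
  xml2::xml_find_first(node, sprintf(".//*[local-name()='%s']", name))
xattr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
  v
}
xattr_vec <- function(nodes, name) {
  v <- xml2::xml_attr(nodes, name)
  miss <- is.na(v)
  if (any(miss)) v[miss] <- xml2::xml_attr(nodes[miss], paste0("fbc:", name))
  v
}

fbc_to_gpr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef")
    return(xattr(node, "geneProduct"))
  kids <- xml2::xml_children(node)
  args <- lapply(kids, fbc_to_gpr)
  if (nm %in% c("and", "or")) {
    if (length(args) == 1) return(args[[1]])
    return(list(op = nm, args = args))
  }
  if (length(args) == 1) return(args[[1]])
  stop_nf("unsupported geneProductAssociation node '%s'", nm)
}

#' @rdname write_sbml
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  species <- xfind_all(doc, "species")
  met_ids <- xml2::xml_attr(species, "id")
  external <- xml2::xml_attr(species, "boundaryCondition") == "true"
  external[is.na(external)] <- FALSE
  pars <- xfind_all(doc, "parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                           xml2::xml_attr(pars, "id"))
  rxns <- xfind_all(doc, "reaction")
  rxn_ids <- xml2::xml_attr(rxns, "id")
  S <- matrix(0, length(met_ids), length(rxns),
              dimnames = list(met_ids, rxn_ids))
  lb <- numeric(length(rxns)); ub <- numeric(length(rxns))
  gpr <- character(length(rxns))
  for (j in seq_along(rxns)) {
    r <- rxns[[j]]
    lb[j] <- pvals[[xattr(r, "lowerFluxBound")]]
    ub[j] <- pvals[[xattr(r, "upperFluxBound")]]
    for (sr in xml2::xml_find_all(
      r, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']"))
      S[xml2::xml_attr(sr, "species"), j] <-
        S[xml2::xml_attr(sr, "species"), j] -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(
      r, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']"))
      S[xml2::xml_attr(sr, "species"), j] <-
        S[xml2::xml_attr(sr, "species"), j] +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    gpa <- xml2::xml_find_first(r, "./*[local-name()='geneProductAssociation']")
    gpr[j] <- if (inherits(gpa, "xml_missing")) "" else
      deparse_gpr(fbc_to_gpr(xml2::xml_child(gpa)))
  }
  genes <- xattr_vec(xfind_all(doc, "geneProduct"), "id")
  biomass <- xattr(xfind_first(doc, "fluxObjective"), "reaction")
  metabolic_model(S, external = external, lb = lb, ub = ub, gpr = gpr,
                  biomass = biomass, genes = genes)
}

#' Read a metabolic model from SBML or the TSV dialect
#' @param path an `.xml`/`.sbml` file, or a directory containing
#'   `reactions.tsv` and `metabolites.tsv`.
#' @return a [metabolic_model()].
#' @export
read_model <- function(path) {
  if (dir.exists(path)) return(read_model_tsv(path))
  if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
    return(read_sbml(path))
  stop_nf("cannot determine model format of '%s'", path)
}

#' Write a JSON parameter sidecar
#' @param params named list.
#' @param path output `.json` path.
#' @export
write_json_sidecar <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
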