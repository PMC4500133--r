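# Gene-protein-reaction (GPR) boolean rules.
#
# Grammar (case-insensitive keywords):
#   expr   := term ( OR term )*
#   term   := factor ( AND factor )*
#   factor := '(' expr ')' | gene-identifier
#
# A rule is parsed once into a nested list AST and then evaluated either
# numerically (AND -> min, OR -> max; used to map expression onto
# reactions) or boolean (gene present/absent; used for knockouts).

gpr_tokenize <- function(rule) {
  pat <- "\\(|\\)|[A-Za-z0-9_.:-]+"
  toks <- regmatches(rule, gregexpr(pat, rule))[[1]]
  leftover <- gsub(pat, "", rule)
  if (grepl("[^[:space:]]", leftover))
    stop_nf("cannot tokenize GPR rule: '%s'", rule)
  toks
}

#' Parse a GPR boolean rule
#'
#' @param rule a string such as `"(g1 AND g2) OR g3"`; `""` or `NA` give
#'   `NULL` (no gene association).
#' @return an AST: a gene ID string, or `list(op = "and"|"or", args = ...)`.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw

  parse_expr <- function() {
    args <- list(parse_term())
    while (is_kw(peek(), "or")) { take(); args <- c(args, list(parse_term())) }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_kw(peek(), "and")) { take(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop_nf("unexpected end of GPR rule: '%s'", rule)
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) stop_nf("unbalanced parentheses in GPR: '%s'", rule)
      return(e)
    }
    if (t == ")" || is_kw(t, "and") || is_kw(t, "or"))
      stop_nf("malformed GPR rule: '%s'", rule)
    t
  }
  ast <- parse_expr()
  if (pos <= length(toks)) stop_nf("trailing tokens in GPR rule: '%s'", rule)
  ast
}

#' Genes referenced by a GPR AST
#' @param ast output of [parse_gpr()].
#' @return character vector of gene IDs (possibly empty).
#' @export
gpr_genes <- function(ast) {
  if (is.null(ast)) return(character())
  if (is.character(ast)) return(ast)
  unique(unlist(lapply(ast$args, gpr_genes)))
}

#' Evaluate a GPR rule numerically (AND -> min, OR -> max)
#' @param ast output of [parse_gpr()].
#' @param values named numeric vector of per-gene expression values.
#' @return a single number, or `NA` for a `NULL` (absent) rule.
#' @export
eval_gpr_numeric <- function(ast, values) {
  if (is.null(ast)) return(NA_real_)
  if (is.character(ast)) {
    if (!ast %in% names(values)) stop_nf("no expression value for gene '%s'", ast)
    return(unname(values[[ast]]))
  }
  vals <- vapply(ast$args, eval_gpr_numeric, numeric(1), values = values)
  if (ast$op == "and") min(vals) else max(vals)
}

#' Evaluate a GPR rule boolean (gene present/absent)
#' @param ast output of [parse_gpr()].
#' @param active named logical vector; genes absent from `active` count as
#'   present (TRUE).
#' @return TRUE/FALSE; a `NULL` rule evaluates TRUE (reaction not
#'   gene-associated, never disabled by a knockout).
#' @export
eval_gpr_boolean <- function(ast, active) {
  if (is.null(ast)) return(TRUE)
  if (is.character(ast)) {
    if (ast %in% names(active)) return(unname(active[[ast]]))
    return(TRUE)
  }
  vals <- vapply(ast$args, eval_gpr_boolean, logical(1), active = active)
  if (ast$op == "and") all(vals) else any(vals)
}

#' Render a GPR AST back to a rule string
#' @param ast output of [parse_gpr()].
#' @return a single string (`""` for `NULL`).
#' @export
deparse_gpr <- function(ast) {
  if (is.null(ast)) return("")
  if (is.character(ast)) return(ast)
  parts <- vapply(ast$args, function(a) {
    s <- deparse_gpr(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", toupper(ast$op), " "))
}
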