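# Gene-protein-reaction (GPR) rules: boolean expressions over gene IDs with
# AND/OR and parentheses, e.g. "g1 AND (g2 OR g3)". A complex (AND) is limited
# by its scarcest subunit; isozymes (OR) are dominated by the most abundant
# member. On signed log2 fold changes this becomes AND -> min, OR -> max.

#' Parse a GPR rule into an expression tree
#'
#' Grammar (case-insensitive keywords, standard precedence AND > OR):
#' `expr := term (OR term)*`, `term := factor (AND factor)*`,
#' `factor := gene | "(" expr ")"`. An empty or all-whitespace rule parses to
#' `NULL` (reaction not gene-associated).
#'
#' @param rule character scalar GPR string.
#' @return a tree of nested lists: `list(op = "and"|"or", args = list(...))`
#'   with gene leaves as character scalars, or `NULL` for an empty rule.
#' @examples
#' parse_gpr("g1 AND (g2 OR g3)")
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0 || is.na(rule)) return(NULL)
  stopifnot(is.character(rule), length(rule) == 1L)
  if (!nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed GPR: unexpected token '", st$toks[st$pos],
         "' in rule: ", rule, call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_factor(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_factor(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_factor <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop("malformed GPR: unexpected end of rule", call. = FALSE)
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop("malformed GPR: missing ')'", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop("malformed GPR: unexpected token '", tok, "'", call. = FALSE)
  }
  st$pos <- st$pos + 1L
  tok
}

#' Evaluate a GPR tree against per-gene values
#'
#' AND combines by the signed minimum of its operands, OR by the signed
#' maximum. Genes absent from `values` contribute 0 (not differentially
#' expressed).
#'
#' @param tree result of [parse_gpr()]; `NULL` evaluates to 0.
#' @param values named numeric vector of per-gene values (e.g. log2FC of DEGs).
#' @return numeric scalar.
#' @export
eval_gpr <- function(tree, values) {
  if (is.null(tree)) return(0)
  if (is.character(tree)) {
    v <- unname(values[tree])
    return(if (is.na(v) || length(v) == 0) 0 else v)
  }
  vals <- vapply(tree$args, eval_gpr, numeric(1), values = values)
  if (tree$op == "and") min(vals) else max(vals)
}

#' Genes referenced by a GPR tree
#' @param tree result of [parse_gpr()].
#' @return character vector of gene IDs (empty for `NULL`).
#' @keywords internal
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}
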