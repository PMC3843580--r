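# Gene-protein-reaction (GPR) association rules: boolean AND/OR expressions
# over gene identifiers that state which gene products a reaction requires.
# "a and b" means an enzyme complex needing both products, "a or b" isoenzymes.

# token kinds: "(", ")", "and", "or", literal
gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|&{1,2}|\\|{1,2}|[A-Za-z0-9_.-]+"
  m <- gregexpr(pat, text)[[1]]
  toks <- if (m[1] == -1) character(0) else regmatches(text, gregexpr(pat, text))[[1]]
  starts <- if (m[1] == -1) integer(0) else as.integer(m)
  # anything not matched and not whitespace is illegal
  covered <- rep(FALSE, nchar(text))
  for (k in seq_along(starts)) {
    covered[starts[k]:(starts[k] + nchar(toks[k]) - 1L)] <- TRUE
  }
  chars <- strsplit(text, "")[[1]]
  bad <- which(!covered & !grepl("^\\s$", chars))
  if (length(bad)) {
    fk_syntax_error(sprintf("unexpected character '%s' at position %d in GPR rule", chars[bad[1]], bad[1]))
  }
  kind <- ifelse(toks == "(", "(",
          ifelse(toks == ")", ")",
          ifelse(tolower(toks) == "and" | toks == "&" | toks == "&&", "and",
          ifelse(tolower(toks) == "or" | toks == "|" | toks == "||", "or", "lit"))))
  list(tok = toks, kind = kind, pos = starts)
}

#' Parse a gene-protein-reaction rule
#'
#' Parses boolean gene association text into an expression tree. Gene tokens
#' match `[A-Za-z0-9_.-]+`; operators are `and`/`or` (case-insensitive) with
#' `&`/`|` accepted as synonyms; `and` binds tighter than `or`; parentheses
#' group; empty or blank text yields the empty rule (a reaction without gene
#' association, unaffected by any knockout).
#'
#' @param text rule text, e.g. `"(g1 and g2) or g3"`.
#' @return an object of class `gpr_rule`: a nested list with nodes of kind
#'   `lit` (gene), `and`, `or`, or `empty`.
#' @examples
#' r <- parse_gpr("(g1 and g2) or g3")
#' evaluate_gpr(r, "g1")          # TRUE: g3 alone suffices
#' evaluate_gpr(r, c("g1", "g3")) # FALSE
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(trimws(text))) {
    return(structure(list(op = "empty"), class = "gpr_rule"))
  }
  tk <- gpr_tokenize(text)
  n <- length(tk$tok)
  i <- 0L

  peek <- function() if (i < n) tk$kind[i + 1L] else NA_character_
  advance <- function() { i <<- i + 1L; i }
  err_here <- function(what) {
    pos <- if (i < n) tk$pos[i + 1L] else nchar(text) + 1L
    fk_syntax_error(sprintf("%s at position %d in GPR rule '%s'", what, pos, text))
  }

  parse_primary <- function() {
    k <- peek()
    if (is.na(k)) err_here("unexpected end of rule")
    if (k == "lit") {
      advance()
      return(list(op = "lit", gene = tk$tok[i]))
    }
    if (k == "(") {
      advance()
      nd <- parse_or()
      if (!identical(peek(), ")")) err_here("unbalanced parentheses: expected ')'")
      advance()
      return(nd)
    }
    err_here(sprintf("dangling operator '%s'", tk$tok[i + 1L]))
  }
  parse_and <- function() {
    args <- list(parse_primary())
    while (identical(peek(), "and")) {
      advance()
      args <- c(args, list(parse_primary()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), "or")) {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }

  nd <- parse_or()
  if (i < n) err_here(sprintf("unexpected token '%s'", tk$tok[i + 1L]))
  structure(nd, class = "gpr_rule")
}

#' Evaluate a GPR rule under a set of knocked-out genes
#'
#' @param rule a `gpr_rule` from [parse_gpr()].
#' @param knocked_out character vector of deleted gene identifiers.
#' @return `TRUE` if the reaction remains catalysable, `FALSE` otherwise.
#'   The empty rule always evaluates to `TRUE`.
#' @export
evaluate_gpr <- function(rule, knocked_out = character(0)) {
  eval_node <- function(nd) {
    switch(nd$op,
      empty = TRUE,
      lit = !(nd$gene %in% knocked_out),
      and = all(vapply(nd$args, eval_node, logical(1))),
      or  = any(vapply(nd$args, eval_node, logical(1))),
      stop("corrupt GPR node")
    )
  }
  eval_node(unclass(rule))
}

#' Render a GPR rule as canonical text
#'
#' Fully parenthesised, lower-case `and`/`or`. Parsing the rendered text
#' reproduces the identical tree; the TSV writer uses this rendering.
#'
#' @param rule a `gpr_rule`.
#' @return a character scalar; `""` for the empty rule.
#' @export
unparse_gpr <- function(rule) {
  render <- function(nd) {
    switch(nd$op,
      empty = "",
      lit = nd$gene,
      and = paste0("(", paste(vapply(nd$args, render, character(1)), collapse = " and "), ")"),
      or  = paste0("(", paste(vapply(nd$args, render, character(1)), collapse = " or "), ")")
    )
  }
  render(unclass(rule))
}

#' Genes referenced by a GPR rule
#' @param rule a `gpr_rule`.
#' @return character vector of unique gene identifiers (possibly empty).
#' @export
gpr_genes <- function(rule) {
  collect <- function(nd) {
    switch(nd$op,
      empty = character(0),
      lit = nd$gene,
      unlist(lapply(nd$args, collect))
    )
  }
  unique(collect(unclass(rule)))
}

#' Reactions disabled by a gene knockout
#'
#' Evaluates every reaction's GPR rule with the given genes removed and
#' returns the reactions that can no longer be catalysed. Genes not present
#' in the model are ignored (with a message), so gene lists from external
#' annotations can be screened directly. Reactions without gene association
#' are never affected.
#'
#' @param model a [MetabolicModel].
#' @param knocked_out character vector of gene identifiers to delete.
#' @return character vector of reaction identifiers.
#' @export
affected_reactions <- function(model, knocked_out) {
  unknown <- setdiff(knocked_out, model@genes)
  if (length(unknown)) {
    message("ignoring genes absent from model: ", paste(unknown, collapse = ", "))
  }
  hit <- vapply(model@gpr, function(r) !evaluate_gpr(r, knocked_out), logical(1))
  model@reactions[hit]
}
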