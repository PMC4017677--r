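#' Parse a gene-protein-reaction (GPR) rule
#'
#' Parses a boolean gene-association expression such as
#' `"(G1 and G2) or G3"` into an expression tree.  `and`/`or` are accepted
#' case-insensitively, as are the symbolic forms `&`, `&&`, `|`, `||`.
#' `or` binds weaker than `and`, the community convention for isozyme
#' (OR) and enzyme-complex (AND) semantics.
#'
#' @param text rule string; `NA`, `NULL` or an empty string yield `NULL`
#'   (no gene association).
#' @return a GPR tree: either a gene identifier (character scalar leaf) or
#'   a list with elements `op` (`"and"` or `"or"`) and `args` (list of
#'   subtrees); `NULL` for an empty rule.
#' @examples
#' parse_gpr("(G1 and G2) or G3")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text)) return(NULL)
  text <- trimws(text)
  if (!nzchar(text)) return(NULL)

  # tokenize
  raw <- gsub("([()])", " \\1 ", text)
  raw <- gsub("\\|\\||\\|", " or ", raw)
  raw <- gsub("&&|&", " and ", raw)
  toks <- strsplit(trimws(raw), "\\s+")[[1]]
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() pos <<- pos + 1L

  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    tk <- peek()
    if (is.na(tk)) stop("malformed GPR rule: unexpected end of input in '",
                        text, "'", call. = FALSE)
    if (tk == "(") {
      advance()
      node <- parse_or()
      if (is.na(peek()) || peek() != ")")
        stop("malformed GPR rule: missing ')' in '", text, "'", call. = FALSE)
      advance()
      return(node)
    }
    if (tk == ")" || tolower(tk) %in% c("and", "or"))
      stop("malformed GPR rule: unexpected token '", tk, "' in '", text, "'",
           call. = FALSE)
    advance()
    tk
  }

  tree <- parse_or()
  if (pos <= length(toks))
    stop("malformed GPR rule: trailing tokens in '", text, "'", call. = FALSE)
  tree
}

#' Genes referenced by a GPR tree
#' @param tree a tree from [parse_gpr()].
#' @return character vector of unique gene identifiers (empty for `NULL`).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Evaluate a GPR tree against per-gene values
#'
#' Recursively aggregates per-gene values through the rule: `or` nodes by
#' `or_fun` (default `max`, isozymes) and `and` nodes by `and_fun`
#' (default `min`, complex subunits).  With logical values and the
#' defaults this reduces to boolean evaluation.
#'
#' @param tree a tree from [parse_gpr()].
#' @param values named numeric (or logical) vector of per-gene values.
#' @param default value used for genes absent from `values`.
#' @param or_fun,and_fun aggregation functions.
#' @return scalar aggregate; `NA` for a `NULL` tree.
#' @export
eval_gpr <- function(tree, values, default = NA_real_,
                     or_fun = max, and_fun = min) {
  if (is.null(tree)) return(NA_real_)
  if (is.character(tree)) {
    if (tree %in% names(values)) return(as.numeric(values[[tree]]))
    return(as.numeric(default))
  }
  vals <- vapply(tree$args, eval_gpr, numeric(1), values = values,
                 default = default, or_fun = or_fun, and_fun = and_fun)
  if (tree$op == "or") or_fun(vals) else and_fun(vals)
}

#' Serialise a GPR tree back to rule text
#' @param tree a tree from [parse_gpr()].
#' @return rule string (empty string for `NULL`).
#' @export
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gpr(a)
    if (!is.character(a) && a$op != tree$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
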