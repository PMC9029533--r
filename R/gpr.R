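#' @name gpr
#' @title GPR Boolean rule parsing and evaluation
#'
#' @description
#' Gene-protein-reaction (GPR) rules link genes to the reactions they
#' catalyse: `and` joins subunits of an enzyme complex, `or` joins isozymes.
#' `parse_gpr()` turns the rule text into an AST; `evaluate_gpr()` maps
#' expression values through it under a choice of AND/OR operators;
#' `evaluate_gpr_boolean()` evaluates catalytic capability under gene
#' knockouts.
NULL

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^\\s()]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(token = character(), pos = integer()))
  data.frame(token = regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

gpr_node <- function(kind, children = NULL, gene = NULL) {
  structure(list(kind = kind, children = children, gene = gene),
            class = "gpr_node")
}

#' Parse a GPR rule
#'
#' Grammar: gene ids, `and`, `or` (case-insensitive), parentheses; `and`
#' binds tighter than `or`. Operator runs at one syntactic level become one
#' n-ary node (`a and b and c` has three children), but parenthesised
#' sub-rules keep their own node: nesting is semantically significant for
#' the geometric-mean AND operator, which is not associative. An empty or
#' whitespace-only rule returns `NULL` (no gene association).
#'
#' @param text GPR rule text.
#' @return A `gpr_node` tree (kinds `gene`, `and_node` -> `and`, `or_node`
#'   -> `or`), or `NULL` for an empty rule.
#' @export
#' @examples
#' parse_gpr("(g1 and g2) or g3")
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  i <- 1L
  n <- nrow(toks)
  peek <- function() if (i <= n) toks$token[i] else NA_character_
  fail <- function(msg) {
    pos <- if (i <= n) toks$pos[i] else nchar(text) + 1L
    stop("GPR parse error at position ", pos, " in '", text, "': ", msg)
  }

  parse_or <- function() {
    left <- parse_and()
    kids <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      i <<- i + 1L
      kids <- c(kids, list(parse_and()))
    }
    if (length(kids) == 1L) left else gpr_node("or", children = kids)
  }
  parse_and <- function() {
    left <- parse_atom()
    kids <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      i <<- i + 1L
      kids <- c(kids, list(parse_atom()))
    }
    if (length(kids) == 1L) left else gpr_node("and", children = kids)
  }
  parse_atom <- function() {
    tok <- peek()
    if (is.na(tok)) fail("expected gene id or '('")
    if (tok == "(") {
      i <<- i + 1L
      inner <- parse_or()
      if (is.na(peek()) || peek() != ")") fail("expected ')'")
      i <<- i + 1L
      return(inner)
    }
    if (tok == ")") fail("unexpected ')'")
    if (tolower(tok) %in% c("and", "or")) fail(paste0("dangling operator '", tok, "'"))
    i <<- i + 1L
    gpr_node("gene", gene = tok)
  }

  root <- parse_or()
  if (i <= n) fail(paste0("unexpected token '", peek(), "'"))
  root
}

#' Genes referenced by a GPR rule
#'
#' @param text GPR rule text.
#' @return Character vector of gene ids (empty for an empty rule).
#' @export
gpr_genes <- function(text) {
  expr <- parse_gpr(text)
  collect <- function(node) {
    if (is.null(node)) return(character())
    if (node$kind == "gene") return(node$gene)
    unlist(lapply(node$children, collect))
  }
  unique(collect(expr))
}

#' Mapping scheme for GPR evaluation
#'
#' The operator pair used to reduce expression values across GPR nodes:
#' complexes (`and`) by minimum or geometric mean, isozymes (`or`) by
#' maximum or sum.
#'
#' @param and_operator `"MIN"` or `"GEOMETRIC_MEAN"`.
#' @param or_operator `"MAX"` or `"SUM"`.
#' @return A `mapping_scheme` object.
#' @export
mapping_scheme <- function(and_operator = c("MIN", "GEOMETRIC_MEAN"),
                           or_operator = c("MAX", "SUM")) {
  structure(list(and_operator = match.arg(and_operator),
                 or_operator = match.arg(or_operator)),
            class = "mapping_scheme")
}

geometric_mean <- function(x) {
  if (any(x == 0)) return(0)  # limit of the formula; no epsilon injected
  exp(mean(log(x)))
}

#' Evaluate a GPR rule against expression values
#'
#' Leaves take their gene's expression value; `and` nodes reduce children by
#' MIN or geometric mean, `or` nodes by MAX or SUM. Genes absent from
#' `expression` are handled by `missing_policy`: `"skip"` drops undefined
#' operands (a node with no defined operand is itself undefined), so one
#' unmeasured isozyme does not nullify a reaction; `"undefined"` makes any
#' missing gene undefine the whole rule.
#'
#' @param expr result of [parse_gpr()] (or `NULL`).
#' @param expression named numeric vector, gene id -> value (>= 0).
#' @param scheme a [mapping_scheme()].
#' @param missing_policy `"skip"` (default) or `"undefined"`.
#' @return Non-negative numeric value, or `NA_real_` when undefined.
#' @export
#' @examples
#' e <- parse_gpr("(g1 and g2) or g3")
#' evaluate_gpr(e, c(g1 = 871, g2 = 126, g3 = 319), mapping_scheme("MIN", "MAX"))
evaluate_gpr <- function(expr, expression, scheme = mapping_scheme(),
                         missing_policy = c("skip", "undefined")) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(expr)) return(NA_real_)
  recur <- function(node) {
    if (node$kind == "gene") {
      v <- expression[node$gene]
      return(if (node$gene %in% names(expression)) unname(v) else NA_real_)
    }
    vals <- vapply(node$children, recur, numeric(1))
    if (missing_policy == "undefined" && anyNA(vals)) return(NA_real_)
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_real_)
    if (node$kind == "and") {
      if (scheme$and_operator == "MIN") min(vals) else geometric_mean(vals)
    } else {
      if (scheme$or_operator == "MAX") max(vals) else sum(vals)
    }
  }
  recur(expr)
}

#' Boolean GPR evaluation under gene deletion
#'
#' A reaction remains catalysable iff its GPR has a satisfiable operand path
#' avoiding the deleted genes: deleted leaves are FALSE, present leaves TRUE,
#' `and` = all, `or` = any. Standard COBRA knockout semantics.
#'
#' @param expr result of [parse_gpr()] (or `NULL`).
#' @param deleted_genes character vector of knocked-out gene ids.
#' @return `TRUE` if catalysis is still possible; empty rules (`NULL`) are
#'   always `TRUE` (no gene dependency).
#' @export
evaluate_gpr_boolean <- function(expr, deleted_genes) {
  if (is.null(expr)) return(TRUE)
  recur <- function(node) {
    if (node$kind == "gene") return(!(node$gene %in% deleted_genes))
    vals <- vapply(node$children, recur, logical(1))
    if (node$kind == "and") all(vals) else any(vals)
  }
  recur(expr)
}
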