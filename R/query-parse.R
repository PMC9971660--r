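# The search grammar: terms joined by AND; taxon terms are tax_-prefixed
# functions (tax_eq, tax_name, tax_tree, tax_rank, tax_depth, tax_lineage)
# whose comma-separated arguments may carry a name-class prefix
# ("tol_id:*"), glob wildcards, and "!" negation; attribute terms compare a
# summarised value ("assembly_span>500000000"), optionally through a
# min()/max()/length() modifier, with comma-separated values meaning OR and
# a bare attribute name meaning an existence filter.

TAX_FUNCTIONS <- c("tax_eq", "tax_name", "tax_tree", "tax_rank",
                   "tax_depth", "tax_lineage")
QUERY_OPERATORS <- c("<=", ">=", "!=", "==", "=", "<", ">")

parse_error <- function(msg, text, at = NA) {
  where <- if (!is.na(at)) paste0(" (near character ", at, ")") else ""
  stop_taxatlas(paste0("query parse error: ", msg, where,
                       " in \"", text, "\""), "taxatlas_parse_error")
}

taxon_term <- function(fn, args) {
  list(kind = "taxon", fn = fn, args = args)
}

attribute_term <- function(attribute, modifier = "none",
                           operator = "exists", values = character(),
                           negated = FALSE) {
  list(kind = "attribute", attribute = attribute, modifier = modifier,
       operator = operator, values = values, negated = negated)
}

parse_tax_arg <- function(arg, text) {
  negated <- startsWith(arg, "!")
  if (negated) arg <- trimws(sub("^!", "", arg))
  if (!nzchar(arg)) parse_error("empty taxon argument", text)
  m <- regmatches(arg, regexec("^([A-Za-z_][A-Za-z0-9_]*):(.*)$", arg))[[1]]
  if (length(m)) {
    list(name_class = m[2], pattern = trimws(m[3]), negated = negated)
  } else {
    list(name_class = NA_character_, pattern = arg, negated = negated)
  }
}

parse_term <- function(term, text, offset) {
  if (!nzchar(term)) parse_error("empty term", text, offset)
  n_open <- lengths(regmatches(term, gregexpr("(", term, fixed = TRUE)))
  n_close <- lengths(regmatches(term, gregexpr(")", term, fixed = TRUE)))
  if (n_open != n_close) parse_error("unbalanced parentheses", text, offset)

  # taxon function term
  m <- regmatches(term, regexec("^(tax_[a-z]+)\\s*\\((.*)\\)$", term))[[1]]
  if (length(m)) {
    fn <- m[2]
    if (!fn %in% TAX_FUNCTIONS) parse_error(
      paste0("unknown taxon function ", fn, "()"), text, offset)
    raw_args <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    if (!length(raw_args)) parse_error(
      paste0(fn, "() needs at least one argument"), text, offset)
    args <- lapply(raw_args, parse_tax_arg, text = text)
    return(taxon_term(fn, args))
  }
  if (grepl("^tax_", term)) parse_error(
    "malformed taxon function call", text, offset)

  # modifier term: min()/max()/length()
  m <- regmatches(term, regexec(
    "^(min|max|length)\\s*\\(\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*\\)\\s*(<=|>=|!=|==|=|<|>)\\s*(.+)$",
    term))[[1]]
  if (length(m)) {
    op <- if (m[4] == "==") "=" else m[4]
    vals <- trimws(strsplit(m[5], ",", fixed = TRUE)[[1]])
    return(attribute_term(m[3], modifier = m[2], operator = op,
                          values = vals))
  }

  # plain comparison
  m <- regmatches(term, regexec(
    "^(!?)\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*(<=|>=|!=|==|=|<|>)\\s*(.+)$",
    term))[[1]]
  if (length(m)) {
    op <- if (m[4] == "==") "=" else m[4]
    vals <- trimws(strsplit(m[5], ",", fixed = TRUE)[[1]])
    if (!length(vals)) parse_error("comparison with no value", text, offset)
    return(attribute_term(m[3], operator = op, values = vals,
                          negated = m[2] == "!"))
  }

  # bare attribute = existence filter
  m <- regmatches(term, regexec("^(!?)\\s*([A-Za-z_][A-Za-z0-9_]*)$",
                                term))[[1]]
  if (length(m)) {
    return(attribute_term(m[3], negated = m[2] == "!"))
  }
  parse_error("unparseable term", text, offset)
}

#' Parse a search query string
#'
#' @param text the query, e.g.
#'   `"tax_tree(Lepidoptera) AND assembly_span > 500000000"`.
#' @return an object of class `taxatlas_query`: a conjunction of taxon and
#'   attribute terms. [render_query()] produces the canonical string form
#'   and `parse_query(render_query(q))` reproduces `q` exactly.
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  trimmed <- trimws(text)
  if (!nzchar(trimmed)) parse_error("empty query", text)
  pieces <- strsplit(trimmed, "\\s+AND\\s+")[[1]]
  offsets <- cumsum(c(1, nchar(pieces) + 5))[seq_along(pieces)]
  terms <- purrr::map2(trimws(pieces), offsets, parse_term, text = text)

  fns <- vapply(purrr::keep(terms, ~ .x$kind == "taxon"), `[[`, "", "fn")
  if ("tax_depth" %in% fns &&
      !any(fns %in% c("tax_eq", "tax_name", "tax_tree"))) {
    parse_error(
      "tax_depth() requires an anchoring tax_eq/tax_name/tax_tree term",
      text)
  }
  structure(list(terms = terms), class = "taxatlas_query")
}

render_tax_arg <- function(a) {
  paste0(if (a$negated) "!" else "",
         if (!is.na(a$name_class)) paste0(a$name_class, ":") else "",
         a$pattern)
}

#' Render a parsed query back to its canonical string form
#'
#' @param query a `taxatlas_query`.
#' @return a single string; whitespace is normalised (no spaces around
#'   operators, `" AND "` between terms).
#' @export
render_query <- function(query) {
  stopifnot(inherits(query, "taxatlas_query"))
  out <- vapply(query$terms, function(t) {
    if (t$kind == "taxon") {
      paste0(t$fn, "(",
             paste(vapply(t$args, render_tax_arg, ""), collapse = ","), ")")
    } else {
      lhs <- if (t$modifier == "none") t$attribute
             else paste0(t$modifier, "(", t$attribute, ")")
      body <- if (t$operator == "exists") lhs
              else paste0(lhs, t$operator, paste(t$values, collapse = ","))
      paste0(if (t$negated) "!" else "", body)
    }
  }, "")
  paste(out, collapse = " AND ")
}

#' @export
print.taxatlas_query <- function(x, ...) {
  cat("<taxatlas_query> ", render_query(x), "\n", sep = "")
  invisible(x)
}
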