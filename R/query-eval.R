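# Query evaluation over the in-process taxon and assembly indexes. A
# document matches when every term matches; taxon terms resolve to taxon
# sets (descendant closure for tax_tree via child-pointer traversal) and
# attribute terms to vectorised comparisons on the summarised value table.

# taxa matching one name-class/pattern argument (ignoring negation)
resolve_taxa_by_name <- function(store, arg) {
  nt <- store$names_tbl
  rows <- if (!is.na(arg$name_class)) nt[nt$name_class == arg$name_class, ]
          else nt
  unique(rows$taxon_id[glob_match(arg$pattern, rows$name)])
}

# taxon ids matched by a single taxon term, at taxon level
taxon_term_ids <- function(store, term) {
  all_ids <- names(store$parent)
  expand <- function(arg) {
    switch(term$fn,
      tax_eq = intersect(arg$pattern, all_ids),
      tax_name = resolve_taxa_by_name(store, arg),
      tax_tree = {
        anchors <- unique(c(intersect(arg$pattern, all_ids),
                            resolve_taxa_by_name(store, arg)))
        unique(c(anchors,
                 unlist(lapply(anchors, descendant_ids, store = store))))
      },
      tax_rank = all_ids[store$rank[all_ids] == tolower(arg$pattern)],
      tax_lineage = {
        anchors <- unique(c(intersect(arg$pattern, all_ids),
                            resolve_taxa_by_name(store, arg)))
        if (length(anchors) != 1) stop_taxatlas(
          paste0("tax_lineage() must match exactly one taxon; '",
                 arg$pattern, "' matched ", length(anchors)),
          "taxatlas_query_error")
        store$lineage[[anchors]]
      },
      tax_depth = stop_taxatlas("tax_depth resolved separately",
                                "taxatlas_internal_error"))
  }
  pos <- purrr::keep(term$args, ~ !.x$negated)
  neg <- purrr::keep(term$args, ~ .x$negated)
  base <- if (length(pos)) unique(unlist(lapply(pos, expand))) else all_ids
  if (length(neg)) base <- setdiff(base, unlist(lapply(neg, expand)))
  base
}

# anchors for tax_depth: union of taxa named by the query's other taxon terms
depth_anchor_ids <- function(store, query) {
  anchors <- character()
  for (t in query$terms) {
    if (t$kind != "taxon" || !t$fn %in% c("tax_eq", "tax_name", "tax_tree"))
      next
    for (a in purrr::keep(t$args, ~ !.x$negated)) {
      anchors <- c(anchors, intersect(a$pattern, names(store$parent)),
                   resolve_taxa_by_name(store, a))
    }
  }
  unique(anchors)
}

# taxa within `d` edges below (or at) any anchor
within_depth <- function(store, anchors, d) {
  out <- anchors
  frontier <- anchors
  k <- 0
  while (k < d && length(frontier)) {
    frontier <- unlist(store$children[frontier], use.names = FALSE)
    out <- c(out, frontier)
    k <- k + 1
  }
  unique(out)
}

coerce_query_value <- function(v, def) {
  if (def$type %in% c("integer", "float")) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) stop_taxatlas(
      paste0("non-numeric comparison value '", v, "' for ", def$name),
      "taxatlas_query_error")
    num
  } else if (def$type == "date") {
    d <- suppressWarnings(as.Date(v))
    if (is.na(d)) stop_taxatlas(
      paste0("unparseable date '", v, "' for ", def$name),
      "taxatlas_query_error")
    as.numeric(d)
  } else if (def$type == "ordered_keyword") {
    enum <- def$constraints$enum
    hit <- match(tolower(v), tolower(enum))
    if (is.na(hit)) stop_taxatlas(
      paste0("'", v, "' is not an allowed value of ", def$name),
      "taxatlas_query_error")
    enum_score(enum[hit], enum)
  } else v
}

# logical mask over `ids` for one attribute term
attribute_term_mask <- function(store, term, index, ids, include_estimates) {
  def <- attr_def(store, term$attribute, index)
  ordered <- def$type %in% c("integer", "float", "date", "ordered_keyword")
  if (term$modifier == "length") ordered <- TRUE  # comparisons on counts
  if (term$operator %in% c("<", "<=", ">=", ">") && !ordered) stop_taxatlas(
    paste0("ordering operator '", term$operator,
           "' is not defined for unordered attribute '", term$attribute,
           "'"), "taxatlas_query_error")

  if (term$modifier == "length") {
    raws <- raw_tbl(store, index, term$attribute)
    counts <- table(raws$id)
    n <- as.integer(counts[ids])
    n[is.na(n)] <- 0L
    if (term$operator == "exists") return(n > 0L)
    qv <- suppressWarnings(as.numeric(term$values))
    return(compare_mask(n, term$operator, qv, has = n > 0L))
  }

  slots <- slot_tbl(store, index, term$attribute)
  if (!include_estimates)
    slots <- slots[slots$provenance %in% c("direct", "descendant"), ]
  idx <- match(ids, slots$id)
  has <- !is.na(idx)

  if (term$modifier %in% c("min", "max")) {
    col <- if (term$modifier == "min") slots$min else slots$max
    x <- col[idx]
    if (term$operator == "exists") return(has & !is.na(x))
    qv <- vapply(term$values, coerce_query_value, 0, def = def)
    return(compare_mask(x, term$operator, qv, has = has & !is.na(x)))
  }

  if (term$operator == "exists") return(has)

  if (def$type == "list") {
    vals <- slots$value_list[idx]
    qv <- tolower(term$values)
    mask <- vapply(seq_along(ids), function(i) {
      if (!has[i]) return(FALSE)
      hit <- any(tolower(vals[[i]]) %in% qv)
      if (term$operator == "=") hit else !hit
    }, TRUE)
    return(mask)
  }

  if (def$type == "keyword") {
    x <- tolower(slots$value_chr[idx])
    qv <- tolower(term$values)
    if (term$operator == "=") return(has & x %in% qv)
    if (term$operator == "!=") return(has & !x %in% qv)
    stop_taxatlas(paste0("operator '", term$operator,
                         "' not supported for keyword attributes"),
                  "taxatlas_query_error")
  }

  x <- slots$value_num[idx]
  qv <- vapply(term$values, coerce_query_value, 0, def = def)
  compare_mask(x, term$operator, qv, has = has & !is.na(x))
}

# x vs a value list: comma means OR for =, NOT IN for !=
compare_mask <- function(x, op, qv, has) {
  m <- switch(op,
    "=" = Reduce(`|`, lapply(qv, function(v) x == v)),
    "!=" = !Reduce(`|`, lapply(qv, function(v) x == v)),
    "<" = Reduce(`|`, lapply(qv, function(v) x < v)),
    "<=" = Reduce(`|`, lapply(qv, function(v) x <= v)),
    ">=" = Reduce(`|`, lapply(qv, function(v) x >= v)),
    ">" = Reduce(`|`, lapply(qv, function(v) x > v)))
  m[is.na(m)] <- FALSE
  m & has
}

# ids (in deterministic ascending order) matching the query
matching_ids <- function(store, query, index = "taxon",
                         include_estimates = TRUE) {
  ids <- if (index == "taxon") names(store$parent)
         else store$assemblies$assembly_id
  if (!length(ids)) return(character())
  owner <- if (index == "assembly") assembly_taxon(store) else NULL
  mask <- rep(TRUE, length(ids))
  for (term in query$terms) {
    if (term$kind == "taxon") {
      tset <- if (term$fn == "tax_depth") {
        anchors <- depth_anchor_ids(store, query)
        d <- suppressWarnings(as.numeric(term$args[[1]]$pattern))
        if (is.na(d)) stop_taxatlas("tax_depth() needs a numeric depth",
                                    "taxatlas_query_error")
        within_depth(store, anchors, d)
      } else {
        taxon_term_ids(store, term)
      }
      tmask <- if (index == "taxon") ids %in% tset
               else unname(owner[ids]) %in% tset
      mask <- mask & tmask
    } else {
      mask <- mask & attribute_term_mask(store, term, index, ids,
                                         include_estimates)
    }
  }
  value_sort(ids[mask])
}

#' Count the documents matching a query
#'
#' Equivalent to `nrow(search_docs(...))` but never materialises result
#' fields.
#'
#' @inheritParams search_docs
#' @return an integer count.
#' @export
count_docs <- function(store, query, index = "taxon",
                       include_estimates = TRUE) {
  if (is.character(query)) query <- parse_query(query)
  length(matching_ids(store, query, index, include_estimates))
}

#' Search the taxon or assembly index
#'
#' @param store a [taxatlas_store()].
#' @param query a query string or parsed `taxatlas_query`.
#' @param index `"taxon"` (one row per taxon) or `"assembly"` (one row per
#'   assembly).
#' @param include_estimates when `FALSE`, only direct and
#'   descendant-derived values can satisfy attribute filters and only those
#'   values appear as result fields; ancestor-derived estimates are
#'   ignored.
#' @param ranks optional rank labels added as ancestor-name columns.
#' @param fields attribute names to include as result columns (default:
#'   every attribute registered for the index, in name order).
#' @return a tibble, one row per matching document, ordered by id, with a
#'   value and provenance column per requested field. Attributes `query`
#'   and `options` carry the parsed query and evaluation options for
#'   [format_results()] and the report builders.
#' @export
search_docs <- function(store, query, index = "taxon",
                        include_estimates = TRUE, ranks = NULL,
                        fields = NULL) {
  if (is.character(query)) query <- parse_query(query)
  ids <- matching_ids(store, query, index, include_estimates)
  fields <- fields %||% sort(names(attr_defs_for(store, index)))

  if (index == "taxon") {
    res <- tibble(
      taxon_id = ids,
      rank = unname(store$rank[ids]),
      scientific_name = unname(store$sci_name[ids]))
  } else {
    owner <- assembly_taxon(store)[ids]
    res <- tibble(
      assembly_id = ids,
      taxon_id = unname(owner),
      scientific_name = unname(store$sci_name[unname(owner)]))
  }

  for (r in ranks) {
    anchor_tax <- if (index == "taxon") ids else res$taxon_id
    res[[r]] <- vapply(anchor_tax, function(tid) {
      anc <- c(tid, store$lineage[[tid]])
      at <- anc[store$rank[anc] == r]
      if (length(at)) store$sci_name[[at[1]]] else NA_character_
    }, "")
  }

  for (f in fields) {
    def <- store$attr_defs[[slot_key(index, f)]]
    if (is.null(def)) next
    slots <- slot_tbl(store, index, f)
    if (!include_estimates)
      slots <- slots[slots$provenance %in% c("direct", "descendant"), ]
    idx <- match(ids, slots$id)
    res[[f]] <- slot_display_value(slots, idx, def)
    res[[paste0(f, "_provenance")]] <- slots$provenance[idx]
  }
  attr(res, "query") <- query
  attr(res, "options") <- list(index = index,
                               include_estimates = include_estimates,
                               ranks = ranks, fields = fields)
  attr(res, "store") <- store
  class(res) <- c("taxatlas_results", class(res))
  res
}

# display value of slot rows (typed): numeric, date string, label, or
# ";"-joined list
slot_display_value <- function(slots, idx, def) {
  if (def$type == "list") {
    vapply(idx, function(i) {
      if (is.na(i)) NA_character_
      else paste(slots$value_list[[i]], collapse = ";")
    }, "")
  } else if (def$type == "date") {
    slots$value_chr[idx]
  } else if (is_numeric_type(def$type)) {
    slots$value_num[idx]
  } else {
    slots$value_chr[idx]
  }
}

#' Retrieve the full stored document for one taxon or assembly
#'
#' @param store a store; @param id a taxon or assembly identifier.
#' @return a list of class `taxatlas_record` with identifiers, names (or
#'   assembly identifiers), the full lineage, and one slot per attribute
#'   holding the raw values with sources, the direct summary (value,
#'   statistic, range, count) and/or the estimate (value, provenance,
#'   source taxon).
#' @export
get_record <- function(store, id) {
  stopifnot(inherits(store, "taxatlas_store"))
  if (taxon_exists(store, id)) {
    index <- "taxon"
    rec <- list(
      doc_type = "taxon", taxon_id = id,
      rank = unname(store$rank[[id]]),
      scientific_name = unname(store$sci_name[[id]]),
      names = select(
        store$names_tbl[store$names_tbl$taxon_id == id, ], -"name_lower"),
      lineage = taxon_lineage(store, id))
  } else if (assembly_exists(store, id)) {
    index <- "assembly"
    tid <- assembly_taxon(store)[[id]]
    rec <- list(
      doc_type = "assembly", assembly_id = id, taxon_id = tid,
      scientific_name = unname(store$sci_name[[tid]]),
      identifiers = select(
        store$assembly_identifiers[
          store$assembly_identifiers$assembly_id == id, ], -"id_lower"),
      lineage = taxon_lineage(store, tid))
  } else {
    stop_taxatlas(paste0("no taxon or assembly with id '", id, "'"),
                  "taxatlas_not_found")
  }

  attrs <- attr_defs_for(store, index)
  rec$attributes <- purrr::compact(purrr::imap(attrs, function(def, a) {
    raws <- raw_tbl(store, index, a)
    raws <- raws[raws$id == id, ]
    slots <- slot_tbl(store, index, a)
    slots <- slots[slots$id == id, ]
    if (!nrow(raws) && !nrow(slots)) return(NULL)
    out <- list(raw = select(raws, -"id"))
    for (i in seq_len(nrow(slots))) {
      row <- slots[i, ]
      v <- if (def$type == "list") slots$value_list[[i]]
           else slot_display_value(slots, i, def)
      if (row$provenance == "direct") {
        out$summary <- list(
          value = v, statistic = row$statistic,
          min = if (!is.na(row$min_label)) row$min_label else row$min,
          max = if (!is.na(row$max_label)) row$max_label else row$max,
          count = row$count)
      } else {
        out$estimate <- list(
          value = v, provenance = row$provenance,
          source_taxon_id = row$source_id)
      }
    }
    out
  }))
  structure(rec, class = "taxatlas_record")
}

#' @export
print.taxatlas_record <- function(x, ...) {
  cat("<taxatlas_record> ", x$doc_type, " ",
      x[[if (x$doc_type == "taxon") "taxon_id" else "assembly_id"]],
      " (", x$scientific_name, ")\n", sep = "")
  for (a in names(x$attributes)) {
    s <- x$attributes[[a]]
    if (!is.null(s$summary)) {
      cat("  ", a, ": ", format(s$summary$value), " [direct, ",
          s$summary$statistic, " of ", s$summary$count, "]\n", sep = "")
    } else if (!is.null(s$estimate)) {
      cat("  ", a, ": ", format(s$estimate$value), " [",
          s$estimate$provenance, " estimate from ",
          s$estimate$source_taxon_id, "]\n", sep = "")
    }
  }
  invisible(x)
}

#' Format search results as JSON, CSV or TSV
#'
#' Three layouts: `summary` is one row per document with one column per
#' requested field; `tidy` is one row per (document, attribute, value) with
#' provenance and source columns; `raw` is the tidy layout restricted to
#' directly measured raw values only.
#'
#' @param results a tibble from [search_docs()].
#' @param format `"tsv"`, `"csv"` or `"json"`.
#' @param mode `"summary"`, `"tidy"` or `"raw"`.
#' @return a single string of formatted text.
#' @export
format_results <- function(results, format = c("tsv", "csv", "json"),
                           mode = c("summary", "tidy", "raw")) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  tbl <- switch(mode,
    summary = as_tibble(results),
    tidy = tidy_values(results, raw_only = FALSE),
    raw = tidy_values(results, raw_only = TRUE))
  switch(format,
    json = as.character(jsonlite::toJSON(tbl, dataframe = "rows",
                                         na = "null", auto_unbox = TRUE,
                                         digits = NA)),
    csv = readr::format_csv(tbl),
    tsv = readr::format_tsv(tbl))
}

# long layout: one row per reported (or raw) value
tidy_values <- function(results, raw_only = FALSE) {
  store <- attr(results, "store")
  opts <- attr(results, "options")
  id_col <- if (opts$index == "taxon") "taxon_id" else "assembly_id"
  ids <- results[[id_col]]
  out <- list()
  for (f in opts$fields %||% character()) {
    def <- store$attr_defs[[slot_key(opts$index, f)]]
    if (is.null(def)) next
    if (raw_only) {
      raws <- raw_tbl(store, opts$index, f)
      raws <- raws[raws$id %in% ids, ]
      if (!nrow(raws)) next
      out[[f]] <- tibble(
        id = raws$id, attribute = f,
        value = as.character(
          ifelse(is.na(raws$value_chr), raws$value_num, raws$value_chr)),
        provenance = "direct", source = raws$source_name)
    } else {
      slots <- slot_tbl(store, opts$index, f)
      if (!isTRUE(opts$include_estimates))
        slots <- slots[slots$provenance %in% c("direct", "descendant"), ]
      slots <- slots[slots$id %in% ids, ]
      if (!nrow(slots)) next
      out[[f]] <- tibble(
        id = slots$id, attribute = f,
        value = vapply(seq_len(nrow(slots)), function(i)
          as.character(slot_display_value(slots, i, def)), ""),
        provenance = slots$provenance,
        source = slots$source_id)
    }
  }
  if (!length(out)) {
    return(tibble(id = character(), attribute = character(),
                  value = character(), provenance = character(),
                  source = character()))
  }
  res <- bind_rows(out)
  names(res)[1] <- "id"
  arrange(res, .data$id, .data$attribute)
}

#' @importFrom rlang .data
NULL
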