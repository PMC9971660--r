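# Structured aggregation reports over query results. Each builder returns a
# classed list with `report_type`, `queries` (the source query strings) and
# a type-specific payload; tidy() methods flatten payloads to tibbles and
# autoplot() methods draw the standard ggplot for each type. Payload totals
# always reconcile with count_docs() of the source queries.

new_report <- function(type, queries, payload, caption = NULL) {
  structure(
    list(report_type = type, queries = queries, payload = payload,
         caption = caption),
    class = c(paste0("taxatlas_report_", type), "taxatlas_report"))
}

#' @export
print.taxatlas_report <- function(x, ...) {
  cat("<taxatlas_report:", x$report_type, ">\n", sep = "")
  cat("  queries: ", paste(x$queries, collapse = " | "), "\n", sep = "")
  print(generics::tidy(x))
  invisible(x)
}

#' Per-rank result counts for a query
#'
#' Counts the matching documents at each requested taxonomic rank.
#'
#' @param store a [taxatlas_store()].
#' @param query a query string or parsed query.
#' @param ranks ordered rank labels; defaults to superkingdom through
#'   species.
#' @param include_estimates forwarded to query evaluation.
#' @return a `taxatlas_report` whose payload is a tibble `rank`, `count`.
#' @export
report_x_per_rank <- function(store, query,
                              ranks = DEFAULT_REPORT_RANKS,
                              include_estimates = TRUE) {
  if (is.character(query)) query <- parse_query(query)
  ids <- matching_ids(store, query, "taxon", include_estimates)
  rk <- store$rank[ids]
  payload <- tibble(
    rank = ranks,
    count = unname(vapply(ranks, function(r) sum(rk == r), 0L)))
  new_report("xPerRank", render_query(query), payload)
}

#' Subset ratio of one query within another
#'
#' Reports the size of query `x` as a subset of query `y` (e.g. species
#' with a chromosomal assembly as a fraction of all species in a clade).
#' The ratio is `NA` when `y` matches nothing.
#'
#' @param store a store; @param query_x,query_y query strings or parsed
#'   queries; @param index,include_estimates forwarded to evaluation.
#' @return a `taxatlas_report` with payload `x_count`, `y_count`, `ratio`.
#' @export
report_arc <- function(store, query_x, query_y, index = "taxon",
                       include_estimates = TRUE) {
  if (is.character(query_x)) query_x <- parse_query(query_x)
  if (is.character(query_y)) query_y <- parse_query(query_y)
  x <- count_docs(store, query_x, index, include_estimates)
  y <- count_docs(store, query_y, index, include_estimates)
  payload <- list(x_count = x, y_count = y,
                  ratio = if (y > 0) x / y else NA_real_)
  new_report("arc", c(render_query(query_x), render_query(query_y)),
             payload)
}

# snap breaks covering `x` with the requested width or bin count
histogram_breaks <- function(x, width = NULL, count = NULL) {
  if (!is.null(width)) {
    # bins anchor at the smallest value: [min, min+width), ...
    lo <- min(x)
    hi <- max(x)
    breaks <- seq(lo, hi + width, by = width)
  } else {
    count <- count %||% 10L
    lo <- min(x)
    hi <- max(x)
    if (lo == hi) hi <- lo + 1
    breaks <- seq(lo, hi, length.out = count + 1)
    breaks[length(breaks)] <- breaks[length(breaks)] +
      diff(range(breaks)) * 1e-9
  }
  breaks
}

#' Binned distribution of an attribute over a query result
#'
#' Documents matching the query contribute their reported value for
#' `attribute` to half-open bins `[lo, hi)`; documents without a value are
#' returned in an explicit `no_value` remainder so that bin sums plus the
#' remainder always equal the query's document count. An optional category
#' attribute stacks counts per category within each bin.
#'
#' @param store a store; @param query query string or parsed query.
#' @param attribute a numeric or date attribute to bin.
#' @param width,bins bin width in attribute units, or a bin count
#'   (width wins when both are given).
#' @param log10_scale bin on log10 of the values (bounds are reported on
#'   the original scale).
#' @param category optional keyword attribute to stack by.
#' @param index,include_estimates forwarded to evaluation.
#' @return a `taxatlas_report`; payload has `bins` (tibble `bin_lo`,
#'   `bin_hi`, optional `category`, `count`), `no_value`, `total`.
#' @export
report_histogram <- function(store, query, attribute, width = NULL,
                             bins = NULL, log10_scale = FALSE,
                             category = NULL, index = "taxon",
                             include_estimates = TRUE) {
  if (is.character(query)) query <- parse_query(query)
  def <- attr_def(store, attribute, index)
  if (!is_numeric_type(def$type)) stop_taxatlas(
    paste0("attribute '", attribute, "' is not binnable (type ", def$type,
           ")"), "taxatlas_query_error")
  ids <- matching_ids(store, query, index, include_estimates)
  slots <- slot_tbl(store, index, attribute)
  if (!include_estimates)
    slots <- slots[slots$provenance %in% c("direct", "descendant"), ]
  idx <- match(ids, slots$id)
  vals <- slots$value_num[idx]
  have <- !is.na(vals)

  cat_vals <- NULL
  if (!is.null(category)) {
    cdef <- attr_def(store, category, index)
    cslots <- slot_tbl(store, index, category)
    if (!include_estimates)
      cslots <- cslots[cslots$provenance %in% c("direct", "descendant"), ]
    cat_vals <- cslots$value_chr[match(ids, cslots$id)]
  }

  if (!any(have)) {
    payload <- list(
      bins = tibble(bin_lo = double(), bin_hi = double(), count = integer()),
      no_value = length(ids), total = length(ids))
    return(new_report("histogram", render_query(query), payload))
  }

  x <- vals[have]
  xb <- if (log10_scale) log10(x) else x
  breaks <- histogram_breaks(xb, width = width, count = bins)
  bin_idx <- findInterval(xb, breaks, rightmost.closed = FALSE,
                          left.open = FALSE)
  back <- function(b) if (log10_scale) 10^b else b
  mk <- tibble(
    bin = seq_len(length(breaks) - 1),
    bin_lo = back(breaks[-length(breaks)]),
    bin_hi = back(breaks[-1]))
  if (is.null(category)) {
    counts <- tibble(bin = bin_idx) |>
      dplyr::count(.data$bin, name = "count")
    bins_tbl <- left_join(mk, counts, by = "bin")
    bins_tbl$count <- as.integer(bins_tbl$count %||% 0L)
    bins_tbl$count[is.na(bins_tbl$count)] <- 0L
    bins_tbl <- select(bins_tbl, -"bin")
  } else {
    cf <- cat_vals[have]
    cf[is.na(cf)] <- "uncategorised"
    counts <- tibble(bin = bin_idx, category = cf) |>
      dplyr::count(.data$bin, .data$category, name = "count")
    bins_tbl <- tidyr::crossing(mk, category = unique(cf)) |>
      left_join(counts, by = c("bin", "category"))
    bins_tbl$count[is.na(bins_tbl$count)] <- 0L
    bins_tbl <- select(bins_tbl, -"bin")
  }
  payload <- list(bins = bins_tbl, no_value = sum(!have),
                  total = length(ids))
  new_report("histogram", render_query(query), payload)
}

#' Paired attribute values (or a heatmap) for a query result
#'
#' Documents with both attribute values present contribute one x/y point.
#' When the number of points exceeds `threshold`, a two-dimensional
#' histogram (heatmap cells whose counts sum to the point count) is
#' returned in place of the raw points.
#'
#' @param store a store; @param query query string or parsed query.
#' @param attr_x,attr_y numeric, date or ordered attributes.
#' @param threshold point count above which the report switches to heatmap
#'   cells; defaults to the store's `scatter_threshold` (10,000).
#' @param nbins number of heatmap bins per axis.
#' @param breaks_x,breaks_y optional explicit interior break points per
#'   axis (e.g. reference-standard thresholds); extended to cover the data
#'   range, overriding `nbins` and log scaling for that axis.
#' @param log10_x,log10_y bin the corresponding axis on a log10 scale.
#' @param category optional keyword attribute carried per point / cell
#'   stack.
#' @param index,include_estimates forwarded to evaluation.
#' @return a `taxatlas_report`; payload has `mode` ("points" or "heatmap"),
#'   `points` or `cells`, `n_points`, `no_value`, `total`.
#' @export
report_scatter <- function(store, query, attr_x, attr_y, threshold = NULL,
                           nbins = 20L, breaks_x = NULL, breaks_y = NULL,
                           log10_x = FALSE, log10_y = FALSE,
                           category = NULL, index = "taxon",
                           include_estimates = TRUE) {
  if (is.character(query)) query <- parse_query(query)
  threshold <- threshold %||% store$config$scatter_threshold
  for (a in c(attr_x, attr_y)) {
    def <- attr_def(store, a, index)
    if (!def$type %in% c("integer", "float", "date", "ordered_keyword"))
      stop_taxatlas(paste0("attribute '", a, "' cannot be plotted"),
                    "taxatlas_query_error")
  }
  ids <- matching_ids(store, query, index, include_estimates)
  grab <- function(a) {
    slots <- slot_tbl(store, index, a)
    if (!include_estimates)
      slots <- slots[slots$provenance %in% c("direct", "descendant"), ]
    slots$value_num[match(ids, slots$id)]
  }
  x <- grab(attr_x)
  y <- grab(attr_y)
  have <- !is.na(x) & !is.na(y)
  cat_vals <- NULL
  if (!is.null(category)) {
    cslots <- slot_tbl(store, index, category)
    cat_vals <- cslots$value_chr[match(ids, cslots$id)]
    cat_vals[is.na(cat_vals)] <- "uncategorised"
  }
  pts <- tibble(id = ids[have], x = x[have], y = y[have])
  if (!is.null(category)) pts$category <- cat_vals[have]

  if (nrow(pts) <= threshold) {
    payload <- list(mode = "points", points = pts, n_points = nrow(pts),
                    no_value = sum(!have), total = length(ids))
  } else {
    if (!is.null(breaks_x)) log10_x <- FALSE
    if (!is.null(breaks_y)) log10_y <- FALSE
    tx <- if (log10_x) log10(pts$x) else pts$x
    ty <- if (log10_y) log10(pts$y) else pts$y
    with_user <- function(v, user) {
      lo <- min(v); hi <- max(v) + (max(v) - min(v) + 1) * 1e-9
      sort(unique(c(lo, user[user > lo & user < hi], hi)))
    }
    bx <- if (is.null(breaks_x)) histogram_breaks(tx, count = nbins)
          else with_user(tx, breaks_x)
    by <- if (is.null(breaks_y)) histogram_breaks(ty, count = nbins)
          else with_user(ty, breaks_y)
    ix <- findInterval(tx, bx, rightmost.closed = FALSE)
    iy <- findInterval(ty, by, rightmost.closed = FALSE)
    backx <- function(b) if (log10_x) 10^b else b
    backy <- function(b) if (log10_y) 10^b else b
    grp <- if (is.null(category)) tibble(ix = ix, iy = iy)
           else tibble(ix = ix, iy = iy, category = pts$category)
    cells <- dplyr::count(grp, dplyr::across(dplyr::everything()),
                          name = "count")
    cells$x_lo <- backx(bx[cells$ix])
    cells$x_hi <- backx(bx[cells$ix + 1])
    cells$y_lo <- backy(by[cells$iy])
    cells$y_hi <- backy(by[cells$iy + 1])
    cells <- select(cells, -"ix", -"iy")
    payload <- list(mode = "heatmap", cells = cells, n_points = nrow(pts),
                    no_value = sum(!have), total = length(ids))
  }
  new_report("scatter", render_query(query), payload)
}

#' Annotated minimal spanning subtree of a query result
#'
#' Builds the union of the lineage paths of all matched taxa, truncated at
#' their most recent common ancestor. Every node carries the number of
#' matched taxa in its subtree and, when `attribute` is given, the
#' reported value and its traffic-light provenance class for display.
#'
#' @param store a store; @param query query string or parsed query (taxon
#'   index only: trees are taxon-level).
#' @param attribute optional attribute to annotate nodes with.
#' @param include_estimates forwarded to evaluation and annotation.
#' @return a `taxatlas_report`; payload has `nodes` (tibble `taxon_id`,
#'   `parent_id` within the subtree, `scientific_name`, `rank`, `matched`,
#'   `n_matched`, optional `value`, `provenance`) and `root` (the MRCA id).
#' @export
report_tree <- function(store, query, attribute = NULL,
                        include_estimates = TRUE) {
  if (is.character(query)) query <- parse_query(query)
  ids <- matching_ids(store, query, "taxon", include_estimates)
  if (!length(ids)) stop_taxatlas(
    "tree report needs a query matching at least one taxon",
    "taxatlas_query_error")

  paths <- lapply(ids, function(id) c(id, store$lineage[[id]]))
  common <- Reduce(intersect, paths)
  # deepest common ancestor (largest lineage) is the MRCA
  mrca <- common[which.max(lengths(store$lineage[common]))]
  node_set <- unique(unlist(lapply(paths, function(p) {
    p[seq_len(which(p == mrca))]
  })))

  in_set <- setNames(rep(TRUE, length(node_set)), node_set)
  parent_in <- vapply(node_set, function(id) {
    if (id == mrca) return(NA_character_)
    p <- store$parent[[id]]
    while (!is.na(p) && is.na(in_set[p])) p <- store$parent[[p]]
    p
  }, "")

  # matched taxa per subtree: count self, then push up to the MRCA
  n_matched <- setNames(rep(0L, length(node_set)), node_set)
  for (id in ids) {
    p <- id
    while (!is.na(p)) {
      n_matched[p] <- n_matched[p] + 1L
      if (p == mrca) break
      p <- parent_in[[p]]
    }
  }

  nodes <- tibble(
    taxon_id = node_set,
    parent_id = unname(parent_in),
    scientific_name = unname(store$sci_name[node_set]),
    rank = unname(store$rank[node_set]),
    matched = node_set %in% ids,
    n_matched = unname(n_matched[node_set]))

  if (!is.null(attribute)) {
    def <- attr_def(store, attribute, "taxon")
    slots <- slot_tbl(store, "taxon", attribute)
    if (!include_estimates)
      slots <- slots[slots$provenance %in% c("direct", "descendant"), ]
    idx <- match(node_set, slots$id)
    nodes$value <- slot_display_value(slots, idx, def)
    nodes$provenance <- slots$provenance[idx]
  }

  new_report("tree", render_query(query),
             list(nodes = nodes, root = mrca, attribute = attribute))
}

# ---------------------------------------------------------------------------
# tree exports

# Newick-quote a label: spaces become underscores; anything still outside
# the unquoted alphabet is single-quoted (internal quotes doubled)
newick_label <- function(x) {
  x <- gsub(" ", "_", x)
  ok <- grepl("^[A-Za-z0-9_.|/-]+$", x)
  ifelse(ok, x, paste0("'", gsub("'", "''", x), "'"))
}

#' Export a tree report as a Newick string
#'
#' Labels are scientific names (spaces as underscores, other problem
#' characters quoted); the backbone taxonomy has no branch lengths so none
#' are written.
#'
#' @param report a tree report from [report_tree()].
#' @return a Newick string terminated with `;`.
#' @export
export_newick <- function(report) {
  stopifnot(inherits(report, "taxatlas_report_tree"))
  nodes <- report$payload$nodes
  kids <- split(nodes$taxon_id, nodes$parent_id)
  label <- setNames(newick_label(nodes$scientific_name), nodes$taxon_id)
  build <- function(id) {
    ch <- kids[[id]]
    if (is.null(ch) || !length(ch)) return(label[[id]])
    paste0("(", paste(vapply(sort(ch), build, ""), collapse = ","), ")",
           label[[id]])
  }
  paste0(build(report$payload$root), ";")
}

#' Export a tree report as PhyloXML
#'
#' Clade names carry the scientific names; per-node annotations (matched
#' descendant count, attribute value, provenance class) are written as
#' `property` elements.
#'
#' @param report a tree report from [report_tree()].
#' @return an `xml_document` (serialise with `as.character()` or
#'   [xml2::write_xml()]).
#' @export
export_phyloxml <- function(report) {
  stopifnot(inherits(report, "taxatlas_report_tree"))
  nodes <- report$payload$nodes
  kids <- split(nodes$taxon_id, nodes$parent_id)
  row_of <- setNames(seq_len(nrow(nodes)), nodes$taxon_id)
  doc <- xml2::xml_new_root(
    "phyloxml", xmlns = "http://www.phyloxml.org")
  phy <- xml2::xml_add_child(doc, "phylogeny", rooted = "true")
  add_clade <- function(parent_node, id) {
    r <- nodes[row_of[[id]], ]
    cl <- xml2::xml_add_child(parent_node, "clade")
    xml2::xml_add_child(cl, "name", r$scientific_name)
    prop <- function(ref, value) {
      if (is.na(value)) return()
      p <- xml2::xml_add_child(cl, "property", as.character(value))
      xml2::xml_set_attr(p, "ref", ref)
      xml2::xml_set_attr(p, "applies_to", "clade")
      xml2::xml_set_attr(p, "datatype", "xsd:string")
    }
    prop("taxatlas:taxon_id", r$taxon_id)
    prop("taxatlas:rank", r$rank)
    prop("taxatlas:n_matched", r$n_matched)
    if ("value" %in% names(r)) prop("taxatlas:value", r$value)
    if ("provenance" %in% names(r)) prop("taxatlas:provenance", r$provenance)
    for (ch in sort(kids[[id]] %||% character())) add_clade(cl, ch)
  }
  add_clade(phy, report$payload$root)
  doc
}
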