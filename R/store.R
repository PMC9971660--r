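#' Create an empty taxatlas store
#'
#' A store is a mutable handle (an environment, analogous to a database
#' connection) holding the backbone taxonomy, the taxon and assembly
#' document collections, the attribute registry, raw imported values and
#' summarised/estimated values. All indexing and filling verbs modify the
#' store in place; all query verbs return tibbles.
#'
#' @param config optional named list of defaults overriding
#'   `empty_markers` (cell contents treated as missing on import),
#'   `pg_to_bp` (picogram to base-pair conversion constant) and
#'   `scatter_threshold` (point count above which scatter reports switch
#'   to a heatmap).
#' @return an object of class `taxatlas_store`.
#' @export
taxatlas_store <- function(config = list()) {
  store <- new.env(parent = emptyenv())
  store$parent <- character()     # named: taxon_id -> parent taxon_id (NA for root)
  store$rank <- character()       # named: taxon_id -> rank
  store$sci_name <- character()   # named: taxon_id -> scientific name
  store$children <- list()        # named: taxon_id -> character vector of child ids
  store$lineage <- list()         # named: taxon_id -> ancestor ids, parent..root
  store$root_id <- NA_character_
  store$names_tbl <- tibble(
    taxon_id = character(), name = character(),
    name_class = character(), name_lower = character()
  )
  store$assemblies <- tibble(assembly_id = character(), taxon_id = character())
  store$assembly_identifiers <- tibble(
    assembly_id = character(), id = character(),
    class = character(), id_lower = character()
  )
  store$attr_defs <- list()
  store$raws <- new.env(parent = emptyenv())   # "index.attribute" -> tibble
  store$slots <- new.env(parent = emptyenv())  # "index.attribute" -> tibble
  store$insert_counter <- 0L
  store$config <- utils::modifyList(
    list(
      empty_markers = DEFAULT_EMPTY_MARKERS,
      pg_to_bp = DEFAULT_PG_TO_BP,
      scatter_threshold = 10000L
    ),
    config
  )
  class(store) <- c("taxatlas_store", "environment")
  store
}

#' @export
print.taxatlas_store <- function(x, ...) {
  cat("<taxatlas_store>\n")
  cat("  taxa:       ", length(x$parent), "\n")
  cat("  assemblies: ", nrow(x$assemblies), "\n")
  cat("  attributes: ", length(x$attr_defs),
      paste0("(", paste(sort(vapply(x$attr_defs, `[[`, "", "name")),
                        collapse = ", "), ")"), "\n")
  invisible(x)
}

n_taxa <- function(store) length(store$parent)

taxon_exists <- function(store, id) id %in% names(store$parent)

# ---------------------------------------------------------------------------
# taxdump parsing

read_dmp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  # classic dialect: fields separated by "\t|\t", row terminated by "\t|";
  # fallback: plain TSV
  if (any(grepl("\t\\|", lines[seq_len(min(5, length(lines)))]))) {
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  } else {
    strsplit(lines, "\t")
  }
}

#' Load an NCBI-style taxdump into a store
#'
#' Reads `nodes.dmp` (taxon id, parent id, rank) and `names.dmp` (taxon id,
#' name, name class) in the classic `"\t|\t"`-delimited dialect (plain TSV is
#' accepted as a fallback), builds one taxon document per node and indexes
#' the full ancestral lineage of every node by walking parent pointers from
#' the single root (the node that is its own parent).
#'
#' @param store a [taxatlas_store()].
#' @param taxdump_dir directory containing `nodes.dmp` and `names.dmp`, or
#'   `NULL` if `nodes_path`/`names_path` are given directly.
#' @param nodes_path,names_path explicit file paths (override `taxdump_dir`).
#' @return the store, invisibly. Errors on duplicate taxon ids, parent ids
#'   that reference no node, or cycles in the parent pointers.
#' @export
load_taxdump <- function(store, taxdump_dir = NULL, nodes_path = NULL,
                         names_path = NULL) {
  stopifnot(inherits(store, "taxatlas_store"))
  nodes_path <- nodes_path %||% file.path(taxdump_dir, "nodes.dmp")
  names_path <- names_path %||% file.path(taxdump_dir, "names.dmp")
  if (!file.exists(nodes_path)) stop_taxatlas(
    paste0("nodes file not found: ", nodes_path), "taxatlas_io_error")
  if (!file.exists(names_path)) stop_taxatlas(
    paste0("names file not found: ", names_path), "taxatlas_io_error")

  rows <- read_dmp(nodes_path)
  ids <- vapply(rows, `[[`, "", 1)
  parents <- vapply(rows, `[[`, "", 2)
  ranks <- vapply(rows, function(r) if (length(r) >= 3) r[[3]] else "no rank", "")

  dup <- ids[duplicated(ids)]
  if (length(dup)) stop_taxatlas(
    paste0("duplicate taxon_id in nodes file: ",
           paste(unique(dup), collapse = ", ")),
    "taxatlas_taxdump_error")

  root <- ids[ids == parents]
  if (length(root) != 1) stop_taxatlas(
    paste0("expected exactly one root (parent == self), found ",
           length(root)),
    "taxatlas_taxdump_error")

  dangling <- setdiff(parents, ids)
  if (length(dangling)) stop_taxatlas(
    paste0("parent_id references undefined node(s): ",
           paste(dangling, collapse = ", ")),
    "taxatlas_taxdump_error")

  parent_vec <- setNames(parents, ids)
  parent_vec[root] <- NA_character_

  # children map
  kids <- split(ids[!is.na(parent_vec)], parent_vec[!is.na(parent_vec)])
  children <- setNames(vector("list", length(ids)), ids)
  children[names(kids)] <- kids

  # build lineages in BFS order from root; unreached nodes imply a cycle
  lineage <- setNames(vector("list", length(ids)), ids)
  lineage[[root]] <- character()
  queue <- root
  seen <- 0L
  while (length(queue)) {
    nxt <- character()
    for (id in queue) {
      seen <- seen + 1L
      ch <- children[[id]]
      if (length(ch)) {
        for (c_id in ch) lineage[[c_id]] <- c(id, lineage[[id]])
        nxt <- c(nxt, ch)
      }
    }
    queue <- nxt
  }
  if (seen < length(ids)) {
    stranded <- ids[vapply(lineage, is.null, TRUE) & ids != root]
    # walk one stranded node to name the cycle
    cyc <- character()
    cur <- stranded[1]
    while (!(cur %in% cyc)) {
      cyc <- c(cyc, cur)
      cur <- parent_vec[[cur]]
    }
    cyc <- cyc[which(cyc == cur):length(cyc)]
    stop_taxatlas(
      paste0("cycle in parent pointers: ",
             paste(c(cyc, cur), collapse = " -> ")),
      "taxatlas_taxdump_error")
  }

  nrows <- read_dmp(names_path)
  nm_tbl <- tibble(
    taxon_id = vapply(nrows, `[[`, "", 1),
    name = vapply(nrows, `[[`, "", 2),
    name_class = vapply(nrows, function(r) {
      if (length(r) >= 4) r[[4]] else "scientific name"
    }, "")
  )
  nm_tbl$name_lower <- tolower(nm_tbl$name)
  unknown <- setdiff(nm_tbl$taxon_id, ids)
  if (length(unknown)) stop_taxatlas(
    paste0("names file references undefined taxon_id(s): ",
           paste(head(unknown, 5), collapse = ", ")),
    "taxatlas_taxdump_error")

  sci <- nm_tbl[nm_tbl$name_class == "scientific name", ]
  sci_vec <- setNames(rep(NA_character_, length(ids)), ids)
  sci_vec[sci$taxon_id] <- sci$name
  missing_sci <- ids[is.na(sci_vec)]
  if (length(missing_sci)) {
    sci_vec[missing_sci] <- missing_sci
    nm_tbl <- bind_rows(nm_tbl, tibble(
      taxon_id = missing_sci, name = missing_sci,
      name_class = "scientific name", name_lower = tolower(missing_sci)
    ))
  }

  store$parent <- parent_vec
  store$rank <- setNames(ranks, ids)
  store$sci_name <- sci_vec
  store$children <- lapply(children, function(x) x %||% character())
  store$lineage <- lineage
  store$root_id <- root
  store$names_tbl <- nm_tbl
  sci_all <- nm_tbl[nm_tbl$name_class == "scientific name", ]
  store$sci_index <- split(sci_all$taxon_id, sci_all$name_lower)
  invisible(store)
}

# iterative parent walk; independent of the cached lineage (used by tests
# through taxatlas:::walk_lineage as well as by insert_taxon)
walk_lineage <- function(store, id) {
  out <- character()
  cur <- store$parent[[id]]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- store$parent[[cur]]
  }
  out
}

#' Lineage of a taxon as a tibble of ancestor references
#'
#' @param store a store; @param taxon_id focal taxon.
#' @return tibble with `taxon_id`, `rank`, `scientific_name`, `depth`
#'   (edges from the focal taxon), ordered from the immediate parent to the
#'   root.
#' @export
taxon_lineage <- function(store, taxon_id) {
  if (!taxon_exists(store, taxon_id)) stop_taxatlas(
    paste0("unknown taxon_id: ", taxon_id), "taxatlas_not_found")
  anc <- store$lineage[[taxon_id]]
  tibble(
    taxon_id = anc,
    rank = unname(store$rank[anc]),
    scientific_name = unname(store$sci_name[anc]),
    depth = seq_along(anc)
  )
}

# all descendant ids (self excluded) by child-pointer traversal
descendant_ids <- function(store, id) {
  out <- character()
  queue <- store$children[[id]] %||% character()
  while (length(queue)) {
    out <- c(out, queue)
    queue <- unlist(store$children[queue], use.names = FALSE)
  }
  out
}

# ---------------------------------------------------------------------------
# off-backbone insertion

resolve_name_at_rank <- function(store, name, rank) {
  hits <- store$sci_index[[tolower(name)]] %||% character()
  unique(hits[store$rank[hits] == rank])
}

#' Insert an off-backbone taxon anchored at an existing node
#'
#' Taxa absent from the backbone taxonomy (for example newly described
#' species on a project target list) are inserted as children of the most
#' specific resolvable anchor: the anchor mapping gives candidate parent
#' names by rank (e.g. `list(genus = "Drosophila", family = "Drosophilidae")`)
#' and the tip-most rank whose name resolves to exactly one backbone taxon
#' wins. Inserted taxa receive identifiers in a reserved `local:` namespace,
#' assigned sequentially, so backbone ids are never shadowed and reruns over
#' identical input order reproduce identical ids.
#'
#' @param store a store.
#' @param name scientific name of the new taxon.
#' @param rank rank label for the new taxon.
#' @param anchor named list/character vector, rank label -> taxon name.
#' @return the new taxon_id (character). Errors of class
#'   `taxatlas_anchor_error` when no anchor resolves or the most specific
#'   anchor name is ambiguous at its rank.
#' @export
insert_taxon <- function(store, name, rank, anchor) {
  stopifnot(inherits(store, "taxatlas_store"))
  anchor <- unlist(anchor)
  if (!length(anchor)) stop_taxatlas("empty anchor", "taxatlas_anchor_error")
  ord <- order(-rank_position(names(anchor)))   # most specific (tip-most) first
  parent_id <- NULL
  for (i in ord) {
    r <- names(anchor)[i]
    hits <- resolve_name_at_rank(store, anchor[[i]], r)
    if (length(hits) == 1) { parent_id <- hits; break }
    if (length(hits) > 1) stop_taxatlas(
      paste0("anchor name '", anchor[[i]], "' is ambiguous at rank ", r),
      "taxatlas_anchor_error")
  }
  if (is.null(parent_id)) stop_taxatlas(
    paste0("no anchor resolves: ",
           paste(names(anchor), anchor, sep = "=", collapse = ", ")),
    "taxatlas_anchor_error")

  store$insert_counter <- store$insert_counter + 1L
  new_id <- paste0("local:", store$insert_counter)
  store$parent[new_id] <- parent_id
  store$rank[new_id] <- rank
  store$sci_name[new_id] <- name
  store$children[[parent_id]] <- c(store$children[[parent_id]], new_id)
  store$children[[new_id]] <- character()
  store$lineage[[new_id]] <- c(parent_id, store$lineage[[parent_id]])
  store$names_tbl <- bind_rows(store$names_tbl, tibble(
    taxon_id = new_id, name = name, name_class = "scientific name",
    name_lower = tolower(name)
  ))
  nl <- tolower(name)
  store$sci_index[[nl]] <- c(store$sci_index[[nl]], new_id)
  new_id
}

# ---------------------------------------------------------------------------
# assemblies

add_assembly <- function(store, assembly_id, taxon_id, identifiers = NULL) {
  if (!taxon_exists(store, taxon_id)) stop_taxatlas(
    paste0("assembly ", assembly_id, " references unknown taxon ", taxon_id),
    "taxatlas_not_found")
  if (!assembly_id %in% store$assemblies$assembly_id) {
    store$assemblies <- bind_rows(
      store$assemblies, tibble(assembly_id = assembly_id, taxon_id = taxon_id))
  }
  ids <- tibble(
    assembly_id = assembly_id,
    id = c(assembly_id, identifiers %||% character()),
    class = c("accession", rep("alias", length(identifiers %||% character())))
  )
  ids$id_lower <- tolower(ids$id)
  store$assembly_identifiers <- distinct(
    bind_rows(store$assembly_identifiers, ids))
  invisible(store)
}

assembly_exists <- function(store, id) id %in% store$assemblies$assembly_id

# owning taxon of every assembly id (named vector)
assembly_taxon <- function(store) {
  setNames(store$assemblies$taxon_id, store$assemblies$assembly_id)
}
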