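#' Parse a YAML import specification
#'
#' An import spec pairs a delimited data file with everything needed to load
#' it: which columns fill which attributes (with optional value transforms
#' and label translations), which columns identify the taxon (a verbatim
#' taxon id, or a scientific name plus higher ranks for homonym
#' disambiguation), matching options, and source metadata. Attributes may
#' be declared inline (type, constraints, summary and traverse rules); an
#' inline declaration that conflicts with an existing registry entry is a
#' hard error rather than a silent merge.
#'
#' Spec layout (YAML):
#' ```yaml
#' file: {name: cvalues.tsv, delimiter: "\t"}
#' attributes:
#'   genome_size:
#'     header: c_value
#'     type: float
#'     units: bp
#'     summary: [median]
#'     traverse: {direction: both}
#'     transform: {multiply: 978000000}
#' taxonomy:
#'   scientific_name: species
#'   family: family
#' options: {allow_synonyms: true, create_missing_taxa: false}
#' source: {name: cvaldb, url: "https://example.org", date: 2020-11-30}
#' ```
#'
#' @param store a [taxatlas_store()]; inline attribute declarations are
#'   registered into its attribute registry.
#' @param yaml_path path to the YAML spec. The data file path is resolved
#'   relative to the YAML file's directory.
#' @return a list of class `taxatlas_import_spec`.
#' @export
parse_import_spec <- function(store, yaml_path) {
  stopifnot(inherits(store, "taxatlas_store"))
  raw <- yaml::read_yaml(yaml_path)
  if (is.null(raw$file) || is.null(raw$file$name)) stop_taxatlas(
    paste0("import spec ", yaml_path, " is missing the file.name field"),
    "taxatlas_config_error")
  index <- raw$options$index %||% "taxon"
  if (!length(raw$attributes)) stop_taxatlas(
    paste0("import spec ", yaml_path, " declares no attributes"),
    "taxatlas_config_error")

  attr_cols <- purrr::imap(raw$attributes, function(a, name) {
    if (is.null(a$header)) stop_taxatlas(
      paste0("attribute '", name, "' in ", yaml_path, " has no header"),
      "taxatlas_config_error")
    a_index <- a$index %||% index
    inline <- !is.null(a$type)
    if (!inline &&
        is.null(store$attr_defs[[slot_key(a_index, name)]])) stop_taxatlas(
      paste0("attribute '", name, "' is neither declared inline nor in the ",
             "registry"), "taxatlas_config_error")
    if (inline) {
      define_attribute(
        store, name, index = a$index %||% index, type = a$type,
        constraints = a$constraints %||% list(),
        summary = unlist(a$summary),
        traverse = a$traverse %||% list(direction = "none"),
        units = a$units, display_group = a$display_group,
        source_priority = unlist(a$source_priority)
      )
    }
    if (!is.null(a$transform)) validate_transform(a$transform, name)
    list(attribute = name, index = a_index, header = a$header,
         transform = a$transform, translate = a$translate)
  })

  taxo <- raw$taxonomy %||% list()
  if (index == "taxon" &&
      is.null(taxo$taxon_id) &&
      (is.null(taxo$scientific_name) ||
       !length(setdiff(names(taxo), c("taxon_id", "scientific_name"))))) {
    stop_taxatlas(paste0(
      "import spec ", yaml_path, " needs taxonomy.taxon_id or ",
      "taxonomy.scientific_name plus at least one higher rank column"),
      "taxatlas_config_error")
  }
  if (index == "assembly" && is.null(raw$assembly$assembly_id)) stop_taxatlas(
    paste0("assembly import spec ", yaml_path,
           " needs assembly.assembly_id"), "taxatlas_config_error")

  spec <- list(
    path = file.path(dirname(yaml_path), raw$file$name),
    delimiter = raw$file$delimiter %||% "\t",
    index = index,
    attribute_columns = attr_cols,
    taxonomy_columns = taxo,
    assembly_columns = raw$assembly %||% list(),
    options = utils::modifyList(
      list(allow_fuzzy = FALSE, allow_synonyms = FALSE,
           create_missing_taxa = FALSE),
      raw$options %||% list()),
    source = utils::modifyList(
      list(name = "unspecified", url = NA_character_,
           date = format(Sys.Date(), "%Y-%m-%d")),
      lapply(raw$source %||% list(), as.character))
  )
  structure(spec, class = "taxatlas_import_spec")
}

SUPPORTED_TRANSFORMS <- c("multiply", "add", "template", "lowercase",
                          "uppercase", "date")

validate_transform <- function(tf, attr_name) {
  kind <- intersect(names(tf) %||% as.character(tf), SUPPORTED_TRANSFORMS)
  if (is.character(tf) && length(tf) == 1 && tf %in% SUPPORTED_TRANSFORMS)
    return(invisible(tf))
  if (!length(kind)) stop_taxatlas(
    paste0("unknown transform for attribute '", attr_name, "': ",
           paste(names(tf) %||% tf, collapse = ", ")),
    "taxatlas_config_error")
  invisible(kind)
}

#' Apply a declarative value transform
#'
#' Transforms run before type coercion and constraint checks. Supported
#' forms: `list(multiply = k)`, `list(add = k)` (arithmetic on numeric
#' input), `list(template = "{colA}-{colB}")` (string join over the row's
#' columns), `"lowercase"`, `"uppercase"`, and `"date"` (normalise to ISO
#' `YYYY-MM-DD`). The canonical use is unit conversion, e.g. C-values in
#' picograms times `0.978e9` to obtain genome size in base pairs.
#'
#' @param value the raw cell value.
#' @param spec transform spec (a string naming a parameter-free transform or
#'   a single-entry named list).
#' @param row optional named list/one-row data frame for template joins.
#' @return the transformed value. Non-numeric input to an arithmetic
#'   transform aborts with class `taxatlas_type_error` (row-level, caught
#'   during import and routed to the exceptions file).
#' @export
apply_transform <- function(value, spec, row = NULL) {
  if (is.null(spec)) return(value)
  if (is.character(spec) && length(spec) == 1) {
    return(switch(spec,
      lowercase = tolower(value),
      uppercase = toupper(value),
      date = {
        d <- suppressWarnings(as.Date(as.character(value)))
        if (is.na(d)) stop_taxatlas(
          paste0("unparseable date '", value, "'"), "taxatlas_type_error")
        format(d, "%Y-%m-%d")
      },
      stop_taxatlas(paste0("unknown transform '", spec, "'"),
                    "taxatlas_config_error")))
  }
  kind <- names(spec)[1]
  arg <- spec[[1]]
  switch(kind,
    multiply = ,
    add = {
      num <- suppressWarnings(as.numeric(value))
      if (is.na(num)) stop_taxatlas(
        paste0("non-numeric value '", value, "' for arithmetic transform"),
        "taxatlas_type_error")
      if (kind == "multiply") num * as.numeric(arg) else num + as.numeric(arg)
    },
    template = {
      out <- arg
      for (col in names(row)) {
        out <- gsub(paste0("{", col, "}"), as.character(row[[col]]),
                    out, fixed = TRUE)
      }
      out
    },
    lowercase = tolower(value),
    uppercase = toupper(value),
    date = apply_transform(value, "date"),
    stop_taxatlas(paste0("unknown transform '", kind, "'"),
                  "taxatlas_config_error"))
}

# ---------------------------------------------------------------------------
# taxon matching

#' Match one data row to a backbone taxon
#'
#' Tiers, in priority order: (1) a verbatim taxon id; (2) a unique
#' scientific-name match; (3) a name match disambiguated by higher-rank
#' columns (homonym resolution); (4) a synonym match, if allowed; (5) a
#' fuzzy match within edit distance 2, if allowed; (6) insertion of a new
#' taxon anchored at the most specific resolvable higher rank, if
#' `create_missing_taxa` is set. Tiers 3-5 are flagged `inferred` so they
#' can be logged for manual review.
#'
#' @param store a store.
#' @param row one-row data frame (or named list) of the input table.
#' @param taxonomy_columns mapping from taxonomy roles to column headers
#'   (`taxon_id`, `scientific_name`, and/or rank labels).
#' @param options list with `allow_synonyms`, `allow_fuzzy`,
#'   `create_missing_taxa`.
#' @return list with `taxon_id` (NA on failure), `tier`, `inferred`
#'   (logical) and `reason` (non-NA only on failure).
#' @export
match_row_to_taxon <- function(store, row, taxonomy_columns,
                               options = list()) {
  res <- function(id, tier, inferred = FALSE, reason = NA_character_) {
    list(taxon_id = id, tier = tier, inferred = inferred, reason = reason)
  }
  getcol <- function(role) {
    col <- taxonomy_columns[[role]]
    if (is.null(col) || !col %in% names(row)) return(NA_character_)
    v <- as.character(row[[col]])
    if (is_missing_cell(v, store$config$empty_markers)) NA_character_ else v
  }

  tid <- getcol("taxon_id")
  if (!is.na(tid)) {
    if (taxon_exists(store, tid)) return(res(tid, "taxon_id"))
    return(res(NA_character_, "taxon_id", reason = "no-taxon-match"))
  }

  name <- getcol("scientific_name")
  if (is.na(name)) return(res(NA_character_, "none", reason = "no-taxon-match"))
  nl <- tolower(name)
  hits <- unique(store$sci_index[[nl]] %||% character())

  if (length(hits) == 1) return(res(hits, "scientific_name"))

  rank_cols <- setdiff(names(taxonomy_columns),
                       c("taxon_id", "scientific_name"))
  if (length(hits) > 1) {
    # homonym: disambiguate by higher-rank columns against each lineage
    constraints <- purrr::compact(lapply(
      setNames(rank_cols, rank_cols), function(r) {
        v <- getcol(r)
        if (is.na(v)) NULL else tolower(v)
      }))
    if (length(constraints)) {
      ok <- vapply(hits, function(id) {
        anc <- store$lineage[[id]]
        all(vapply(names(constraints), function(r) {
          at_rank <- anc[store$rank[anc] == r]
          length(at_rank) > 0 &&
            any(tolower(store$sci_name[at_rank]) == constraints[[r]])
        }, TRUE))
      }, TRUE)
      if (sum(ok) == 1) return(res(hits[ok], "higher_rank", inferred = TRUE))
    }
    return(res(NA_character_, "none", reason = "ambiguous-match"))
  }

  if (isTRUE(options$allow_synonyms)) {
    syn <- store$names_tbl[store$names_tbl$name_class != "scientific name" &
                             store$names_tbl$name_lower == nl, ]
    syn_hits <- unique(syn$taxon_id)
    if (length(syn_hits) == 1)
      return(res(syn_hits, "synonym", inferred = TRUE))
    if (length(syn_hits) > 1)
      return(res(NA_character_, "none", reason = "ambiguous-match"))
  }

  if (isTRUE(options$allow_fuzzy)) {
    sci <- store$names_tbl[store$names_tbl$name_class == "scientific name", ]
    d <- drop(adist(nl, sci$name_lower))
    fz <- unique(sci$taxon_id[d <= 2 & d == min(d)])
    if (length(fz) == 1 && min(d) <= 2)
      return(res(fz, "fuzzy", inferred = TRUE))
    if (length(fz) > 1)
      return(res(NA_character_, "none", reason = "ambiguous-match"))
  }

  if (isTRUE(options$create_missing_taxa) && length(rank_cols)) {
    anchor <- purrr::compact(lapply(
      setNames(rank_cols, rank_cols), function(r) {
        v <- getcol(r)
        if (is.na(v)) NULL else v
      }))
    if (length(anchor)) {
      id <- tryCatch(
        insert_taxon(store, name, rank = "species", anchor = anchor),
        taxatlas_anchor_error = function(e) NA_character_)
      if (!is.na(id)) return(res(id, "inserted"))
    }
  }
  res(NA_character_, "none", reason = "no-taxon-match")
}

# ---------------------------------------------------------------------------
# file indexing

#' Import one data file under its YAML specification
#'
#' Each row is matched to a taxon (or assembly), every non-empty attribute
#' cell is translated, transformed, type-checked and appended as a raw
#' value, and direct summaries are recomputed for the touched attributes.
#' Re-importing the identical file is idempotent: a raw value is only
#' appended when no value with the same (document, attribute, value,
#' source) key exists. A bad cell voids only that cell; rows that cannot be
#' matched to a taxon, and cells failing type or constraint checks, are
#' collected as exception records.
#'
#' @param store a store.
#' @param spec a `taxatlas_import_spec` (from [parse_import_spec()]), or a
#'   path to a YAML spec.
#' @return list with counts `indexed`, `inferred`, `exceptions` plus the
#'   tibbles `exceptions_tbl` (input row columns, then `reason`) and
#'   `inferred_tbl` (review log of tier 3-5 matches).
#' @export
index_file <- function(store, spec) {
  if (is.character(spec)) spec <- parse_import_spec(store, spec)
  stopifnot(inherits(spec, "taxatlas_import_spec"))
  if (!file.exists(spec$path)) stop_taxatlas(
    paste0("data file not found: ", spec$path), "taxatlas_io_error")

  tbl <- readr::read_delim(
    spec$path, delim = spec$delimiter, col_types = readr::cols(
      .default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE)

  markers <- store$config$empty_markers
  exceptions <- list()
  inferred <- list()
  n_indexed <- 0L

  add_exception <- function(row, reason) {
    exceptions[[length(exceptions) + 1L]] <<-
      c(lapply(row, as.character), list(reason = reason))
  }

  # duplicate-detection keys (doc, attribute, value, source) for
  # idempotent re-imports, held in a hashed environment
  seen_keys <- new.env(parent = emptyenv(), hash = TRUE)
  for (ac in spec$attribute_columns) {
    raws <- raw_tbl(store, ac$index, ac$attribute)
    if (!nrow(raws)) next
    keys <- paste(raws$id, ac$attribute,
                  ifelse(is.na(raws$value_chr), raws$value_num,
                         raws$value_chr),
                  raws$source_name, sep = "\r")
    for (k in keys) seen_keys[[paste0("k", k)]] <- TRUE
  }

  new_raws <- list()
  touched <- character()

  cols <- as.list(tbl)
  for (i in seq_len(nrow(tbl))) {
    row <- lapply(cols, `[[`, i)

    if (spec$index == "assembly") {
      acc_col <- spec$assembly_columns$assembly_id
      acc <- as.character(row[[acc_col]] %||% NA)
      if (is_missing_cell(acc, markers)) {
        add_exception(row, "no-taxon-match"); next
      }
      m <- match_row_to_taxon(store, row, spec$taxonomy_columns,
                              spec$options)
      if (is.na(m$taxon_id)) { add_exception(row, m$reason); next }
      alias_cols <- spec$assembly_columns$identifiers %||% character()
      aliases <- unlist(lapply(alias_cols, function(cl) {
        v <- as.character(row[[cl]] %||% NA)
        if (is_missing_cell(v, markers)) NULL else v
      }))
      add_assembly(store, acc, m$taxon_id, aliases)
      doc_id <- acc
    } else {
      m <- match_row_to_taxon(store, row, spec$taxonomy_columns,
                              spec$options)
      if (is.na(m$taxon_id)) { add_exception(row, m$reason); next }
      doc_id <- m$taxon_id
    }
    if (isTRUE(m$inferred)) {
      inferred[[length(inferred) + 1L]] <- tibble(
        row = i, taxon_id = m$taxon_id, tier = m$tier)
    }

    n_attempted <- 0L
    n_succeeded <- 0L
    for (ac in spec$attribute_columns) {
      cell <- as.character(row[[ac$header]] %||% NA)
      if (is_missing_cell(cell, markers)) next
      n_attempted <- n_attempted + 1L
      def <- attr_def(store, ac$attribute, ac$index)
      vals <- if (def$type == "list") {
        strsplit(cell, ";", fixed = TRUE)[[1]]
      } else cell
      for (v0 in vals) {
        v <- trimws(v0)
        if (!is.null(ac$translate) && v %in% names(ac$translate))
          v <- ac$translate[[v]]
        typed <- tryCatch({
          v2 <- apply_transform(v, ac$transform, row = row)
          coerce_value(v2, def)
        },
        taxatlas_type_error = function(e) e,
        taxatlas_constraint_error = function(e) e)
        if (inherits(typed, "error")) {
          reason <- if (inherits(typed, "taxatlas_constraint_error"))
            "constraint-violation" else "type-error"
          add_exception(row, reason)
          next
        }
        key <- paste(doc_id, ac$attribute,
                     ifelse(is.na(typed$chr), typed$num, typed$chr),
                     spec$source$name, sep = "\r")
        kslot <- slot_key(def$index, ac$attribute)
        if (!is.null(seen_keys[[paste0("k", key)]])) {
          n_succeeded <- n_succeeded + 1L
          next
        }
        seen_keys[[paste0("k", key)]] <- TRUE
        new_raws[[length(new_raws) + 1L]] <-
          list(kslot, doc_id, typed$chr, typed$num)
        touched <- union(touched, kslot)
        n_succeeded <- n_succeeded + 1L
      }
    }
    # a row counts as indexed unless every one of its non-empty cells failed
    if (n_attempted == 0L || n_succeeded > 0L) n_indexed <- n_indexed + 1L
  }

  if (length(new_raws)) {
    all_new <- tibble(
      slot = vapply(new_raws, `[[`, "", 1),
      id = vapply(new_raws, `[[`, "", 2),
      value_chr = vapply(new_raws, `[[`, "", 3),
      value_num = vapply(new_raws, `[[`, 0, 4),
      source_name = spec$source$name,
      source_url = spec$source$url %||% NA_character_,
      imported_at = spec$source$date)
    for (k in unique(all_new$slot)) {
      add <- select(all_new[all_new$slot == k, ], -"slot")
      store$raws[[k]] <- bind_rows(store$raws[[k]] %||% empty_raw_tbl(), add)
    }
  }
  for (k in touched) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    summarise_attribute(store, paste(parts[-1], collapse = "."), parts[1])
  }

  exceptions_tbl <- if (length(exceptions)) {
    bind_rows(lapply(exceptions, function(e) as_tibble(e)))
  } else tibble(reason = character())
  inferred_tbl <- if (length(inferred)) bind_rows(inferred) else
    tibble(row = integer(), taxon_id = character(), tier = character())

  # `exceptions` counts rows that contributed nothing (rows in = indexed +
  # exceptions); the exceptions table additionally carries cell-level
  # records for rows that were otherwise kept
  list(indexed = n_indexed, inferred = nrow(inferred_tbl),
       exceptions = nrow(tbl) - n_indexed,
       exceptions_tbl = exceptions_tbl, inferred_tbl = inferred_tbl)
}

#' Import every YAML+data pair found in a directory
#'
#' Scans `dir` for `*.yaml` files with sibling data files, imports each in
#' filename order, and writes per-file exception and inferred-match review
#' files (`<name>.exceptions.tsv`, `<name>.inferred.tsv`) next to the
#' sources.
#'
#' @param store a store; @param dir directory to scan.
#' @param write_logs write the review TSVs (default TRUE).
#' @return tibble of per-file counts.
#' @export
index_directory <- function(store, dir, write_logs = TRUE) {
  specs <- sort(list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE))
  purrr::map_dfr(specs, function(y) {
    res <- index_file(store, y)
    if (write_logs) {
      base <- sub("\\.ya?ml$", "", y)
      if (nrow(res$exceptions_tbl))
        readr::write_tsv(res$exceptions_tbl,
                         paste0(base, ".exceptions.tsv"))
      if (nrow(res$inferred_tbl))
        readr::write_tsv(res$inferred_tbl, paste0(base, ".inferred.tsv"))
    }
    tibble(spec = basename(y), indexed = res$indexed,
           inferred = res$inferred, exceptions = res$exceptions)
  })
}
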