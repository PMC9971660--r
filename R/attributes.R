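#' Register an attribute definition
#'
#' Every attribute carries its value type, optional constraints, the ordered
#' list of summary rules used to reduce raw values to one reported value,
#' and propagation (traverse) rules for tree-based filling. Ordered keyword
#' attributes declare their `enum` from highest to lowest (e.g.
#' `c("complete genome", "chromosome", "scaffold", "contig")`), which both
#' defines priority for summarisation and the total order used by the
#' query operators `<`, `<=`, `>=`, `>`.
#'
#' @param store a [taxatlas_store()].
#' @param name attribute name.
#' @param index `"taxon"` or `"assembly"`.
#' @param type one of integer, float, date, keyword, ordered_keyword, list.
#' @param constraints optional list with `min`, `max` and/or `enum`.
#' @param summary ordered character vector of summary rules, first
#'   applicable wins: min, max, mean, median, mode, list, priority-by-enum,
#'   priority-by-source.
#' @param traverse list with `direction` (up, down, both, none),
#'   optional `ancestor_summary` statistic (defaults: median for numeric
#'   and date, mode otherwise) and optional `limit` (a clade name/id or
#'   `list(rank = "family")`) beyond which no estimate propagates.
#' @param units,display_group,source_priority optional display metadata and
#'   source priority order.
#' @param overwrite replace an identical-name definition instead of erroring.
#' @return the definition, invisibly.
#' @export
define_attribute <- function(store, name, index = "taxon", type = "float",
                             constraints = list(), summary = NULL,
                             traverse = list(direction = "none"),
                             units = NULL, display_group = NULL,
                             source_priority = NULL, overwrite = FALSE) {
  stopifnot(inherits(store, "taxatlas_store"))
  if (!index %in% c("taxon", "assembly")) stop_taxatlas(
    paste0("unknown index '", index, "' for attribute ", name),
    "taxatlas_config_error")
  if (!type %in% c("integer", "float", "date", "keyword", "ordered_keyword",
                   "list")) stop_taxatlas(
    paste0("unknown value type '", type, "' for attribute ", name),
    "taxatlas_config_error")
  if (type == "ordered_keyword" && !length(constraints$enum)) stop_taxatlas(
    paste0("ordered_keyword attribute '", name, "' requires an enum"),
    "taxatlas_config_error")
  summary <- summary %||%
    if (type %in% c("integer", "float", "date")) "median"
    else if (type == "list") "list"
    else if (type == "ordered_keyword") "priority-by-enum"
    else "mode"
  bad <- setdiff(summary, c("min", "max", "mean", "median", "mode", "list",
                            "priority-by-enum", "priority-by-source"))
  if (length(bad)) stop_taxatlas(
    paste0("unknown summary rule(s) for ", name, ": ",
           paste(bad, collapse = ", ")),
    "taxatlas_config_error")
  traverse$direction <- traverse$direction %||% "none"
  if (!traverse$direction %in% c("up", "down", "both", "none")) stop_taxatlas(
    paste0("traverse direction must be up/down/both/none for ", name),
    "taxatlas_config_error")
  traverse$ancestor_summary <- traverse$ancestor_summary %||%
    if (type %in% c("integer", "float", "date")) "median" else "mode"

  def <- list(
    name = name, index = index, type = type, constraints = constraints,
    summary = summary, traverse = traverse, units = units,
    display_group = display_group, source_priority = source_priority
  )
  key <- slot_key(index, name)
  existing <- store$attr_defs[[key]]
  if (!is.null(existing) && !overwrite) {
    same <- identical(existing[c("index", "type", "constraints")],
                      def[c("index", "type", "constraints")])
    if (!same) stop_taxatlas(
      paste0("attribute '", name,
             "' conflicts with an existing registry entry"),
      "taxatlas_config_error")
    return(invisible(existing))
  }
  store$attr_defs[[key]] <- def
  invisible(def)
}

# registry lookup. The same attribute name may exist on both indexes
# (e.g. assembly_span per assembly and aggregated per taxon); an explicit
# `index` is authoritative, otherwise the taxon-index entry wins.
attr_def <- function(store, name, index = NULL) {
  if (!is.null(index)) {
    def <- store$attr_defs[[slot_key(index, name)]]
    if (!is.null(def)) return(def)
    other <- setdiff(c("taxon", "assembly"), index)
    if (!is.null(store$attr_defs[[slot_key(other, name)]])) stop_taxatlas(
      paste0("attribute '", name, "' belongs to the ", other, " index"),
      "taxatlas_query_error")
    stop_taxatlas(paste0("unknown attribute: ", name),
                  "taxatlas_config_error")
  }
  for (idx in c("taxon", "assembly")) {
    def <- store$attr_defs[[slot_key(idx, name)]]
    if (!is.null(def)) return(def)
  }
  stop_taxatlas(paste0("unknown attribute: ", name),
                "taxatlas_config_error")
}

# definitions registered for one index, as a list named by attribute name
attr_defs_for <- function(store, index) {
  defs <- purrr::keep(store$attr_defs, ~ .x$index == index)
  setNames(defs, vapply(defs, `[[`, "", "name"))
}

slot_key <- function(index, attribute) paste(index, attribute, sep = ".")

is_numeric_type <- function(type) type %in% c("integer", "float", "date")

# score of an ordered-keyword label: highest-priority label gets the
# largest score so that ">=" reads "at least as good as"
enum_score <- function(labels, enum) {
  idx <- match(labels, enum)
  length(enum) - idx + 1
}

# typed coercion of a raw cell; returns list(chr=, num=) or aborts with a
# taxatlas_type_error / taxatlas_constraint_error
coerce_value <- function(x, def) {
  x <- trimws(as.character(x))
  type <- def$type
  if (type %in% c("integer", "float")) {
    num <- suppressWarnings(as.numeric(x))
    if (is.na(num)) stop_taxatlas(
      paste0("non-numeric value '", x, "' for ", def$name),
      "taxatlas_type_error")
    if (type == "integer" && num != round(num)) stop_taxatlas(
      paste0("non-integer value '", x, "' for ", def$name),
      "taxatlas_type_error")
    lims <- def$constraints
    if (!is.null(lims$min) && num < lims$min) stop_taxatlas(
      paste0(def$name, " value ", num, " below minimum ", lims$min),
      "taxatlas_constraint_error")
    if (!is.null(lims$max) && num > lims$max) stop_taxatlas(
      paste0(def$name, " value ", num, " above maximum ", lims$max),
      "taxatlas_constraint_error")
    return(list(chr = NA_character_, num = num))
  }
  if (type == "date") {
    d <- suppressWarnings(as.Date(x))
    if (is.na(d)) stop_taxatlas(
      paste0("unparseable date '", x, "' for ", def$name),
      "taxatlas_type_error")
    return(list(chr = format(d, "%Y-%m-%d"), num = as.numeric(d)))
  }
  if (type == "ordered_keyword") {
    enum <- def$constraints$enum
    hit <- enum[match(tolower(x), tolower(enum))]
    if (is.na(hit)) stop_taxatlas(
      paste0("value '", x, "' not in enum for ", def$name),
      "taxatlas_constraint_error")
    return(list(chr = hit, num = enum_score(hit, enum)))
  }
  if (type %in% c("keyword", "list")) {
    enum <- def$constraints$enum
    if (!is.null(enum) && !tolower(x) %in% tolower(enum)) stop_taxatlas(
      paste0("value '", x, "' not in enum for ", def$name),
      "taxatlas_constraint_error")
    return(list(chr = x, num = NA_real_))
  }
  stop_taxatlas(paste0("unhandled type ", type), "taxatlas_internal_error")
}

empty_raw_tbl <- function() {
  tibble(
    id = character(), value_chr = character(), value_num = double(),
    source_name = character(), source_url = character(),
    imported_at = character()
  )
}

empty_slot_tbl <- function() {
  tibble(
    id = character(), value_chr = character(), value_num = double(),
    value_list = list(), statistic = character(),
    min = double(), max = double(),
    min_label = character(), max_label = character(),
    count = integer(), provenance = character(), source_id = character()
  )
}

raw_tbl <- function(store, index, attribute) {
  store$raws[[slot_key(index, attribute)]] %||% empty_raw_tbl()
}

slot_tbl <- function(store, index, attribute) {
  store$slots[[slot_key(index, attribute)]] %||% empty_slot_tbl()
}

# ---------------------------------------------------------------------------
# summarisation of raw value lists

mode_value <- function(x, enum = NULL) {
  tab <- table(x)
  best <- names(tab)[tab == max(tab)]
  if (length(best) == 1) return(best)
  if (!is.null(enum)) {
    pos <- match(best, enum)
    if (!anyNA(pos)) return(best[which.min(pos)])
  }
  value_sort(best)[1]
}

#' Summarise a list of raw values into one reported value
#'
#' The first rule in `rules` that is applicable to the value type determines
#' the reported value: `min`/`max`/`mean`/`median` apply to numeric and date
#' values (`min`/`max` also to ordered keywords, by enum position), `mode`
#' and `list` to any type, `priority-by-enum` to enum-typed values (the
#' label highest in the enum wins), `priority-by-source` to any type when a
#' source priority order is configured. The range (`min`, `max`) is reported
#' for numeric and ordered-keyword values regardless of the rule used, and
#' `count` is always the number of raw values.
#'
#' @param values vector of typed raw values (numeric, or character labels).
#' @param rules ordered character vector of summary rules.
#' @param type value type of the attribute.
#' @param enum ordered labels (highest first) for enum-typed attributes.
#' @param sources optional character vector parallel to `values`.
#' @param source_priority optional ordered list of source names.
#' @return list with `value`, `statistic`, `min`, `max`, `count`.
#' @export
summarise_values <- function(values, rules, type = "float", enum = NULL,
                             sources = NULL, source_priority = NULL) {
  if (!length(values)) stop_taxatlas(
    "cannot summarise an empty value list", "taxatlas_precondition_error")
  n <- length(values)
  numericish <- is_numeric_type(type)
  scores <- if (type == "ordered_keyword") enum_score(values, enum) else NULL

  rng <- if (numericish) {
    list(min = min(values), max = max(values))
  } else if (type == "ordered_keyword") {
    list(min = values[which.min(scores)], max = values[which.max(scores)])
  } else {
    list(min = NA, max = NA)
  }

  for (rule in rules) {
    res <- switch(
      rule,
      "min" = if (numericish) min(values)
              else if (type == "ordered_keyword") rng$min,
      "max" = if (numericish) max(values)
              else if (type == "ordered_keyword") rng$max,
      "mean" = if (numericish) mean(values),
      "median" = if (numericish) median(values),
      "mode" = {
        mv <- mode_value(values, enum)
        if (numericish) as.numeric(mv) else mv
      },
      "list" = list(value_sort(unique(values))),
      "priority-by-enum" = {
        if (is.null(enum)) stop_taxatlas(
          "priority-by-enum requires an enum", "taxatlas_config_error")
        pos <- match(values, enum)
        values[which.min(pos)]
      },
      "priority-by-source" = {
        if (is.null(source_priority) || is.null(sources)) NULL
        else {
          pos <- match(sources, source_priority)
          if (all(is.na(pos))) NULL else values[which.min(pos)]
        }
      },
      stop_taxatlas(paste0("unknown summary rule: ", rule),
                    "taxatlas_config_error")
    )
    if (!is.null(res)) {
      value <- if (is.list(res)) res[[1]] else res
      return(list(value = value, statistic = rule,
                  min = rng$min, max = rng$max, count = n))
    }
  }
  stop_taxatlas("no applicable summary rule", "taxatlas_config_error")
}

# recompute direct summaries for one attribute from its raw values
summarise_attribute <- function(store, attribute, index = NULL) {
  def <- attr_def(store, attribute, index)
  raws <- raw_tbl(store, def$index, attribute)
  slots <- slot_tbl(store, def$index, attribute)
  slots <- slots[slots$provenance != "direct", ]
  if (nrow(raws)) {
    enum <- def$constraints$enum
    by_id <- split(seq_len(nrow(raws)), raws$id)
    ids <- names(by_id)
    summaries <- lapply(by_id, function(idx) {
      vals <- if (is_numeric_type(def$type)) raws$value_num[idx]
              else raws$value_chr[idx]
      summarise_values(vals, def$summary, type = def$type, enum = enum,
                       sources = raws$source_name[idx],
                       source_priority = def$source_priority)
    })
    new_rows <- build_slot_tbl(
      def, ids,
      value = lapply(summaries, `[[`, "value"),
      statistic = vapply(summaries, `[[`, "", "statistic"),
      vmin = lapply(summaries, `[[`, "min"),
      vmax = lapply(summaries, `[[`, "max"),
      count = vapply(summaries, function(s) as.integer(s$count), 0L),
      provenance = "direct", source_id = NA_character_)
    slots <- bind_rows(new_rows, slots)
  }
  store$slots[[slot_key(def$index, attribute)]] <- slots
  invisible(store)
}

# vectorised slot-row constructor; `value`, `vmin`, `vmax` are lists (or
# vectors) parallel to `id`
build_slot_tbl <- function(def, id, value, statistic, vmin = NULL,
                           vmax = NULL, count = NA_integer_,
                           provenance = "direct",
                           source_id = NA_character_) {
  n <- length(id)
  if (!n) return(empty_slot_tbl())
  type <- def$type
  enum <- def$constraints$enum
  na1 <- function(x) if (is.null(x)) rep(NA, n) else {
    out <- unlist(lapply(x, function(v) if (is.null(v) || !length(v)) NA
                         else v[[1]]))
    out
  }
  vals1 <- if (type == "list") rep(NA, n) else na1(value)
  mins <- na1(vmin)
  maxs <- na1(vmax)

  if (type == "list") {
    tibble(
      id = id, value_chr = NA_character_, value_num = NA_real_,
      value_list = lapply(value, function(v) as.character(unlist(v))),
      statistic = statistic, min = NA_real_, max = NA_real_,
      min_label = NA_character_, max_label = NA_character_,
      count = as.integer(count), provenance = provenance,
      source_id = source_id)
  } else if (is_numeric_type(type)) {
    num <- as.numeric(vals1)
    chr <- if (type == "date") format(as.Date(num, origin = "1970-01-01"),
                                      "%Y-%m-%d") else NA_character_
    tibble(
      id = id, value_chr = chr, value_num = num,
      value_list = vector("list", n), statistic = statistic,
      min = suppressWarnings(as.numeric(mins)),
      max = suppressWarnings(as.numeric(maxs)),
      min_label = NA_character_, max_label = NA_character_,
      count = as.integer(count), provenance = provenance,
      source_id = source_id)
  } else {
    chr <- as.character(vals1)
    num <- if (type == "ordered_keyword") enum_score(chr, enum)
           else rep(NA_real_, n)
    min_chr <- as.character(mins)
    max_chr <- as.character(maxs)
    tibble(
      id = id, value_chr = chr, value_num = num,
      value_list = vector("list", n), statistic = statistic,
      min = if (type == "ordered_keyword")
        enum_score(min_chr, enum) else NA_real_,
      max = if (type == "ordered_keyword")
        enum_score(max_chr, enum) else NA_real_,
      min_label = if (type == "ordered_keyword") min_chr
                  else NA_character_,
      max_label = if (type == "ordered_keyword") max_chr
                  else NA_character_,
      count = as.integer(count), provenance = provenance,
      source_id = source_id)
  }
}
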