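# Tree-based inference of missing attribute values.
#
# The backbone taxonomy has no branch lengths, so propagation is purely
# topological: an UP pass infers a value for each internal node lacking a
# direct summary from the (direct or descendant-derived) values of its
# children, then a DOWN pass assigns each still-empty node the value of its
# nearest informative ancestor (fewest edges). Provenance follows the
# traffic-light scheme: green = direct measurement, orange = derived from
# descendants, red = inherited from an ancestor.

# breadth-first order of all taxa from the root (parents before children)
bfs_order <- function(store) {
  out <- character(n_taxa(store))
  out[1] <- store$root_id
  i <- 1L; j <- 1L
  while (i <= j) {
    ch <- store$children[[out[i]]]
    if (length(ch)) {
      out[(j + 1L):(j + length(ch))] <- ch
      j <- j + length(ch)
    }
    i <- i + 1L
  }
  out[seq_len(j)]
}

# ids excluded from propagation by the traverse limit (clade and/or rank
# barrier). A clade barrier excludes the barrier node and its entire
# subtree: values inside never leave it and no estimate enters it. A rank
# limit acts as a ceiling: nodes above the limit rank receive and relay
# nothing; rank-less nodes count as below the ceiling only when they sit
# under a node at or below the limit rank.
barrier_excluded <- function(store, limit, order) {
  if (is.null(limit)) return(character())
  if (is.character(limit)) limit <- list(clade = limit)
  excluded <- character()
  if (!is.null(limit$clade)) {
    hits <- unique(c(
      intersect(limit$clade, names(store$parent)),
      names(store$sci_name)[tolower(store$sci_name) %in%
                              tolower(limit$clade)]))
    for (b in hits) excluded <- c(excluded, b, descendant_ids(store, b))
  }
  if (!is.null(limit$rank)) {
    pos_limit <- rank_position(limit$rank)
    if (is.na(pos_limit)) stop_taxatlas(
      paste0("unknown rank limit: ", limit$rank), "taxatlas_config_error")
    ok <- setNames(logical(length(order)), order)
    for (id in order) {  # parents first: inherit the below-ceiling flag
      pos <- rank_position(store$rank[[id]])
      p <- store$parent[[id]]
      ok[id] <- (!is.na(pos) && pos >= pos_limit) || (!is.na(p) && ok[[p]])
    }
    excluded <- c(excluded, order[!ok])
  }
  unique(excluded)
}

# one propagation statistic over child values
stat_apply <- function(values, stat, type, enum = NULL) {
  if (is_numeric_type(type)) {
    switch(stat,
      median = median(values), mean = mean(values),
      min = min(values), max = max(values),
      mode = as.numeric(mode_value(values)),
      stop_taxatlas(paste0("statistic '", stat,
                           "' not usable for numeric propagation"),
                    "taxatlas_config_error"))
  } else {
    switch(stat,
      mode = mode_value(values, enum),
      "priority-by-enum" = values[which.min(match(values, enum))],
      min = values[which.min(enum_score(values, enum))],
      max = values[which.max(enum_score(values, enum))],
      stop_taxatlas(paste0("statistic '", stat,
                           "' not usable for keyword propagation"),
                    "taxatlas_config_error"))
  }
}

#' Propagate one attribute's values through the taxonomy
#'
#' Recomputes direct summaries from raw values, then runs the UP pass
#' (post-order: each internal node lacking a direct summary gets the
#' configured ancestor-summary statistic of its children's direct or
#' descendant-derived values) if the attribute's traverse direction is
#' `up` or `both`, and the DOWN pass (pre-order: each node still without a
#' value inherits the nearest ancestor's value, recording that ancestor as
#' `source_id`) if the direction is `down` or `both`. Direct summaries are
#' never overwritten, ancestor-derived values never feed the UP pass, and
#' propagation never crosses a configured clade or rank barrier in either
#' direction (taxa inside a barrier clade receive no estimates at all).
#'
#' @param store a [taxatlas_store()].
#' @param attribute a registered taxon-index attribute with traverse
#'   direction other than `none`.
#' @return invisibly, a list with `written` (number of estimates new or
#'   changed relative to the previous fill; 0 on an idempotent rerun) and
#'   the tallies `direct`, `descendant`, `ancestor`.
#' @export
fill_attribute <- function(store, attribute) {
  def <- attr_def(store, attribute)  # taxon-index entry preferred
  if (def$index != "taxon") stop_taxatlas(
    paste0("fill applies to the taxon index only; '", attribute,
           "' is an assembly attribute"), "taxatlas_config_error")
  dir <- def$traverse$direction
  if (dir == "none") stop_taxatlas(
    paste0("attribute '", attribute, "' has traverse direction 'none'"),
    "taxatlas_config_error")
  if (def$type == "list") stop_taxatlas(
    "list-typed attributes cannot be propagated", "taxatlas_config_error")

  summarise_attribute(store, attribute, "taxon")
  slots <- slot_tbl(store, "taxon", attribute)
  prev_est <- slots[slots$provenance != "direct", ]
  direct <- slots[slots$provenance == "direct", ]

  order <- bfs_order(store)
  n <- length(order)
  pos <- setNames(seq_len(n), order)           # id -> position in order
  parent_pos <- ifelse(is.na(store$parent[order]), NA_integer_,
                       pos[store$parent[order]])
  children_pos <- lapply(store$children[order], function(ch)
    unname(pos[ch]))

  excluded <- barrier_excluded(store, def$traverse$limit, order)
  exc <- logical(n)
  exc[pos[excluded]] <- TRUE

  numeric_attr <- is_numeric_type(def$type)
  enum <- def$constraints$enum
  stat <- def$traverse$ancestor_summary

  # working value map: direct values first (NA = no value yet)
  val_num <- rep(NA_real_, n)
  val_chr <- rep(NA_character_, n)
  has_val <- logical(n)
  if (nrow(direct)) {
    at <- pos[direct$id]
    if (numeric_attr) val_num[at] <- direct$value_num
    else val_chr[at] <- direct$value_chr
    has_val[at] <- TRUE
  }
  is_direct <- has_val

  est_rows <- list()

  if (dir %in% c("up", "both")) {
    for (i in n:1) {                  # post-order: children before parents
      if (exc[i] || is_direct[i]) next
      ch <- children_pos[[i]]
      if (!length(ch)) next
      ch <- ch[!exc[ch] & has_val[ch]]
      if (!length(ch)) next
      vals <- if (numeric_attr) val_num[ch] else val_chr[ch]
      v <- stat_apply(vals, stat, def$type, enum)
      if (numeric_attr) val_num[i] <- v else val_chr[i] <- v
      has_val[i] <- TRUE
      est_rows[[length(est_rows) + 1L]] <- list(
        id = order[i], v = v, provenance = "descendant",
        source = NA_character_)
    }
  }

  if (dir %in% c("down", "both")) {
    # pre-order with a carried (value, source) pair; a barrier node stops
    # the descent into its subtree entirely
    carry_val_num <- rep(NA_real_, n)
    carry_val_chr <- rep(NA_character_, n)
    carry_src <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      if (exc[i]) next
      p <- parent_pos[i]
      if (!has_val[i] && !is.na(p) && !is.na(carry_src[p])) {
        v <- if (numeric_attr) carry_val_num[p] else carry_val_chr[p]
        src <- carry_src[p]
        if (numeric_attr) val_num[i] <- v else val_chr[i] <- v
        has_val[i] <- TRUE
        est_rows[[length(est_rows) + 1L]] <- list(
          id = order[i], v = v, provenance = "ancestor", source = src)
        carry_val_num[i] <- carry_val_num[p]
        carry_val_chr[i] <- carry_val_chr[p]
        carry_src[i] <- src
      } else if (has_val[i]) {
        if (numeric_attr) carry_val_num[i] <- val_num[i]
        else carry_val_chr[i] <- val_chr[i]
        carry_src[i] <- order[i]
      } else if (!is.na(p)) {
        carry_val_num[i] <- carry_val_num[p]
        carry_val_chr[i] <- carry_val_chr[p]
        carry_src[i] <- carry_src[p]
      }
    }
  }

  est_tbl <- if (length(est_rows)) {
    prov <- vapply(est_rows, `[[`, "", "provenance")
    build_slot_tbl(
      def,
      id = vapply(est_rows, `[[`, "", "id"),
      value = lapply(est_rows, `[[`, "v"),
      statistic = ifelse(prov == "descendant", stat, NA_character_),
      count = NA_integer_, provenance = prov,
      source_id = vapply(est_rows, `[[`, "", "source"))
  } else empty_slot_tbl()

  store$slots[[slot_key("taxon", attribute)]] <- bind_rows(direct, est_tbl)

  est_key <- function(tb) paste(
    tb$id, ifelse(is.na(tb$value_chr), tb$value_num, tb$value_chr),
    tb$provenance, tb$source_id, sep = "\r")
  written <- length(setdiff(est_key(est_tbl), est_key(prev_est)))

  invisible(list(
    written = written,
    direct = nrow(direct),
    descendant = sum(est_tbl$provenance == "descendant"),
    ancestor = sum(est_tbl$provenance == "ancestor")))
}

#' Fill every eligible attribute
#'
#' Applies [fill_attribute()] to each registered taxon-index attribute
#' whose traverse direction is not `none`, in attribute-name order.
#' Per-attribute failures are reported without aborting the batch.
#'
#' @param store a store.
#' @return tibble with one row per eligible attribute: `attribute`,
#'   `written`, `direct`, `descendant`, `ancestor`, `error`.
#' @export
fill_all <- function(store) {
  defs <- attr_defs_for(store, "taxon")
  eligible <- sort(names(purrr::keep(
    defs, ~ .x$traverse$direction != "none" && .x$type != "list")))
  purrr::map_dfr(eligible, function(a) {
    res <- tryCatch(fill_attribute(store, a), error = function(e) e)
    if (inherits(res, "error")) {
      tibble(attribute = a, written = NA_integer_, direct = NA_integer_,
             descendant = NA_integer_, ancestor = NA_integer_,
             error = conditionMessage(res))
    } else {
      tibble(attribute = a, written = res$written, direct = res$direct,
             descendant = res$descendant, ancestor = res$ancestor,
             error = NA_character_)
    }
  })
}
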