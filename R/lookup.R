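#' Resolve a free-text name to taxon or assembly identifiers
#'
#' Matching is case-insensitive over every indexed name class (scientific
#' names, synonyms, common names, tol ids, ...) and over assembly accessions
#' and aliases. Results are tiered: exact matches first, then prefix
#' matches, and only when neither exists, fuzzy matches within edit
#' distance 2. Within a tier, ties are broken by shorter matched name, then
#' lexicographically, then by id, so result order is deterministic. Each
#' hit carries the rank and immediate parent name of the matched taxon so
#' that homonyms can be told apart by the caller; equal-tier homonyms are
#' never collapsed or auto-picked.
#'
#' @param store a [taxatlas_store()].
#' @param query the name or identifier fragment to look up.
#' @param limit maximum number of results.
#' @return a tibble with columns `match_tier` ("exact", "prefix" or
#'   "fuzzy"), `doc_type` ("taxon" or "assembly"), `id`, `matched_name`,
#'   `name_class`, `rank`, `parent_name`. Zero rows when nothing matches.
#' @export
lookup_names <- function(store, query, limit = 10L) {
  stopifnot(inherits(store, "taxatlas_store"))
  q <- tolower(trimws(query))
  if (!nzchar(q)) return(lookup_empty())

  cand <- bind_rows(
    tibble(
      doc_type = "taxon",
      id = store$names_tbl$taxon_id,
      matched_name = store$names_tbl$name,
      name_class = store$names_tbl$name_class,
      key = store$names_tbl$name_lower
    ),
    tibble(
      doc_type = "assembly",
      id = store$assembly_identifiers$assembly_id,
      matched_name = store$assembly_identifiers$id,
      name_class = store$assembly_identifiers$class,
      key = store$assembly_identifiers$id_lower
    )
  )
  if (!nrow(cand)) return(lookup_empty())

  exact <- cand[cand$key == q, ]
  if (nrow(exact)) {
    res <- mutate(exact, match_tier = "exact")
  } else {
    pref <- cand[startsWith(cand$key, q), ]
    if (nrow(pref)) {
      res <- mutate(pref, match_tier = "prefix")
    } else {
      d <- drop(adist(q, cand$key))
      fz <- cand[d <= 2, ]
      res <- if (nrow(fz)) mutate(fz, match_tier = "fuzzy") else lookup_empty()
    }
  }
  if (!nrow(res)) return(lookup_empty())

  res <- res[order(nchar(res$matched_name), res$matched_name, res$id), ]
  res <- head(res, limit)
  parent_of <- function(doc_type, id) {
    tid <- if (doc_type == "assembly") {
      store$assemblies$taxon_id[match(id, store$assemblies$assembly_id)]
    } else id
    p <- store$parent[[tid]]
    if (is.na(p)) NA_character_ else store$sci_name[[p]]
  }
  res$rank <- vapply(seq_len(nrow(res)), function(i) {
    if (res$doc_type[i] == "assembly") "assembly"
    else unname(store$rank[[res$id[i]]])
  }, "")
  res$parent_name <- vapply(seq_len(nrow(res)), function(i) {
    parent_of(res$doc_type[i], res$id[i]) %||% NA_character_
  }, "")
  select(res, "match_tier", "doc_type", "id", "matched_name",
         "name_class", "rank", "parent_name")
}

lookup_empty <- function() {
  tibble(
    match_tier = character(), doc_type = character(), id = character(),
    matched_name = character(), name_class = character(),
    rank = character(), parent_name = character()
  )
}
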