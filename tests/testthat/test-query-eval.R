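# A populated store: tiny taxonomy + hand-placed attribute values.
query_fixture_store <- function() {
  store <- tiny_store()
  add_direct_values(store, "genome_size",
                    c("5" = 2.4e9, "9" = 2.5e9, "14" = 0.5e9),
                    direction = "both")
  fill_attribute(store, "genome_size")
  define_attribute(store, "assembly_level", index = "taxon",
                   type = "ordered_keyword",
                   constraints = list(enum = c("complete genome",
                                               "chromosome", "scaffold",
                                               "contig")),
                   summary = "priority-by-enum")
  store$raws[["taxon.assembly_level"]] <- tibble::tibble(
    id = c("5", "6", "9", "14"),
    value_chr = c("chromosome", "scaffold", "complete genome", "contig"),
    value_num = NA_real_, source_name = "fx", source_url = NA_character_,
    imported_at = "2022-11-16")
  taxatlas:::summarise_attribute(store, "assembly_level")
  define_attribute(store, "long_list", type = "list", summary = "list")
  store$raws[["taxon.long_list"]] <- tibble::tibble(
    id = c("5", "5", "9", "14"),
    value_chr = c("DTOL", "VGP", "DTOL", "ERGA"),
    value_num = NA_real_, source_name = "fx", source_url = NA_character_,
    imported_at = "2022-11-16")
  taxatlas:::summarise_attribute(store, "long_list")
  store
}

test_that("tax_tree matches exactly the lineage-closure set", {
  store <- query_fixture_store()
  got <- search_docs(store, "tax_tree(Animalia)")$taxon_id
  want <- names(store$parent)[vapply(names(store$parent), function(d)
    "2" %in% c(d, store$lineage[[d]]), TRUE)]
  expect_setequal(got, want)
  # self-inclusive
  expect_true("2" %in% got)
  # named-argument negation subtracts a nested subtree
  got2 <- search_docs(store, "tax_tree(Animalia, !Canidae)")$taxon_id
  expect_setequal(got2, setdiff(got,
    search_docs(store, "tax_tree(Canidae)")$taxon_id))
})

test_that("taxon functions: eq, name, rank, depth, lineage", {
  store <- query_fixture_store()
  expect_equal(search_docs(store, "tax_eq(5)")$taxon_id, "5")
  expect_equal(search_docs(store, "tax_name(Panthera leo)")$taxon_id, "5")
  expect_equal(search_docs(store, "tax_name(synonym:Leo africanus)")$taxon_id,
               "5")
  # wildcard over a name class
  expect_equal(search_docs(store, "tax_name(tol_id:*)")$taxon_id, "5")
  expect_setequal(search_docs(store, "tax_rank(genus)")$taxon_id,
                  c("4", "8", "13"))
  # depth relative to the anchoring tree term
  got <- search_docs(store, "tax_tree(Animalia) AND tax_depth(1)")$taxon_id
  expect_setequal(got, c("2", "3", "7"))
  # lineage of a single taxon = its ancestors
  got <- search_docs(store, "tax_lineage(Panthera leo)")$taxon_id
  expect_setequal(got, c("4", "3", "2", "1"))
  expect_error(search_docs(store, "tax_lineage(Vulpes shared)"),
               class = "taxatlas_query_error")
})

test_that("ordered enums form a total order under comparison operators", {
  store <- query_fixture_store()
  # >= chromosome means chromosome or better
  got <- search_docs(store, "assembly_level>=chromosome")$taxon_id
  expect_setequal(got, c("5", "9"))
  lvl <- function(id) {
    s <- taxatlas:::slot_tbl(store, "taxon", "assembly_level")
    s$value_chr[s$id == id]
  }
  for (id in got) expect_true(lvl(id) %in% c("chromosome",
                                             "complete genome"))
  expect_setequal(search_docs(store, "assembly_level=chromosome")$taxon_id,
                  "5")
  expect_setequal(search_docs(store, "assembly_level<scaffold")$taxon_id,
                  "14")
  expect_setequal(
    search_docs(store, "assembly_level=chromosome,complete genome")$taxon_id,
    c("5", "9"))
  expect_setequal(search_docs(store, "assembly_level!=contig")$taxon_id,
                  c("5", "6", "9"))
})

test_that("estimate inclusion is controlled by the include_estimates flag", {
  store <- query_fixture_store()
  # Panthera onca (6) has only an ancestor-derived genome size
  slots <- taxatlas:::slot_tbl(store, "taxon", "genome_size")
  expect_equal(slots$provenance[slots$id == "6"], "ancestor")
  with_est <- search_docs(store, "genome_size>1e9")$taxon_id
  without <- search_docs(store, "genome_size>1e9",
                         include_estimates = FALSE)$taxon_id
  expect_true("6" %in% with_est)
  expect_false("6" %in% without)
  # descendant-derived values still satisfy terms without estimates
  expect_true("4" %in% without)
})

test_that("min/max/length modifiers use ranges and raw cardinalities", {
  store <- query_fixture_store()
  store$raws[["taxon.genome_size"]] <- dplyr::bind_rows(
    taxatlas:::raw_tbl(store, "taxon", "genome_size"),
    tibble::tibble(id = "5", value_chr = NA_character_, value_num = 3.0e9,
                   source_name = "fx2", source_url = NA_character_,
                   imported_at = "2022-11-16"))
  fill_attribute(store, "genome_size")
  expect_setequal(search_docs(store, "min(genome_size)<1e9")$taxon_id, "14")
  expect_setequal(search_docs(store, "max(genome_size)>2.9e9")$taxon_id, "5")
  expect_setequal(search_docs(store, "length(long_list)>1")$taxon_id, "5")
  expect_setequal(search_docs(store, "length(genome_size)=2")$taxon_id, "5")
  expect_setequal(search_docs(store, "long_list=dtol")$taxon_id,
                  c("5", "9"))
})

test_that("count agrees with evaluation cardinality", {
  store <- query_fixture_store()
  for (q in c("tax_tree(Animalia)", "genome_size>1e9",
              "tax_rank(species) AND assembly_level>=chromosome",
              "length(long_list)>1")) {
    expect_equal(count_docs(store, q), nrow(search_docs(store, q)),
                 info = q)
  }
})

test_that("evaluation matches the naive per-document matcher on random queries", {
  store <- synthetic_pipeline_store(n_species = 300, seed = 42L)
  maps_t <- oracle_attr_maps(store, "taxon")
  maps_a <- oracle_attr_maps(store, "assembly")
  withr::local_seed(808)
  for (i in 1:60) {
    index <- if (i %% 4 == 0) "assembly" else "taxon"
    qs <- random_query(store, index)
    inc <- stats::runif(1) < 0.8
    ast <- parse_query(qs)
    got <- taxatlas:::matching_ids(store, ast, index, inc)
    want <- oracle_match(store, ast, index, inc,
                         maps = if (index == "taxon") maps_t else maps_a)
    expect_identical(got, want, info = paste(index, qs, "inc:", inc))
  }
})

test_that("assembly-index evaluation returns one row per assembly", {
  store <- synthetic_pipeline_store(n_species = 300, seed = 42L)
  res <- search_docs(store, "assembly_span", index = "assembly")
  expect_true(all(!duplicated(res$assembly_id)))
  expect_equal(nrow(res),
               count_docs(store, "assembly_span", index = "assembly"))
  # taxon scoping applies through the owning taxon
  fam <- names(store$rank)[store$rank == "family"][1]
  q <- paste0("tax_tree(", store$sci_name[[fam]], ")")
  res2 <- search_docs(store, q, index = "assembly")
  owners <- res2$taxon_id
  expect_true(all(vapply(owners, function(t)
    fam %in% c(t, store$lineage[[t]]), TRUE)))
})

test_that("records round-trip stored values with provenance and sources", {
  store <- query_fixture_store()
  rec <- get_record(store, "5")
  expect_s3_class(rec, "taxatlas_record")
  expect_equal(rec$scientific_name, "Panthera leo")
  expect_equal(rec$attributes$genome_size$summary$value, 2.4e9)
  expect_equal(rec$attributes$genome_size$summary$count, 1)
  expect_equal(sort(rec$attributes$long_list$summary$value),
               c("DTOL", "VGP"))
  # a filled taxon's record shows the estimate and its source
  rec6 <- get_record(store, "6")
  est <- rec6$attributes$genome_size$estimate
  expect_equal(est$provenance, "ancestor")
  expect_true(est$source_taxon_id %in% c("4", store$lineage[["6"]]))
  expect_error(get_record(store, "no-such-id"),
               class = "taxatlas_not_found")
  # record agrees with the search row for the same id
  row <- search_docs(store, "tax_eq(5)", fields = "genome_size")
  expect_equal(row$genome_size, rec$attributes$genome_size$summary$value)
})

test_that("summary, tidy and raw output modes are consistent", {
  store <- query_fixture_store()
  res <- search_docs(store, "tax_tree(Felidae)",
                     fields = c("genome_size", "assembly_level"))
  tsv <- format_results(res, "tsv", "summary")
  expect_equal(nrow(readr::read_tsv(I(tsv), show_col_types = FALSE)),
               nrow(res))
  tidy_tbl <- readr::read_tsv(I(format_results(res, "tsv", "tidy")),
                              show_col_types = FALSE)
  # one row per reported value across the requested attributes
  n_reported <- sum(vapply(c("genome_size", "assembly_level"), function(a) {
    s <- taxatlas:::slot_tbl(store, "taxon", a)
    sum(s$id %in% res$taxon_id)
  }, 0))
  expect_equal(nrow(tidy_tbl), n_reported)
  # raw mode drops every estimated value
  raw_tbl <- readr::read_tsv(I(format_results(res, "tsv", "raw")),
                             show_col_types = FALSE)
  expect_true(all(raw_tbl$provenance == "direct"))
  expect_false("4" %in% raw_tbl$id)   # genus value is descendant-derived
  # CSV and TSV differ only in the delimiter
  csv <- format_results(res, "csv", "summary")
  expect_equal(gsub(",", "\t", csv), tsv)
  js <- jsonlite::fromJSON(format_results(res, "json", "summary"))
  expect_equal(nrow(js), nrow(res))
})
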