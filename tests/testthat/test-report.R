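test_that("per-rank counts match a rank-filtered brute force", {
  store <- synthetic_pipeline_store(n_species = 300, seed = 42L)
  rep <- report_x_per_rank(store, "genome_size",
                           ranks = c("phylum", "class", "order", "family",
                                     "genus", "species"))
  d <- tidy(rep)
  ids <- search_docs(store, "genome_size")$taxon_id
  for (i in seq_len(nrow(d))) {
    expect_equal(d$count[i], sum(store$rank[ids] == d$rank[i]),
                 info = d$rank[i])
  }
  # totals reconcile with count()
  expect_true(sum(d$count) <= count_docs(store, "genome_size"))

  # single-species store: species 1, all other ranks 0
  single <- make_tree_store(setNames(c("1", "1"), c("1", "2")),
                            setNames(c("no rank", "species"), c("1", "2")))
  add_direct_values(single, "x", c("2" = 1))
  d1 <- tidy(report_x_per_rank(single, "x"))
  expect_equal(d1$count[d1$rank == "species"], 1)
  expect_equal(sum(d1$count), 1)

  # empty query gives zeros
  d0 <- tidy(report_x_per_rank(store, "tax_name(NoSuchTaxonAnywhere)"))
  expect_true(all(d0$count == 0))
})

test_that("arc reports count a query as a subset of another", {
  store <- synthetic_pipeline_store(n_species = 300, seed = 42L)
  same <- report_arc(store, "genome_size", "genome_size")
  expect_equal(tidy(same)$ratio, 1)
  # AND-refinement is anti-monotone
  narrowed <- report_arc(store, "tax_rank(species) AND genome_size>2e9",
                         "tax_rank(species)")
  d <- tidy(narrowed)
  expect_true(d$x_count <= d$y_count)
  # mirrors two explicit linear scans (species with assemblies / species)
  sp <- names(store$rank)[store$rank == "species"]
  with_asm <- unique(store$assemblies$taxon_id)
  got <- report_arc(store, "tax_rank(species) AND assembly_span",
                    "tax_rank(species)", include_estimates = FALSE)
  expect_equal(tidy(got)$x_count, sum(sp %in% with_asm))
  expect_equal(tidy(got)$y_count, length(sp))
  empty <- report_arc(store, "tax_name(None)", "tax_name(None)")
  expect_true(is.na(tidy(empty)$ratio))
})

test_that("histogram bins are half-open and conserve document counts", {
  store <- make_tree_store(setNames(c("1", rep("1", 4)),
                                    as.character(1:5)))
  add_direct_values(store, "v", c("2" = 1, "3" = 2, "4" = 3, "5" = 4),
                    direction = "none")
  rep <- report_histogram(store, "v", "v", width = 2)
  d <- tidy(rep)
  expect_equal(d$count[d$bin_lo == 1], 2)  # [1,3): {1,2}
  expect_equal(d$count[d$bin_lo == 3], 2)  # [3,5): {3,4}
  expect_equal(sum(d$count) + rep$payload$no_value,
               count_docs(store, "v"))
})

test_that("log-scaled histograms match direct binning of the value list", {
  store <- synthetic_pipeline_store(n_species = 300, seed = 42L)
  rep <- report_histogram(store, "tax_rank(species)", "genome_size",
                          bins = 12, log10_scale = TRUE)
  d <- tidy(rep)
  ids <- taxatlas:::matching_ids(store, parse_query("tax_rank(species)"))
  slots <- taxatlas:::slot_tbl(store, "taxon", "genome_size")
  vals <- slots$value_num[match(ids, slots$id)]
  expect_equal(sum(d$count), sum(!is.na(vals)))
  expect_equal(rep$payload$no_value, sum(is.na(vals)))
  for (i in seq_len(nrow(d))) {
    expect_equal(d$count[i],
                 sum(vals >= d$bin_lo[i] & vals < d$bin_hi[i], na.rm = TRUE),
                 tolerance = 0, info = paste("bin", i))
  }
  # excluding estimates drops exactly the estimate-only taxa
  rep2 <- report_histogram(store, "tax_rank(species)", "genome_size",
                           bins = 12, log10_scale = TRUE,
                           include_estimates = FALSE)
  direct_desc <- slots$id[slots$provenance %in% c("direct", "descendant")]
  expect_equal(sum(tidy(rep2)$count), sum(ids %in% direct_desc))
})

test_that("scatter switches to a count-conserving heatmap over the threshold", {
  store <- make_tree_store(setNames(rep("1", 5), as.character(1:5)))
  add_direct_values(store, "a", c("2" = 1, "3" = 2, "4" = 3),
                    direction = "none")
  add_direct_values(store, "b", c("2" = 10, "3" = 20, "4" = 30, "5" = 9),
                    direction = "none")
  pts <- report_scatter(store, "a", "a", "b", threshold = 10)
  expect_equal(pts$payload$mode, "points")
  expect_equal(nrow(tidy(pts)), 3)  # only docs with both values
  hm <- report_scatter(store, "a", "a", "b", threshold = 2)
  expect_equal(hm$payload$mode, "heatmap")
  expect_equal(sum(tidy(hm)$count), 3)
  expect_equal(hm$payload$n_points, 3)
})

test_that("scatter cells above the reference-standard thresholds match a direct filter", {
  store <- synthetic_pipeline_store(n_species = 300, seed = 42L)
  q <- "contig_n50 AND scaffold_n50"
  hm <- report_scatter(store, q, "contig_n50", "scaffold_n50",
                       threshold = 0, nbins = 25, log10_x = TRUE,
                       log10_y = TRUE, index = "assembly")
  cells <- tidy(hm)
  # brute-force count of assemblies meeting contig N50 > 1 Mb and
  # scaffold N50 > 10 Mb, via cells entirely inside the standard zone
  # (bins are data-driven, so compare against the filter on raw points)
  pts <- report_scatter(store, q, "contig_n50", "scaffold_n50",
                        threshold = Inf, index = "assembly")$payload$points
  want <- sum(pts$x > 1e6 & pts$y > 1e7)
  expect_equal(count_docs(store, "contig_n50>1000000 AND scaffold_n50>10000000",
                          index = "assembly"), want)
  expect_equal(sum(cells$count), nrow(pts))
})

test_that("tree reports span matched taxa up to their common ancestor", {
  store <- tiny_store()
  add_direct_values(store, "gs", c("5" = 1, "6" = 2), direction = "none")
  rep <- report_tree(store, "gs")
  d <- tidy(rep)
  # two sibling species -> parent genus plus the two tips
  expect_setequal(d$taxon_id, c("4", "5", "6"))
  expect_equal(rep$payload$root, "4")
  expect_equal(d$n_matched[d$taxon_id == "4"], 2)
  expect_true(all(d$matched[d$taxon_id %in% c("5", "6")]))

  # node set is the union of lineage paths truncated at the MRCA
  store2 <- synthetic_pipeline_store(n_species = 300, seed = 42L)
  rep2 <- report_tree(store2, "tax_rank(family)")
  d2 <- tidy(rep2)
  matched <- taxatlas:::matching_ids(store2, parse_query("tax_rank(family)"))
  mrca <- rep2$payload$root
  want <- unique(unlist(lapply(matched, function(id) {
    p <- c(id, store2$lineage[[id]])
    p[seq_len(which(p == mrca))]
  })))
  expect_setequal(d2$taxon_id, want)
  # totals reconcile with count()
  expect_equal(sum(d2$matched), count_docs(store2, "tax_rank(family)"))

  expect_error(report_tree(store2, "tax_name(NothingMatchesThis)"),
               class = "taxatlas_query_error")
})

test_that("tree node annotations copy fill provenance", {
  store <- synthetic_pipeline_store(n_species = 300, seed = 42L)
  rep <- report_tree(store, "tax_rank(genus)", attribute = "genome_size")
  d <- tidy(rep)
  slots <- taxatlas:::slot_tbl(store, "taxon", "genome_size")
  withr::local_seed(11)
  for (id in sample(d$taxon_id, min(20, nrow(d)))) {
    expect_equal(d$provenance[d$taxon_id == id],
                 if (id %in% slots$id) slots$provenance[slots$id == id]
                 else NA_character_,
                 info = id)
  }
})

test_that("newick export round-trips through an independent parser", {
  store <- synthetic_pipeline_store(n_species = 300, seed = 42L)
  withr::local_seed(909)
  fams <- names(store$rank)[store$rank %in% c("family", "order")]
  for (i in 1:10) {
    anchor <- store$sci_name[[sample(fams, 1)]]
    q <- paste0("tax_tree(", anchor, ") AND tax_rank(species)")
    if (count_docs(store, q) < 2) next
    rep <- report_tree(store, q)
    nwk <- export_newick(rep)
    tr <- ape::read.tree(text = nwk)
    d <- tidy(rep)
    n_tips <- sum(!d$taxon_id %in% d$parent_id)
    expect_equal(ape::Ntip(tr), n_tips, info = anchor)
    # labels survive (ape maps underscores back to spaces)
    got_labels <- gsub("_", " ", c(tr$tip.label, tr$node.label))
    expect_setequal(setdiff(got_labels, ""), d$scientific_name)
  }
})

test_that("phyloxml export is well-formed and carries annotations", {
  store <- tiny_store()
  add_direct_values(store, "gs", c("5" = 1, "6" = 2), direction = "both")
  fill_attribute(store, "gs")
  rep <- report_tree(store, "tax_tree(Felidae)", attribute = "gs")
  doc <- export_phyloxml(rep)
  reread <- xml2::read_xml(as.character(doc))
  clades <- xml2::xml_find_all(reread, "//*[local-name()='clade']")
  expect_equal(length(clades), nrow(tidy(rep)))
  names <- xml2::xml_text(
    xml2::xml_find_all(reread, "//*[local-name()='name']"))
  expect_true("Panthera leo" %in% names)
  props <- xml2::xml_find_all(reread, "//*[local-name()='property']")
  expect_true(length(props) > 0)
})

test_that("report objects expose tidy, glance and autoplot", {
  store <- synthetic_pipeline_store(n_species = 300, seed = 42L)
  rep <- report_histogram(store, "tax_rank(species)", "genome_size",
                          bins = 8)
  expect_s3_class(glance(rep), "tbl_df")
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
  p2 <- ggplot2::autoplot(report_x_per_rank(store, "genome_size"))
  expect_s3_class(p2, "ggplot")
  sc <- report_scatter(store, "genome_size", "genome_size",
                       "chromosome_number", threshold = 1e6)
  expect_s3_class(ggplot2::autoplot(sc), "ggplot")
})
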