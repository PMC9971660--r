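test_that("star tree: parent from children, empty sibling from parent", {
  # root "1" with children 2,3,4; 2 and 3 measured, 4 empty
  store <- make_tree_store(setNames(c("1", "1", "1", "1"),
                                    c("1", "2", "3", "4")))
  add_direct_values(store, "genome_size", c("2" = 10, "3" = 20),
                    ancestor_summary = "median")
  fill_attribute(store, "genome_size")
  slots <- taxatlas:::slot_tbl(store, "taxon", "genome_size")
  root_row <- slots[slots$id == "1", ]
  expect_equal(root_row$value_num, 15)
  expect_equal(root_row$provenance, "descendant")
  tip_row <- slots[slots$id == "4", ]
  expect_equal(tip_row$value_num, 15)
  expect_equal(tip_row$provenance, "ancestor")
  expect_equal(tip_row$source_id, "1")
  # measured tips keep their direct values
  expect_equal(slots$provenance[slots$id %in% c("2", "3")],
               c("direct", "direct"))
})

test_that("a lone measured node is left untouched", {
  store <- make_tree_store(setNames("1", "1"))
  add_direct_values(store, "genome_size", c("1" = 7))
  res <- fill_attribute(store, "genome_size")
  slots <- taxatlas:::slot_tbl(store, "taxon", "genome_size")
  expect_equal(nrow(slots), 1)
  expect_equal(slots$provenance, "direct")
  expect_equal(res$written, 0)
})

test_that("random trees match the recursive oracle in all four directions", {
  withr::local_seed(101)
  for (rep in 1:25) {
    n <- sample(20:120, 1)
    store <- make_tree_store(random_parent_map(n))
    tips <- names(store$parent)[lengths(store$children) == 0]
    informative <- sample(names(store$parent),
                          max(1, round(0.3 * length(tips))))
    vals <- setNames(round(stats::rlnorm(length(informative),
                                         log(1e9), 0.5)), informative)
    dirn <- sample(c("up", "down", "both"), 1)
    stat <- sample(c("median", "mean", "min", "max"), 1)
    limit <- if (rep %% 3 == 0) sample(names(store$parent), 1) else NULL
    add_direct_values(store, "trait", vals, direction = dirn,
                      ancestor_summary = stat, limit = limit)
    fill_attribute(store, "trait")
    expect_fill_matches_oracle(store, "trait")
  }
})

test_that("keyword attributes propagate by mode with enum tie-breaks", {
  withr::local_seed(202)
  enum <- c("complete genome", "chromosome", "scaffold", "contig")
  for (rep in 1:5) {
    store <- make_tree_store(random_parent_map(60))
    informative <- sample(names(store$parent), 20)
    vals <- setNames(sample(enum, 20, replace = TRUE), informative)
    add_direct_values(store, "assembly_level", vals,
                      type = "ordered_keyword", enum = enum,
                      direction = "both", ancestor_summary = "mode",
                      summary = "priority-by-enum")
    fill_attribute(store, "assembly_level")
    expect_fill_matches_oracle(store, "assembly_level")
  }
})

test_that("no taxon inside a clade barrier receives any estimate", {
  # root 1 -> {2 (barrier clade root), 5}; 2 -> {3, 4}; values outside
  parent <- setNames(c("1", "1", "2", "2", "1", "5"),
                     c("1", "2", "3", "4", "5", "6"))
  store <- make_tree_store(parent)
  add_direct_values(store, "plastid_span", c("6" = 150000, "3" = 99),
                    direction = "both", limit = "Tax2")
  fill_attribute(store, "plastid_span")
  slots <- taxatlas:::slot_tbl(store, "taxon", "plastid_span")
  inside <- c("2", "3", "4")
  est <- slots[slots$provenance != "direct", ]
  expect_false(any(est$id %in% inside))
  # the measured value inside the barrier never leaks out
  expect_false(any(est$value_num == 99))
  # direct values inside the barrier are conserved
  expect_equal(slots$value_num[slots$id == "3"], 99)
  expect_fill_matches_oracle(store, "plastid_span")
})

test_that("a rank ceiling stops upward and downward propagation", {
  # kingdom (2) above family (3) above species (4,5); limit rank family
  parent <- setNames(c("1", "1", "2", "3", "3"),
                     c("1", "2", "3", "4", "5"))
  rank <- setNames(c("no rank", "kingdom", "family", "species", "species"),
                   names(parent))
  store <- make_tree_store(parent, rank)
  add_direct_values(store, "trait", c("4" = 10),
                    direction = "both", limit = list(rank = "family"))
  fill_attribute(store, "trait")
  slots <- taxatlas:::slot_tbl(store, "taxon", "trait")
  expect_setequal(slots$id, c("4", "3", "5"))  # nothing above the family
  expect_equal(slots$provenance[slots$id == "3"], "descendant")
  expect_equal(slots$provenance[slots$id == "5"], "ancestor")
})

test_that("fill is idempotent and conserves direct summaries bit-for-bit", {
  store <- make_tree_store(random_parent_map(80))
  withr::local_seed(303)
  informative <- sample(names(store$parent), 25)
  add_direct_values(store, "trait",
                    setNames(stats::runif(25, 1, 100), informative))
  r1 <- fill_attribute(store, "trait")
  slots1 <- taxatlas:::slot_tbl(store, "taxon", "trait")
  direct1 <- slots1[slots1$provenance == "direct", ]
  r2 <- fill_attribute(store, "trait")
  slots2 <- taxatlas:::slot_tbl(store, "taxon", "trait")
  expect_equal(r2$written, 0)
  expect_identical(slots2[slots2$provenance == "direct", ], direct1)
  expect_identical(dplyr::arrange(slots2, id), dplyr::arrange(slots1, id))
})

test_that("provenance is sound: sources hold the values they lend", {
  store <- make_tree_store(random_parent_map(100))
  withr::local_seed(404)
  informative <- sample(names(store$parent), 30)
  add_direct_values(store, "trait",
                    setNames(round(stats::runif(30, 1, 100)), informative))
  fill_attribute(store, "trait")
  slots <- taxatlas:::slot_tbl(store, "taxon", "trait")
  by_id <- setNames(slots$value_num, slots$id)
  anc <- slots[slots$provenance == "ancestor", ]
  for (i in seq_len(nrow(anc))) {
    # every ancestor-derived value equals its source taxon's stored value,
    # and the source lies on the lineage
    expect_equal(anc$value_num[i], unname(by_id[anc$source_id[i]]))
    expect_true(anc$source_id[i] %in% store$lineage[[anc$id[i]]])
  }
  # descendant-derived estimates are reproducible from the subtree's
  # direct values alone
  desc <- slots[slots$provenance == "descendant", ]
  direct_ids <- slots$id[slots$provenance == "direct"]
  for (i in seq_len(nrow(desc))) {
    below <- taxatlas:::descendant_ids(store, desc$id[i])
    expect_true(any(direct_ids %in% below))
  }
})

test_that("min and max propagation bound the subtree's direct values", {
  withr::local_seed(505)
  for (stat in c("min", "max")) {
    store <- make_tree_store(random_parent_map(60))
    tips <- names(store$parent)[lengths(store$children) == 0]
    informative <- sample(tips, min(20, length(tips)))
    vals <- setNames(stats::runif(length(informative), 0, 1000),
                     informative)
    add_direct_values(store, "trait", vals, direction = "up",
                      ancestor_summary = stat)
    fill_attribute(store, "trait")
    slots <- taxatlas:::slot_tbl(store, "taxon", "trait")
    desc <- slots[slots$provenance == "descendant", ]
    for (i in seq_len(nrow(desc))) {
      below <- taxatlas:::descendant_ids(store, desc$id[i])
      sub_direct <- vals[names(vals) %in% below]
      if (stat == "min") expect_true(desc$value_num[i] <= min(sub_direct))
      else expect_true(desc$value_num[i] >= max(sub_direct))
    }
  }
})

test_that("adding one tip value only perturbs its root path and dependants", {
  store <- make_tree_store(random_parent_map(60))
  withr::local_seed(606)
  informative <- sample(names(store$parent)[-1], 15)
  vals <- setNames(round(stats::runif(15, 1, 100)), informative)
  add_direct_values(store, "trait", vals)
  fill_attribute(store, "trait")
  before <- taxatlas:::slot_tbl(store, "taxon", "trait")

  # new measured tip: re-fill and diff against a full recompute
  tip <- setdiff(names(store$parent)[lengths(store$children) == 0],
                 informative)[1]
  add_direct_values(store, "trait", c(vals, setNames(999, tip)))
  fill_attribute(store, "trait")
  after <- taxatlas:::slot_tbl(store, "taxon", "trait")
  expect_fill_matches_oracle(store, "trait")

  key <- function(tb) setNames(
    paste(tb$value_num, tb$provenance, tb$source_id), tb$id)
  kb <- key(before); ka <- key(after)
  changed <- union(setdiff(names(ka), names(kb)),
                   names(ka)[ka[names(ka)] != kb[names(ka)]])
  changed <- changed[!is.na(changed)]
  # only the tip's root path can gain new descendant-derived values, and
  # only nodes served by an ancestor on that path can see their inherited
  # value change; unrelated subtrees stay untouched
  path <- c(tip, store$lineage[[tip]])
  src_of <- function(k, id) {
    if (!id %in% names(k)) NA_character_ else strsplit(k[[id]], " ")[[1]][3]
  }
  for (id in changed) {
    on_path <- id %in% path
    old_src <- src_of(kb, id)
    new_src <- src_of(ka, id)
    expect_true(on_path || (!is.na(old_src) && old_src %in% path) ||
                  (!is.na(new_src) && new_src %in% path),
                info = paste("unexpected change at node", id))
  }
})

test_that("fill_all fills only eligible attributes and reports counts", {
  store <- make_tree_store(random_parent_map(30))
  withr::local_seed(707)
  add_direct_values(store, "fillable",
                    setNames(stats::runif(5, 1, 9),
                             sample(names(store$parent), 5)))
  add_direct_values(store, "static",
                    setNames(stats::runif(5, 1, 9),
                             sample(names(store$parent), 5)),
                    direction = "none")
  res <- fill_all(store)
  expect_equal(res$attribute, "fillable")
  expect_true(res$written > 0)
  expect_error(fill_attribute(store, "static"),
               class = "taxatlas_config_error")
  expect_error(fill_attribute(store, "nonexistent"),
               class = "taxatlas_config_error")
  # assembly attributes are never filled
  define_attribute(store, "asm_attr", index = "assembly", type = "float",
                   traverse = list(direction = "both"))
  expect_error(fill_attribute(store, "asm_attr"),
               class = "taxatlas_config_error")
})
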