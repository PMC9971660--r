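# Shared fixtures (built in code) and independent oracles.

# A small hand-written taxonomy:
#   Root
#   +- Animalia (kingdom)
#   |  +- Felidae (family)
#   |  |  +- Panthera (genus)
#   |  |     +- Panthera leo, Panthera onca (species)
#   |  +- Canidae (family)
#   |     +- Canis (genus)
#   |        +- Canis lupus (species)
#   |        +- Vulpes shared (species)      <- homonym partner A
#   +- Plantae (kingdom)
#      +- Rosaceae (family)
#         +- Rosa (genus)
#            +- Rosa canina (species)
#            +- Vulpes shared (species)      <- homonym partner B
# plus a synonym row: "Leo africanus" -> Panthera leo
write_tiny_taxdump <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- c(
    "1\t|\t1\t|\tno rank\t|",
    "2\t|\t1\t|\tkingdom\t|",
    "3\t|\t2\t|\tfamily\t|",
    "4\t|\t3\t|\tgenus\t|",
    "5\t|\t4\t|\tspecies\t|",
    "6\t|\t4\t|\tspecies\t|",
    "7\t|\t2\t|\tfamily\t|",
    "8\t|\t7\t|\tgenus\t|",
    "9\t|\t8\t|\tspecies\t|",
    "10\t|\t8\t|\tspecies\t|",
    "11\t|\t1\t|\tkingdom\t|",
    "12\t|\t11\t|\tfamily\t|",
    "13\t|\t12\t|\tgenus\t|",
    "14\t|\t13\t|\tspecies\t|",
    "15\t|\t13\t|\tspecies\t|")
  nms <- c(
    "1\t|\tRoot\t|\t\t|\tscientific name\t|",
    "2\t|\tAnimalia\t|\t\t|\tscientific name\t|",
    "3\t|\tFelidae\t|\t\t|\tscientific name\t|",
    "4\t|\tPanthera\t|\t\t|\tscientific name\t|",
    "5\t|\tPanthera leo\t|\t\t|\tscientific name\t|",
    "5\t|\tLeo africanus\t|\t\t|\tsynonym\t|",
    "5\t|\tlion\t|\t\t|\tcommon name\t|",
    "5\t|\tqqPanLeo1\t|\t\t|\ttol_id\t|",
    "6\t|\tPanthera onca\t|\t\t|\tscientific name\t|",
    "7\t|\tCanidae\t|\t\t|\tscientific name\t|",
    "8\t|\tCanis\t|\t\t|\tscientific name\t|",
    "9\t|\tCanis lupus\t|\t\t|\tscientific name\t|",
    "10\t|\tVulpes shared\t|\t\t|\tscientific name\t|",
    "11\t|\tPlantae\t|\t\t|\tscientific name\t|",
    "12\t|\tRosaceae\t|\t\t|\tscientific name\t|",
    "13\t|\tRosa\t|\t\t|\tscientific name\t|",
    "14\t|\tRosa canina\t|\t\t|\tscientific name\t|",
    "15\t|\tVulpes shared\t|\t\t|\tscientific name\t|")
  writeLines(nodes, file.path(dir, "nodes.dmp"))
  writeLines(nms, file.path(dir, "names.dmp"))
  dir
}

tiny_store <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_tiny_taxdump(dir)
  store <- taxatlas_store()
  load_taxdump(store, dir)
  store
}

# store built from the seeded synthetic pipeline: taxonomy + trait tables
# + assemblies, imported and filled. Memoised per (n_species, seed).
synthetic_pipeline_store <- local({
  cache <- new.env(parent = emptyenv())
  function(n_species = 300, seed = 42L, fill = TRUE,
           spec = synth_fixture_spec(n_species = n_species)) {
    key <- paste(n_species, seed, fill, digest_spec(spec))
    if (!is.null(cache[[key]])) return(cache[[key]])
    root <- file.path(tempdir(), paste0("synthfix-", abs(seed), "-",
                                        n_species, "-", digest_spec(spec)))
    tx <- synth_taxonomy(file.path(root, "taxdump"), spec, seed)
    store <- taxatlas_store()
    load_taxdump(store, tx$dir)
    synth_attributes(file.path(root, "data"), store, spec, seed)
    synth_assemblies(file.path(root, "data"), store, spec, seed)
    index_directory(store, file.path(root, "data"), write_logs = FALSE)
    if (fill) fill_all(store)
    attr(store, "fixture_root") <- root
    cache[[key]] <- store
    store
  }
})

digest_spec <- function(spec) {
  paste0("h", sum(utils::head(utf8ToInt(paste(
    names(spec), unlist(spec), collapse = "")), 500) *
      seq_len(min(500, nchar(paste(names(spec), unlist(spec),
                                   collapse = ""))))) %% 99991)
}

# --------------------------------------------------------------------------
# independent oracles

# plain dynamic-programming Levenshtein distance (independent of adist)
oracle_edit_distance <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(a) + 1, length(b) + 1)
  d[, 1] <- 0:length(a); d[1, ] <- 0:length(b)
  for (i in seq_along(a)) for (j in seq_along(b)) {
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (a[i] != b[j]))
  }
  d[length(a) + 1, length(b) + 1]
}

# naive recursive fill oracle. Returns list(value=named vec, provenance=,
# source=). Mirrors the contract directly: descendant values by explicit
# recursion over children, ancestor values by walking up the lineage.
oracle_fill <- function(store, attribute) {
  def <- store$attr_defs[[paste0("taxon.", attribute)]]
  slots <- taxatlas:::slot_tbl(store, "taxon", attribute)
  direct <- slots[slots$provenance == "direct", ]
  numeric_attr <- def$type %in% c("integer", "float", "date")
  dval <- if (numeric_attr) setNames(direct$value_num, direct$id)
          else setNames(direct$value_chr, direct$id)
  enum <- def$constraints$enum
  stat <- def$traverse$ancestor_summary
  dirn <- def$traverse$direction
  excluded <- taxatlas:::barrier_excluded(store, def$traverse$limit,
                                          taxatlas:::bfs_order(store))

  stat_fn <- function(v) {
    if (numeric_attr) {
      switch(stat, median = stats::median(v), mean = mean(v),
             min = min(v), max = max(v),
             mode = as.numeric(taxatlas:::mode_value(v)))
    } else {
      switch(stat, mode = taxatlas:::mode_value(v, enum),
             "priority-by-enum" = v[which.min(match(v, enum))],
             min = v[which.min(taxatlas:::enum_score(v, enum))],
             max = v[which.max(taxatlas:::enum_score(v, enum))])
    }
  }

  memo <- new.env(parent = emptyenv())
  # value available to a parent from this subtree: direct, else recursive
  # combination of children (NULL if none)
  up_value <- function(id) {
    if (id %in% excluded) return(NULL)
    if (!is.null(memo[[id]])) return(memo[[id]]$v)
    if (id %in% names(dval)) { memo[[id]] <- list(v = dval[[id]]); return(dval[[id]]) }
    ch <- store$children[[id]]
    vals <- list()
    for (c_id in ch) {
      v <- up_value(c_id)
      if (!is.null(v)) vals[[length(vals) + 1]] <- v
    }
    v <- if (length(vals)) stat_fn(unlist(vals)) else NULL
    memo[[id]] <- list(v = v)
    v
  }

  value <- list(); provenance <- list(); source <- list()
  for (id in names(store$parent)) {
    if (id %in% excluded) next
    if (id %in% names(dval)) {
      value[[id]] <- dval[[id]]; provenance[[id]] <- "direct"
      next
    }
    if (dirn %in% c("up", "both")) {
      v <- up_value(id)
      if (!is.null(v)) {
        value[[id]] <- v; provenance[[id]] <- "descendant"
        next
      }
    }
    if (dirn %in% c("down", "both")) {
      # nearest ancestor with a value of its own (direct, or
      # descendant-derived when the up pass runs), not crossing a barrier
      for (anc in store$lineage[[id]]) {
        if (anc %in% excluded) break
        av <- if (anc %in% names(dval)) dval[[anc]]
              else if (dirn == "both") up_value(anc)
              else NULL
        if (!is.null(av)) {
          value[[id]] <- av; provenance[[id]] <- "ancestor"
          source[[id]] <- anc
          break
        }
      }
    }
  }
  list(value = value, provenance = provenance, source = source)
}

# per-attribute value maps for the naive query matcher: plain named
# vectors so the per-document loop stays cheap
oracle_attr_maps <- function(store, index) {
  defs <- Filter(function(d) d$index == index, store$attr_defs)
  names(defs) <- vapply(defs, `[[`, "", "name")
  lapply(defs, function(def) {
    slots <- taxatlas:::slot_tbl(store, index, def$name)
    raws <- taxatlas:::raw_tbl(store, index, def$name)
    rc <- table(raws$id)
    list(
      def = def,
      num = setNames(slots$value_num, slots$id),
      chr = setNames(tolower(slots$value_chr), slots$id),
      lst = setNames(lapply(slots$value_list, tolower), slots$id),
      provenance = setNames(slots$provenance, slots$id),
      vmin = setNames(slots$min, slots$id),
      vmax = setNames(slots$max, slots$id),
      raw_counts = setNames(as.numeric(rc), names(rc)))
  })
}

# naive per-document matcher over a parsed query: every document is
# examined against every term with straight-line conditional logic
oracle_match <- function(store, query, index = "taxon",
                         include_estimates = TRUE,
                         maps = oracle_attr_maps(store, index)) {
  ids <- if (index == "taxon") names(store$parent)
         else store$assemblies$assembly_id
  owner <- if (index == "assembly")
    setNames(store$assemblies$taxon_id, store$assemblies$assembly_id)

  resolve_named <- function(arg) {
    nt <- store$names_tbl
    if (!is.na(arg$name_class)) nt <- nt[nt$name_class == arg$name_class, ]
    pat <- utils::glob2rx(tolower(arg$pattern))
    unique(c(nt$taxon_id[grepl(pat, nt$name_lower)],
             intersect(arg$pattern, names(store$parent))))
  }

  # resolve each taxon term's name arguments once, up front
  prepped <- lapply(query$terms, function(term) {
    if (term$kind != "taxon") return(term)
    term$resolved <- lapply(term$args, function(arg) {
      if (term$fn %in% c("tax_name", "tax_tree", "tax_lineage"))
        resolve_named(arg)
      else arg$pattern
    })
    term
  })
  anchors <- unique(unlist(lapply(prepped, function(t2) {
    if (t2$kind != "taxon" ||
        !t2$fn %in% c("tax_eq", "tax_name", "tax_tree")) return(NULL)
    unlist(t2$resolved[!vapply(t2$args, `[[`, TRUE, "negated")])
  })))

  match_taxon_term <- function(tid, term) {
    self_lin <- c(tid, store$lineage[[tid]])
    arg_match <- function(k) {
      arg <- term$args[[k]]
      res <- term$resolved[[k]]
      switch(term$fn,
        tax_eq = tid == arg$pattern,
        tax_name = tid %in% res,
        tax_tree = any(res %in% self_lin),
        tax_rank = store$rank[[tid]] == tolower(arg$pattern),
        tax_depth = {
          d <- as.numeric(arg$pattern)
          any(vapply(anchors, function(a) {
            if (a == tid) return(TRUE)
            pos <- match(a, store$lineage[[tid]])
            !is.na(pos) && pos <= d
          }, TRUE))
        },
        tax_lineage = length(res) == 1 && tid %in% store$lineage[[res]])
    }
    neg <- vapply(term$args, `[[`, TRUE, "negated")
    base <- if (any(!neg)) any(vapply(which(!neg), arg_match, TRUE))
            else TRUE
    base && !any(vapply(which(neg), arg_match, TRUE))
  }

  match_attr_term <- function(id, term) {
    m <- maps[[term$attribute]]
    def <- m$def
    est_ok <- include_estimates
    inner <- function() {
      if (term$modifier == "length") {
        n <- m$raw_counts[id]
        if (is.na(n)) n <- 0
        qv <- as.numeric(term$values)
        return(switch(term$operator,
          "=" = n > 0 && any(n == qv), "!=" = n > 0 && !any(n == qv),
          "<" = n > 0 && any(n < qv), "<=" = n > 0 && any(n <= qv),
          ">=" = n > 0 && any(n >= qv), ">" = n > 0 && any(n > qv),
          "exists" = n > 0))
      }
      prov <- m$provenance[id]
      if (is.na(prov)) return(FALSE)
      if (!est_ok && !prov %in% c("direct", "descendant")) return(FALSE)
      if (term$operator == "exists") return(TRUE)
      if (term$modifier %in% c("min", "max")) {
        x <- if (term$modifier == "min") m$vmin[[id]] else m$vmax[[id]]
        if (is.na(x)) return(FALSE)
        qv <- vapply(term$values, taxatlas:::coerce_query_value, 0,
                     def = def)
        return(switch(term$operator,
          "=" = any(x == qv), "!=" = !any(x == qv),
          "<" = any(x < qv), "<=" = any(x <= qv),
          ">=" = any(x >= qv), ">" = any(x > qv)))
      }
      if (def$type == "list") {
        hit <- any(m$lst[[id]] %in% tolower(term$values))
        return(if (term$operator == "=") hit else !hit)
      }
      if (def$type == "keyword") {
        hit <- m$chr[[id]] %in% tolower(term$values)
        return(if (term$operator == "=") hit else !hit)
      }
      x <- m$num[[id]]
      if (is.na(x)) return(FALSE)
      qv <- vapply(term$values, taxatlas:::coerce_query_value, 0, def = def)
      switch(term$operator,
        "=" = any(x == qv), "!=" = !any(x == qv),
        "<" = any(x < qv), "<=" = any(x <= qv),
        ">=" = any(x >= qv), ">" = any(x > qv))
    }
    out <- inner()
    if (isTRUE(term$negated)) !out else out
  }

  keep <- vapply(ids, function(id) {
    tid <- if (index == "assembly") owner[[id]] else id
    for (term in prepped) {
      ok <- if (term$kind == "taxon") match_taxon_term(tid, term)
            else match_attr_term(id, term)
      if (!ok) return(FALSE)
    }
    TRUE
  }, TRUE)
  sort_ids(ids[keep])
}

sort_ids <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) x[order(num)] else sort(as.character(x))
}

# random grammar-driven query generator for oracle-equivalence checks
random_query <- function(store, index = "taxon") {
  defs <- Filter(function(d) d$index == index, store$attr_defs)
  names(defs) <- vapply(defs, `[[`, "", "name")
  attrs <- names(defs)
  taxa_names <- store$names_tbl$name[
    store$names_tbl$name_class == "scientific name"]
  rand_taxon_term <- function() {
    fn <- sample(c("tax_tree", "tax_tree", "tax_rank", "tax_name",
                   "tax_eq"), 1)
    switch(fn,
      tax_tree = {
        nm <- sample(taxa_names, 1)
        if (stats::runif(1) < 0.25) {
          paste0("tax_tree(", nm, ",!", sample(taxa_names, 1), ")")
        } else paste0("tax_tree(", nm, ")")
      },
      tax_rank = paste0("tax_rank(", sample(unique(store$rank), 1), ")"),
      tax_name = paste0("tax_name(", sample(taxa_names, 1), ")"),
      tax_eq = paste0("tax_eq(", sample(names(store$parent), 1), ")"))
  }
  rand_attr_term <- function() {
    a <- sample(attrs, 1)
    def <- defs[[a]]
    slots <- taxatlas:::slot_tbl(store, index, a)
    if (!nrow(slots)) return(a)
    if (def$type %in% c("integer", "float")) {
      v <- stats::quantile(slots$value_num, stats::runif(1), na.rm = TRUE,
                           names = FALSE)
      mod <- sample(c("", "", "", "min(", "max(", "length("), 1)
      lhs <- if (mod == "") a else paste0(mod, a, ")")
      if (mod == "length(") v <- sample(0:3, 1)
      op <- sample(c("<", "<=", "=", ">=", ">", "!="), 1)
      paste0(lhs, op, format(v, scientific = FALSE))
    } else if (def$type == "date") {
      v <- slots$value_chr[sample(nrow(slots), 1)]
      paste0(a, sample(c("<", ">=", ">"), 1), v)
    } else if (def$type == "ordered_keyword") {
      v <- sample(def$constraints$enum, 1)
      paste0(a, sample(c("=", "!=", ">=", "<"), 1), v)
    } else if (def$type == "list") {
      if (stats::runif(1) < 0.5) {
        paste0("length(", a, ")>", sample(0:2, 1))
      } else paste0(a, "=", "PROJA,PROJB")
    } else {
      slots_v <- unique(slots$value_chr)
      paste0(a, sample(c("=", "!="), 1), sample(slots_v, 1))
    }
  }
  n_tax <- sample(0:1, 1)
  n_att <- sample(if (n_tax == 0) 1:2 else 0:2, 1)
  terms <- c(replicate(n_tax, rand_taxon_term()),
             replicate(n_att, rand_attr_term()))
  if (!length(terms)) terms <- rand_attr_term()
  paste(terms, collapse = " AND ")
}

# --------------------------------------------------------------------------
# direct store construction for fill tests

# build a store from a parent map (ids "1".."n"; parent of the root is
# itself); optional rank vector, default "clade" with a "no rank" root
make_tree_store <- function(parent, rank = NULL) {
  ids <- names(parent)
  if (is.null(rank)) {
    rank <- setNames(rep("clade", length(ids)), ids)
    rank[parent == ids] <- "no rank"
  }
  dir <- file.path(tempdir(), paste0("tree-", paste0(sample(letters, 8),
                                                     collapse = "")))
  dir.create(dir)
  writeLines(paste0(ids, "\t|\t", parent, "\t|\t", rank[ids], "\t|"),
             file.path(dir, "nodes.dmp"))
  writeLines(paste0(ids, "\t|\tTax", ids, "\t|\t\t|\tscientific name\t|"),
             file.path(dir, "names.dmp"))
  store <- taxatlas_store()
  load_taxdump(store, dir)
  unlink(dir, recursive = TRUE)
  store
}

# random rooted tree as a parent map over ids "1".."n" (root = "1")
random_parent_map <- function(n) {
  parent <- c("1", vapply(2:n, function(i)
    as.character(sample.int(i - 1, 1)), ""))
  setNames(parent, as.character(seq_len(n)))
}

# register an attribute and inject direct values (named vector id -> value)
add_direct_values <- function(store, name, values, type = "float",
                              direction = "both",
                              ancestor_summary = NULL, limit = NULL,
                              enum = NULL, summary = NULL) {
  define_attribute(
    store, name, index = "taxon", type = type,
    constraints = if (is.null(enum)) list() else list(enum = enum),
    summary = summary,
    traverse = list(direction = direction,
                    ancestor_summary = ancestor_summary, limit = limit),
    overwrite = TRUE)
  if (length(values)) {
    numericish <- type %in% c("integer", "float", "date")
    store$raws[[paste0("taxon.", name)]] <- tibble::tibble(
      id = names(values),
      value_chr = if (numericish) NA_character_ else as.character(values),
      value_num = if (numericish) as.numeric(values) else NA_real_,
      source_name = "fixture", source_url = NA_character_,
      imported_at = "2022-11-16")
  } else {
    store$raws[[paste0("taxon.", name)]] <- NULL
  }
  store$slots[[paste0("taxon.", name)]] <- NULL
  taxatlas:::summarise_attribute(store, name, "taxon")
  invisible(store)
}

# compare a filled attribute against the recursive oracle
expect_fill_matches_oracle <- function(store, attribute) {
  slots <- taxatlas:::slot_tbl(store, "taxon", attribute)
  def <- store$attr_defs[[paste0("taxon.", attribute)]]
  numericish <- def$type %in% c("integer", "float", "date")
  oracle <- oracle_fill(store, attribute)
  est <- slots[slots$provenance != "direct", ]
  oracle_est_ids <- names(oracle$provenance)[
    unlist(oracle$provenance) != "direct"]
  if (is.null(oracle_est_ids)) oracle_est_ids <- character()
  expect_setequal(as.character(est$id), oracle_est_ids)
  for (i in seq_len(nrow(est))) {
    id <- est$id[i]
    expect_equal(est$provenance[i], oracle$provenance[[id]],
                 info = paste("provenance of", id))
    got <- if (numericish) est$value_num[i] else est$value_chr[i]
    expect_equal(got, unname(oracle$value[[id]]),
                 info = paste("value of", id))
    if (est$provenance[i] == "ancestor") {
      expect_equal(est$source_id[i], oracle$source[[id]],
                   info = paste("source of", id))
    }
  }
}
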