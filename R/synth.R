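# Seeded synthetic fixtures: taxonomies in taxdump format, trait tables
# with configurable missingness and clade effects, and assembly tables.
# These emulate the engine's real inputs (a backbone taxonomy; C-value-like
# numeric traits; chromosome-number-like small integers; assembly-level-like
# ordered keywords; project target lists) so the full pipeline runs and is
# testable without any download.

SYLLABLES <- c("ba", "ce", "di", "fo", "gu", "ha", "ki", "lo", "mu", "ne",
               "pi", "ro", "sa", "tu", "ve", "xa", "zo", "ch", "br", "pl")

make_names <- function(n, n_syllables = 3) {
  out <- character(n)
  used <- character()
  for (i in seq_len(n)) {
    repeat {
      nm <- paste(sample(SYLLABLES, n_syllables, replace = TRUE),
                  collapse = "")
      if (!nm %in% used) break
    }
    used <- c(used, nm)
    out[i] <- paste0(toupper(substr(nm, 1, 1)), substr(nm, 2, nchar(nm)))
  }
  out
}

#' Fixture generation parameters
#'
#' Defaults define the reference synthetic study conditions used throughout
#' the test-suite: a 1,000-species taxonomy over six higher ranks, 30%
#' attribute missingness, three families whose genome-size-like trait is
#' shifted four-fold against lognormal within-family noise (sdlog 0.25),
#' and roughly one assembly per second species.
#'
#' @param n_species number of species tips.
#' @param ranks higher ranks between the root and species, root-most first.
#' @param n_homonyms species binomials duplicated under a second family.
#' @param n_synonyms extra synonym name rows.
#' @param missingness fraction of species without a direct trait value.
#' @param n_shifted_clades families with a shifted genome-size trait.
#' @param shift_factor multiplicative clade shift (set well above noise so
#'   descendant estimates are statistically distinguishable).
#' @param noise_sdlog lognormal within-family noise on the trait.
#' @param assembly_fraction fraction of species with assemblies.
#' @param assemblies_per_species mean extra assemblies per sequenced
#'   species.
#' @return a list of class `taxatlas_fixture_spec`.
#' @export
synth_fixture_spec <- function(n_species = 1000,
                               ranks = c("kingdom", "phylum", "class",
                                         "order", "family", "genus"),
                               n_homonyms = 0, n_synonyms = 0,
                               missingness = 0.3, n_shifted_clades = 3,
                               shift_factor = 4, noise_sdlog = 0.25,
                               assembly_fraction = 0.5,
                               assemblies_per_species = 0.5) {
  stopifnot(n_species >= 1, missingness >= 0, missingness <= 1)
  structure(
    list(n_species = n_species, ranks = ranks, n_homonyms = n_homonyms,
         n_synonyms = n_synonyms, missingness = missingness,
         n_shifted_clades = n_shifted_clades, shift_factor = shift_factor,
         noise_sdlog = noise_sdlog, assembly_fraction = assembly_fraction,
         assemblies_per_species = assemblies_per_species),
    class = "taxatlas_fixture_spec")
}

#' Generate a synthetic taxonomy in taxdump format
#'
#' Builds a single-root tree with the requested ranks, writes `nodes.dmp`
#' and `names.dmp` in the classic `"\t|\t"` dialect, and optionally injects
#' homonyms (identical species binomials under different families, to
#' exercise higher-rank disambiguation) and synonym name rows.
#'
#' @param dir output directory (created if needed).
#' @param spec a [synth_fixture_spec()].
#' @param seed integer seed; fully determines the output.
#' @return invisibly, a list with `dir` and the `nodes` tibble
#'   (`taxon_id`, `parent_id`, `rank`, `scientific_name`).
#' @export
synth_taxonomy <- function(dir, spec = synth_fixture_spec(), seed = 1L) {
  stopifnot(inherits(spec, "taxatlas_fixture_spec"))
  if (spec$n_species < 1) stop_taxatlas("n_species must be >= 1",
                                        "taxatlas_config_error")
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  ranks <- spec$ranks
  n_sp <- spec$n_species
  # geometric interpolation of level sizes from 2 up to ~ n_species / 3
  n_levels <- length(ranks)
  top <- max(2, min(5, n_sp))
  bottom <- max(top, ceiling(n_sp / 3))
  sizes <- pmax(2, pmin(round(exp(seq(log(top), log(bottom),
                                      length.out = n_levels))), n_sp))

  next_id <- 1L
  new_id <- function() {
    id <- as.character(next_id)
    next_id <<- next_id + 1L
    id
  }

  root <- new_id()
  nodes <- list(tibble(taxon_id = root, parent_id = root, rank = "no rank",
                       scientific_name = "Root"))
  prev_ids <- root
  for (li in seq_len(n_levels)) {
    k <- sizes[li]
    ids <- vapply(seq_len(k), function(i) new_id(), "")
    parents <- sample(prev_ids, k, replace = TRUE)
    # every parent keeps at least one child where possible
    if (length(prev_ids) <= k) parents[seq_along(prev_ids)] <- prev_ids
    nodes[[length(nodes) + 1L]] <- tibble(
      taxon_id = ids, parent_id = parents, rank = ranks[li],
      scientific_name = make_names(k))
    prev_ids <- ids
  }
  genera <- nodes[[length(nodes)]]
  sp_parent <- sample(genera$taxon_id, n_sp, replace = TRUE)
  if (length(genera$taxon_id) <= n_sp)
    sp_parent[seq_len(nrow(genera))] <- genera$taxon_id
  genus_name <- setNames(genera$scientific_name, genera$taxon_id)
  epithet <- tolower(make_names(n_sp, n_syllables = 4))
  sp_ids <- vapply(seq_len(n_sp), function(i) new_id(), "")
  species <- tibble(
    taxon_id = sp_ids, parent_id = sp_parent, rank = "species",
    scientific_name = paste(genus_name[sp_parent], epithet))
  nodes[[length(nodes) + 1L]] <- species
  nodes <- bind_rows(nodes)

  names_tbl <- tibble(taxon_id = nodes$taxon_id,
                      name = nodes$scientific_name,
                      name_class = "scientific name")

  # homonyms: give k species the binomial of a species in another family
  if (spec$n_homonyms > 0 && n_sp >= 2 * spec$n_homonyms) {
    fam_of <- function(id) {
      # walk up to the family-rank ancestor
      cur <- id
      repeat {
        cur <- nodes$parent_id[nodes$taxon_id == cur]
        r <- nodes$rank[nodes$taxon_id == cur]
        if (r == "family" || cur == root) return(cur)
      }
    }
    pool <- sample(species$taxon_id)
    made <- 0L
    i <- 1L
    while (made < spec$n_homonyms && i + 1 <= length(pool)) {
      a <- pool[i]; b <- pool[i + 1]
      i <- i + 2L
      if (identical(fam_of(a), fam_of(b))) next
      nm <- nodes$scientific_name[nodes$taxon_id == a]
      nodes$scientific_name[nodes$taxon_id == b] <- nm
      names_tbl$name[names_tbl$taxon_id == b] <- nm
      made <- made + 1L
    }
  }

  if (spec$n_synonyms > 0) {
    syn_for <- sample(species$taxon_id, min(spec$n_synonyms, n_sp))
    syn_names <- paste(make_names(length(syn_for)),
                       tolower(make_names(length(syn_for))))
    names_tbl <- bind_rows(names_tbl, tibble(
      taxon_id = syn_for, name = syn_names, name_class = "synonym"))
  }

  writeLines(
    paste0(nodes$taxon_id, "\t|\t", nodes$parent_id, "\t|\t", nodes$rank,
           "\t|"),
    file.path(dir, "nodes.dmp"))
  writeLines(
    paste0(names_tbl$taxon_id, "\t|\t", names_tbl$name, "\t|\t\t|\t",
           names_tbl$name_class, "\t|"),
    file.path(dir, "names.dmp"))
  invisible(list(dir = dir, nodes = nodes, names = names_tbl))
}

# family ancestor lookup table for a loaded store
family_of_species <- function(store, sp_ids) {
  vapply(sp_ids, function(id) {
    anc <- store$lineage[[id]]
    at <- anc[store$rank[anc] == "family"]
    if (length(at)) at[1] else NA_character_
  }, "")
}

#' Generate trait tables and import specs against a taxonomy
#'
#' Emits paired TSV+YAML files for a genome-size-like numeric trait
#' (supplied as C-values in picograms with a pg-to-bp multiply transform),
#' a chromosome-number-like small integer, an assembly-level-like ordered
#' keyword, a project target list (list type) and a sequencing-status
#' keyword. The genome-size trait carries family-level effects with
#' `n_shifted_clades` families shifted by `shift_factor`, and a ground
#' truth table (true per-species values, per-family means, shifted flags)
#' is written alongside for parameter-recovery checks.
#'
#' @param dir output directory for the TSV/YAML pairs.
#' @param store a store with the backbone taxonomy loaded.
#' @param spec a [synth_fixture_spec()].
#' @param seed integer seed.
#' @return invisibly, a list with the YAML paths and the `ground_truth`
#'   tibble.
#' @export
synth_attributes <- function(dir, store, spec = synth_fixture_spec(),
                             seed = 1L) {
  stopifnot(inherits(store, "taxatlas_store"),
            inherits(spec, "taxatlas_fixture_spec"))
  set.seed(seed + 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  sp <- names(store$rank)[store$rank == "species"]
  fam <- family_of_species(store, sp)
  fams <- unique(fam[!is.na(fam)])
  shifted <- sample(fams, min(spec$n_shifted_clades, length(fams)))
  fam_mean <- setNames(rlnorm(length(fams), meanlog = log(1.2e9),
                              sdlog = 0.4), fams)
  fam_mean[shifted] <- fam_mean[shifted] * spec$shift_factor
  true_bp <- rlnorm(length(sp), meanlog = log(fam_mean[fam]),
                    sdlog = spec$noise_sdlog)

  ground_truth <- tibble(
    taxon_id = sp,
    scientific_name = unname(store$sci_name[sp]),
    family_id = fam,
    family_name = unname(store$sci_name[fam]),
    shifted = fam %in% shifted,
    genome_size_bp = true_bp)
  readr::write_tsv(ground_truth, file.path(dir, "ground_truth.tsv"))

  observed <- runif(length(sp)) >= spec$missingness
  pg <- true_bp / store$config$pg_to_bp

  genus_of <- vapply(sp, function(id) {
    anc <- store$lineage[[id]]
    at <- anc[store$rank[anc] == "genus"]
    if (length(at)) store$sci_name[[at[1]]] else NA_character_
  }, "")

  base_cols <- tibble(
    species = unname(store$sci_name[sp]),
    genus = unname(genus_of),
    family = unname(store$sci_name[fam]))

  write_pair <- function(stem, data, yaml_spec) {
    readr::write_tsv(data, file.path(dir, paste0(stem, ".tsv")))
    yaml::write_yaml(yaml_spec, file.path(dir, paste0(stem, ".yaml")))
    file.path(dir, paste0(stem, ".yaml"))
  }

  taxonomy_block <- list(scientific_name = "species", genus = "genus",
                         family = "family")

  y1 <- write_pair(
    "genome_size",
    dplyr::bind_cols(base_cols, tibble(c_value = round(pg, 4)))[observed, ],
    list(
      file = list(name = "genome_size.tsv", delimiter = "\t"),
      attributes = list(genome_size = list(
        header = "c_value", type = "float", units = "bp",
        constraints = list(min = 0),
        summary = list("median"),
        traverse = list(direction = "both", ancestor_summary = "median"),
        transform = list(multiply = store$config$pg_to_bp))),
      taxonomy = taxonomy_block,
      source = list(name = "synthetic_cvalues", date = "2022-11-16")))

  set.seed(seed + 2L)
  fam_chr <- setNames(sample(seq(4, 60, by = 2), length(fams),
                             replace = TRUE), fams)
  chr_obs <- runif(length(sp)) >= spec$missingness
  chr_n <- fam_chr[fam] + sample(c(-2L, 0L, 0L, 2L), length(sp),
                                 replace = TRUE)
  y2 <- write_pair(
    "chromosome_number",
    dplyr::bind_cols(base_cols, tibble(chromosome_number = chr_n))[chr_obs, ],
    list(
      file = list(name = "chromosome_number.tsv", delimiter = "\t"),
      attributes = list(chromosome_number = list(
        header = "chromosome_number", type = "integer",
        constraints = list(min = 1),
        summary = list("mode"),
        traverse = list(direction = "both", ancestor_summary = "mode"))),
      taxonomy = taxonomy_block,
      source = list(name = "synthetic_karyotypes", date = "2022-11-16")))

  set.seed(seed + 3L)
  projects <- c("PROJA", "PROJB", "PROJC", "PROJD")
  n_proj <- sample(0:3, length(sp), replace = TRUE,
                   prob = c(0.35, 0.4, 0.18, 0.07))
  ll_rows <- purrr::map_dfr(seq_along(sp)[n_proj > 0], function(i) {
    tibble(species = store$sci_name[[sp[i]]],
           genus = genus_of[[i]],
           family = store$sci_name[[fam[i]]],
           long_list = paste(sample(projects, n_proj[i]), collapse = ";"))
  })
  y3 <- write_pair(
    "target_lists", ll_rows,
    list(
      file = list(name = "target_lists.tsv", delimiter = "\t"),
      attributes = list(long_list = list(
        header = "long_list", type = "list",
        summary = list("list"))),
      taxonomy = taxonomy_block,
      source = list(name = "synthetic_targets", date = "2022-11-16")))

  set.seed(seed + 4L)
  statuses <- c("sample_collected", "in_progress", "insdc_open")
  st_obs <- runif(length(sp)) < 0.4
  y4 <- write_pair(
    "sequencing_status",
    dplyr::bind_cols(base_cols, tibble(
      sequencing_status = sample(statuses, length(sp),
                                 replace = TRUE)))[st_obs, ],
    list(
      file = list(name = "sequencing_status.tsv", delimiter = "\t"),
      attributes = list(sequencing_status = list(
        header = "sequencing_status", type = "keyword",
        summary = list("mode"))),
      taxonomy = taxonomy_block,
      source = list(name = "synthetic_status", date = "2022-11-16")))

  invisible(list(yaml_paths = c(y1, y2, y3, y4),
                 ground_truth = ground_truth))
}

ASSEMBLY_LEVELS <- c("complete genome", "chromosome", "scaffold", "contig")

#' Generate a synthetic assembly table and import spec
#'
#' A fraction of species receive one or more assemblies with correlated
#' span, contig/scaffold N50 and assembly level (chromosome-level
#' assemblies have high N50s), plus an assembly date. Rows reference taxa
#' by verbatim taxon id.
#'
#' @param dir output directory.
#' @param store a store with the taxonomy loaded.
#' @param spec a [synth_fixture_spec()].
#' @param seed integer seed.
#' @return invisibly, the YAML path and the data tibble.
#' @export
synth_assemblies <- function(dir, store, spec = synth_fixture_spec(),
                             seed = 1L) {
  set.seed(seed + 5L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- names(store$rank)[store$rank == "species"]
  with_asm <- sp[runif(length(sp)) < spec$assembly_fraction]
  n_each <- 1L + rpois(length(with_asm), spec$assemblies_per_species)
  owner <- rep(with_asm, n_each)
  n <- length(owner)
  if (n == 0) stop_taxatlas("assembly fixture came out empty; increase ",
                            "assembly_fraction", "taxatlas_config_error")
  span <- rlnorm(n, meanlog = log(1e9), sdlog = 0.6)
  scaffold_n50 <- pmin(span / 2, rlnorm(n, meanlog = log(8e6), sdlog = 1.4))
  contig_n50 <- scaffold_n50 * stats::rbeta(n, 2, 4)
  level <- ifelse(scaffold_n50 > 3e7, "chromosome",
           ifelse(scaffold_n50 > 1e6, "scaffold", "contig"))
  level[sample(n, max(1, round(0.02 * n)))] <- "complete genome"
  date <- as.Date("2015-01-01") + sample.int(2800, n, replace = TRUE)
  asm <- tibble(
    accession = sprintf("GCA_%06d.1", seq_len(n) + 900000L),
    taxon_id = owner,
    assembly_span = round(span),
    contig_n50 = round(contig_n50),
    scaffold_n50 = round(scaffold_n50),
    assembly_level = level,
    assembly_date = format(date, "%Y-%m-%d"))
  readr::write_tsv(asm, file.path(dir, "assemblies.tsv"))
  yml <- list(
    file = list(name = "assemblies.tsv", delimiter = "\t"),
    attributes = list(
      assembly_span = list(header = "assembly_span", type = "integer",
                           units = "bp", summary = list("max")),
      contig_n50 = list(header = "contig_n50", type = "integer",
                        summary = list("max")),
      scaffold_n50 = list(header = "scaffold_n50", type = "integer",
                          summary = list("max")),
      assembly_level = list(
        header = "assembly_level", type = "ordered_keyword",
        constraints = list(enum = as.list(ASSEMBLY_LEVELS)),
        summary = list("priority-by-enum")),
      assembly_date = list(header = "assembly_date", type = "date",
                           summary = list("min"))),
    options = list(index = "assembly"),
    taxonomy = list(taxon_id = "taxon_id"),
    assembly = list(assembly_id = "accession"),
    source = list(name = "synthetic_insdc", date = "2022-11-16"))
  yaml::write_yaml(yml, file.path(dir, "assemblies.yaml"))
  # the same table aggregated per taxon: best N50s and span per species,
  # propagated towards the root so clade-level gap reports work
  yml_taxon <- list(
    file = list(name = "assemblies.tsv", delimiter = "\t"),
    attributes = list(
      assembly_span = list(header = "assembly_span", type = "integer",
                           units = "bp", summary = list("max"),
                           traverse = list(direction = "up",
                                           ancestor_summary = "median")),
      contig_n50 = list(header = "contig_n50", type = "integer",
                        summary = list("max"),
                        traverse = list(direction = "up",
                                        ancestor_summary = "max")),
      scaffold_n50 = list(header = "scaffold_n50", type = "integer",
                          summary = list("max"),
                          traverse = list(direction = "up",
                                          ancestor_summary = "max")),
      assembly_level = list(
        header = "assembly_level", type = "ordered_keyword",
        constraints = list(enum = as.list(ASSEMBLY_LEVELS)),
        summary = list("priority-by-enum"))),
    options = list(index = "taxon"),
    taxonomy = list(taxon_id = "taxon_id"),
    source = list(name = "synthetic_insdc", date = "2022-11-16"))
  yaml::write_yaml(yml_taxon, file.path(dir, "assemblies_taxon.yaml"))
  invisible(list(yaml_path = file.path(dir, "assemblies.yaml"), data = asm))
}
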