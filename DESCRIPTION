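Package: taxatlas
Title: Taxonomy-Indexed Metadata Store for Eukaryotic Taxa and Genome Assemblies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-process search engine for taxon and genome-assembly
    metadata anchored on a backbone taxonomy. Loads an NCBI-style taxdump,
    imports attribute values declaratively from paired TSV+YAML files,
    summarises raw measurements into a single reported value per taxon,
    propagates estimates through the taxonomy (bottom-up to ancestors, then
    top-down to descendants) with traffic-light provenance labels, and
    evaluates a taxon-scoped query language (tax_tree, tax_rank, attribute
    filters with min/max/length modifiers). Aggregation reports cover
    per-rank counts, subset ratios, histograms, scatter/heatmap summaries
    and annotated subtrees exportable as Newick or PhyloXML. A seeded
    synthetic-fixture generator produces taxonomies, trait tables and
    assembly tables so every component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    jsonlite,
    xml2,
    ggplot2,
    generics,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
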