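# taxatlas

An in-process search engine for taxon and genome-assembly metadata
anchored on a backbone taxonomy, for the kind of cross-project
coordination that large-scale biodiversity genomics requires: which
species already have chromosome-level assemblies, what genome size should
we expect for a taxon nobody has measured, which clades are sequencing
gaps, which targets overlap between projects.

It is aimed at genome-project coordinators, curators of trait databases
(C-values, karyotypes, assembly statistics) and comparative genomicists
who want taxonomy-aware queries and clade-level inference over tabular
metadata without standing up a search cluster.

## What it does

* **Taxonomy backbone.** Loads an NCBI-style taxdump (`nodes.dmp`,
  `names.dmp`), indexes every taxon with its full ancestral lineage, and
  inserts off-backbone taxa at the nearest matching genus, family or
  other rank. Free-text lookup resolves names across all name classes
  (scientific names, synonyms, common names, assembly accessions) in
  tiers: exact, then prefix, then fuzzy within edit distance 2.
* **Declarative import.** Paired TSV+YAML files define what each column
  means, how to transform values (e.g. C-values in picograms × 0.978×10⁹
  → genome size in bp), and how rows map to taxa. Homonyms are resolved
  through higher-rank columns; unmatched rows land in an exceptions file.
* **Tree-based filling.** Raw values are summarised to one reported value
  per taxon (median, mode, enum priority, ...), then missing values are
  inferred over the tree: bottom-up to ancestors, then top-down from the
  nearest informative ancestor. Every value carries traffic-light
  provenance — **direct** (green), from **descendants** (orange), from an
  **ancestor** (red) — and clade or rank barriers stop propagation where
  inference would be biologically meaningless.
* **Query language.** `tax_tree(Lepidoptera) AND assembly_span>500000000`
  style queries: `tax_eq`, `tax_name` (with name classes and wildcards),
  `tax_tree`, `tax_rank`, `tax_depth`, `tax_lineage`, attribute
  comparisons with `min()`/`max()`/`length()` modifiers, comma-OR and `!`
  negation, over either the taxon or the assembly index, with or without
  estimated values.
* **Reports.** Per-rank counts, subset ratios, histograms,
  scatter/heatmap summaries, and annotated subtrees exportable as Newick
  or PhyloXML. Report objects support `tidy()`, `glance()` and
  `autoplot()`.
* **Synthetic fixtures.** A seeded generator produces taxonomies, trait
  tables and assembly tables, so the whole engine runs and is tested
  entirely offline.

## Worked example

```r
library(taxatlas)

# seeded synthetic corpus: 200 species, trait tables, assemblies
fx <- file.path(tempdir(), "demo")
spec <- synth_fixture_spec(n_species = 200)
synth_taxonomy(file.path(fx, "taxdump"), spec, seed = 11)

store <- taxatlas_store()
load_taxdump(store, file.path(fx, "taxdump"))
synth_attributes(file.path(fx, "data"), store, spec, seed = 11)
synth_assemblies(file.path(fx, "data"), store, spec, seed = 11)
index_directory(store, file.path(fx, "data"))

fill_all(store)
#> # A tibble: 5 × 6
#>   attribute         written direct descendant ancestor error
#>   <chr>               <int>  <int>      <int>    <int> <chr>
#> 1 assembly_span         142     96        142        0 <NA>
#> 2 chromosome_number     216    143        153       63 <NA>
#> 3 contig_n50            142     96        142        0 <NA>
#> 4 genome_size           217    142        156       61 <NA>
#> 5 scaffold_n50          142     96        142        0 <NA>
```

142 species have directly measured genome sizes; the fill pass adds 156
clade-level (descendant-derived) and 61 inherited (ancestor-derived)
estimates. Queries then see complete coverage — or only measured data,
on request:

```r
search_docs(store, "tax_rank(species) AND genome_size>2e9",
            fields = "genome_size") |> head(4)
#> # A tibble: 4 × 5
#>   taxon_id rank    scientific_name genome_size genome_size_provenance
#>   <chr>    <chr>   <chr>                 <dbl> <chr>
#> 1 175      species Gubrne diplnedi  4855281000 direct
#> 2 176      species Plbrba guhahane  2368716000 direct
#> 3 185      species Nehadi muhachki  3154636800 direct
#> 4 186      species Sapipl pibadixa  3484027200 direct

count_docs(store, "tax_rank(species) AND genome_size>2e9")
#> [1] 59
count_docs(store, "tax_rank(species) AND genome_size>2e9",
           include_estimates = FALSE)
#> [1] 40
```

59 species exceed 2 Gbp when estimates count; 40 of those are direct
measurements. A per-rank report shows where the large-genome signal sits
in the taxonomy:

```r
tidy(report_x_per_rank(store, "genome_size>2e9"))
#> # A tibble: 8 × 2
#>   rank         count
#>   <chr>        <int>
#> 1 superkingdom     0
#> 2 kingdom          0
#> 3 phylum           0
#> 4 class            0
#> 5 order            3
#> 6 family           8
#> 7 genus           19
#> 8 species         59
```

Records show full provenance per attribute:

```r
get_record(store, "160")
#> <taxatlas_record> taxon 160 (Zocesa xacepich)
#>   chromosome_number: 52 [direct, mode of 1]
#>   genome_size: 788268000 [direct, median of 1]
#>   long_list: PROJB [direct, list of 1]
```

A command-line front end mirroring the import verbs (`init`, `index`,
`fill`, `search`, `count`, `record`, `report`, `synth`) is installed at
`system.file("cli", "taxatlas", package = "taxatlas")`.

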