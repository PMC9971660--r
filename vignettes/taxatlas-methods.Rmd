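---
title: "taxatlas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{taxatlas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxatlas)
```

## The problem

Coordinating genome sequencing across thousands of eukaryotic species
requires a single queryable view of heterogeneous metadata: genome sizes
measured cytologically or estimated from C-values, chromosome numbers,
assembly statistics (span, contig and scaffold N50, assembly level),
project target lists and sequencing statuses. Three properties make this
harder than an ordinary tabular database:

1. every value is anchored to a taxon in a backbone taxonomy, and queries
   are naturally *taxon-scoped* ("all Lepidoptera", "species under this
   family");
2. most species have no direct measurements, so useful answers require
   *tree-based inference* of missing values from relatives, with honest
   labelling of how each value was obtained; and
3. the data model must be extensible without code changes, because new
   sources arrive continuously as delimited tables.

taxatlas implements this as an in-process engine: a mutable store object
(a handle, in the style of a database connection) populated by
`load_taxdump()`, `index_file()`/`index_directory()` and `fill_all()`, and
interrogated by `search_docs()`, `count_docs()`, `get_record()`,
`lookup_names()` and the `report_*()` builders, which all return tibbles
or tidy-able report objects. The store is deliberately not a copy-on-write
tibble: indexing and filling are in-place verbs over shared state, and a
handle keeps the import pipeline's plumbing out of the user's way.

## The data model

One document per taxon and one per genome assembly, in two separate
indexes. Each taxon document carries its identifier, rank, scientific
name, all name records (synonyms, common names, `tol_id`-style name
classes), and an ordered lineage of ancestors from the immediate parent
to the root, each with rank and depth. Assembly documents carry their
accession, aliases and owning taxon, and inherit that taxon's lineage,
which is what lets taxon-scoped queries work identically on either index.

Attributes are declared in a registry, per index, with a value type
(integer, float, date, keyword, ordered keyword, list), optional
constraints, an ordered list of summary rules, and traverse (propagation)
rules. The same attribute name may exist on both indexes — `assembly_span`
is a per-assembly measurement in the assembly index and an aggregated
per-taxon value in the taxon index — which is why the registry key is
(index, name).

Ordered keywords declare their labels from best to worst (e.g.
`complete genome > chromosome > scaffold > contig`), and this single
declaration drives both summarisation priority and the total order used
by `<`, `<=`, `>=`, `>` in queries.

## Declarative import

Each data file is paired with a YAML specification naming the file and
delimiter, mapping columns to attributes (with optional transforms and
label translations), mapping taxonomy columns, and recording the source.
Rows are matched to taxa in a fixed priority order: verbatim taxon id;
unique scientific name; name disambiguated by higher-rank columns
(homonym resolution); synonym (if allowed); fuzzy match within edit
distance 2 (if allowed); and finally insertion of a new taxon anchored at
the most specific resolvable higher rank (if enabled). Matches below the
first two tiers are logged to a review file; unresolvable rows go to an
exceptions file with a reason. A bad cell voids only that cell, never the
whole row — this maximises retained data and matches the exceptions-file
framing of the import contract. Re-importing an identical file is a no-op
because raw values are deduplicated on (document, attribute, value,
source).

Transforms run *before* type coercion and constraint checks. The
canonical example is the C-value conversion: a column of haploid DNA
masses in picograms times `0.978e9` yields genome size in base pairs.
The constant is the standard flow-cytometry conversion; it lives in the
YAML (and in the store configuration), not in code, so a source using a
different calibration can override it per file.

## Summarisation and tree filling

Raw values are reduced to one reported value per document by the first
applicable rule in the attribute's summary list (`min`, `max`, `mean`,
`median`, `mode`, `list`, `priority-by-enum`, `priority-by-source`).
The range and count of raw values are always kept alongside, which is
what the query modifiers `min()`, `max()` and `length()` test.

Missing values are then inferred over the taxonomy by `fill_attribute()`.
The backbone has no branch lengths, so the algorithm is purely
topological, in two passes:

* **UP** (post-order): an internal node without a direct summary receives
  the attribute's ancestor-summary statistic (default: median for
  numeric, mode for keywords) of its children's values, where a child
  contributes its direct summary or its own descendant-derived estimate —
  never an ancestor-derived value, which would make propagation circular.
* **DOWN** (pre-order): any node still empty inherits the value of its
  nearest ancestor (fewest edges) that has one, and records that ancestor
  as the estimate's source.

Provenance follows a traffic-light scheme: *direct* (green) for measured
summaries, *descendant* (orange) for UP-pass estimates, *ancestor* (red)
for DOWN-pass estimates. Direct values are never overwritten or blended:
when a node has both raw data and informative descendants, the direct
summary wins and the descendants are ignored for that node. The
alternative (recomputing internal nodes from children even when measured)
was rejected because it silently discards curated measurements.

Propagation limits support two barrier kinds. A *clade barrier* severs
the barrier node's entire subtree: no estimate enters it, nothing inside
it leaks out, and direct values inside are preserved untouched (the
motivating case is preventing plastid-genome attributes from being
inferred for animals). A *rank ceiling* stops propagation above a given
rank: nodes more rootward than the limit receive and relay nothing, and
rank-less intermediate nodes count as inside the ceiling only when they
sit below a node at or under the limit rank. The two kinds compose by
union. The barrier node itself receives no estimate in either case.

`fill_attribute()` recomputes estimates from scratch on each call and
reports how many changed; `fill ∘ fill = fill` is asserted in the tests,
and direct summaries are bit-identical across passes.

## The query language

Queries are conjunctions of terms joined by `AND`. Taxon terms are
`tax_`-prefixed functions — `tax_eq()` (by id), `tax_name()` (by name,
with optional `class:` prefixes and `*` globs), `tax_tree()` (the named
taxa and all descendants, self-inclusive), `tax_rank()`, `tax_depth()`
(edges below an anchoring taxon term; standalone use is rejected at parse
time since depth is meaningless without an anchor), and `tax_lineage()`
(the ancestors of a single matched taxon). Attribute terms compare the
reported value (`assembly_span>500000000`), a summary bound
(`min(assembly_span)>2e9`), or the raw-value count (`length(long_list)>1`);
a bare attribute name is an existence filter. Commas inside a term mean
OR; `!` on a taxon argument or `!=` on a value subtracts. General
boolean `OR`/`NOT` connectives between terms are deliberately not part of
the grammar. Keyword comparisons are case-insensitive (project labels
arrive in inconsistent case across sources); stored forms are preserved.

`parse_query()` builds an AST and `render_query()` prints its canonical
form; parse–render–parse is the identity, which the tests assert for
every documented query form.

Evaluation is per-index. Setting `include_estimates = FALSE` restricts
attribute filters and result fields to direct and descendant-derived
values — ancestor-derived values are the weakest evidence class and the
one users most often want to exclude. Results are ordered by document id
so output is deterministic. `count_docs()` computes cardinalities without
materialising fields. Output modes: `summary` (one row per document),
`tidy` (one row per value with provenance and source), `raw` (tidy,
direct measurements only), each as TSV, CSV or JSON.

## Reports

Five report types aggregate a query result: `xPerRank` (counts per rank),
`arc` (one query as a subset of another, with ratio), `histogram`
(half-open, lower-inclusive bins, optional log10 scale and category
stacking, with an explicit no-value remainder so counts always
reconcile), `scatter` (paired values; above a configurable threshold —
default 10,000 points — a two-dimensional histogram whose cell counts sum
to the point count is returned instead; explicit break points let cell
edges sit on reference thresholds such as contig N50 > 1 Mb and scaffold
N50 > 10 Mb), and `tree` (the union of matched taxa's lineage paths
truncated at their most recent common ancestor, annotated with matched
counts, attribute values and provenance). Tree reports export to Newick
(labels only — there are no branch lengths to write; spaces become
underscores per Newick convention, other problem characters are quoted)
and to PhyloXML, where annotations travel as `property` elements. Every
report object supports `tidy()`, `glance()` and `autoplot()`.

## Synthetic data generator

The generator is first-class, tested code: the engine's offline study
conditions. `synth_taxonomy()` emits a valid single-root taxdump with
configurable homonym and synonym injection; `synth_attributes()` emits
TSV+YAML pairs for a genome-size-like trait (delivered as picogram
C-values to exercise the unit transform), a chromosome-number-like
integer, a target-list list attribute and a status keyword;
`synth_assemblies()` emits an assembly table with correlated span, N50s,
level and date, plus a taxon-level aggregation spec over the same file.

Reference conditions (the defaults of `synth_fixture_spec()`): 1,000
species under six higher ranks; 30% missingness per trait; three families
whose genome-size trait is shifted four-fold, against lognormal
within-family noise of sdlog 0.25 around family means drawn with sdlog
0.4 — a shift chosen to be far larger than the noise so that recovering
it in genus-level descendant estimates is a property of the algorithm,
not luck; roughly half the species carry one or more assemblies. A ground
truth table (true values, family means, shifted flags) is written
alongside for parameter-recovery checks. All generation is a pure
function of the seed; identical seeds give byte-identical files.

What the generator does *not* emulate: real taxonomies' extreme size
imbalance and rank irregularity (subspecies, unplaced clades, "no rank"
interior nodes at arbitrary depths), correlated missingness (data are
missing at random here, but in reality missingness tracks clades and
research effort), measurement error structure across sources, and name
noise beyond simple homonyms/synonyms. Passing tests therefore
demonstrate algorithmic correctness under controlled conditions, not
robustness to every pathology of live taxonomic data.

## Numerical and procedural choices

* Median of an even-length list is the mean of the central pair; mode
  ties break by enum order, then numerically/lexicographically ascending.
* Ordered-keyword comparisons map labels to integer scores (best label
  highest), so `>=` reads "at least as good as".
* Lookup tiers: exact, then prefix, then fuzzy within edit distance 2;
  ties within a tier break by shorter name, then lexicographically, so
  results are deterministic. Equal-tier homonyms are all returned, each
  with rank and parent name; the engine never auto-picks among them.
* Inserted off-backbone taxa get sequential ids in a reserved `local:`
  namespace and are indexed under their scientific name only (whether
  such taxa should participate in synonym lookup is an open question; we
  chose the conservative answer).
* Empty-cell markers default to `""`, `NA`, `None`, `-` and are
  configurable; delimiters come from the YAML, never sniffed.
* Histogram bins anchor at the smallest value; log binning uses base 10.
* Dates compare at day granularity on the ISO calendar.
* A YAML attribute declaration that conflicts with the registry (same
  index and name, different type or constraints) is a hard error, never a
  silent merge.

## Problem sizes used in validation

The test-suite validates filling against an independent recursive oracle
on 200 random taxonomies of up to 200 nodes with 30% informative tips,
across all traverse directions and with clade barriers; query evaluation
against a naive per-document matcher on 500 grammar-generated queries
over a ~13,000-document corpus (6,000 species plus higher ranks and
assemblies); and Newick export through an independent tree parser on 50
random subtree reports. `scripts/acceptance.R` reruns the same classes of
checks from scratch at the reference fixture size and writes the
resulting counts and agreement rates as JSON.

## Known limitations

* Propagation is topology-only; no branch-length-aware or model-based
  ancestral reconstruction, and no uncertainty on estimates.
* One backbone taxonomy per store; no taxonomy merging.
* The query grammar covers conjunctions with comma-OR and negation only.
* `tax_depth()` counts edges, which across ranks of unequal depth is a
  crude proxy for taxonomic distance.
* The store lives in memory; the CLI persists it by serialisation. This
  is a desk-scale engine by design: correctness and reproducibility over
  horizontal scale.
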