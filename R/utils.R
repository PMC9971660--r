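#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select arrange bind_rows left_join group_by
#'   summarise ungroup distinct n pull across slice
#' @importFrom stats median setNames rbinom rpois runif rnorm rlnorm
#' @importFrom utils head tail adist glob2rx
NULL

# Canonical rank ordering from root-most to tip-most. Used for anchor
# specificity, rank barriers, and the default per-rank report axis.
RANK_ORDER <- c(
  "superkingdom", "kingdom", "subkingdom", "superphylum", "phylum",
  "subphylum", "superclass", "class", "subclass", "superorder", "order",
  "suborder", "superfamily", "family", "subfamily", "tribe", "genus",
  "subgenus", "species group", "species", "subspecies", "varietas", "forma"
)

DEFAULT_REPORT_RANKS <- c(
  "superkingdom", "kingdom", "phylum", "class", "order", "family",
  "genus", "species"
)

# Cell contents treated as missing on import (configurable per store).
DEFAULT_EMPTY_MARKERS <- c("", "NA", "None", "-")

# Haploid DNA mass to base pairs: 1 pg = 0.978e9 bp.
DEFAULT_PG_TO_BP <- 0.978e9

rank_position <- function(rank) {
  match(rank, RANK_ORDER)
}

is_missing_cell <- function(x, markers = DEFAULT_EMPTY_MARKERS) {
  is.na(x) | trimws(as.character(x)) %in% markers
}

#' @keywords internal
glob_match <- function(pattern, x) {
  if (identical(pattern, "*")) return(rep(TRUE, length(x)))
  grepl(glob2rx(tolower(pattern)), tolower(x))
}

# Deterministic sort for mixed value vectors: numeric ascending when all
# parse as numbers, lexicographic otherwise.
value_sort <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) x[order(num)] else sort(as.character(x))
}

stop_taxatlas <- function(msg, class, ...) {
  abort(msg, class = c(class, "taxatlas_error"), ...)
}
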