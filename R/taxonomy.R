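#' Greengenes-style taxonomy strings
#'
#' Lineages are semicolon-joined rank tokens with canonical single-letter
#' prefixes `k__`, `p__`, `c__`, `o__`, `f__`, `g__`, `s__` (kingdom through
#' species). `parse_taxonomy()` splits one lineage into a tibble of
#' (prefix, name) pairs; `truncate_taxonomy()` cuts a lineage at a rank and
#' re-serializes it, which is how OTUs are binned for genus-level filtering.
#'
#' Tokens without a recognizable `x__` prefix are kept verbatim as names with
#' an empty prefix (a warning is raised), so nonstandard lineages survive a
#' round trip instead of being dropped.
#'
#' @param x A single lineage string, e.g.
#'   `"k__Bacteria; p__Firmicutes; c__; o__; f__; g__; s__"`.
#' @return For `parse_taxonomy()`, a tibble with columns `prefix` and `name`
#'   (possibly zero rows for an empty lineage). For `truncate_taxonomy()`, a
#'   lineage string with at most `rank` tokens.
#' @export
#' @examples
#' parse_taxonomy("k__Bacteria; p__Firmicutes; c__; o__; f__; g__; s__")
#' truncate_taxonomy("k__Bacteria; p__Firmicutes; c__Bacilli", "phylum")
parse_taxonomy <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (!nzchar(x)) {
    return(tibble::tibble(prefix = character(), name = character()))
  }
  tokens <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  has_prefix <- grepl("^[a-z]__", tokens)
  if (any(!has_prefix & nzchar(tokens))) {
    warning("taxonomy tokens without rank prefix kept verbatim: ",
            paste(tokens[!has_prefix & nzchar(tokens)], collapse = ", "))
  }
  tibble::tibble(
    prefix = ifelse(has_prefix, substr(tokens, 1L, 3L), ""),
    name = ifelse(has_prefix, substring(tokens, 4L), tokens)
  )
}

tax_rank_prefixes <- c(
  kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
  family = "f__", genus = "g__", species = "s__"
)

#' @rdname parse_taxonomy
#' @param rank Rank to truncate at: a name (`"genus"`) or depth (1-7).
#'   Empty-named ranks are kept, so unnamed genera bin by their deepest named
#'   lineage rather than collapsing into one global unknown.
#' @export
truncate_taxonomy <- function(x, rank = "genus") {
  depth <- if (is.character(rank)) {
    match(match.arg(rank, names(tax_rank_prefixes)), names(tax_rank_prefixes))
  } else {
    as.integer(rank)
  }
  stopifnot(depth >= 1L, depth <= 7L)
  vapply(x, function(lineage) {
    tokens <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
    paste(utils::head(tokens, depth), collapse = "; ")
  }, character(1), USE.NAMES = FALSE)
}

format_taxonomy <- function(ranks) {
  paste0(ranks$prefix, ranks$name, collapse = "; ")
}

#' Sentinel lineage for OTUs with no reference hit
#' @keywords internal
UNASSIGNED <- "Unassigned"
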