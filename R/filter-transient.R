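#' Filter transient taxa from an OTU table
#'
#' Oral (and other host-associated) communities contain transient organisms
#' that are not part of the core community under study. This two-pass filter
#' removes them working on OTUs aggregated by taxonomy truncated at `rank`
#' (genus by default, keeping empty rank names so unnamed genera bin by
#' their deepest named lineage):
#'
#' * **prevalence pass** -- an aggregate present (count > 0) in strictly
#'   fewer than `prevalence_frac` of samples is removed;
#' * **abundance pass** -- among the survivors, an aggregate whose total
#'   count is strictly less than `abundance_frac` of the *original* table's
#'   grand total is removed.
#'
#' Both inequalities are strict, so an aggregate sitting exactly on a
#' threshold is retained. Removed aggregates are reported with their percent
#' abundance and (when an OTU map is supplied) their member sequence IDs,
#' for examination rather than silent loss.
#'
#' @param table An [otu_table()] of counts.
#' @param assignments Taxonomy assignment tibble covering every OTU in the
#'   table (columns `otu_id`, `taxonomy`); defaults to the table's attached
#'   taxonomy.
#' @param prevalence_frac Prevalence threshold as a fraction of samples
#'   (default 0.05, i.e. "less than 5% of samples").
#' @param abundance_frac Abundance threshold as a fraction of total
#'   sequences (default 1e-4, i.e. "less than 0.01% of the data").
#' @param rank Taxonomic rank for aggregation (default `"genus"`).
#' @param otu_map Optional OTU map supplying member sequence IDs for the
#'   removal report.
#' @param denominator Whether pass 2's fraction is of the `"original"`
#'   grand total (default) or of the `"surviving"` total after pass 1.
#' @return A list with `table` (the filtered [otu_table()]) and `report`
#'   (a tibble: `aggregate_id`, `pass`, `percent_abundance`, `otu_ids`,
#'   `seq_ids`). Retained plus removed counts equal the original total.
#' @export
filter_transient <- function(table, assignments = NULL,
                             prevalence_frac = 0.05, abundance_frac = 1e-4,
                             rank = "genus", otu_map = NULL,
                             denominator = c("original", "surviving")) {
  stopifnot(inherits(table, "otu_table"),
            prevalence_frac >= 0, prevalence_frac <= 1,
            abundance_frac >= 0, abundance_frac <= 1)
  denominator <- match.arg(denominator)
  if (is.null(assignments)) {
    tx <- otu_taxonomy(table)
    if (is.null(tx)) stop("no taxonomy attached to table and no assignments given")
    assignments <- tibble::tibble(otu_id = names(tx), taxonomy = unname(tx))
  }
  tax <- stats::setNames(assignments$taxonomy, assignments$otu_id)
  missing <- setdiff(otu_ids(table), names(tax))
  if (length(missing) > 0) {
    stop("OTU(s) without taxonomy assignment: ", paste(missing, collapse = ", "))
  }
  agg_key <- truncate_taxonomy(unname(tax[otu_ids(table)]), rank)
  grand_total <- sum(table)
  ns <- n_samples(table)

  groups <- split(otu_ids(table), agg_key)
  agg_presence <- vapply(groups, function(ids) {
    sum(colSums(table[ids, , drop = FALSE]) > 0)
  }, numeric(1))
  agg_total <- vapply(groups, function(ids) sum(table[ids, , drop = FALSE]),
                      numeric(1))

  removed1 <- names(groups)[agg_presence < prevalence_frac * ns]
  survivors <- setdiff(names(groups), removed1)
  denom <- if (denominator == "original") grand_total else sum(agg_total[survivors])
  removed2 <- survivors[agg_total[survivors] < abundance_frac * denom]

  report_row <- function(agg, pass) {
    ids <- groups[[agg]]
    seqs <- if (is.null(otu_map)) character(0) else {
      unlist(otu_map[intersect(ids, names(otu_map))], use.names = FALSE)
    }
    tibble::tibble(
      aggregate_id = agg, pass = pass,
      percent_abundance = 100 * agg_total[[agg]] / grand_total,
      otu_ids = list(ids), seq_ids = list(seqs)
    )
  }
  report <- dplyr::bind_rows(
    purrr::map(removed1, report_row, pass = "prevalence"),
    purrr::map(removed2, report_row, pass = "abundance")
  )
  if (nrow(report) == 0L) {
    report <- tibble::tibble(
      aggregate_id = character(), pass = character(),
      percent_abundance = numeric(),
      otu_ids = list(), seq_ids = list()
    )
  }
  keep_otus <- setdiff(otu_ids(table),
                       unlist(groups[c(removed1, removed2)], use.names = FALSE))
  list(table = table[keep_otus, ], report = report)
}

#' Write a transient-filter removal report as TSV
#'
#' @param report Removal report from [filter_transient()].
#' @param path Output path; sequence IDs are semicolon-joined.
#' @export
write_removal_report <- function(report, path) {
  out <- data.frame(
    aggregate_id = report$aggregate_id,
    pass = report$pass,
    percent_abundance = report$percent_abundance,
    otu_ids = vapply(report$otu_ids, paste, character(1), collapse = ";"),
    seq_ids = vapply(report$seq_ids, paste, character(1), collapse = ";")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
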