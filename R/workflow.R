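#' Split a sequence collection into picking chunks
#'
#' BLAST-based OTU picking treats every read independently, so a large
#' dataset can be split into chunks, picked in parallel, and the per-chunk
#' OTU maps merged afterwards. The default chunk size of 20,000 reads is a
#' practical balance of per-job runtime against job count on a batch
#' cluster.
#'
#' @param records A vector-like collection of sequence records (a
#'   `DNAStringSet`, character vector, or list); records are never split.
#' @param chunk_size Records per chunk (>= 1); every chunk except possibly
#'   the last has exactly this many records.
#' @return A list of record collections whose concatenation equals the
#'   input in order. Empty input yields an empty list.
#' @export
split_sequences <- function(records, chunk_size = 20000L) {
  chunk_size <- as.integer(chunk_size)
  stopifnot(chunk_size >= 1L)
  n <- length(records)
  if (n == 0L) return(list())
  starts <- seq.int(1L, n, by = chunk_size)
  lapply(starts, function(s) records[s:min(s + chunk_size - 1L, n)])
}

#' Merge per-chunk OTU maps into one
#'
#' Reassembles the OTU maps from parallel picking runs. For each OTU ID the
#' merged member list is the concatenation of its lists across inputs, in
#' input order; OTU order follows first appearance. Sequence IDs must be
#' globally unique across the inputs (each read was picked exactly once).
#'
#' @param maps A list of OTU maps (named lists of sequence-ID vectors).
#' @return A single merged OTU map.
#' @export
merge_otu_results <- function(maps) {
  stopifnot(is.list(maps))
  maps <- maps[lengths(maps) > 0L]
  if (length(maps) == 0L) return(stats::setNames(list(), character()))
  all_seq <- unlist(maps, use.names = FALSE)
  if (anyDuplicated(all_seq)) {
    dup <- unique(all_seq[duplicated(all_seq)])
    stop("sequence ID(s) assigned in more than one input map: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  merged <- list()
  for (m in maps) {
    for (id in names(m)) {
      merged[[id]] <- c(merged[[id]], m[[id]])
    }
  }
  validate_otu_map(merged, "merged map")
}

#' Average OTU abundances captured by two sequencing primers
#'
#' Targeting two 16S hypervariable regions captures more of the community
#' than one, but species amplified by both primers are counted twice. This
#' reconciliation keeps OTUs seen by only one primer unchanged and scales
#' a doubly-captured OTU with `nA` and `nB` members down to
#' `ceiling((nA + nB) / 2)` members. The retained member list is built by
#' alternating IDs from the two maps (first map first) and truncating, so
#' the output is deterministic and the ceiling ensures a shared singleton
#' is never annihilated.
#'
#' @param map_a,map_b OTU maps from the two primer-specific picking runs on
#'   the same samples. Sequence IDs must be unique within each map.
#' @return A single averaged OTU map. Total output count equals the sum of
#'   exclusive OTU counts plus `ceiling((nA + nB) / 2)` over shared OTUs.
#' @export
primer_average <- function(map_a, map_b) {
  validate_otu_map(map_a, "map_a")
  validate_otu_map(map_b, "map_b")
  out <- map_a
  only_b <- setdiff(names(map_b), names(map_a))
  shared <- intersect(names(map_a), names(map_b))
  for (id in shared) {
    a <- map_a[[id]]
    b <- map_b[[id]]
    keep <- ceiling((length(a) + length(b)) / 2)
    out[[id]] <- interleave_truncate(a, b, keep)
  }
  out[only_b] <- map_b[only_b]
  out
}

interleave_truncate <- function(a, b, keep) {
  k <- min(length(a), length(b))
  woven <- character(0)
  if (k > 0) woven <- as.vector(rbind(a[seq_len(k)], b[seq_len(k)]))
  woven <- c(woven, a[seq_len(length(a)) > k], b[seq_len(length(b)) > k])
  woven[seq_len(keep)]
}

#' Assign taxonomy to OTUs by reference lookup
#'
#' When OTUs are picked by BLAST against a reference database, the OTU IDs
#' are reference IDs and taxonomy assignment reduces to a lookup in the
#' reference taxonomy table -- no classifier run needed. OTUs absent from
#' the reference receive the `"Unassigned"` sentinel and are reported.
#'
#' @param otu_map An OTU map keyed by reference IDs.
#' @param reference Named character vector mapping reference ID to lineage
#'   string (see [read_taxonomy_table()]).
#' @return A tibble with columns `otu_id`, `taxonomy`, `reference_id`, and
#'   attribute `missing` listing OTU IDs not found in the reference.
#' @export
assign_taxonomy <- function(otu_map, reference) {
  validate_otu_map(otu_map)
  ids <- names(otu_map)
  hit <- ids %in% names(reference)
  if (any(!hit)) {
    message(sum(!hit), " OTU(s) missing from reference taxonomy; assigned '",
            UNASSIGNED, "'")
  }
  out <- tibble::tibble(
    otu_id = ids,
    taxonomy = ifelse(hit, unname(reference[ids]), UNASSIGNED),
    reference_id = ids
  )
  attr(out, "missing") <- ids[!hit]
  out
}

#' Substitute full-length reference sequences as OTU representatives
#'
#' Downstream alignment and tree building benefit from full-length 16S
#' sequences, so instead of choosing a representative read per OTU the
#' full-length reference sequence is substituted for each reference-picked
#' OTU ID.
#'
#' @param otu_ids Character vector of reference-database OTU IDs.
#' @param reference_sequences Named `DNAStringSet` (or character vector)
#'   keyed by reference ID.
#' @return A `DNAStringSet` with one record per input ID, in input order.
#' @export
pick_representatives <- function(otu_ids, reference_sequences) {
  if (is.character(reference_sequences)) {
    reference_sequences <- Biostrings::DNAStringSet(reference_sequences)
  }
  ref_ids <- sub("\\s.*$", "", names(reference_sequences))
  missing <- setdiff(otu_ids, ref_ids)
  if (length(missing) > 0) {
    stop("OTU ID(s) absent from reference sequences: ",
         paste(missing, collapse = ", "))
  }
  out <- reference_sequences[match(otu_ids, ref_ids)]
  names(out) <- otu_ids
  out
}

#' Condense taxonomically redundant OTUs
#'
#' Reference databases carry many entries for the same species (dozens of
#' 16S records for a single named organism is common), so reference-picked
#' OTU results contain redundant taxa that clutter visualization without
#' adding information. Condensing proceeds in three steps: (1) group OTU
#' IDs by their full taxonomy string; (2) choose the lexicographically
#' smallest OTU ID in each group as its representative (any member would do
#' biologically; determinism wins); (3) merge member sequence lists in
#' representative-first then ascending-ID order.
#'
#' @param assignments A taxonomy assignment tibble from [assign_taxonomy()]
#'   (columns `otu_id`, `taxonomy`).
#' @param otu_map The OTU map to condense; every OTU must have an
#'   assignment.
#' @return A list with `otu_map` (condensed, keyed by representatives),
#'   `representatives` (tibble `taxonomy`, `representative`, `members`),
#'   and `assignments` (one row per distinct taxonomy). The sequence-ID
#'   multiset is conserved.
#' @export
condense_otus <- function(assignments, otu_map) {
  validate_otu_map(otu_map)
  tax <- stats::setNames(assignments$taxonomy, assignments$otu_id)
  missing <- setdiff(names(otu_map), names(tax))
  if (length(missing) > 0) {
    stop("OTU(s) without taxonomy assignment: ", paste(missing, collapse = ", "))
  }
  groups <- split(names(otu_map), unname(tax[names(otu_map)]))
  reps <- vapply(groups, function(ids) sort(ids)[1L], character(1))
  condensed <- lapply(names(groups), function(g) {
    ids <- sort(groups[[g]])
    ids <- c(reps[[g]], setdiff(ids, reps[[g]]))
    unlist(otu_map[ids], use.names = FALSE)
  })
  names(condensed) <- unname(reps)
  ord <- order(match(names(condensed), names(otu_map)))
  condensed <- condensed[ord]
  rep_tbl <- tibble::tibble(
    taxonomy = names(groups),
    representative = unname(reps),
    members = unname(lapply(groups, sort))
  )[ord, ]
  list(
    otu_map = validate_otu_map(condensed, "condensed map"),
    representatives = rep_tbl,
    assignments = tibble::tibble(
      otu_id = names(condensed),
      taxonomy = unname(tax[names(condensed)]),
      reference_id = names(condensed)
    )
  )
}

#' Build an OTU table from an OTU map and sample metadata
#'
#' Tabulates total sequence abundance by OTU and originating sample. Each
#' sequence ID encodes its sample as the prefix before the final underscore
#' (the QIIME read-naming convention, e.g. `"S1_000123"`; underscores inside
#' sample IDs are tolerated).
#'
#' @param otu_map An OTU map.
#' @param assignments Optional taxonomy assignment tibble; lineages are
#'   attached as per-OTU metadata.
#' @param metadata Sample metadata with a `SampleID` column; every decoded
#'   sample must appear here, and the table's columns follow metadata order.
#' @return An [otu_table()] of counts whose grand total equals the number
#'   of sequence IDs in the map.
#' @export
build_otu_table <- function(otu_map, assignments = NULL, metadata) {
  validate_otu_map(otu_map)
  stopifnot(is.data.frame(metadata), "SampleID" %in% names(metadata))
  samples <- metadata$SampleID
  all_seq <- unlist(otu_map, use.names = FALSE)
  decoded <- decode_sample(all_seq)
  bad <- all_seq[is.na(decoded)]
  if (length(bad) > 0) {
    stop("sequence ID(s) without a decodable sample prefix: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  unknown <- setdiff(unique(decoded), samples)
  if (length(unknown) > 0) {
    stop("decoded sample(s) not present in metadata: ",
         paste(unknown, collapse = ", "))
  }
  otus <- names(otu_map)
  counts <- matrix(0, nrow = length(otus), ncol = length(samples),
                   dimnames = list(otus, samples))
  otu_of_seq <- rep(otus, lengths(otu_map))
  tab <- table(factor(otu_of_seq, levels = otus),
               factor(decoded, levels = samples))
  counts[] <- as.numeric(tab)
  taxonomy <- NULL
  if (!is.null(assignments)) {
    tax <- stats::setNames(assignments$taxonomy, assignments$otu_id)
    miss <- setdiff(otus, names(tax))
    if (length(miss) > 0) {
      stop("OTU(s) without taxonomy assignment: ", paste(miss, collapse = ", "))
    }
    taxonomy <- unname(tax[otus])
  }
  otu_table(counts, taxonomy = taxonomy)
}

decode_sample <- function(seq_ids) {
  out <- sub("_[^_]*$", "", seq_ids)
  out[!grepl("_", seq_ids, fixed = TRUE)] <- NA_character_
  out
}
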