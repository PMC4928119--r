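#' Read and write BIOM 1.0 OTU tables
#'
#' The JSON dialect of the BIological Observation Matrix format, as produced
#' by QIIME-era `make_otu_table` runs. Both `sparse` and `dense`
#' `matrix_type` encodings are accepted. Taxonomy stored as per-observation
#' metadata (either a plain string or the QIIME list-of-ranks form) is
#' reattached to the table; `write_biom()` writes it back so that a
#' write-then-read round trip is the identity on identifiers, counts and
#' taxonomy.
#'
#' @param path Path to a BIOM 1.0 JSON file.
#' @return An [otu_table()].
#' @export
read_biom <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  b <- tryCatch(biomformat::read_biom(path), error = function(e) {
    stop("malformed BIOM file '", path, "': ", conditionMessage(e))
  })
  row_ids <- vapply(b$rows, function(r) r$id, character(1))
  col_ids <- vapply(b$columns, function(col) col$id, character(1))
  dat <- biomformat::biom_data(b)
  if (is.matrix(dat) || inherits(dat, "Matrix")) {
    counts <- as.matrix(dat)
    if (is.null(dimnames(counts))) dimnames(counts) <- list(row_ids, col_ids)
  } else {
    # degenerate single-row/column tables come back as a plain vector
    counts <- matrix(as.numeric(dat), nrow = length(row_ids), byrow = TRUE,
                     dimnames = list(row_ids, col_ids))
  }
  taxonomy <- NULL
  md <- tryCatch(suppressWarnings(biomformat::observation_metadata(b)),
                 error = function(e) NULL)
  if (!is.null(md)) {
    if (is.data.frame(md)) {
      tx <- apply(md, 1L, function(r) {
        r <- r[!is.na(r) & nzchar(trimws(r))]
        paste(trimws(r), collapse = "; ")
      })
      taxonomy <- as.character(tx)[match(rownames(counts), rownames(md))]
    } else if (is.list(md)) {
      taxonomy <- vapply(md, function(r) {
        paste(trimws(unlist(r)), collapse = "; ")
      }, character(1))[rownames(counts)]
      taxonomy <- unname(taxonomy)
    } else if (is.character(md)) {
      taxonomy <- unname(md[rownames(counts)])
    }
    if (!is.null(taxonomy) && all(!nzchar(taxonomy))) taxonomy <- NULL
  }
  otu_table(counts, taxonomy = taxonomy)
}

#' @rdname read_biom
#' @param table An [otu_table()].
#' @export
write_biom <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  tx <- otu_taxonomy(table)
  om <- NULL
  if (!is.null(tx)) {
    om <- data.frame(taxonomy = unname(tx), row.names = rownames(table),
                     stringsAsFactors = FALSE)
  }
  b <- biomformat::make_biom(unclass(table), observation_metadata = om)
  # fixed date field so identical tables serialize byte-identically
  b$date <- "0000-00-00T00:00:00"
  biomformat::write_biom(b, path)
  invisible(path)
}

#' Read a QIIME mapping file
#'
#' Tab-delimited sample metadata whose header line starts `#SampleID`.
#' Comment lines (leading `#`) after the header are skipped. The QIIME
#' convention requires at least the sample identifier, barcode sequence,
#' linker/primer sequence and description columns; arbitrary category
#' columns in between are preserved in file order.
#'
#' @param path Path to the mapping file.
#' @param required Column names that must be present (set to `character()`
#'   to accept minimal metadata tables).
#' @return A tibble with one row per sample; the `#SampleID` column is
#'   renamed `SampleID`.
#' @export
read_mapping <- function(path,
                         required = c("SampleID", "BarcodeSequence",
                                      "LinkerPrimerSequence", "Description")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(lines[[1]], "#SampleID")) {
    stop("mapping file must begin with a '#SampleID' header line: ", path)
  }
  header <- strsplit(sub("^#", "", lines[[1]]), "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  body <- body[!startsWith(body, "#")]
  rows <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad) > 0) {
    stop("mapping rows with wrong field count (expected ", length(header),
         "): data line(s) ", paste(bad, collapse = ", "))
  }
  df <- tibble::as_tibble(do.call(rbind, c(rows, list(deparse.level = 0))),
                          .name_repair = "minimal")
  if (length(body) == 0L) {
    df <- tibble::as_tibble(matrix(character(), 0, length(header)),
                            .name_repair = "minimal")
  }
  names(df) <- header
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("mapping file missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$SampleID)) {
    stop("duplicate sample IDs in mapping file: ",
         paste(unique(df$SampleID[duplicated(df$SampleID)]), collapse = ", "))
  }
  df
}

#' Write a QIIME mapping file
#'
#' @param metadata A data frame with a `SampleID` first column (as returned
#'   by [read_mapping()]).
#' @param path Output path.
#' @export
write_mapping <- function(metadata, path) {
  stopifnot(is.data.frame(metadata), names(metadata)[1] == "SampleID")
  header <- paste0("#", paste(names(metadata), collapse = "\t"))
  body <- apply(metadata, 1L, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write OTU maps
#'
#' The `pick_otus`-style assignment file: each tab-delimited line is an OTU
#' ID followed by the IDs of its member sequences. Member order is
#' preserved, and duplicate OTU ID lines are an error (merging chunked
#' results is [merge_otu_results()]'s job, not the parser's).
#'
#' @param path Path to the tab-delimited OTU map.
#' @return A named list of character vectors (OTU ID -> sequence IDs).
#' @export
read_otu_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(list(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate OTU ID line(s) in map: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(lapply(fields, function(f) f[-1L]), ids)
}

#' @rdname read_otu_map
#' @param map A named list of character vectors.
#' @export
write_otu_map <- function(map, path) {
  validate_otu_map(map)
  lines <- vapply(seq_along(map), function(i) {
    paste(c(names(map)[i], map[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

validate_otu_map <- function(map, arg = "otu map") {
  if (length(map) == 0L) return(invisible(map))
  if (is.null(names(map)) || any(!nzchar(names(map)))) {
    stop(arg, " must be a named list keyed by OTU ID")
  }
  if (anyDuplicated(names(map))) {
    stop("duplicate OTU IDs in ", arg, ": ",
         paste(unique(names(map)[duplicated(names(map))]), collapse = ", "))
  }
  all_ids <- unlist(map, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("sequence IDs duplicated within ", arg, ": ",
         paste(utils::head(unique(all_ids[duplicated(all_ids)]), 5), collapse = ", "))
  }
  if (any(lengths(map) == 0L)) {
    stop(arg, " contains empty OTU entries: ",
         paste(names(map)[lengths(map) == 0L], collapse = ", "))
  }
  invisible(map)
}

#' Read a Greengenes-style taxonomy table
#'
#' Two tab-delimited columns: reference ID, semicolon-joined lineage.
#' Whitespace around semicolons is tolerated. Duplicate reference IDs keep
#' the last entry (with a warning); an empty lineage field parses to an
#' empty lineage (with a warning).
#'
#' @param path Path to the taxonomy table.
#' @return A named character vector (reference ID -> lineage string).
#' @export
read_taxonomy_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) return(stats::setNames(character(), character()))
  no_tab <- which(!grepl("\t", lines, fixed = TRUE))
  if (length(no_tab) > 0) {
    stop("taxonomy table line without tab separator at line ",
         which(keep)[no_tab[1]], ": ", lines[no_tab[1]])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- trimws(vapply(fields, `[[`, character(1), 1L))
  lineages <- trimws(vapply(fields, function(f) {
    if (length(f) >= 2L) f[[2L]] else ""
  }, character(1)))
  lineages <- gsub("[[:space:]]*;[[:space:]]*", "; ", lineages)
  if (any(!nzchar(lineages))) {
    warning("empty lineage for reference ID(s): ",
            paste(ids[!nzchar(lineages)], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    warning("duplicate reference ID(s), last entry wins: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    last <- !duplicated(ids, fromLast = TRUE)
    ids <- ids[last]
    lineages <- lineages[last]
  }
  stats::setNames(lineages, ids)
}

#' @rdname read_taxonomy_table
#' @param taxonomy Named character vector of lineages.
#' @export
write_taxonomy_table <- function(taxonomy, path) {
  writeLines(paste(names(taxonomy), taxonomy, sep = "\t"), path)
  invisible(path)
}

#' Read a labeled distance matrix
#'
#' Tab-delimited square matrix whose first row and first column carry the
#' sample labels (the layout QIIME's beta-diversity scripts emit for, e.g.,
#' UniFrac distances). Tiny off-diagonal asymmetries -- floating-point
#' artifacts of the upstream computation -- are symmetrized by averaging;
#' asymmetry beyond `tol` is an error. The diagonal is forced to zero.
#'
#' @param path Path to the matrix file.
#' @param tol Largest tolerated absolute asymmetry (default `1e-9`).
#' @return A symmetric numeric matrix with zero diagonal and sample-label
#'   dimnames.
#' @export
read_distance_matrix <- function(path, tol = 1e-9) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    stop("distance matrix is not square: ", nrow(m), " x ", ncol(m))
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("distance matrix row and column labels disagree")
  }
  as_distance_matrix(m, tol = tol)
}

as_distance_matrix <- function(m, tol = 1e-9) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop("duplicate distance-matrix labels")
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop(sprintf("distance matrix asymmetric beyond tolerance (max |d_ij - d_ji| = %g > %g)",
                 asym, tol))
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (any(m < 0)) stop("distance matrix has negative entries")
  m
}

#' @rdname read_distance_matrix
#' @param d Symmetric labeled matrix.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(d, check.names = FALSE)
  out <- cbind(rownames(d), format(df, trim = TRUE, digits = 15))
  lines <- c(paste(c("", colnames(d)), collapse = "\t"),
             apply(out, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write Newick trees
#'
#' Thin wrappers over \pkg{ape}'s Newick parser that additionally strip the
#' surrounding quotes ape keeps on quoted labels, so leaf labels come back
#' as their text.
#'
#' @param path Path to a Newick file.
#' @return An \pkg{ape} `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- tryCatch(ape::read.tree(path), error = function(e) {
    stop("malformed Newick in '", path, "': ", conditionMessage(e))
  })
  if (is.null(tree)) stop("malformed Newick in '", path, "'")
  tree$tip.label <- gsub("^'(.*)'$", "\\1", tree$tip.label)
  tree
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read and write FASTA sequence files
#'
#' @param path Path to a FASTA file.
#' @return A \pkg{Biostrings} `DNAStringSet` whose names are the full header
#'   lines (ID plus description).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("empty FASTA record(s): ",
         paste(names(seqs)[Biostrings::width(seqs) == 0L], collapse = ", "))
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs A `DNAStringSet` (or named character vector of sequences).
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, format = "fasta")
  invisible(path)
}
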