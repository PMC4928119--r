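#' OTU abundance table
#'
#' An OTU table holds nonnegative abundances (counts or proportions) indexed
#' by OTU and sample, plus an optional Greengenes-style taxonomy string per
#' OTU. It is the in-memory form of a BIOM 1.0 contingency table.
#'
#' @param counts Numeric matrix, OTUs in rows and samples in columns, with
#'   unique non-empty dimnames. All values must be nonnegative.
#' @param taxonomy Optional character vector of semicolon-joined lineages,
#'   one per OTU (named or in row order).
#'
#' @return An object of class `otu_table`: a numeric matrix with a
#'   `taxonomy` attribute.
#' @export
#' @examples
#' m <- matrix(c(5, 0, 2, 3), 2, 2,
#'             dimnames = list(c("otu1", "otu2"), c("s1", "s2")))
#' tab <- otu_table(m, taxonomy = c("k__Bacteria; p__Firmicutes", "k__Bacteria"))
#' n_otus(tab)
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) > 0 && is.null(rownames(counts))) {
    stop("OTU table requires OTU row names")
  }
  if (ncol(counts) > 0 && is.null(colnames(counts))) {
    stop("OTU table requires sample column names")
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate OTU identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("OTU table values must be nonnegative and non-missing")
  }
  if (!is.null(taxonomy)) {
    if (!is.null(names(taxonomy))) {
      missing <- setdiff(rownames(counts), names(taxonomy))
      if (length(missing) > 0) {
        stop("taxonomy missing for OTUs: ", paste(missing, collapse = ", "))
      }
      taxonomy <- unname(taxonomy[rownames(counts)])
    } else if (length(taxonomy) != nrow(counts)) {
      stop("taxonomy length (", length(taxonomy),
           ") does not match number of OTUs (", nrow(counts), ")")
    }
    taxonomy <- as.character(taxonomy)
  }
  structure(counts, taxonomy = taxonomy, class = c("otu_table", "matrix", "array"))
}

#' @rdname otu_table
#' @param x An `otu_table`.
#' @export
otu_ids <- function(x) rownames(x)

#' @rdname otu_table
#' @export
sample_ids <- function(x) colnames(x)

#' @rdname otu_table
#' @export
n_otus <- function(x) nrow(x)

#' @rdname otu_table
#' @export
n_samples <- function(x) ncol(x)

#' @rdname otu_table
#' @export
otu_taxonomy <- function(x) {
  tx <- attr(x, "taxonomy")
  if (is.null(tx)) return(NULL)
  stats::setNames(tx, rownames(x))
}

#' Subset an OTU table, keeping taxonomy aligned
#'
#' @param x An `otu_table`.
#' @param i,j Row (OTU) and column (sample) indices.
#' @param ... Ignored.
#' @param drop Ignored; subsetting always returns an `otu_table`.
#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  tx <- attr(x, "taxonomy")
  m <- unclass(x)
  attr(m, "taxonomy") <- NULL
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  out <- m[i, j, drop = FALSE]
  if (!is.null(tx)) {
    names(tx) <- rownames(m)
    tx <- unname(tx[rownames(out)])
  }
  otu_table(out, taxonomy = tx)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples (total %g)\n",
              nrow(x), ncol(x), sum(x)))
  if (!is.null(attr(x, "taxonomy"))) cat("taxonomy: attached\n")
  k <- min(nrow(x), 6L)
  l <- min(ncol(x), 6L)
  print(unclass(x)[seq_len(k), seq_len(l), drop = FALSE])
  if (nrow(x) > k || ncol(x) > l) cat("...\n")
  invisible(x)
}

#' Convert an OTU table to a long tibble
#'
#' One row per (OTU, sample) pair; taxonomy carried along when attached.
#'
#' @param x An `otu_table`.
#' @param ... Ignored.
#' @return A tibble with columns `otu_id`, `sample_id`, `abundance`, and
#'   `taxonomy` when available.
#' @method as_tibble otu_table
#' @export
as_tibble.otu_table <- function(x, ...) {
  out <- tibble::tibble(
    otu_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    abundance = as.vector(unclass(x))
  )
  tx <- otu_taxonomy(x)
  if (!is.null(tx)) out$taxonomy <- unname(tx[out$otu_id])
  out
}
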