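#' Display labels from taxonomy strings
#'
#' Builds human-readable branch labels for tree annotation: `"Genus_species"`
#' when both are named, otherwise the deepest named rank prefixed by its
#' rank letter (e.g. `"f__Lachnospiraceae"`). Characters outside
#' `[A-Za-z0-9_.-]` become `_`; an empty taxonomy yields `"Unassigned"`.
#' `make_species_labels()` vectorizes and enforces uniqueness by appending
#' `_2`, `_3`, ... to repeats in input order.
#'
#' @param taxonomy A lineage string (for `species_label()`) or character
#'   vector of lineages (for `make_species_labels()`).
#' @return Display label(s).
#' @export
#' @examples
#' species_label("k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Peptostreptococcaceae; g__Filifactor; s__alocis")
species_label <- function(taxonomy) {
  ranks <- suppressWarnings(parse_taxonomy(taxonomy))
  named <- nzchar(ranks$name)
  if (nrow(ranks) == 0L || !any(named)) return(UNASSIGNED)
  genus <- ranks$name[ranks$prefix == "g__"]
  spp <- ranks$name[ranks$prefix == "s__"]
  label <- if (length(genus) == 1L && length(spp) == 1L &&
               nzchar(genus) && nzchar(spp)) {
    paste(genus, spp)
  } else {
    deepest <- max(which(named))
    paste0(ranks$prefix[deepest], ranks$name[deepest])
  }
  gsub("[^A-Za-z0-9_.-]", "_", label)
}

#' @rdname species_label
#' @export
make_species_labels <- function(taxonomy) {
  labels <- vapply(taxonomy, species_label, character(1), USE.NAMES = FALSE)
  counts <- list()
  for (i in seq_along(labels)) {
    l <- labels[[i]]
    n <- (counts[[l]] %||% 0L) + 1L
    counts[[l]] <- n
    if (n > 1L) labels[[i]] <- paste0(l, "_", n)
  }
  labels
}

#' Relabel tree leaves with species names
#'
#' Replaces the OTU-ID leaf labels of a phylogenetic tree with display
#' labels derived from each OTU's taxonomy, leaving topology and branch
#' lengths untouched. The old-to-new mapping is returned so data tracks can
#' be aligned to the relabeled tree.
#'
#' @param tree A `phylo` tree whose tips are OTU IDs.
#' @param assignments Taxonomy assignment tibble (columns `otu_id`,
#'   `taxonomy`) covering every leaf.
#' @return A list with `tree` (relabeled `phylo`) and `labels` (tibble
#'   `otu_id`, `label`).
#' @export
relabel_tree <- function(tree, assignments) {
  stopifnot(inherits(tree, "phylo"))
  tax <- stats::setNames(assignments$taxonomy, assignments$otu_id)
  missing <- setdiff(tree$tip.label, names(tax))
  if (length(missing) > 0) {
    stop("leaf label(s) without taxonomy assignment: ",
         paste(missing, collapse = ", "))
  }
  new_labels <- make_species_labels(unname(tax[tree$tip.label]))
  mapping <- tibble::tibble(otu_id = tree$tip.label, label = new_labels)
  tree$tip.label <- new_labels
  list(tree = tree, labels = mapping)
}

#' Quantitative annotation tracks for iTOL
#'
#' Computes per-OTU abundance metrics from a count table for display as
#' data tracks around a phylogenetic tree:
#'
#' * `log10_raw` -- `log10(1 + total count)` per OTU (the +1 keeps OTUs
#'   absent from a subset table representable);
#' * `mra` -- mean (over samples) relative abundance, optionally variance
#'   stabilized by the arcsine square-root transform `asin(sqrt(p))`
#'   applied to each per-sample proportion *before* averaging;
#' * `nmra` -- the per-group MRA of each OTU normalized across the groups
#'   of a metadata category, so the values for one OTU sum to 1 and show
#'   which groups carry it (an OTU absent everywhere gets all zeros,
#'   flagged).
#'
#' @param table An [otu_table()] of counts.
#' @param metadata Sample metadata (required for `nmra`).
#' @param category Metadata column defining the groups for `nmra`; group
#'   column order follows first appearance in the metadata.
#' @param mode One of `"log10_raw"`, `"mra"`, `"nmra"`.
#' @param stabilize Apply the arcsine square-root transform (proportions
#'   only; an error with `log10_raw`).
#' @param labels Optional old-to-new label mapping from [relabel_tree()]
#'   used to key rows by tree leaf labels instead of OTU IDs.
#' @return A tibble of class `itol_dataset` with a `leaf` column and one
#'   (or one-per-group) value column; attributes `mode`, `stabilized`,
#'   `zero_total` (OTU IDs with zero denominator under `nmra`).
#' @export
itol_metrics <- function(table, metadata = NULL, category = NULL,
                         mode = c("log10_raw", "mra", "nmra"),
                         stabilize = FALSE, labels = NULL) {
  stopifnot(inherits(table, "otu_table"))
  mode <- match.arg(mode)
  if (stabilize && mode == "log10_raw") {
    stop("variance stabilization applies to proportions (mra/nmra), not log10_raw")
  }
  leaf <- otu_ids(table)
  zero_total <- character(0)
  if (mode == "log10_raw") {
    values <- tibble::tibble(log10_raw = unname(log10(1 + rowSums(table))))
  } else {
    rel <- unclass(suppressWarnings(relative_abundance(table)))
    if (stabilize) rel <- asin(sqrt(rel))
    if (mode == "mra") {
      values <- tibble::tibble(mra = unname(rowMeans(rel)))
    } else {
      if (is.null(metadata) || is.null(category)) {
        stop("nmra requires metadata and a category column")
      }
      if (!category %in% names(metadata)) {
        stop("unknown metadata category: ", category)
      }
      grp <- metadata[[category]][match(sample_ids(table), metadata$SampleID)]
      if (any(is.na(grp))) {
        stop("sample(s) missing from metadata: ",
             paste(sample_ids(table)[is.na(grp)], collapse = ", "))
      }
      group_order <- unique(metadata[[category]])
      group_order <- group_order[group_order %in% grp]
      mra_g <- vapply(group_order, function(g) {
        rowMeans(rel[, grp == g, drop = FALSE])
      }, numeric(nrow(rel)))
      mra_g <- matrix(mra_g, nrow = nrow(rel),
                      dimnames = list(leaf, group_order))
      denom <- rowSums(mra_g)
      zero_total <- leaf[denom == 0]
      norm <- sweep(mra_g, 1L, pmax(denom, 1e-300), "/")
      norm[denom == 0, ] <- 0
      values <- tibble::as_tibble(norm)
    }
  }
  out <- dplyr::bind_cols(tibble::tibble(leaf = leaf), values)
  if (!is.null(labels)) {
    idx <- match(out$leaf, labels$otu_id)
    out$leaf[!is.na(idx)] <- labels$label[idx[!is.na(idx)]]
  }
  attr(out, "mode") <- mode
  attr(out, "stabilized") <- stabilize
  attr(out, "zero_total") <- zero_total
  class(out) <- c("itol_dataset", class(out))
  out
}

#' Write an iTOL dataset file
#'
#' Serializes an annotation dataset in the iTOL text template format: a
#' header block (dataset type, separator, label, field labels/colors)
#' followed by a `DATA` section with one comma-separated line per leaf.
#' Single-column metrics become a `DATASET_SIMPLEBAR`, multi-column
#' (group-normalized) metrics a `DATASET_MULTIBAR`.
#'
#' @param ds An `itol_dataset` from [itol_metrics()].
#' @param path Output path.
#' @param label Dataset label shown in iTOL (defaults to the metric mode).
#' @export
write_itol_dataset <- function(ds, path, label = NULL) {
  stopifnot(inherits(ds, "itol_dataset"))
  fields <- setdiff(names(ds), "leaf")
  label <- label %||% attr(ds, "mode") %||% "abundance"
  palette <- grDevices::hcl.colors(max(length(fields), 2L), "Dark 3")
  header <- if (length(fields) == 1L) {
    c("DATASET_SIMPLEBAR",
      "SEPARATOR COMMA",
      paste0("DATASET_LABEL,", label),
      paste0("COLOR,", palette[[1]]),
      paste0("FIELD_LABELS,", fields))
  } else {
    c("DATASET_MULTIBAR",
      "SEPARATOR COMMA",
      paste0("DATASET_LABEL,", label),
      paste0("COLOR,", palette[[1]]),
      paste0("FIELD_COLORS,", paste(palette[seq_along(fields)], collapse = ",")),
      paste0("FIELD_LABELS,", paste(fields, collapse = ",")))
  }
  data_lines <- vapply(seq_len(nrow(ds)), function(i) {
    paste(c(ds$leaf[[i]],
            format(unlist(ds[i, fields]), trim = TRUE, digits = 15)),
          collapse = ",")
  }, character(1))
  writeLines(c(header, "DATA", data_lines), path)
  invisible(path)
}

#' @rdname write_itol_dataset
#' @export
read_itol_dataset <- function(path) {
  lines <- readLines(path)
  data_at <- match("DATA", lines)
  if (is.na(data_at)) stop("no DATA section in iTOL dataset: ", path)
  header <- lines[seq_len(data_at - 1L)]
  fl <- header[startsWith(header, "FIELD_LABELS,")]
  fields <- if (length(fl) == 1L) {
    strsplit(sub("^FIELD_LABELS,", "", fl), ",", fixed = TRUE)[[1]]
  } else {
    "value"
  }
  body <- lines[-seq_len(data_at)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  out <- tibble::tibble(leaf = vapply(parts, `[[`, character(1), 1L))
  for (k in seq_along(fields)) {
    out[[fields[[k]]]] <- vapply(parts, function(p) as.numeric(p[[k + 1L]]),
                                 numeric(1))
  }
  mode_line <- header[[1]]
  attr(out, "mode") <- if (identical(mode_line, "DATASET_MULTIBAR")) "nmra" else NA
  class(out) <- c("itol_dataset", class(out))
  out
}
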