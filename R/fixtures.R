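#' Specification for a synthetic amplicon community
#'
#' Describes a Dirichlet-multinomial community used to generate complete,
#' internally consistent synthetic datasets (OTU map, taxonomy table,
#' mapping file, reference FASTA, tree) for testing every pipeline stage
#' without sequencing data. Defaults describe a two-group study (20 samples
#' per group, 1000 reads each) of 20 species whose ranked base composition
#' follows a 1/i series, with an 8-fold enrichment of the first 5 species
#' in the second group and 3 redundant reference records per species (to
#' exercise taxonomy condensing).
#'
#' @param n_species Number of true species.
#' @param redundancy Reference-database records per species (all sharing
#'   one taxonomy string).
#' @param groups Group labels (sample IDs avoid underscores so they decode
#'   cleanly from read IDs).
#' @param n_per_group Samples per group (scalar or one per group).
#' @param depth Reads per sample.
#' @param base_concentration Dirichlet concentration vector (length
#'   `n_species`); default `total_concentration * (1/i) / sum(1/i)`.
#' @param total_concentration Total concentration for the default base
#'   (controls overdispersion; 100 gives moderate sample-to-sample
#'   variability at which injected fold-8 effects remain recoverable).
#' @param effect_species How many species are differentially abundant in
#'   the last group.
#' @param fold_change Multiplicative effect on those species'
#'   concentrations.
#' @param seed Integer seed fixing every output byte-for-byte.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(n_species = 20L, redundancy = 3L,
                           groups = c("NonSmoker", "Smoker"),
                           n_per_group = 20L, depth = 1000L,
                           base_concentration = NULL,
                           total_concentration = 100,
                           effect_species = 5L, fold_change = 8,
                           seed = 42L) {
  stopifnot(n_species >= 1, redundancy >= 1, length(groups) >= 1,
            all(n_per_group >= 1), depth >= 1, fold_change > 0,
            effect_species >= 0, effect_species <= n_species)
  if (length(n_per_group) == 1L) {
    n_per_group <- rep(as.integer(n_per_group), length(groups))
  }
  stopifnot(length(n_per_group) == length(groups))
  if (is.null(base_concentration)) {
    w <- 1 / seq_len(n_species)
    base_concentration <- total_concentration * w / sum(w)
  }
  stopifnot(length(base_concentration) == n_species, all(base_concentration > 0))
  structure(list(
    n_species = as.integer(n_species), redundancy = as.integer(redundancy),
    groups = groups, n_per_group = n_per_group, depth = as.integer(depth),
    base_concentration = base_concentration,
    effect_species = as.integer(effect_species), fold_change = fold_change,
    seed = as.integer(seed)
  ), class = "community_spec")
}

spec_lineage <- function(i) {
  sprintf(paste0("k__Bacteria; p__Phylum%02d; c__Class%02d; o__Order%02d; ",
                 "f__Family%02d; g__Genus%02d; s__species%02d"),
          (i - 1L) %% 5L + 1L, (i - 1L) %% 5L + 1L, (i - 1L) %% 7L + 1L,
          i, i, i)
}

spec_ref_ids <- function(spec) {
  as.character(100000L + seq_len(spec$n_species * spec$redundancy))
}

spec_sample_ids <- function(spec) {
  unlist(lapply(seq_along(spec$groups), function(g) {
    sprintf("%s%02d", gsub("[^A-Za-z0-9]", "", spec$groups[[g]]),
            seq_len(spec$n_per_group[[g]]))
  }))
}

spec_alpha <- function(spec, group_index) {
  a <- spec$base_concentration
  if (group_index == length(spec$groups) && spec$effect_species > 0) {
    idx <- seq_len(spec$effect_species)
    a[idx] <- a[idx] * spec$fold_change
  }
  a
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a complete synthetic amplicon dataset
#'
#' Draws, per sample, a composition from a Dirichlet whose concentration is
#' the base vector times the group's fold-change effect, then multinomial
#' read counts at the specified depth. Reads of each species are spread
#' uniformly over that species' redundant reference IDs, so condensing the
#' result recovers exactly one OTU per distinct lineage. Also emits a
#' QIIME-style mapping table, a Greengenes-style taxonomy table, a
#' placeholder-sequence reference FASTA and a random coalescent tree over
#' the reference IDs. Output is fully determined by `spec$seed`.
#'
#' @param spec A [community_spec()].
#' @return A list with `otu_map`, `taxonomy` (named lineage vector over
#'   reference IDs), `metadata` (tibble), `reference_seqs`
#'   (`DNAStringSet`), `tree` (`phylo`), `lineages` (the distinct lineage
#'   strings), and `spec`.
#' @export
make_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  withr::with_seed(spec$seed, {
    ref_ids <- spec_ref_ids(spec)
    species_of_ref <- rep(seq_len(spec$n_species), each = spec$redundancy)
    lineages <- vapply(seq_len(spec$n_species), spec_lineage, character(1))
    taxonomy <- stats::setNames(lineages[species_of_ref], ref_ids)
    samples <- spec_sample_ids(spec)
    group_of_sample <- rep(spec$groups, spec$n_per_group)

    otu_map <- stats::setNames(vector("list", length(ref_ids)), ref_ids)
    for (si in seq_along(samples)) {
      gi <- match(group_of_sample[[si]], spec$groups)
      comp <- rdirichlet1(spec_alpha(spec, gi))
      counts <- as.vector(stats::rmultinom(1L, spec$depth, comp))
      next_read <- 1L
      for (sp in which(counts > 0)) {
        copies <- which(species_of_ref == sp)
        split_counts <- as.vector(
          stats::rmultinom(1L, counts[[sp]], rep(1, length(copies)))
        )
        for (ci in seq_along(copies)) {
          k <- split_counts[[ci]]
          if (k == 0L) next
          ids <- sprintf("%s_%06d", samples[[si]],
                         seq.int(next_read, length.out = k))
          next_read <- next_read + k
          ref <- ref_ids[[copies[[ci]]]]
          otu_map[[ref]] <- c(otu_map[[ref]], ids)
        }
      }
    }
    otu_map <- otu_map[lengths(otu_map) > 0L]

    barcodes <- replicate(length(samples), paste(
      sample(c("A", "C", "G", "T"), 8L, replace = TRUE), collapse = ""))
    while (anyDuplicated(barcodes)) {
      dup <- duplicated(barcodes)
      barcodes[dup] <- replicate(sum(dup), paste(
        sample(c("A", "C", "G", "T"), 8L, replace = TRUE), collapse = ""))
    }
    metadata <- tibble::tibble(
      SampleID = samples,
      BarcodeSequence = barcodes,
      LinkerPrimerSequence = "CATGCTGCCTCCCGTAGGAGT",
      Group = group_of_sample,
      Description = paste("synthetic sample", samples)
    )

    seqs <- Biostrings::DNAStringSet(vapply(ref_ids, function(id) {
      paste(sample(c("A", "C", "G", "T"), 250L, replace = TRUE), collapse = "")
    }, character(1)))
    names(seqs) <- ref_ids

    tree <- ape::rcoal(length(ref_ids), tip.label = sample(ref_ids))

    list(otu_map = otu_map, taxonomy = taxonomy, metadata = metadata,
         reference_seqs = seqs, tree = tree, lineages = lineages, spec = spec)
  })
}

#' Generate paired primer-specific OTU maps
#'
#' Emulates two-region sequencing of one community: a fraction of species
#' is captured by both primers (with independent multinomial draws per
#' primer) and the remainder is split alternately between the two. Read IDs
#' are disjoint across primers; sample encoding follows the usual
#' convention. Deterministic under `spec$seed`.
#'
#' @param spec A [community_spec()].
#' @param overlap_frac Fraction of species captured by both primers.
#' @return A list with `map_a`, `map_b`, and `shared_otus` /
#'   `exclusive_otus` bookkeeping (species-level OTU IDs, one reference ID
#'   per species).
#' @export
make_two_primer_maps <- function(spec, overlap_frac = 0.5) {
  stopifnot(inherits(spec, "community_spec"),
            overlap_frac >= 0, overlap_frac <= 1)
  withr::with_seed(spec$seed, {
    n <- spec$n_species
    otu_ids <- spec_ref_ids(spec)[seq.int(1L, by = spec$redundancy, length.out = n)]
    n_shared <- round(overlap_frac * n)
    shared <- seq_len(n_shared)
    rest <- setdiff(seq_len(n), shared)
    excl_a <- rest[seq_along(rest) %% 2L == 1L]
    excl_b <- rest[seq_along(rest) %% 2L == 0L]
    samples <- spec_sample_ids(spec)
    group_of_sample <- rep(spec$groups, spec$n_per_group)

    draw_map <- function(species_set, read_offset) {
      m <- stats::setNames(vector("list", length(species_set)),
                           otu_ids[species_set])
      for (si in seq_along(samples)) {
        gi <- match(group_of_sample[[si]], spec$groups)
        a <- spec_alpha(spec, gi)[species_set]
        comp <- rdirichlet1(a)
        counts <- as.vector(stats::rmultinom(1L, spec$depth, comp))
        next_read <- read_offset + 1L
        for (k in which(counts > 0)) {
          ids <- sprintf("%s_%06d", samples[[si]],
                         seq.int(next_read, length.out = counts[[k]]))
          next_read <- next_read + counts[[k]]
          m[[otu_ids[species_set[[k]]]]] <- c(m[[otu_ids[species_set[[k]]]]], ids)
        }
      }
      m[lengths(m) > 0L]
    }
    map_a <- draw_map(sort(c(shared, excl_a)), 0L)
    map_b <- draw_map(sort(c(shared, excl_b)), 500000L)
    list(map_a = map_a, map_b = map_b,
         shared_otus = otu_ids[shared],
         exclusive_otus = list(a = otu_ids[excl_a], b = otu_ids[excl_b]))
  })
}

#' Write a complete synthetic dataset directory
#'
#' Materializes [make_community()] output as the standard file set: BIOM
#' table, mapping file, OTU map, taxonomy table, reference FASTA and Newick
#' tree.
#'
#' @param community Output of [make_community()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_map(community$otu_map, file.path(dir, "otu_map.txt"))
  write_taxonomy_table(community$taxonomy, file.path(dir, "taxonomy.txt"))
  write_mapping(community$metadata, file.path(dir, "mapping.txt"))
  write_fasta(community$reference_seqs, file.path(dir, "reference.fasta"))
  write_newick(community$tree, file.path(dir, "tree.nwk"))
  assignments <- assign_taxonomy(community$otu_map, community$taxonomy)
  table <- build_otu_table(community$otu_map, assignments, community$metadata)
  write_biom(table, file.path(dir, "table.biom"))
  invisible(dir)
}
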