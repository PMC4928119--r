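full_lineage <- paste0("k__Bacteria; p__Firmicutes; c__Clostridia; ",
                       "o__Clostridiales; f__Peptostreptococcaceae; ",
                       "g__Filifactor; s__alocis")

test_that("species labels prefer Genus species and fall back to deepest rank", {
  expect_equal(species_label(full_lineage), "Filifactor_alocis")
  expect_equal(species_label("k__Bacteria; p__; c__; o__; f__; g__; s__"),
               "k__Bacteria")
  expect_equal(species_label(""), "Unassigned")
  expect_equal(species_label("k__; p__; c__; o__; f__; g__; s__"), "Unassigned")
  no_species <- "k__Bacteria; p__Firmicutes; c__Clostridia; o__; f__Lachnospiraceae; g__; s__"
  expect_equal(species_label(no_species), "f__Lachnospiraceae")
  messy <- "k__Bacteria; g__Prevotella; s__sp. oral taxon 306"
  expect_equal(species_label(messy), "Prevotella_sp._oral_taxon_306")
})

test_that("duplicate labels get deterministic numeric suffixes", {
  labels <- make_species_labels(rep(full_lineage, 3))
  expect_equal(labels, c("Filifactor_alocis", "Filifactor_alocis_2",
                         "Filifactor_alocis_3"))
  expect_equal(make_species_labels(c(full_lineage, "", full_lineage)),
               c("Filifactor_alocis", "Unassigned", "Filifactor_alocis_2"))
})

test_that("relabel_tree renames leaves without touching the topology", {
  tree <- ape::read.tree(text = "((42:1.5,43:2.5):0.5,44:3.0);")
  asg <- tibble::tibble(
    otu_id = c("42", "43", "44"),
    taxonomy = c(full_lineage,
                 "k__Bacteria; p__Firmicutes; g__Veillonella; s__dispar",
                 "k__Bacteria; p__Proteobacteria; g__; s__")
  )
  out <- relabel_tree(tree, asg)
  expect_equal(sort(out$tree$tip.label),
               sort(c("Filifactor_alocis", "Veillonella_dispar",
                      "p__Proteobacteria")))
  expect_equal(sort(out$tree$edge.length), sort(tree$edge.length))
  expect_equal(out$tree$Nnode, tree$Nnode)
  expect_equal(out$labels$otu_id, tree$tip.label)

  shared <- ape::rcoal(7, tip.label = as.character(1:7))
  asg7 <- tibble::tibble(otu_id = as.character(1:7), taxonomy = full_lineage)
  out7 <- relabel_tree(shared, asg7)
  expect_equal(length(unique(out7$tree$tip.label)), 7L)

  expect_error(relabel_tree(tree, asg[-1, ]), "42")
})

test_that("relabeling with identity assignments preserves the Newick text", {
  tree <- ape::read.tree(text = "((A:1,B:2):0.5,C:3);")
  asg <- tibble::tibble(otu_id = c("A", "B", "C"),
                        taxonomy = paste0("k__", c("A", "B", "C")))
  out <- relabel_tree(tree, asg)
  expect_equal(gsub("k__", "", ape::write.tree(out$tree)),
               ape::write.tree(tree))
})

itol_fixture <- function() {
  # two groups of two samples; otuX has relative abundance 0.02 in every g1
  # sample and 0.06 in every g2 sample (sample depth 100)
  m <- matrix(c(2, 98, 0,
                2, 98, 0,
                6, 93, 1,
                6, 93, 1), nrow = 3,
              dimnames = list(c("otuX", "otuY", "otuZ"),
                              c("a1", "a2", "b1", "b2")))
  md <- tibble::tibble(SampleID = c("a1", "a2", "b1", "b2"),
                       Group = c("g1", "g1", "g2", "g2"))
  list(table = otu_table(m), metadata = md)
}

test_that("iTOL metrics follow the stated abundance algebra", {
  tab <- otu_table(matrix(c(999, 1), 2, 1,
                          dimnames = list(c("big", "small"), "s1")))
  ds <- itol_metrics(tab, mode = "log10_raw")
  expect_equal(ds$log10_raw[ds$leaf == "big"], 3)

  half <- otu_table(matrix(c(1, 1, 2, 2), 2, 2,
                           dimnames = list(c("h", "o"), c("s1", "s2"))))
  mra <- itol_metrics(half, mode = "mra")
  expect_equal(mra$mra[mra$leaf == "h"], 0.5)
  stab <- itol_metrics(half, mode = "mra", stabilize = TRUE)
  expect_equal(stab$mra[stab$leaf == "h"], pi / 4)

  fx <- itol_fixture()
  nm <- itol_metrics(fx$table, fx$metadata, category = "Group", mode = "nmra")
  expect_equal(unlist(nm[nm$leaf == "otuX", c("g1", "g2")]),
               c(g1 = 0.25, g2 = 0.75))
  sums <- rowSums(as.matrix(nm[, c("g1", "g2")]))
  expect_equal(unname(sums), rep(1, 3), tolerance = 1e-9)

  expect_error(itol_metrics(fx$table, mode = "log10_raw", stabilize = TRUE),
               "stabiliz")
  expect_error(itol_metrics(fx$table, fx$metadata, category = "Nope",
                            mode = "nmra"), "Nope")
  expect_error(itol_metrics(fx$table, mode = "nmra"), "category")
})

test_that("an OTU absent everywhere gets a zero nmra row and is flagged", {
  fx <- itol_fixture()
  m <- rbind(unclass(fx$table), otuGone = 0)
  tab <- otu_table(m)
  nm <- suppressWarnings(
    itol_metrics(tab, fx$metadata, category = "Group", mode = "nmra")
  )
  gone <- nm[nm$leaf == "otuGone", c("g1", "g2")]
  expect_equal(unname(unlist(gone)), c(0, 0))
  expect_equal(attr(nm, "zero_total"), "otuGone")
})

test_that("arcsine square-root stabilization happens before averaging", {
  tab <- otu_table(matrix(c(1, 9, 5, 5), 2, 2,
                          dimnames = list(c("t", "u"), c("s1", "s2"))))
  # t has proportions 0.1 and 0.5
  stab <- itol_metrics(tab, mode = "mra", stabilize = TRUE)
  mean_of_transforms <- mean(asin(sqrt(c(0.1, 0.5))))
  transform_of_mean <- asin(sqrt(mean(c(0.1, 0.5))))
  expect_equal(stab$mra[stab$leaf == "t"], mean_of_transforms)
  expect_false(isTRUE(all.equal(mean_of_transforms, transform_of_mean)))
  # monotone [0,1] -> [0, pi/2]
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(asin(sqrt(p))) > 0))
  expect_equal(range(asin(sqrt(p))), c(0, pi / 2))
})

test_that("iTOL dataset files round-trip and name fields in metadata order", {
  fx <- itol_fixture()
  md4 <- tibble::tibble(SampleID = c("a1", "a2", "b1", "b2"),
                        Site = c("w", "x", "y", "z"))
  nm4 <- itol_metrics(fx$table, md4, category = "Site", mode = "nmra")
  path <- withr::local_tempfile(fileext = ".txt")
  write_itol_dataset(nm4, path)
  lines <- readLines(path)
  expect_equal(lines[[1]], "DATASET_MULTIBAR")
  expect_equal(sub("FIELD_LABELS,", "", lines[grepl("^FIELD_LABELS", lines)]),
               "w,x,y,z")
  back <- read_itol_dataset(path)
  expect_equal(back$leaf, nm4$leaf)
  for (g in c("w", "x", "y", "z")) expect_equal(back[[g]], nm4[[g]])

  single <- itol_metrics(fx$table, mode = "log10_raw")
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_itol_dataset(single, p2)
  l2 <- readLines(p2)
  expect_equal(l2[[1]], "DATASET_SIMPLEBAR")
  expect_true("DATA" %in% l2)
  b2 <- read_itol_dataset(p2)
  expect_equal(b2[[2]], single$log10_raw)
})

test_that("metric rows can be keyed by relabeled tree leaves", {
  fx <- itol_fixture()
  tree <- ape::read.tree(text = "((otuX:1,otuY:1):1,otuZ:2);")
  asg <- tibble::tibble(otu_id = c("otuX", "otuY", "otuZ"),
                        taxonomy = c(full_lineage,
                                     "k__Bacteria; g__Veillonella; s__dispar",
                                     "k__Bacteria; g__Rothia; s__aeria"))
  rel <- relabel_tree(tree, asg)
  ds <- itol_metrics(fx$table, mode = "mra", labels = rel$labels)
  expect_setequal(ds$leaf, rel$tree$tip.label)
})
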