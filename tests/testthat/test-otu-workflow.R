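test_that("split_sequences chunks without splitting or reordering records", {
  ids <- sprintf("S1_%06d", 1:45000)
  chunks <- split_sequences(ids, 20000L)
  expect_equal(lengths(chunks), c(20000L, 20000L, 5000L))
  expect_identical(unlist(chunks), ids)

  expect_equal(lengths(split_sequences(ids[1:10], 20000L)), 10L)
  expect_equal(split_sequences(letters[1:3], 1L),
               list("a", "b", "c"))
  expect_identical(split_sequences(character(0), 5L), list())
})

test_that("merge_otu_results concatenates member lists in input order", {
  merged <- merge_otu_results(list(list(A = "s1"), list(A = "s2", B = "s3")))
  expect_identical(merged, list(A = c("s1", "s2"), B = "s3"))

  single <- list(A = c("s1", "s2"), B = "s3")
  expect_identical(merge_otu_results(list(single)), single)

  expect_error(
    merge_otu_results(list(list(A = "s1"), list(B = "s1"))),
    "s1"
  )
})

test_that("split, per-chunk picking, then merge equals direct picking", {
  withr::with_seed(21, {
    ids <- sprintf("S%d_%06d", sample(1:5, 5000, replace = TRUE), 1:5000)
  })
  direct <- mock_picker(ids)
  for (chunk_size in c(1L, 7L, 20000L)) {
    merged <- merge_otu_results(lapply(split_sequences(ids, chunk_size),
                                       mock_picker))
    expect_identical(merged[sort(names(merged))], direct[sort(names(direct))],
                     info = paste("chunk_size", chunk_size))
  }
})

test_that("primer averaging halves shared OTUs and passes exclusives through", {
  map_a <- list(otuX = sprintf("a%02d", 1:10), otuY = sprintf("y%02d", 1:7))
  map_b <- list(otuX = sprintf("b%02d", 1:20), otuZ = "z1")
  out <- primer_average(map_a, map_b)
  expect_length(out$otuX, 15L)     # ceiling((10 + 20) / 2)
  expect_identical(out$otuY, map_a$otuY)
  expect_identical(out$otuZ, "z1")
  # a-first interleaving then truncation
  expect_equal(out$otuX[1:4], c("a01", "b01", "a02", "b02"))

  shared_singleton <- primer_average(list(o = "a1"), list(o = "b1"))
  expect_identical(shared_singleton$o, "a1")
})

test_that("primer averaging conserves or reduces totals; equality iff disjoint", {
  map_a <- list(o1 = paste0("a", 1:9), o2 = paste0("c", 1:4))
  map_b <- list(o1 = paste0("b", 1:6), o3 = paste0("d", 1:5))
  out <- primer_average(map_a, map_b)
  total_in <- sum(lengths(map_a)) + sum(lengths(map_b))
  expect_lt(sum(lengths(out)), total_in)
  expect_equal(sum(lengths(out)),
               4 + 5 + ceiling((9 + 6) / 2))

  disjoint <- primer_average(list(o1 = paste0("a", 1:3)),
                             list(o2 = paste0("b", 1:2)))
  expect_equal(sum(lengths(disjoint)), 5L)

  # self-averaging keeps per-OTU counts: ceiling(2n/2) = n
  self <- primer_average(map_a, stats::setNames(map_a, names(map_a)))
  expect_equal(lengths(self), lengths(map_a))
})

test_that("assign_taxonomy looks up reference lineages and reports misses", {
  ref <- c(`42` = "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Enterobacteriales; f__Enterobacteriaceae; g__Escherichia; s__coli")
  asg <- assign_taxonomy(list(`42` = "s1_1"), ref)
  expect_equal(asg$taxonomy, unname(ref))

  expect_message(
    asg2 <- assign_taxonomy(list(`42` = "s1_1", `999` = "s1_2"), ref),
    "missing"
  )
  expect_equal(asg2$taxonomy[asg2$otu_id == "999"], "Unassigned")
  expect_equal(attr(asg2, "missing"), "999")

  withr::with_seed(13, {
    ids <- as.character(sample.int(5000, 1000))
    covered <- sample(ids, 900)
  })
  ref_big <- stats::setNames(rep("k__Bacteria", 900), covered)
  map_big <- stats::setNames(lapply(seq_along(ids), function(i) paste0("S1_", i)),
                             ids)
  suppressMessages(asg3 <- assign_taxonomy(map_big, ref_big))
  expect_length(attr(asg3, "missing"), 100L)
  expect_setequal(attr(asg3, "missing"), setdiff(ids, covered))
})

test_that("condense_otus bins by full taxonomy and conserves sequences", {
  lineage <- "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Enterobacteriales; f__Enterobacteriaceae; g__Escherichia; s__coli"
  map <- list(`30` = paste0("s1_", 1:2), `12` = paste0("s2_", 1:3),
              `25` = paste0("s3_", 1:5))
  asg <- tibble::tibble(otu_id = names(map), taxonomy = lineage)
  res <- condense_otus(asg, map)
  expect_length(res$otu_map, 1L)
  expect_equal(names(res$otu_map), "12")   # lexicographically smallest
  expect_length(res$otu_map[["12"]], 10L)
  # representative's members first, then ascending OTU ID order
  expect_equal(res$otu_map[["12"]],
               c(paste0("s2_", 1:3), paste0("s3_", 1:5), paste0("s1_", 1:2)))
  expect_setequal(unname(unlist(res$otu_map)), unname(unlist(map)))
  expect_equal(nrow(res$assignments), 1L)
})

test_that("condensing distinct lineages is the identity up to bookkeeping", {
  map <- list(a = "s1_1", b = "s1_2", c = "s1_3")
  asg <- tibble::tibble(otu_id = c("a", "b", "c"),
                        taxonomy = paste0("k__K; p__P", 1:3))
  res <- condense_otus(asg, map)
  expect_identical(res$otu_map, map)

  withr::with_seed(31, {
    lineages <- paste0("k__K; p__P; c__C; o__O; f__F; g__G; s__sp", 1:7)
    ids <- sprintf("%05d", sample.int(99999, 100))
    asg100 <- tibble::tibble(otu_id = ids,
                             taxonomy = sample(lineages, 100, replace = TRUE))
    map100 <- stats::setNames(lapply(seq_along(ids), function(i) {
      sprintf("S%d_%05d", i %% 4 + 1, i)
    }), ids)
  })
  res100 <- condense_otus(asg100, map100)
  expect_length(res100$otu_map, 7L)
  expect_setequal(unname(unlist(res100$otu_map)), unname(unlist(map100)))
  expect_error(condense_otus(asg100[-1, ], map100), "without taxonomy")
})

test_that("pick_representatives copies reference sequences verbatim", {
  ref <- Biostrings::DNAStringSet(c(`42` = "ACGTACGT", `43` = "GGGG"))
  out <- pick_representatives("42", ref)
  expect_equal(as.character(out), c(`42` = "ACGTACGT"))
  expect_length(pick_representatives(character(0), ref), 0L)
  expect_error(pick_representatives(c("42", "999"), ref), "999")
})

test_that("build_otu_table counts sequences per decoded sample", {
  md <- tibble::tibble(SampleID = c("S1", "S2"))
  tab <- build_otu_table(list(otuA = c("S1_1", "S1_2", "S2_1")), metadata = md)
  expect_equal(unclass(tab)["otuA", ], c(S1 = 2, S2 = 1))

  empty <- build_otu_table(stats::setNames(list(), character()), metadata = md)
  expect_equal(dim(empty), c(0L, 2L))
  expect_equal(sample_ids(empty), c("S1", "S2"))

  # underscores inside sample IDs: split on the LAST underscore
  md2 <- tibble::tibble(SampleID = "P_1")
  tab2 <- build_otu_table(list(o = c("P_1_000123")), metadata = md2)
  expect_equal(unclass(tab2)["o", "P_1"], 1)

  expect_error(build_otu_table(list(o = "noseparator"), metadata = md),
               "noseparator")
  expect_error(build_otu_table(list(o = "S9_1"), metadata = md), "S9")
})

test_that("build_otu_table conserves the grand total on random maps", {
  withr::with_seed(17, {
    samples <- sprintf("S%02d", 1:20)
    seqs <- sprintf("%s_%06d", sample(samples, 10000, replace = TRUE), 1:10000)
    otus <- sprintf("otu%03d", sample.int(150, 10000, replace = TRUE))
  })
  map <- split(seqs, otus)
  md <- tibble::tibble(SampleID = samples)
  tab <- build_otu_table(map, metadata = md)
  expect_equal(sum(tab), 10000)
  expect_equal(sum(lengths(map)), 10000L)
  # per-sample column sums are conserved by condensing
  asg <- tibble::tibble(otu_id = names(map),
                        taxonomy = paste0("k__K; s__sp",
                                          as.integer(factor(names(map))) %% 12))
  cond <- condense_otus(asg, map)
  tab2 <- build_otu_table(cond$otu_map, metadata = md)
  expect_equal(colSums(tab2), colSums(tab))
})

test_that("transient filter applies strict boundaries on both passes", {
  fx <- boundary_table()
  # prevalence pass only
  res <- filter_transient(fx$table, fx$assignments,
                          prevalence_frac = 0.05, abundance_frac = 0)
  removed <- res$report$aggregate_id
  expect_length(removed, 1L)
  expect_match(removed, "g__Four")
  expect_true("otuFive" %in% otu_ids(res$table))

  # both passes at the documented defaults
  res2 <- filter_transient(fx$table, fx$assignments)
  expect_setequal(
    unlist(res2$report$otu_ids),
    c("otuFour", "otuNine")
  )
  expect_equal(res2$report$pass[vapply(res2$report$otu_ids, `[[`, "", 1) == "otuNine"],
               "abundance")
  expect_true(all(c("otuFive", "otuTen", "otuFill") %in% otu_ids(res2$table)))
})

test_that("transient filter conserves counts and reports percent abundance", {
  fx <- boundary_table()
  res <- filter_transient(fx$table, fx$assignments)
  removed_total <- sum(unclass(fx$table)[unlist(res$report$otu_ids), ])
  expect_equal(sum(res$table) + removed_total, sum(fx$table))
  expect_true(all(res$report$percent_abundance >= 0 &
                    res$report$percent_abundance <= 100))
  nine <- res$report$percent_abundance[res$report$pass == "abundance"]
  expect_equal(nine, 100 * 9 / 100000)

  # zero thresholds are the identity
  res0 <- filter_transient(fx$table, fx$assignments,
                           prevalence_frac = 0, abundance_frac = 0)
  expect_equal(unclass(res0$table), unclass(fx$table), ignore_attr = TRUE)
  expect_equal(nrow(res0$report), 0L)

  expect_error(filter_transient(fx$table, fx$assignments[-1, ]),
               "without taxonomy")
})

test_that("raising a filter threshold never rescues a removed aggregate", {
  fx <- boundary_table()
  kept <- sapply(c(0, 0.02, 0.05, 0.08, 0.12), function(prev) {
    otu_ids(filter_transient(fx$table, fx$assignments,
                             prevalence_frac = prev,
                             abundance_frac = 0)$table)
  })
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
  # sequence IDs from an OTU map land in the report
  map <- stats::setNames(
    lapply(otu_ids(fx$table), function(o) paste0("s001_", o)),
    otu_ids(fx$table)
  )
  res <- filter_transient(fx$table, fx$assignments, otu_map = map)
  expect_true("s001_otuFour" %in% unlist(res$report$seq_ids))
})
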