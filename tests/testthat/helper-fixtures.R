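# Small in-code fixtures shared by the tests.

# A count table whose genus-level aggregates hit the prevalence and
# abundance filter boundaries exactly (100 samples, grand total 100000):
#   g__Four   present in 4 samples   (< 5% -> removed in pass 1)
#   g__Five   present in 5 samples   (= 5% -> retained in pass 1)
#            with 20 sequences so pass 2 does not remove it either
#   g__Nine   9 sequences  = 0.009%  (< 0.01% -> removed in pass 2)
#   g__Ten    10 sequences = 0.010%  (= 0.01% -> retained)
#   g__Fill   the remainder, everywhere
boundary_table <- function() {
  samples <- sprintf("s%03d", 1:100)
  otus <- c("otuFour", "otuFive", "otuNine", "otuTen", "otuFill")
  m <- matrix(0, length(otus), length(samples), dimnames = list(otus, samples))
  m["otuFour", 1:4] <- 1
  m["otuFive", 1:5] <- 4   # 20 seqs = 0.02%, safely above pass 2
  m["otuNine", 1:9] <- 1
  m["otuTen", 1:10] <- 1
  fill <- 100000 - sum(m)
  per <- fill %/% 100
  m["otuFill", ] <- per
  m["otuFill", 1] <- m["otuFill", 1] + fill - per * 100
  lineage <- function(g) {
    sprintf("k__Bacteria; p__P; c__C; o__O; f__F; g__%s; s__sp", g)
  }
  assignments <- tibble::tibble(
    otu_id = otus,
    taxonomy = vapply(c("Four", "Five", "Nine", "Ten", "Fill"), lineage,
                      character(1), USE.NAMES = FALSE)
  )
  list(table = otu_table(m, taxonomy = assignments$taxonomy),
       assignments = assignments)
}

# Random count table with simple metadata, for round-trip style tests.
random_table <- function(n_otus = 20, n_samples = 5, seed = 7, taxonomy = FALSE) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_otus * n_samples, 30), n_otus, n_samples,
                dimnames = list(sprintf("otu%03d", seq_len(n_otus)),
                                sprintf("s%02d", seq_len(n_samples))))
    tx <- if (taxonomy) {
      sprintf("k__Bacteria; p__P%d; c__C; o__O; f__F; g__G%d; s__sp%d",
              seq_len(n_otus) %% 3, seq_len(n_otus), seq_len(n_otus))
    }
    otu_table(m, taxonomy = tx)
  })
}

# A deterministic mock OTU picker: assigns each read ID to an OTU by a
# pure function of the ID, independent of chunking (stands in for BLAST).
mock_picker <- function(ids) {
  otus <- paste0("otu", vapply(ids, function(s) sum(utf8ToInt(s)) %% 4,
                               numeric(1)))
  m <- split(ids, otus)
  # preserve first-appearance order of OTUs; members stay in input order
  m[unique(otus)]
}
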