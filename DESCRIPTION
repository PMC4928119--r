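Package: otukit
Title: Post-Clustering Toolkit for Species-Level 16S rRNA Amplicon Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for working with QIIME-era 16S rRNA amplicon artifacts after
    OTU picking: chunked-run bookkeeping (split/merge of OTU maps), two-primer
    abundance averaging, transient-taxon filtering, taxonomy assignment by
    reference lookup, condensing of taxonomically redundant OTUs, and OTU-table
    construction. Includes alpha-diversity metrics (Shannon, equitability, ACE
    with Chao1 fallback), kernel-smoothed per-group diversity curves, pairwise
    Wilcoxon rank-sum comparisons with Benjamini-Hochberg FDR control,
    ordination by principal coordinates analysis and regularized Fisher linear
    discriminant analysis, and quantitative annotation of phylogenetic trees
    for the Interactive Tree of Life (iTOL) with log-abundance, mean relative
    abundance, and group-normalized abundance tracks. A deterministic
    Dirichlet-multinomial community simulator generates complete synthetic
    datasets (BIOM, mapping, OTU map, taxonomy, FASTA, Newick) for testing and
    demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    biomformat,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
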