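---
title: "Methods: post-clustering 16S analysis with otukit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-clustering 16S analysis with otukit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otukit)
```

This vignette is the package's account of the methods it implements: what
each step computes, the assumptions behind it, the parameters that matter,
and the choices made where more than one defensible definition exists.
Everything quantitative stated here is computed by the package's own test
suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## The post-picking pipeline

`otukit` operates downstream of reference-based OTU picking. Its unit of
bookkeeping is the *OTU map*: a list mapping each OTU identifier (here, a
reference-database record ID) to the IDs of its member reads. Reads encode
their sample of origin as the prefix before the final underscore
(`"S1_000123"` belongs to sample `S1`); splitting on the *last* underscore
tolerates underscores inside sample names.

**Chunking and merging.** Reference-based picking treats reads
independently, so a run can be split into chunks, picked in parallel, and
the per-chunk maps merged. `split_sequences()` defaults to 20,000 reads
per chunk — a practical batch-cluster job size — and `merge_otu_results()`
concatenates member lists in input order. For any chunk size, splitting,
picking per chunk, and merging yields exactly the map produced by picking
the unsplit input; the suite verifies this identity with a deterministic
mock picker at chunk sizes 1, 7 and 20,000.

**Two-primer averaging.** Sequencing two hypervariable regions captures a
broader slice of the community, but taxa amplified by both primers are
counted twice. The reconciliation rule must say *which* reads survive, not
just how many. `primer_average()` keeps OTUs seen by one primer unchanged
and, for an OTU with $n_A$ and $n_B$ members in the two maps, retains
$\lceil (n_A + n_B)/2 \rceil$ members chosen by alternating IDs from the
two maps (first map first) and truncating. The ceiling, rather than the
floor, guarantees that a species observed once by each primer is never
annihilated; the deterministic interleave makes the retained member list
reproducible. Averaging a map with itself is the identity on per-OTU
counts ($\lceil 2n/2 \rceil = n$).

**Taxonomy by lookup.** When OTU IDs are reference IDs, taxonomy
assignment is a table lookup (`assign_taxonomy()`); records absent from
the reference receive the `"Unassigned"` sentinel and are reported, never
dropped silently.

**Condensing.** Reference databases contain many 16S records per named
species, so reference-picked results are taxonomically redundant.
`condense_otus()` groups OTUs by their *full* taxonomy string, chooses the
lexicographically smallest member ID as each group's representative (any
member is biologically equivalent; lexicographic order makes the choice
deterministic), and concatenates member lists representative-first, then
in ascending ID order. The sequence-ID multiset is conserved, and building
a table before or after condensing gives identical per-sample column sums.

**Transient filtering.** Host-associated communities include organisms
that are transient rather than resident. `filter_transient()` removes
them in two passes over OTUs aggregated by taxonomy truncated at a rank
(genus by default). Pass 1 removes aggregates present in strictly fewer
than `prevalence_frac` (default 0.05) of samples; pass 2 removes surviving
aggregates whose total count is strictly less than `abundance_frac`
(default $10^{-4}$, i.e. 0.01%) of the grand total. Three definitional
choices:

* Both inequalities are strict, so an aggregate sitting exactly on a
  threshold (5 of 100 samples; 0.010% of reads) is retained.
* Pass 2's denominator is the *original* grand total — "fraction of the
  data" reads most naturally as the data as sequenced — but
  `denominator = "surviving"` switches to the post-pass-1 total for users
  who prefer the other reading.
* The genus-level aggregation key keeps empty rank names
  (`"...; f__F; g__"`), so OTUs with an unnamed genus bin by their deepest
  named lineage instead of collapsing into one global "unknown genus" bin.

Removed aggregates go to a report (percent abundance, member OTU IDs, and
member sequence IDs when an OTU map is supplied) for inspection.

## Alpha diversity and group comparison

`shannon()` computes $H = -\sum_{p_i > 0} p_i \ln p_i$ in nats. Natural
log is the default because the companion statistic, Pielou equitability
$H / \ln S$, is then scale-free in the base; a `base` argument covers the
older convention of log base 2. Equitability for a single-species sample
is defined as 0 (the $\ln 1$ denominator is degenerate, and "no evenness"
is the sensible limit).

`ace()` implements the abundance-based coverage estimator with rare
threshold 10: with $S_{rare}$ rare species holding $N_{rare}$ individuals,
$F_k$ species observed exactly $k$ times, and coverage
$C_{ace} = 1 - F_1 / N_{rare}$,

$$S_{ACE} = S_{abund} + \frac{S_{rare}}{C_{ace}} +
  \frac{F_1}{C_{ace}}\,\gamma^2,\qquad
\gamma^2 = \max\!\left[\frac{S_{rare}}{C_{ace}}
  \frac{\sum_k k(k-1)F_k}{N_{rare}(N_{rare}-1)} - 1,\; 0\right].$$

Degenerate inputs are handled explicitly: with no rare species the
estimate is the observed richness; when every rare species is a singleton,
$C_{ace} = 0$ and the estimator is undefined, so the Chao1 estimate
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ is returned with a flag in the
components. The test suite pins the estimator to a fully hand-evaluated
example (counts $\{1,1,2,3,11,12\} \rightarrow 7.7867$) and cross-checks
it against an independent implementation in `vegan`.

`kde_curve()` smooths per-sample diversity values with a Gaussian kernel
at Scott's bandwidth $h = \hat\sigma\, n^{-1/5}$, evaluated on a 256-point
grid over $[\min - 3h, \max + 3h]$; the trapezoidal integral of every
curve is 1 within 1%. A constant input has no data-driven bandwidth and
raises an error suggesting an explicit one.

`pairwise_group_tests()` compares every unordered pair of groups with a
two-sided Wilcoxon rank-sum test — the exact distribution when both groups
have at most 20 observations and there are no ties, otherwise the normal
approximation with tie and continuity corrections — then applies
Benjamini–Hochberg step-up adjustment across all pairs and flags
$q < 0.1$ by default. The exact branch is verified against brute-force
enumeration of all rank assignments for every group-size split with
$n_{total} \le 10$, and the BH arithmetic against the step-up definition
directly.

## Ordination

**PCoA.** `pcoa()` double-centers the squared distance matrix,
$B = -\tfrac12 J D^2 J$ with $J = I - \mathbf{1}\mathbf{1}^\top/n$, and
eigendecomposes $B$. Axes with eigenvalue above $10^{-10} \lambda_{max}$
are kept; coordinates are $v_k \sqrt{\lambda_k}$ and explained fractions
$\lambda_k / \sum \lambda_+$. Distance matrices that are not exactly
Euclidean (unweighted UniFrac commonly is not) produce negative
eigenvalues; these are dropped and their summed magnitude reported in the
result rather than corrected — the standard Cailliez/Lingoes adjustments
change the geometry and are left to the user's discretion. Each axis is
sign-flipped so its largest-magnitude coordinate is positive, which makes
plots identical run to run. For matrices built from points in
$\mathbb{R}^k$ the embedding reconstructs all pairwise distances to
$10^{-8}$ and reports at most $k$ positive axes.

**LDA.** `lda_ordination()` computes Fisher discriminants — directions
maximizing between-group over within-group scatter — on per-sample
proportions (raw counts are rejected with a hint, because scatter on
unnormalized counts conflates sequencing depth with composition). OTU
tables usually have more taxa than samples, leaving the within-class
scatter $S_w$ rank deficient, so it is regularized with a relative ridge,
$S_w + \varepsilon\,(\mathrm{tr}(S_w)/p)\,I$ with
$\varepsilon = 10^{-4}$, before solving the generalized eigenproblem by
symmetric whitening. At most $g - 1$ axes exist for $g$ groups.

One property of training-set LDA deserves emphasis: the separation
statistic (axis-1 group-mean difference over pooled within-group SD) is
*inflated for any labeling* once the number of taxa approaches the number
of samples, because a nearly unconstrained discriminant can separate even
random labels. Measured on this package's own fixtures, shuffled-label
median separation rises from about 0.8 at 8 taxa / 40 samples to about 14
at 40 taxa / 40 samples. A label-permutation control is therefore only
meaningful when taxa $\ll$ samples, and the recovery checks in the test
suite use 7–8 taxa against 40 samples. On real tables with hundreds of
OTUs, an LDA plot shows within-sample structure faithfully but its
apparent group separation should not be read as evidence by itself.

**Bubble plots.** `bubble_sizes()` scales ordination markers by a chosen
OTU's relative abundance, with the most abundant sample at `max_size` and
zero-abundance samples at a fixed minimum so they remain visible.
`autoplot()` draws 2D ordinations with percent-explained axis labels,
optional 95% normal group ellipses (off by default; the geometry is an
interpretation aid, not an inference), and optional bubble sizing. The
command-line `PCoA` tool accepts `--azimuth`/`--elevation` in degrees and
projects the first three axes orthographically under those angles, so a
3D view found interactively can be reproduced exactly in a later session.

## iTOL tree annotation

`relabel_tree()` replaces OTU-ID leaves with display labels built from
taxonomy: `Genus_species` when both are named, otherwise the deepest
named rank with its rank-letter prefix; characters outside
`[A-Za-z0-9_.-]` become underscores and duplicates get numeric suffixes
(`_2`, `_3`, ...) in input order. Topology and branch lengths are
untouched, and the old-to-new mapping is returned for track alignment.

`itol_metrics()` computes three per-OTU tracks:

* `log10_raw` — $\log_{10}(1 + \text{total count})$. The $+1$ keeps OTUs
  with zero count in a subset table representable at value 0.
* `mra` — mean over samples of per-sample relative abundance. With
  `stabilize = TRUE` the arcsine square-root transform
  $\arcsin\sqrt{p}$ (monotone $[0,1] \to [0,\pi/2]$) is applied to each
  per-sample proportion *before* averaging — the variance-stabilizing
  step must precede the mean, and the two orders genuinely differ
  (the suite checks a two-sample case where they do).
* `nmra` — per metadata group $g$, compute $\mathrm{MRA}_g(o)$, then
  normalize across groups per OTU:
  $\mathrm{MRA}_g(o) / \sum_h \mathrm{MRA}_h(o)$. Each OTU's row sums to
  1 and shows which groups carry it — the semantics of an outer
  comparison ring on a circular tree. The alternative reading (normalize
  within a group across OTUs) answers a different question and is not
  what a per-leaf track can display; OTUs absent everywhere get an
  all-zero row and are flagged.

`write_itol_dataset()` emits the iTOL text templates (`DATASET_SIMPLEBAR`
for single-column tracks, `DATASET_MULTIBAR` for the group-normalized
track with `FIELD_LABELS` in mapping-file order); `read_itol_dataset()`
parses them back, and a written dataset self-parses to identical values.

## File formats and numerical conventions

BIOM I/O targets the 1.0 JSON dialect (both `sparse` and `dense`
encodings) through the Bioconductor `biomformat` parser; the serialization
date field is pinned to a constant so identical tables produce identical
bytes. Mapping files follow the tab-delimited convention with a
`#SampleID` header; later `#` lines are comments. Distance matrices are
symmetrized by averaging when the asymmetry is at most $10^{-9}$
(floating-point artifacts from upstream tools) and rejected beyond that;
the diagonal is forced to zero. Newick and FASTA pass through `ape` and
`Biostrings`, with surrounding quotes stripped from quoted leaf labels on
read. Parsers never silently drop records: counts are conserved or an
error/warning is raised.

## The synthetic community generator

`make_community()` draws, per sample, a composition from a Dirichlet
distribution and read counts from a multinomial at fixed depth — the
standard overdispersed model for 16S count data — then spreads each
species' reads uniformly over its redundant reference records. Defaults,
chosen once as the package's study conditions:

* 20 species with ranked base composition $\propto 1/i$ — a simple
  abundance-ranked community;
* total Dirichlet concentration 100 — moderate overdispersion at which an
  injected 8-fold effect on 5 species remains recoverable by the
  discriminant (the generator's documented contract) while samples still
  vary visibly;
* redundancy 3 reference records per species, to exercise condensing;
* two groups of 20 samples at depth 1000, with the 8-fold enrichment of
  the first 5 species in the second group;
* a random coalescent tree over reference IDs and random 250-mer
  placeholder reference sequences.

Every output is byte-for-byte determined by the seed. What the generator
does *not* emulate: sequencing error and chimeras, variable library
sizes, phylogenetic signal in the taxonomy (lineages are synthetic
labels), or compositional correlation structure beyond the Dirichlet.
Passing tests therefore demonstrate the correctness of the *computations*
on realistic count structure, not robustness to the full messiness of
real surveys.

`make_two_primer_maps()` emulates two-region sequencing: a chosen fraction
of species is captured by both primers with independent draws, the rest
split alternately, giving closed-form expectations for post-averaging
totals.

## Problem sizes and runtime

The test suite runs small by design: communities of 6–20 species over
6–40 samples at depths 200–1000, distance matrices of 7–12 samples,
exhaustive Wilcoxon enumeration up to 10 observations, and 20
label-permutation replicates; the whole suite completes in well under a
minute on one core. `scripts/acceptance.R` uses the same sizes and a
single seed flag for every random draw.

## Known limitations

* Primer averaging's ceiling-and-interleave rule is one defensible
  reading of "scale down the doubly-captured abundance"; alternatives
  (floor, random subsampling) change totals by at most one read per
  shared OTU.
* ACE follows the rare-threshold-10 convention; richness estimators are
  known to disagree in skewed communities, and only Shannon,
  equitability, ACE and observed richness are built in (any function of
  a count vector can be plugged into `alpha_diversity()`).
* PCoA reports, but does not correct, negative eigenvalues.
* LDA separation on tables with taxa ≈ samples overstates group
  differences (see above); use the permutation control, or fewer taxa.
* The package consumes distance matrices; it does not compute UniFrac,
  align sequences, or build trees.
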