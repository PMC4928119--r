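#' Per-sample relative abundance
#'
#' Scales each sample column of a count table to proportions summing to 1.
#' All-zero columns (no reads for a sample) are left at zero and flagged
#' with a warning rather than producing NaN.
#'
#' @param table An [otu_table()].
#' @return An [otu_table()] of proportions with the same dimensions and
#'   taxonomy.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  totals <- colSums(table)
  if (all(totals == 0)) stop("all sample columns are zero")
  if (any(totals == 0)) {
    warning("all-zero sample column(s) left at zero: ",
            paste(colnames(table)[totals == 0], collapse = ", "))
  }
  scaled <- sweep(unclass(table), 2L, pmax(totals, 1e-300), "/")
  scaled[, totals == 0] <- 0
  otu_table(scaled, taxonomy = attr(table, "taxonomy"))
}

#' Shannon diversity and equitability
#'
#' Shannon diversity `H = -sum(p_i * log(p_i))` over taxa with nonzero
#' proportion, in nats by default (set `base = 2` for bits, the historical
#' QIIME convention). Equitability (Pielou evenness) is `H / log(S)` with
#' `S` the number of taxa present; for `S = 1` the ratio is defined as 0.
#'
#' @param p Nonnegative abundance vector; renormalized to proportions
#'   internally.
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return `shannon()`: the diversity index. `equitability()`: a value in
#'   \[0, 1\].
#' @export
#' @examples
#' shannon(rep(1, 8))      # log(8)
#' equitability(rep(1, 8)) # 1
shannon <- function(p, base = exp(1)) {
  stopifnot(is.numeric(p), all(p >= 0))
  total <- sum(p)
  if (total == 0) stop("all-zero abundance vector")
  p <- p[p > 0] / total
  -sum(p * log(p, base = base))
}

#' @rdname shannon
#' @export
equitability <- function(p, base = exp(1)) {
  stopifnot(is.numeric(p), all(p >= 0))
  s <- sum(p > 0)
  if (s == 0) stop("all-zero abundance vector")
  if (s == 1) return(0)
  shannon(p, base = base) / log(s, base = base)
}

#' Abundance-based coverage estimator (ACE) of species richness
#'
#' Nonparametric richness estimate built from the frequency counts of rare
#' species (those with at most `rare_threshold` individuals, threshold 10
#' by the EstimateS convention). With `S_abund`/`S_rare` the abundant/rare
#' species counts, `N_rare` the individuals among rare species, `F_k` the
#' number of species seen exactly `k` times, and sample coverage
#' `C_ace = 1 - F_1 / N_rare`:
#'
#' \deqn{S_{ACE} = S_{abund} + S_{rare}/C_{ace} + (F_1/C_{ace})\,\gamma^2}
#'
#' where the squared coefficient of variation
#' \eqn{\gamma^2 = \max\{(S_{rare}/C_{ace}) \sum k(k-1)F_k / (N_{rare}(N_{rare}-1)) - 1,\ 0\}}.
#' If there are no rare species the estimate is the observed richness; if
#' coverage is zero (all rare species are singletons) the estimator is
#' undefined and the Chao1 estimate
#' `S_obs + F_1 (F_1 - 1) / (2 (F_2 + 1))` is returned instead, flagged in
#' the components.
#'
#' @param counts Nonnegative integer abundance vector (zeros ignored).
#' @param rare_threshold Largest count at which a species is "rare"
#'   (default 10).
#' @return A list of class `ace_estimate`: `estimate` plus a `components`
#'   list (`s_obs`, `s_abund`, `s_rare`, `n_rare`, `f_k`, `c_ace`,
#'   `gamma_sq`, `chao1_fallback`).
#' @export
#' @examples
#' ace(c(1, 1, 2, 3, 11, 12))$estimate # ~7.787
ace <- function(counts, rare_threshold = 10L) {
  stopifnot(is.numeric(counts), all(counts >= 0), rare_threshold >= 1)
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("all-zero abundance vector")
  s_obs <- length(counts)
  rare <- counts[counts <= rare_threshold]
  s_rare <- length(rare)
  s_abund <- s_obs - s_rare
  f_k <- vapply(seq_len(rare_threshold), function(k) sum(counts == k), numeric(1))
  n_rare <- sum(rare)
  comp <- list(s_obs = s_obs, s_abund = s_abund, s_rare = s_rare,
               n_rare = n_rare, f_k = f_k, c_ace = NA_real_,
               gamma_sq = NA_real_, chao1_fallback = FALSE)
  if (s_rare == 0L) {
    comp$c_ace <- 1
    comp$gamma_sq <- 0
    return(structure(list(estimate = s_obs, components = comp),
                     class = "ace_estimate"))
  }
  c_ace <- 1 - f_k[[1]] / n_rare
  comp$c_ace <- c_ace
  if (c_ace == 0) {
    comp$chao1_fallback <- TRUE
    f2 <- if (rare_threshold >= 2) f_k[[2]] else 0
    est <- s_obs + f_k[[1]] * (f_k[[1]] - 1) / (2 * (f2 + 1))
    return(structure(list(estimate = est, components = comp),
                     class = "ace_estimate"))
  }
  k <- seq_len(rare_threshold)
  sum_kk1 <- sum(k * (k - 1) * f_k)
  gamma_sq <- max((s_rare / c_ace) * sum_kk1 / (n_rare * (n_rare - 1)) - 1, 0)
  comp$gamma_sq <- gamma_sq
  est <- s_abund + s_rare / c_ace + (f_k[[1]] / c_ace) * gamma_sq
  structure(list(estimate = est, components = comp), class = "ace_estimate")
}

#' @export
print.ace_estimate <- function(x, ...) {
  cat(sprintf("ACE richness estimate: %.4f (S_obs = %d%s)\n",
              x$estimate, x$components$s_obs,
              if (x$components$chao1_fallback) ", Chao1 fallback" else ""))
  invisible(x)
}

#' Gaussian kernel density curve
#'
#' Smooths a set of per-sample diversity values into a density curve for
#' per-group comparison plots. Uses a Gaussian kernel with Scott's
#' bandwidth `h = sd(x) * n^(-1/5)` by default, evaluated on a 256-point
#' grid spanning `[min - 3h, max + 3h]`.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param bandwidth Positive bandwidth, or `"scott"` for the default rule.
#' @return A tibble of class `density_curve` with columns `x` and
#'   `density`, and a `bandwidth` attribute. The trapezoidal integral of
#'   the curve is 1 to within 1%.
#' @export
kde_curve <- function(values, bandwidth = "scott") {
  stopifnot(is.numeric(values), length(values) >= 2L)
  if (identical(bandwidth, "scott")) {
    if (length(unique(values)) < 2L) {
      stop("constant values; supply an explicit bandwidth")
    }
    bandwidth <- stats::sd(values) * length(values)^(-1 / 5)
  }
  stopifnot(is.numeric(bandwidth), bandwidth > 0)
  d <- stats::density(values, bw = bandwidth, kernel = "gaussian", n = 256L,
                      from = min(values) - 3 * bandwidth,
                      to = max(values) + 3 * bandwidth)
  out <- tibble::tibble(x = d$x, density = d$y)
  attr(out, "bandwidth") <- bandwidth
  class(out) <- c("density_curve", class(out))
  out
}

#' Pairwise Wilcoxon rank-sum tests with FDR control
#'
#' Compares every unordered pair of groups by a two-sided Wilcoxon rank-sum
#' test (exact distribution when both groups have at most 20 observations
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity corrections) and adjusts the p-values across all pairs with
#' the Benjamini-Hochberg step-up procedure. Pairs with `q < fdr_level`
#' are flagged significant.
#'
#' @param values_by_group Named list of numeric vectors (group label ->
#'   per-sample values), or a data frame with `group` and `value` columns.
#'   At least two groups, each with at least two observations.
#' @param fdr_level FDR threshold for the significance flag (default 0.1).
#' @return A tibble of class `group_comparison`: `group1`, `group2`,
#'   `statistic` (rank-sum W), `p_value`, `q_value`, `significant`; the
#'   `fdr_level` is kept as an attribute.
#' @export
pairwise_group_tests <- function(values_by_group, fdr_level = 0.1) {
  if (is.data.frame(values_by_group)) {
    stopifnot(all(c("group", "value") %in% names(values_by_group)))
    values_by_group <- split(values_by_group$value, values_by_group$group)
  }
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2L)
  if (is.null(names(values_by_group))) stop("groups must be named")
  small <- names(values_by_group)[lengths(values_by_group) < 2L]
  if (length(small) > 0) {
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  }
  labels <- names(values_by_group)
  pairs <- utils::combn(labels, 2L)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    x <- values_by_group[[g1]]; y <- values_by_group[[g2]]
    ties <- anyDuplicated(c(x, y)) > 0
    use_exact <- length(x) <= 20L && length(y) <= 20L && !ties
    w <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = use_exact, correct = TRUE)
    )
    tibble::tibble(group1 = g1, group2 = g2,
                   statistic = unname(w$statistic), p_value = w$p.value)
  })
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < fdr_level
  attr(res, "fdr_level") <- fdr_level
  class(res) <- c("group_comparison", class(res))
  res
}

#' Per-sample alpha diversity for an OTU table
#'
#' Computes one alpha-diversity value per sample column. Built-in metrics:
#' `"shannon"`, `"equitability"`, `"ace"`, `"observed"` (observed
#' richness); any function mapping a count vector to a scalar can be
#' supplied instead.
#'
#' @param table An [otu_table()] of counts.
#' @param metric Metric name or a function `counts -> scalar`.
#' @param metadata Optional sample metadata; when given with `category`,
#'   a `group` column is attached.
#' @param category Metadata column holding the group label.
#' @param ... Passed to the metric function.
#' @return A tibble with columns `sample_id`, `value`, and optionally
#'   `group`.
#' @export
alpha_diversity <- function(table, metric = "shannon", metadata = NULL,
                            category = NULL, ...) {
  stopifnot(inherits(table, "otu_table"))
  f <- if (is.function(metric)) {
    metric
  } else {
    switch(match.arg(metric, c("shannon", "equitability", "ace", "observed")),
           shannon = shannon,
           equitability = equitability,
           ace = function(v, ...) ace(v, ...)$estimate,
           observed = function(v, ...) sum(v > 0))
  }
  out <- tibble::tibble(
    sample_id = sample_ids(table),
    value = vapply(seq_len(n_samples(table)),
                   function(j) f(unclass(table)[, j], ...), numeric(1))
  )
  if (!is.null(metadata) && !is.null(category)) {
    if (!category %in% names(metadata)) {
      stop("unknown metadata category: ", category)
    }
    out$group <- metadata[[category]][match(out$sample_id, metadata$SampleID)]
  }
  out
}
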