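#' Principal coordinates analysis (classical MDS)
#'
#' Embeds samples in Euclidean space from a distance matrix by Gower double
#' centering: `B = -1/2 * J %*% D^2 %*% J` with `J = I - 11'/n`, followed by
#' a symmetric eigendecomposition. Axes with eigenvalue above
#' `1e-10 * max(lambda)` are kept; coordinates on axis `k` are
#' `eigenvector_k * sqrt(lambda_k)` and explained fractions are
#' `lambda_k / sum(positive lambda)`. Negative eigenvalues (non-Euclidean
#' distances such as unweighted UniFrac can produce them) are dropped and
#' their total magnitude reported in the result; no Cailliez/Lingoes
#' correction is applied. Each axis is sign-flipped so its
#' largest-magnitude coordinate is positive, making plots reproducible.
#'
#' @param d A symmetric distance matrix with sample labels (see
#'   [read_distance_matrix()]), n >= 2.
#' @return An object of class `otukit_ordination` with fields `sample_ids`,
#'   `coordinates` (samples x axes), `explained` (fractions, decreasing),
#'   `eigenvalues`, `negative_magnitude`, `method = "pcoa"`.
#' @export
pcoa <- function(d) {
  d <- as_distance_matrix(d, tol = 1e-9)
  n <- nrow(d)
  if (n < 2L) stop("PCoA needs at least 2 samples")
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lambda <- e$values
  pos <- lambda > 1e-10 * max(abs(lambda), 1e-300)
  neg_mag <- sum(abs(lambda[lambda < 0]))
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda[pos]),
                                                   nrow = sum(pos))
  coords <- flip_axis_signs(coords)
  rownames(coords) <- rownames(d)
  if (ncol(coords) > 0) colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  explained <- if (any(pos)) lambda[pos] / sum(lambda[pos]) else numeric(0)
  new_ordination(rownames(d), coords, explained, method = "pcoa",
                 eigenvalues = lambda, negative_magnitude = neg_mag)
}

flip_axis_signs <- function(coords) {
  for (k in seq_len(ncol(coords))) {
    v <- coords[, k]
    if (length(v) > 0 && v[which.max(abs(v))] < 0) coords[, k] <- -v
  }
  coords
}

new_ordination <- function(sample_ids, coordinates, explained, method, ...) {
  structure(list(sample_ids = sample_ids, coordinates = coordinates,
                 explained = explained, method = method, ...),
            class = "otukit_ordination")
}

#' @export
print.otukit_ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d axes\n",
              toupper(x$method), length(x$sample_ids), ncol(x$coordinates)))
  if (length(x$explained) > 0) {
    cat("explained:",
        paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 5)),
              collapse = ", "),
        if (length(x$explained) > 5) "...\n" else "\n")
  }
  invisible(x)
}

#' Regularized Fisher linear discriminant ordination
#'
#' Supervised ordination of compositional OTU data: finds the linear
#' combinations of taxa that maximize between-group over within-group
#' scatter. Because OTU tables typically have far more taxa than samples,
#' the within-class scatter matrix is rank deficient; it is regularized by
#' a relative ridge, `S_w + eps * (trace(S_w)/p) * I` with `eps = 1e-4`,
#' before solving the generalized eigenproblem (by symmetric whitening).
#' Input must be per-sample proportions (see [relative_abundance()]); raw
#' counts are rejected. Axes are sign-flipped so the largest-magnitude
#' loading on each discriminant is positive.
#'
#' @param table An [otu_table()] of proportions.
#' @param labels Group label per sample: a named vector (names = sample
#'   IDs) or a vector in sample order. At least two groups, each with at
#'   least two samples.
#' @param n_axes Number of discriminant axes (at most `groups - 1`).
#' @param eps Relative ridge regularization (default 1e-4).
#' @return An `otukit_ordination` (method `"lda"`) with per-axis explained
#'   fractions from the discriminant eigenvalues and a `loadings` field
#'   (taxa x axes).
#' @export
lda_ordination <- function(table, labels, n_axes = 2L, eps = 1e-4) {
  stopifnot(inherits(table, "otu_table"))
  tots <- colSums(table)
  if (any(abs(tots[tots > 0] - 1) > 1e-6)) {
    stop("table does not look like proportions (columns must sum to 1); ",
         "run relative_abundance() first")
  }
  if (!is.null(names(labels))) {
    miss <- setdiff(sample_ids(table), names(labels))
    if (length(miss) > 0) stop("unlabeled sample(s): ", paste(miss, collapse = ", "))
    labels <- unname(labels[sample_ids(table)])
  }
  stopifnot(length(labels) == n_samples(table))
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- base::table(labels)
  if (any(sizes < 2L)) {
    stop("group(s) with a single sample: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  if (n_axes > length(groups) - 1L) {
    stop("n_axes (", n_axes, ") exceeds groups - 1 (", length(groups) - 1L, ")")
  }
  x <- t(unclass(table))          # samples x taxa
  p <- ncol(x)
  grand <- colMeans(x)
  sw <- matrix(0, p, p)
  sb <- matrix(0, p, p)
  for (g in groups) {
    xg <- x[labels == g, , drop = FALSE]
    mg <- colMeans(xg)
    cg <- sweep(xg, 2L, mg)
    sw <- sw + crossprod(cg)
    dm <- mg - grand
    sb <- sb + nrow(xg) * tcrossprod(dm)
  }
  tr <- sum(diag(sw))
  ridge <- if (tr > 0) eps * tr / p else eps
  sw_reg <- sw + diag(ridge, p)
  ew <- eigen(sw_reg, symmetric = TRUE)
  w_inv_half <- ew$vectors %*% diag(1 / sqrt(pmax(ew$values, 1e-300)), p) %*%
    t(ew$vectors)
  m <- w_inv_half %*% sb %*% w_inv_half
  em <- eigen((m + t(m)) / 2, symmetric = TRUE)
  k <- min(n_axes, length(groups) - 1L)
  lam <- pmax(em$values[seq_len(k)], 0)
  loadings <- w_inv_half %*% em$vectors[, seq_len(k), drop = FALSE]
  loadings <- flip_axis_signs(loadings)
  coords <- sweep(x, 2L, grand) %*% loadings
  rownames(coords) <- sample_ids(table)
  colnames(coords) <- paste0("LD", seq_len(k))
  rownames(loadings) <- otu_ids(table)
  colnames(loadings) <- colnames(coords)
  lam_all <- pmax(em$values[seq_len(length(groups) - 1L)], 0)
  explained <- if (sum(lam_all) > 0) lam[seq_len(k)] / sum(lam_all) else rep(0, k)
  ord <- new_ordination(sample_ids(table), coords, explained, method = "lda",
                        eigenvalues = em$values[seq_len(k)],
                        loadings = loadings)
  ord$labels <- stats::setNames(labels, sample_ids(table))
  ord
}

#' Bubble sizes from the relative abundance of one OTU
#'
#' Scales ordination plot markers so each sample's size is proportional to
#' its relative abundance of a chosen OTU, with the most abundant sample at
#' `max_size`. Samples where the OTU is absent get a fixed minimum marker
#' size so they stay visible.
#'
#' @param table An [otu_table()] (counts or proportions; proportions are
#'   computed internally).
#' @param otu_id OTU to scale by (must be present in the table).
#' @param max_size Marker size for the most abundant sample.
#' @param min_size Marker size for zero-abundance samples (default
#'   `max_size / 20`).
#' @return A tibble with columns `sample_id`, `relative_abundance`, `size`.
#' @export
bubble_sizes <- function(table, otu_id, max_size = 300, min_size = max_size / 20) {
  stopifnot(inherits(table, "otu_table"), max_size > 0)
  if (!otu_id %in% otu_ids(table)) stop("unknown OTU: ", otu_id)
  rel <- relative_abundance(table)
  r <- unclass(rel)[otu_id, ]
  peak <- max(r)
  if (peak == 0) {
    warning("OTU '", otu_id, "' absent from every sample; all markers at minimum size")
    size <- rep(min_size, length(r))
  } else {
    size <- max_size * r / peak
    size[r == 0] <- min_size
  }
  tibble::tibble(sample_id = sample_ids(table),
                 relative_abundance = unname(r), size = unname(size))
}
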