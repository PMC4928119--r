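#' Tidy an ordination into per-sample scores
#'
#' @param x An `otukit_ordination` from [pcoa()] or [lda_ordination()].
#' @param ... Ignored.
#' @return A tibble with `sample_id`, one column per axis, and `group`
#'   when the ordination carries labels.
#' @method tidy otukit_ordination
#' @export
tidy.otukit_ordination <- function(x, ...) {
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = x$sample_ids),
    tibble::as_tibble(x$coordinates)
  )
  if (!is.null(x$labels)) out$group <- unname(x$labels[x$sample_id])
  out
}

#' @rdname tidy.otukit_ordination
#' @method glance otukit_ordination
#' @export
glance.otukit_ordination <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_samples = length(x$sample_ids),
    n_axes = ncol(x$coordinates),
    explained_1 = if (length(x$explained) >= 1) x$explained[[1]] else NA_real_,
    explained_2 = if (length(x$explained) >= 2) x$explained[[2]] else NA_real_,
    total_explained = sum(x$explained),
    negative_magnitude = x$negative_magnitude %||% NA_real_
  )
}

#' Tidy an ACE richness estimate
#'
#' @param x An `ace_estimate` from [ace()].
#' @param ... Ignored.
#' @return `tidy()`: one row per component; `glance()`: a one-row summary.
#' @method tidy ace_estimate
#' @export
tidy.ace_estimate <- function(x, ...) {
  c <- x$components
  tibble::tibble(
    component = c("s_obs", "s_abund", "s_rare", "n_rare", "c_ace", "gamma_sq"),
    value = c(c$s_obs, c$s_abund, c$s_rare, c$n_rare, c$c_ace, c$gamma_sq)
  )
}

#' @rdname tidy.ace_estimate
#' @method glance ace_estimate
#' @export
glance.ace_estimate <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate,
    s_obs = x$components$s_obs,
    c_ace = x$components$c_ace,
    chao1_fallback = x$components$chao1_fallback
  )
}

#' Plot an ordination
#'
#' Scatter plot of two ordination axes with percent-explained axis labels,
#' optional group coloring, 95% normal confidence ellipses, and per-sample
#' bubble sizing from [bubble_sizes()].
#'
#' @param object An `otukit_ordination`.
#' @param axes Which two axes to draw.
#' @param groups Optional named vector (sample ID -> group) overriding any
#'   labels stored in the ordination.
#' @param ellipse Draw a 95% normal ellipse per group.
#' @param bubble Optional tibble from [bubble_sizes()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot otukit_ordination
#' @export
autoplot.otukit_ordination <- function(object, axes = c(1L, 2L), groups = NULL,
                                       ellipse = FALSE, bubble = NULL, ...) {
  one_axis <- ncol(object$coordinates) == 1L
  if (!one_axis) stopifnot(max(axes) <= ncol(object$coordinates))
  df <- tidy(object)
  if (!is.null(groups)) df$group <- unname(groups[df$sample_id])
  if (one_axis) {
    # single discriminant/coordinate: strip plot against sample rank
    axes <- c(1L, 2L)
    df$.rank <- rank(df[[colnames(object$coordinates)[1]]])
    ax <- c(colnames(object$coordinates)[1], ".rank")
  } else {
    ax <- colnames(object$coordinates)[axes]
  }
  lab <- function(k) {
    if (length(object$explained) >= k) {
      sprintf("%s (%.1f%%)", ax[[match(k, axes)]], 100 * object$explained[[k]])
    } else {
      ax[[match(k, axes)]]
    }
  }
  if (!is.null(bubble)) {
    df$size <- bubble$size[match(df$sample_id, bubble$sample_id)]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[ax[[1]]]], y = .data[[ax[[2]]]]
  ))
  has_group <- "group" %in% names(df)
  if (has_group && !is.null(bubble)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = .data$group, size = .data$size), alpha = 0.8) +
      ggplot2::scale_size_identity()
  } else if (has_group) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2.5)
  } else if (!is.null(bubble)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(size = .data$size), alpha = 0.8) +
      ggplot2::scale_size_identity()
  } else {
    p <- p + ggplot2::geom_point(size = 2.5)
  }
  if (ellipse && has_group) {
    p <- p + ggplot2::stat_ellipse(ggplot2::aes(colour = .data$group),
                                   level = 0.95)
  }
  p + ggplot2::labs(x = lab(axes[[1]]), y = lab(axes[[2]])) +
    ggplot2::theme_minimal()
}

#' Plot a kernel density curve
#'
#' @param object A `density_curve` from [kde_curve()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot density_curve
#' @export
autoplot.density_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "density") +
    ggplot2::theme_minimal()
}

#' Kernel-smoothed per-group diversity curves
#'
#' Draws one kernel density curve per group from per-sample diversity
#' values, the standard way to compare alpha-diversity distributions
#' between study groups.
#'
#' @param values A tibble with `value` and `group` columns (see
#'   [alpha_diversity()]).
#' @param bandwidth Passed to [kde_curve()].
#' @return A ggplot object.
#' @export
plot_group_curves <- function(values, bandwidth = "scott") {
  stopifnot(all(c("value", "group") %in% names(values)))
  curves <- dplyr::bind_rows(lapply(split(values$value, values$group), function(v) {
    kde_curve(v, bandwidth = bandwidth)
  }), .id = "group")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$density,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "diversity", y = "density") +
    ggplot2::theme_minimal()
}
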