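#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Pareto clone-size fit
#'
#' Log-log inverse cumulative clone-size distribution with the fitted OLS
#' line whose negated slope is the reported beta.
#'
#' @param object a [pareto_beta()] fit.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot pareto_fit
#' @export
autoplot.pareto_fit <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$log_size, y = .data$log_frac)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.6) +
    ggplot2::labs(x = "log clone size", y = "log fraction of MLGs ≥ size",
                  title = sprintf("Pareto clone-size spectrum (beta = %.2f, r² = %.2f)",
                                  object$beta, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a principal-coordinates ordination
#'
#' @param object a [pcoa()] result.
#' @param axes which two axes to draw (default 1:2).
#' @param colour_by optional vector (e.g. cluster or site labels) parallel
#'   to the scored points.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, axes = c(1L, 2L), colour_by = NULL, ...) {
  sc <- object$scores
  ax <- paste0("axis", axes)
  if (!all(ax %in% names(sc))) stop("requested axes not retained")
  df <- tibble::tibble(x = sc[[ax[1]]], y = sc[[ax[2]]], id = sc$id)
  pct <- object$pct_variance
  lab <- function(i) sprintf("Axis %d (%.1f%%)", axes[i], pct[axes[i]])
  p <- if (is.null(colour_by)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  } else {
    df$grp <- colour_by
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$grp))
  }
  p + ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = lab(1), y = lab(2), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Map the clonal structure of a sampled site
#'
#' Colonies at their field coordinates; colonies sharing a repeated MLG
#' share a colour, singletons are drawn as crosses — the conventional way
#' of eyeballing clonal aggregation.
#'
#' @param table a `genotype_tbl` with coordinates (one site, or facetted
#'   by site).
#' @param partition matching `clonal_partition`.
#' @return a ggplot.
#' @export
plot_clone_map <- function(table, partition) {
  if (!all(c("x", "y") %in% names(table))) stop("table has no coordinates")
  df <- tibble::tibble(x = table$x, y = table$y, site = table$site,
                       mlg = partition$mlg[match(table$id, partition$id)])
  sizes <- table(df$mlg)
  df$repeated <- sizes[df$mlg] > 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = df[!df$repeated, ], shape = 3, colour = "grey40") +
    ggplot2::geom_point(data = df[df$repeated, ],
                        ggplot2::aes(colour = .data$mlg), size = 2) +
    ggplot2::facet_wrap(~site, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot a clone network
#'
#' Fruchterman-Reingold layout (seeded, hence reproducible); node area
#' scales with ramet count when the network carries a `size` column.
#'
#' @param object a [build_network()] result.
#' @param seed layout seed (default 1).
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot clone_network
#' @export
autoplot.clone_network <- function(object, seed = 1L, ...) {
  g <- object$graph
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  if (!"size" %in% names(nodes)) nodes$size <- 1
  edges <- object$edges
  seg <- tibble::tibble(
    x = nodes$x[match(edges$from, nodes$id)],
    y = nodes$y[match(edges$from, nodes$id)],
    xend = nodes$x[match(edges$to, nodes$id)],
    yend = nodes$y[match(edges$to, nodes$id)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, size = .data$size),
                        colour = "steelblue", alpha = 0.85) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::labs(size = "ramets",
                  title = sprintf("clone network (threshold %.3f)", object$threshold)) +
    ggplot2::theme_void()
}
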