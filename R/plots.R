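#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot consensus expression-trend clusters
#'
#' One panel per cluster; each line is a tag's relative profile (per-stage
#' percentage of its summed count) across the ordered stages.
#'
#' @param object A `consensus_clustering` (or `poissonc_fit`).
#' @param max_tags_per_cluster Thin dense clusters for drawing.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_clustering <- function(object, max_tags_per_cluster = 200,
                                          ...) {
  x <- object$profiles
  pct <- 100 * x / rowSums(x)
  df <- as_tibble(pct, rownames = "tag") |>
    mutate(cluster = object$assignment$cluster) |>
    group_by(.data$cluster) |>
    dplyr::slice_head(n = max_tags_per_cluster) |>
    ungroup() |>
    tidyr::pivot_longer(-c("tag", "cluster"), names_to = "stage",
                        values_to = "pct") |>
    mutate(stage = factor(.data$stage, levels = colnames(pct)))
  ggplot(df, aes(x = .data$stage, y = .data$pct, group = .data$tag)) +
    geom_line(alpha = 0.15) +
    facet_wrap(~cluster) +
    labs(x = "stage", y = "% of tag's summed count",
         title = "Consensus expression-trend clusters") +
    theme_minimal()
}

#' @rdname autoplot.consensus_clustering
#' @export
autoplot.poissonc_fit <- function(object, max_tags_per_cluster = 200, ...) {
  fake <- list(profiles = object$profiles,
               assignment = tibble(cluster = as.integer(object$assignment)))
  class(fake) <- "consensus_clustering"
  autoplot.consensus_clustering(fake, max_tags_per_cluster, ...) +
    labs(title = "Poisson-deviance K-means clusters")
}

#' Plot a within-cluster dispersion curve
#'
#' @param curve Output of [dispersion_curve()] (or its `curve` tibble).
#' @return A ggplot object with the elbow suggestion marked.
#' @export
plot_dispersion_curve <- function(curve) {
  elbow <- NA
  if (!is.data.frame(curve)) {
    elbow <- curve$elbow
    curve <- curve$curve
  }
  p <- ggplot(curve, aes(x = .data$K, y = .data$dispersion)) +
    geom_line() + geom_point() +
    labs(x = "K (number of clusters)", y = "within-cluster dispersion") +
    theme_minimal()
  if (!is.na(elbow)) {
    p <- p + ggplot2::geom_vline(xintercept = elbow, linetype = "dashed")
  }
  p
}

#' Plot sample scores of a principal-component projection
#'
#' @param object A `sage_pca`.
#' @param groups Optional sample group labels (column order of the fitted
#'   matrix).
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2.
#' @export
autoplot.sage_pca <- function(object, groups = NULL, ...) {
  df <- as_tibble(object$sample_scores, rownames = "sample")
  if (!is.null(groups)) df$group <- groups
  mapping <- if (is.null(groups)) {
    aes(x = .data$PC1, y = .data$PC2)
  } else {
    aes(x = .data$PC1, y = .data$PC2, colour = .data$group)
  }
  ggplot(df, mapping) +
    geom_point(size = 2) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])) +
    theme_minimal()
}

#' Plot replicate-consensus enrichment counts
#'
#' Bar height is the number of biological replicates in which a term is
#' enriched, faceted by major trend group.
#'
#' @param consensus Tibble from [replicate_consensus()].
#' @return A ggplot object.
#' @export
plot_enrichment_consensus <- function(consensus) {
  ggplot(consensus,
         aes(x = .data$term, y = .data$n_replicates_enriched)) +
    geom_col() +
    facet_wrap(~group, scales = "free_x") +
    labs(x = NULL, y = "replicates enriched") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a Pearson 1-r library tree
#'
#' @param x A `sage_tree`.
#' @param ... Passed to [ape::plot.phylo()].
#' @method plot sage_tree
#' @export
plot.sage_tree <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  invisible(x)
}
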