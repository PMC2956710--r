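#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Poisson-deviance K-means fit
#'
#' @param x A `poissonc_fit`.
#' @param ... Unused.
#' @return Tibble `tag`, `cluster`.
#' @export
tidy.poissonc_fit <- function(x, ...) {
  tibble(tag = names(x$assignment) %||%
           as.character(seq_along(x$assignment)),
         cluster = as.integer(x$assignment))
}

#' @rdname tidy.poissonc_fit
#' @export
glance.poissonc_fit <- function(x, ...) {
  tibble(K = x$K, dispersion = x$dispersion, iterations = x$iterations,
         n = length(x$assignment), seed = x$seed)
}

#' Tidy a consensus clustering
#'
#' @param x A `consensus_clustering`.
#' @param ... Unused.
#' @return The assignment tibble (`tag`, `cluster`, `stability`).
#' @export
tidy.consensus_clustering <- function(x, ...) x$assignment

#' @rdname tidy.consensus_clustering
#' @export
glance.consensus_clustering <- function(x, ...) {
  tibble(K = x$K, n_runs = x$n_runs,
         best_dispersion = x$best_dispersion,
         mean_stability = mean(x$assignment$stability),
         n = nrow(x$assignment))
}

#' Tidy a principal-component fit
#'
#' @param x A `sage_pca`.
#' @param ... Unused.
#' @return Tibble `sample`, `component`, `score` (projection coordinates).
#' @export
tidy.sage_pca <- function(x, ...) {
  as_tibble(x$sample_scores, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "component",
                        values_to = "score")
}

#' @rdname tidy.sage_pca
#' @export
glance.sage_pca <- function(x, ...) {
  tibble(n_components = x$n_components,
         var_pc1 = x$explained_variance[1],
         var_pc2 = x$explained_variance[2] %||% NA_real_,
         var_pc3 = x$explained_variance[3] %||% NA_real_,
         var_top = sum(x$explained_variance[seq_len(x$n_components)]))
}

#' @export
print.poissonc_fit <- function(x, ...) {
  cat(sprintf(
    "Poisson-deviance K-means: K = %d, n = %d, dispersion = %.4g (%d iter)\n",
    x$K, length(x$assignment), x$dispersion, x$iterations))
  invisible(x)
}

#' @export
print.consensus_clustering <- function(x, ...) {
  cat(sprintf(
    "Consensus clustering: K = %d over %d runs; mean stability %.3f\n",
    x$K, x$n_runs, mean(x$assignment$stability)))
  invisible(x)
}

#' @export
print.sage_atlas <- function(x, ...) {
  cat(sprintf(
    "Synthetic LongSAGE atlas: %d replicates x %d stages, %d tag types, %d tags/library\n",
    x$config$n_replicates, length(x$config$stages), x$config$n_tag_types,
    x$config$library_size))
  invisible(x)
}

#' @export
print.sage_tree <- function(x, ...) {
  cat("Pearson 1-r library tree over", length(x$tree$tip.label),
      "libraries\n")
  cat(x$newick, "\n")
  invisible(x)
}
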