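## Principal-component signature projection.
##
## An expression matrix (genes x samples) is gene-centered and decomposed by
## SVD; sample scores against a component are the plain Pearson correlation
## between the sample's gene vector and the component's loading vector
## ("standard correlation" scoring). A gene signature restricts the matrix
## before decomposition; group separation in the top-3 score space is
## summarised by the mean silhouette width and a 2-means partition
## agreement.

#' Principal components of a gene-centered expression matrix
#'
#' Genes (rows) are mean-centered; no variance scaling by default. Signs are
#' fixed by making each component's largest-magnitude loading positive, so
#' results are deterministic across platforms.
#'
#' @param m Numeric matrix, genes x samples, with dimnames.
#' @param n_components Number of components retained (default 3).
#' @param scale. Also divide each gene by its standard deviation.
#' @return A `sage_pca` object: `loadings` (genes x k), `sample_scores`
#'   (projection coordinates, samples x k), `explained_variance` (all
#'   fractions, non-increasing), `center`, `n_components`.
#' @export
pca_fit <- function(m, n_components = 3, scale. = FALSE) {
  stopifnot(is.matrix(m), ncol(m) >= 2)
  if (n_components > min(dim(m))) {
    stop("`n_components` exceeds matrix rank bound", call. = FALSE)
  }
  center <- rowMeans(m)
  x <- m - center
  if (scale.) {
    s <- apply(m, 1, sd)
    if (any(s == 0)) stop("zero-variance gene under scaling", call. = FALSE)
    x <- x / s
  }
  if (all(x == 0)) stop("degenerate matrix: no variance", call. = FALSE)
  sv <- svd(x)
  ev <- sv$d^2 / sum(sv$d^2)
  k <- n_components
  loadings <- sv$u[, seq_len(k), drop = FALSE]
  scores <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(k)) {
    piv <- which.max(abs(loadings[, j]))
    if (loadings[piv, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(rownames(m), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(colnames(m), paste0("PC", seq_len(k)))
  structure(list(loadings = loadings, sample_scores = scores,
                 explained_variance = ev, center = center,
                 n_components = k, scaled = scale.),
            class = "sage_pca")
}

#' Standard-correlation PC scores
#'
#' The score of a sample on a component is the Pearson correlation between
#' the sample's gene-expression vector and the component's loading vector;
#' scores therefore lie in `[-1, 1]`.
#'
#' @param m Expression matrix over the same genes as the fit.
#' @param fit A [pca_fit()] object.
#' @return Tibble `sample`, `component`, `score`.
#' @export
pc_scores <- function(m, fit) {
  stopifnot(inherits(fit, "sage_pca"))
  m <- m[rownames(fit$loadings), , drop = FALSE]
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop("constant sample vector: ", colnames(m)[which(sds == 0)[1]],
         call. = FALSE)
  }
  sc <- suppressWarnings(cor(m, fit$loadings))
  as_tibble(sc, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "component",
                        values_to = "score")
}

#' Project a gene signature and quantify group separation
#'
#' Restricts the matrix to the signature genes found (missing genes are
#' reported, not fatal), fits the top principal components, computes
#' standard-correlation scores, and summarises group separation in the
#' top-component score space by mean silhouette width and the agreement of
#' an unsupervised 2-means partition with the labels (2-group case).
#'
#' @param m Expression matrix, genes x samples.
#' @param signature Character vector of signature gene ids (>= 2 present).
#' @param groups Factor/character of sample group labels (column order).
#' @param n_components Components used for scoring (default 3).
#' @return List with `fit`, `scores` (wide tibble, one row per sample),
#'   `silhouette` (mean width; `NA` without groups), `kmeans_agreement`,
#'   `missing_genes`.
#' @export
project_signature <- function(m, signature, groups = NULL,
                              n_components = 3) {
  found <- intersect(signature, rownames(m))
  if (length(found) < 2) {
    stop("fewer than 2 signature genes found in the matrix", call. = FALSE)
  }
  missing_genes <- setdiff(signature, found)
  sub <- m[found, , drop = FALSE]
  fit <- pca_fit(sub, n_components = min(n_components, min(dim(sub))))
  scores <- pc_scores(sub, fit) |>
    tidyr::pivot_wider(names_from = "component", values_from = "score")
  smat <- as.matrix(scores[, -1])
  sil <- NA_real_
  agreement <- NA_real_
  if (!is.null(groups)) {
    g <- as.integer(factor(groups))
    if (length(unique(g)) >= 2) {
      sw <- cluster::silhouette(g, dist(smat))
      sil <- mean(sw[, "sil_width"])
      if (length(unique(g)) == 2) {
        km <- kmeans(smat, centers = 2, nstart = 10)$cluster
        match1 <- mean(km == g)
        agreement <- max(match1, 1 - match1)
      }
    }
  }
  list(fit = fit, scores = scores, silhouette = sil,
       kmeans_agreement = agreement, missing_genes = missing_genes)
}
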