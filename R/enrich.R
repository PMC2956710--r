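## Category enrichment of expression-trend clusters.
##
## Each cluster is contrasted against the rest of the clustered genes of the
## same biological replicate in a 2x2 table per annotation term. The score
## is the one-tailed Fisher (hypergeometric upper-tail) p-value, or its
## conservative EASE variant which recomputes the tail after discounting one
## in-cluster success.

#' One-tailed Fisher / EASE score for a 2x2 table
#'
#' Fisher mode: `P(X >= a)` for hypergeometric X with the table's margins.
#' EASE mode: the same upper tail with `a` replaced by `max(a - 1, 0)`
#' (margins unchanged), which penalises categories supported by few genes;
#' EASE p is always >= Fisher p.
#'
#' @param a In-cluster, in-category gene count.
#' @param b In-cluster, not in category.
#' @param c In rest, in category.
#' @param d In rest, not in category.
#' @param mode `"ease"` (default) or `"fisher"`.
#' @return One-tailed p-value in (0, 1], vectorised over table cells.
#' @examples
#' ease_score(3, 7, 2, 88, mode = "fisher")
#' @export
ease_score <- function(a, b, c, d, mode = c("ease", "fisher")) {
  mode <- match.arg(mode)
  if (any(c(a, b, c, d) < 0)) stop("negative cell counts", call. = FALSE)
  a_eff <- if (mode == "ease") pmax(a - 1, 0) else a
  # upper tail P(X >= a_eff) with margins: category size a+c, rest b+d,
  # cluster size a+b
  p <- phyper(a_eff - 1, a + c, b + d, a + b, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Term enrichment of clusters within one replicate
#'
#' Builds, for every (cluster, term) pair, the 2x2 table of the cluster's
#' genes against all other clustered genes of the replicate, and scores it
#' with both Fisher and EASE p-values. Genes are deduplicated within a
#' cluster (a multi-tag gene counts once); genes without any annotation are
#' retained in the table margins.
#'
#' @param assignments Tibble with columns `gene` and `cluster` (e.g. a
#'   consensus assignment joined to a tag map).
#' @param annotations Tibble `gene`, `term`.
#' @param alpha EASE threshold flagging enrichment (default 0.05).
#' @param replicate Optional replicate id carried into the result.
#' @param mode Which p-value decides the `enriched` flag.
#' @return Tibble `cluster`, `term`, `a`, `b`, `c`, `d`, `fisher_p`,
#'   `ease_p`, `enriched` (+ `replicate`), with attribute
#'   `"n_unannotated"`.
#' @export
cluster_enrichment <- function(assignments, annotations, alpha = 0.05,
                               replicate = NULL, mode = c("ease", "fisher")) {
  mode <- match.arg(mode)
  if (nrow(annotations) == 0) stop("empty annotation table", call. = FALSE)
  genes <- assignments |>
    filter(!is.na(.data$gene)) |>
    distinct(.data$gene, .data$cluster)
  universe <- unique(genes$gene)
  ann <- annotations |> filter(.data$gene %in% universe) |> distinct()
  n_unannotated <- length(setdiff(universe, ann$gene))

  term_genes <- split(ann$gene, ann$term)
  res <- purrr::map_dfr(sort(unique(genes$cluster)), function(cl) {
    in_cluster <- unique(genes$gene[genes$cluster == cl])
    n_in <- length(in_cluster)
    n_out <- length(universe) - n_in
    purrr::map_dfr(names(term_genes), function(tm) {
      tg <- term_genes[[tm]]
      a <- sum(in_cluster %in% tg)
      c_ <- length(tg) - a
      tibble(cluster = cl, term = tm, a = a, b = n_in - a, c = c_,
             d = n_out - c_)
    })
  })
  res$fisher_p <- ease_score(res$a, res$b, res$c, res$d, mode = "fisher")
  res$ease_p <- ease_score(res$a, res$b, res$c, res$d, mode = "ease")
  res$enriched <- (if (mode == "ease") res$ease_p else res$fisher_p) <= alpha
  if (!is.null(replicate)) res$replicate <- replicate
  attr(res, "n_unannotated") <- n_unannotated
  res
}

#' Replicate consensus of group-level enrichments
#'
#' Amalgamates each replicate's cluster enrichments to the five major trend
#' groups and counts, for every (group, term), the number of biological
#' replicates in which the term is enriched; terms enriched in no replicate
#' are omitted. Similar terms can be pooled into representative categories
#' via a term-to-category map before counting.
#'
#' @param results Row-bound [cluster_enrichment()] tibbles with a
#'   `replicate` column.
#' @param amalgamation Tibble `replicate`, `cluster`, `group` mapping each
#'   replicate's clusters to major groups.
#' @param pooling Optional tibble `term`, `category`; unpooled terms keep
#'   their own name.
#' @return Tibble `group`, `term`, `n_replicates_enriched`.
#' @export
replicate_consensus <- function(results, amalgamation, pooling = NULL) {
  stopifnot("replicate" %in% names(results))
  results <- results[setdiff(names(results), "group")]
  joined <- results |>
    inner_join(amalgamation, by = c("replicate", "cluster"))
  if (!is.null(pooling)) {
    joined <- joined |>
      left_join(pooling, by = "term") |>
      mutate(term = dplyr::coalesce(.data$category, .data$term)) |>
      select(-"category")
  }
  joined |>
    filter(.data$enriched) |>
    distinct(.data$group, .data$term, .data$replicate) |>
    count(.data$group, .data$term, name = "n_replicates_enriched") |>
    arrange(.data$group, dplyr::desc(.data$n_replicates_enriched))
}
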