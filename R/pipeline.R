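## End-to-end orchestration: simulate (or ingest) -> filter -> differential
## expression -> trend clustering -> enrichment -> library tree -> signature
## projection, with every stage output written to disk and a JSON manifest
## recording parameters and seeds.

#' Pipeline configuration
#'
#' @param seed Master seed; each stochastic stage derives its own sub-seed.
#' @param atlas [atlas_config()] for the synthetic atlas (its seed is tied
#'   to `seed`).
#' @param qf_threshold Quality-factor threshold (default 0.95).
#' @param alphas Significance thresholds for the consistency summary.
#' @param min_total Combined-count threshold for clustering tags (strict >).
#' @param K Number of K-means clusters.
#' @param n_runs Random restarts for consensus clustering (default 100).
#' @param known_genes Genes already associated with the phenotype, for the
#'   novelty funnel.
#' @param signature_separation,signature_groups Parameters of the simulated
#'   signature-projection matrix.
#' @param generate_reads Simulate raw ditag reads and run the filter cascade
#'   (otherwise the atlas counts are used directly).
#' @param out_dir Output directory (default a fresh temporary directory).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            atlas = atlas_config(seed = seed),
                            qf_threshold = 0.95,
                            alphas = c(0.05, 0.01, 0.001),
                            min_total = 10,
                            K = 5L,
                            n_runs = 100L,
                            known_genes = character(),
                            signature_separation = 5,
                            signature_groups = c(tumor = 10L, normal = 10L),
                            generate_reads = TRUE,
                            out_dir = NULL) {
  stopifnot(qf_threshold > 0, qf_threshold <= 1, all(alphas > 0 & alphas < 1),
            min_total >= 0, K >= 1, n_runs >= 1)
  structure(list(seed = as.integer(seed), atlas = atlas,
                 qf_threshold = qf_threshold, alphas = alphas,
                 min_total = min_total, K = as.integer(K),
                 n_runs = as.integer(n_runs), known_genes = known_genes,
                 signature_separation = signature_separation,
                 signature_groups = signature_groups,
                 generate_reads = generate_reads,
                 out_dir = out_dir %||% file.path(tempdir(),
                                                  paste0("sagetrend_run_",
                                                         seed))),
            class = "pipeline_config")
}

#' Run the full synthetic-atlas analysis pipeline
#'
#' Executes every stage in order, writes each stage's tables under
#' `config$out_dir` and returns a manifest (also written as
#' `manifest.json`) listing stage outputs, parameters and seeds. Re-running
#' with the same configuration reproduces all outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with the in-memory stage results (`atlas`,
#'   `filtering`, `de`, `consistency`, `clustering`, `enrichment`, `tree`,
#'   `funnel`, `pca`) and `manifest`.
#' @export
run_atlas_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage_paths <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## 1. synthetic atlas
  atlas <- run_stage("atlas", generate_atlas(config$atlas))
  write_tag_counts(atlas$libraries, file.path(out, "atlas"))
  write_tag_map(atlas$tag_map, file.path(out, "tag_map.tsv"))
  readr::write_tsv(atlas$annotations, file.path(out, "annotations.tsv"))
  readr::write_tsv(atlas$truth_trends, file.path(out, "truth_trends.tsv"))
  stage_paths$atlas <- file.path(out, "atlas")

  ## 2. reads + filter cascade (or pass-through counts)
  if (config$generate_reads) {
    filtering <- run_stage("filtering", {
      reads <- generate_raw_ditags(atlas)
      process_reads(reads, config$atlas$linker_type1,
                    config$atlas$linker_type2, config$qf_threshold)
    })
    counts <- filtering$counts |>
      tidyr::separate_wider_delim("library_id", "_",
                                  names = c("replicate", "stage"),
                                  cols_remove = FALSE) |>
      select("library_id", "replicate", "stage", "tag", "count")
    readr::write_tsv(filtering$composition,
                     file.path(out, "library_composition.tsv"))
    jsonlite::write_json(filtering$composition,
                         file.path(out, "library_composition.json"),
                         dataframe = "columns", auto_unbox = TRUE)
    stage_paths$filtering <- file.path(out, "library_composition.tsv")
  } else {
    filtering <- NULL
    counts <- atlas$libraries
    stage_paths$filtering <- stage_paths$atlas
  }
  write_tag_counts(counts, file.path(out, "filtered"))

  ## 3. pairwise differential expression
  de <- run_stage("de", stagewise_de(counts))
  readr::write_tsv(de, file.path(out, "de_results.tsv"))
  stage_paths$de <- file.path(out, "de_results.tsv")

  ## 4. cross-replicate consistency + trend labels
  consistency <- run_stage("consistency",
                           consistent_de(de, config$alphas,
                                         unique(counts$replicate)))
  readr::write_tsv(consistency$summary,
                   file.path(out, "consistency_summary.tsv"))
  stage_paths$consistency <- file.path(out, "consistency_summary.tsv")
  trends <- run_stage("trends", pipeline_trends(de, config$atlas$stages))
  readr::write_tsv(trends, file.path(out, "trend_labels.tsv"))

  ## 5. consensus clustering per replicate + amalgamation
  clustering <- run_stage("clustering", {
    purrr::map(setNames(nm = unique(counts$replicate)), function(r) {
      prof <- select_clustering_tags(counts |> filter(.data$replicate == r),
                                     atlas$tag_map, config$min_total,
                                     stages = config$atlas$stages)
      if (nrow(prof) < config$K) return(NULL)
      cc <- consensus_cluster(prof, config$K, config$n_runs,
                              seed = derive_seed(config$seed,
                                                 match(r, unique(counts$replicate))))
      groups <- amalgamate_groups(cc)
      list(profiles = prof, consensus = cc, groups = groups)
    })
  })
  assign_tab <- purrr::imap_dfr(clustering, function(cl, r) {
    if (is.null(cl)) return(NULL)
    cl$consensus$assignment |>
      mutate(replicate = r, group = cl$groups[.data$cluster])
  })
  readr::write_tsv(assign_tab, file.path(out, "cluster_assignments.tsv"))
  stage_paths$clustering <- file.path(out, "cluster_assignments.tsv")

  ## 6. enrichment per replicate + replicate consensus
  enrichment <- run_stage("enrichment", {
    res <- purrr::imap_dfr(clustering, function(cl, r) {
      if (is.null(cl)) return(NULL)
      cluster_enrichment(cl$consensus$assignment |>
                           left_join(atlas$tag_map[, c("tag", "gene")],
                                     by = "tag"),
                         atlas$annotations, replicate = r)
    })
    amalg <- purrr::imap_dfr(clustering, function(cl, r) {
      if (is.null(cl)) return(NULL)
      tibble(replicate = r, cluster = seq_along(cl$groups),
             group = cl$groups)
    })
    consensus <- if (nrow(res)) replicate_consensus(res, amalg) else tibble()
    list(results = res, consensus = consensus)
  })
  readr::write_tsv(enrichment$results, file.path(out, "enrichment.tsv"))
  readr::write_tsv(enrichment$consensus,
                   file.path(out, "enrichment_consensus.tsv"))
  stage_paths$enrichment <- file.path(out, "enrichment.tsv")

  ## 7. library tree
  tree <- run_stage("tree", build_library_tree(counts))
  write_newick(tree, file.path(out, "library_tree.nwk"))
  stage_paths$tree <- file.path(out, "library_tree.nwk")

  ## 8. candidate-gene funnel on the middle-vs-last comparison
  stages <- config$atlas$stages
  comp_name <- paste0(stages[2], "_vs_", stages[3])
  funnel <- run_stage("funnel", {
    tags <- consistency$detail |>
      filter(.data$comparison == comp_name,
             .data$alpha == max(config$alphas)) |>
      pull("tag") |> unique()
    candidate_gene_summary(tags, atlas$tag_map, config$known_genes)
  })
  jsonlite::write_json(as.list(funnel), file.path(out, "funnel.json"),
                       auto_unbox = TRUE)
  stage_paths$funnel <- file.path(out, "funnel.json")

  ## 9. signature projection on a simulated expression compendium
  pca <- run_stage("pca", {
    sim <- generate_signature_matrix(
      n_genes = 400, groups = config$signature_groups,
      separation = config$signature_separation,
      seed = derive_seed(config$seed, 99L))
    proj <- project_signature(sim$matrix, sim$signature_genes, sim$groups)
    list(sim = sim, projection = proj)
  })
  readr::write_tsv(pca$projection$scores, file.path(out, "pc_scores.tsv"))
  stage_paths$pca <- file.path(out, "pc_scores.tsv")

  manifest <- list(
    package = "sagetrend",
    version = as.character(utils::packageVersion("sagetrend")),
    seed = config$seed,
    parameters = list(
      qf_threshold = config$qf_threshold, alphas = config$alphas,
      min_total = config$min_total, K = config$K, n_runs = config$n_runs,
      atlas = unclass(config$atlas)),
    stages = stage_paths
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(atlas = atlas, filtering = filtering, de = de,
                 consistency = consistency, trends = trends,
                 clustering = clustering, enrichment = enrichment,
                 tree = tree, funnel = funnel, pca = pca,
                 manifest = manifest))
}

## assemble per-(tag, replicate) three-stage cpm profiles with step p-values
pipeline_trends <- function(de, stages, alpha = 0.05) {
  s12 <- paste0(stages[1], "_vs_", stages[2])
  s23 <- paste0(stages[2], "_vs_", stages[3])
  s13 <- paste0(stages[1], "_vs_", stages[3])
  a <- de |> filter(.data$comparison == s12) |>
    select("tag", "replicate", cpm_1 = "cpm_a", cpm_2 = "cpm_b",
           p_step1 = "p")
  b <- de |> filter(.data$comparison == s23) |>
    select("tag", "replicate", cpm_3 = "cpm_b", p_step2 = "p")
  n <- de |> filter(.data$comparison == s13) |>
    select("tag", "replicate", p_net = "p")
  prof <- a |>
    inner_join(b, by = c("tag", "replicate")) |>
    left_join(n, by = c("tag", "replicate"))
  classify_trend(prof, alpha = alpha)
}
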