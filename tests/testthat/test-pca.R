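test_that("principal components have the SVD identities and fixed signs", {
  set.seed(21)
  m <- matrix(rnorm(50 * 12), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:12)))
  fit <- pca_fit(m, n_components = 12)
  ev <- fit$explained_variance
  expect_true(all(diff(ev) <= 1e-12))
  expect_equal(sum(ev), 1, tolerance = 1e-12)
  # full reconstruction of the centered matrix
  recon <- fit$loadings %*% t(fit$sample_scores)
  expect_equal(recon, m - rowMeans(m), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: the largest-|.| loading of each component is positive
  for (j in 1:3) {
    expect_gt(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
  }

  # rank-1 data: samples on a line -> PC1 carries all variance
  line <- outer(rnorm(30), seq(-2, 2, length.out = 8))
  rownames(line) <- sprintf("g%02d", 1:30)
  colnames(line) <- sprintf("s%d", 1:8)
  fit1 <- pca_fit(line, n_components = 2)
  expect_equal(fit1$explained_variance[1], 1, tolerance = 1e-12)
  expect_error(pca_fit(matrix(1, 5, 4)), "degenerate")
})

test_that("PCA is invariant to gene order and per-gene constant shifts", {
  set.seed(22)
  m <- matrix(rnorm(40 * 8), nrow = 40,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:8)))
  f1 <- pca_fit(m)
  shifted <- m + matrix(rnorm(40), 40, 8)  # constant per gene across samples
  f2 <- pca_fit(shifted)
  expect_equal(f1$sample_scores, f2$sample_scores, tolerance = 1e-8)
  perm <- sample(40)
  f3 <- pca_fit(m[perm, ])
  expect_equal(f1$sample_scores, f3$sample_scores, tolerance = 1e-8)
})

test_that("standard-correlation scores behave as correlations", {
  set.seed(23)
  m <- matrix(rnorm(60 * 10), nrow = 60,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:10)))
  fit <- pca_fit(m)
  sc <- pc_scores(m, fit)
  expect_true(all(sc$score >= -1 & sc$score <= 1))

  # a sample equal to the PC1 loading vector scores 1 on PC1
  m2 <- cbind(m, PCcopy = fit$loadings[, 1])
  sc2 <- pc_scores(m2, fit)
  expect_equal(sc2$score[sc2$sample == "PCcopy" & sc2$component == "PC1"], 1,
               tolerance = 1e-8)

  # an orthogonal, zero-correlation sample scores ~0
  v <- rnorm(60)
  v <- v - mean(v)
  l1 <- fit$loadings[, 1] - mean(fit$loadings[, 1])
  v <- v - sum(v * l1) / sum(l1^2) * l1
  m3 <- cbind(m, ortho = v)
  sc3 <- pc_scores(m3, fit)
  expect_equal(sc3$score[sc3$sample == "ortho" & sc3$component == "PC1"], 0,
               tolerance = 1e-8)

  const <- cbind(m, flat = rep(1, 60))
  expect_error(pc_scores(const, fit), "flat")
})

test_that("signature projection separates planted groups and not null data", {
  sim <- generate_signature_matrix(400, c(tumor = 10, normal = 10),
                                   separation = 5, seed = 31)
  pr <- project_signature(sim$matrix, sim$signature_genes, sim$groups)
  expect_gt(pr$silhouette, 0.5)
  expect_equal(pr$kmeans_agreement, 1)

  # restricting to all genes is plain PCA
  pr_all <- project_signature(sim$matrix, rownames(sim$matrix), sim$groups)
  full <- pca_fit(sim$matrix)
  expect_equal(as.matrix(pr_all$scores[, -1]),
               unname(as.matrix(pc_scores(sim$matrix, full) |>
                                  tidyr::pivot_wider(names_from = component,
                                                     values_from = score) |>
                                  dplyr::select(-sample))),
               tolerance = 1e-10, ignore_attr = TRUE)

  # missing signature genes are tolerated, too few are fatal
  pr_miss <- project_signature(sim$matrix,
                               c(sim$signature_genes, "NOT_A_GENE"),
                               sim$groups)
  expect_equal(pr_miss$missing_genes, "NOT_A_GENE")
  expect_error(project_signature(sim$matrix, c("NO1", "NO2"), sim$groups),
               "signature genes")

  # null separation: |silhouette| stays near zero across seeds
  sils <- vapply(1:20, function(s) {
    sim0 <- generate_signature_matrix(400, c(a = 10, b = 10),
                                      separation = 0, seed = s)
    project_signature(sim0$matrix, sim0$signature_genes,
                      sim0$groups)$silhouette
  }, numeric(1))
  expect_true(all(abs(sils) < 0.15))
})
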