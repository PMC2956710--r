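test_that("clustering-tag selection applies the count and mapping rules", {
  libs <- tibble::tibble(
    library_id = rep(c("R1_AS", "R1_RAD", "R1_CR"), each = 3),
    replicate = "R1",
    stage = rep(c("AS", "RAD", "CR"), each = 3),
    tag = rep(c("T1", "T2", "T3"), 3),
    count = c(3L, 4L, 100L, 3L, 4L, 100L, 4L, 4L, 100L)
  )
  map <- tibble::tibble(tag = c("T1", "T2", "T3"),
                        gene = c("G1", "G2", "G3"),
                        class = c("unique_sense", "unique_sense",
                                  "antisense"))
  sel <- select_clustering_tags(libs, map, stages = c("AS", "RAD", "CR"))
  # T1 sums to 10 (excluded, strict >10), T3 is antisense (excluded)
  expect_equal(sel$tag, "T2")
  expect_equal(sel$total, 12)
  expect_equal(sel$pct_AS + sel$pct_RAD + sel$pct_CR, 100, tolerance = 1e-9)
})

test_that("the Poisson deviance matches hand values and an oracle", {
  expect_equal(poissonc_distance(c(4, 0), c(0.5, 0.5)), 4 * log(2),
               tolerance = 1e-12)
  expect_equal(poissonc_distance(c(2, 2, 2), c(1, 1, 1) / 3), 0,
               tolerance = 1e-9)
  expect_error(poissonc_distance(c(0, 0), c(0.5, 0.5)), "all-zero")

  set.seed(2)
  for (i in 1:25) {
    x <- rpois(3, lambda = sample(1:50, 3, replace = TRUE)) + c(1, 0, 0)
    c0 <- runif(3); c0 <- c0 / sum(c0)
    expect_equal(poissonc_distance(x, c0), deviance_oracle(x, c0),
                 tolerance = 1e-10)
    # scaling behaviour checked against the oracle, alpha = 10
    expect_equal(poissonc_distance(10 * x, c0), deviance_oracle(10 * x, c0),
                 tolerance = 1e-10)
  }
})

test_that("the K-means descends monotonically and nails planted structure", {
  pg <- planted_two_groups()
  fit <- poissonc_fit(pg$x, K = 2, seed = 3)
  expect_true(all(diff(fit$history) <= 1e-8))
  expect_lte(fit$dispersion, fit$history[1])
  # perfect recovery of the two planted groups
  expect_equal(adjusted_rand_index(fit$assignment, pg$truth), 1)

  # K = n puts every profile in its own cluster with zero dispersion
  small <- pg$x[1:8, ]
  fit_n <- poissonc_fit(small, K = 8, seed = 1)
  expect_equal(fit_n$dispersion, 0, tolerance = 1e-9)
  expect_error(poissonc_fit(small, K = 9), "between 1 and")

  g <- glance(fit)
  expect_equal(g$K, 2)
  expect_equal(nrow(tidy(fit)), 200)
})

test_that("consensus equals a single fit at n_runs = 1 and is label-stable", {
  pg <- planted_two_groups()
  cc1 <- consensus_cluster(pg$x, K = 2, n_runs = 1, seed = 5)
  single <- poissonc_fit(pg$x, K = 2, seed = sagetrend:::derive_seed(5, 1))
  expect_equal(adjusted_rand_index(cc1$assignment$cluster,
                                   single$assignment), 1)

  cc <- consensus_cluster(pg$x, K = 2, n_runs = 20, seed = 5)
  # perfectly separated planting: every tag fully stable
  expect_true(all(cc$assignment$stability == 1))
  expect_equal(adjusted_rand_index(cc$assignment$cluster, pg$truth), 1)
})

test_that("the in-package adjusted Rand index agrees with an external implementation", {
  skip_if_not_installed("mclust")
  set.seed(4)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, 1:5), 1)
})

test_that("the dispersion curve is non-increasing and flags the planted K", {
  set.seed(6)
  w <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.2, 0.7), c(0.1, 0.8, 0.1),
             c(1, 1, 1) / 3, c(0.45, 0.1, 0.45))
  x <- do.call(rbind, lapply(1:5, function(g) {
    t(rmultinom(60, 150, w[g, ]))
  }))
  colnames(x) <- c("count_AS", "count_RAD", "count_CR")
  dc <- dispersion_curve(x, K_range = 2:8, seed = 2, n_restarts = 4)
  expect_true(all(diff(dc$curve$dispersion) <= 1e-8))
  expect_true(dc$elbow %in% 4:6)
})

test_that("centroid amalgamation follows the five-trend rule", {
  cen <- rbind(c(20, 30, 50), c(50, 30, 20), c(20, 60, 20),
               c(34, 33, 33), c(45, 10, 45)) / 100
  expect_equal(amalgamate_groups(cen), c(1L, 2L, 3L, 4L, 5L))
  # tolerance band: within tau percentage points everything is constant
  expect_equal(amalgamate_groups(matrix(c(32, 34, 34) / 100, 1)), 4L)
})

test_that("library trees use 1-r distances with least-squares branch lengths", {
  set.seed(9)
  counts <- purrr::map_dfr(c("L1", "L2", "L3"), function(l) {
    tibble::tibble(library_id = l, tag = sprintf("t%03d", 1:200),
                   count = rpois(200, 30) + (l == "L3") * rpois(200, 25))
  })
  tr <- build_library_tree(counts)
  d <- tr$dist
  # three-point closed form: a_i = (d_ij + d_ik - d_jk) / 2
  expected <- c(
    (d[1, 2] + d[1, 3] - d[2, 3]) / 2,
    (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
    (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  )
  edge_len <- tr$tree$edge.length[match(1:3, tr$tree$edge[, 2])]
  expect_equal(edge_len, expected, tolerance = 1e-8)
  expect_true(all(d >= 0 & d <= 2))
  expect_match(tr$newick, "^\\(")

  # identical libraries are at distance zero
  c2 <- dplyr::bind_rows(
    counts,
    counts |> filter(library_id == "L1") |>
      mutate(library_id = "L1copy"))
  tr2 <- build_library_tree(c2)
  expect_equal(tr2$dist["L1", "L1copy"], 0, tolerance = 1e-12)

  const <- dplyr::bind_rows(
    counts,
    tibble::tibble(library_id = "LC", tag = sprintf("t%03d", 1:200),
                   count = 5L))
  expect_error(build_library_tree(const), "constant")
})

test_that("same-stage libraries form clades under strong stage effects", {
  cfg <- atlas_config(seed = 4, n_tag_types = 600, library_size = 20000,
                      effect_size = 4,
                      trend_mix = c(0.25, 0.25, 0.15, 0.20, 0.15))
  a <- generate_atlas(cfg)
  tr <- build_library_tree(a$libraries)
  groups <- setNames(
    a$libraries$stage[match(tr$tree$tip.label, a$libraries$library_id)],
    tr$tree$tip.label)
  clades <- stage_clades(tr, groups)
  expect_true(all(clades$monophyletic))
})
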