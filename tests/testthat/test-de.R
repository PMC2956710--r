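test_that("the exact count test has its closed-form limits and symmetries", {
  expect_equal(ac_pvalue(0, 0, 1e5, 1e5), 1)
  expect_equal(ac_pvalue(0, 0, 1e4, 3e5), 1)
  # exchange symmetry with equal sizes
  expect_equal(ac_pvalue(3, 9, 1e5, 1e5), ac_pvalue(9, 3, 1e5, 1e5),
               tolerance = 1e-12)
  # full exchange: p(x, y, N1, N2) = p(y, x, N2, N1)
  for (cs in list(c(2, 11, 5e4, 2e5), c(0, 7, 1e5, 5e4),
                  c(30, 14, 2e5, 1e5))) {
    expect_equal(ac_pvalue(cs[1], cs[2], cs[3], cs[4]),
                 ac_pvalue(cs[2], cs[1], cs[4], cs[3]), tolerance = 1e-10)
  }
  expect_error(ac_pvalue(1, 1, 0, 1e5), "positive")
  expect_error(ac_pvalue(-1, 1, 1e5, 1e5), ">= 0")
})

test_that("the log-space summation matches the negative-binomial route", {
  grid <- expand.grid(x = 0:50, y = 0:50, ratio = c(0.5, 1, 2))
  n1 <- 1e5
  got <- ac_pvalue(grid$x, grid$y, n1, n1 * grid$ratio)
  want <- mapply(ac_oracle, grid$x, grid$y, n1, n1 * grid$ratio)
  rel <- abs(got - want) / pmax(want, .Machine$double.xmin)
  expect_lt(max(rel), 1e-10)
  expect_true(all(got > 0 & got <= 1))
})

test_that("p-values shrink as y moves away from its conditional mode", {
  x <- 20; n1 <- 1e5; n2 <- 1e5
  up <- ac_pvalue(x, 20:60, n1, n2)
  expect_true(all(diff(up) <= 1e-12))
  down <- ac_pvalue(x, 20:0, n1, n2)
  expect_true(all(diff(down) <= 1e-12))
})

test_that("pairwise comparison joins absent tags as zero and sets direction by cpm", {
  libA <- tibble::tibble(library_id = "A", tag = c("T1", "T2"),
                         count = c(10L, 5L))
  libB <- tibble::tibble(library_id = "B", tag = c("T1", "T3"),
                         count = c(10L, 12L))
  de <- pairwise_de(libA, libB, n1 = 250000, n2 = 250000)
  expect_setequal(de$tag, c("T1", "T2", "T3"))
  t3 <- de[de$tag == "T3", ]
  expect_equal(t3$x, 0)
  expect_equal(t3$direction, "up")
  expect_lte(t3$p, 0.05)  # 0 vs 12 at N = 250k
  expect_equal(t3$p, ac_oracle(0, 12, 250000, 250000), tolerance = 1e-10)
  expect_equal(de$direction[de$tag == "T1"], "none")
  expect_error(pairwise_de(libA, libA), "itself")

  # a library against itself has no significant tag at any usual level
  libA2 <- dplyr::mutate(libA, library_id = "A2")
  same <- pairwise_de(libA, libA2)
  expect_true(all(same$p > 0.05))

  # a planted ten-fold change at moderate depth is significant at 0.001
  expect_lt(ac_pvalue(100, 1000, 1e5, 1e5), 0.001)
})

test_that("consistency requires agreement of all replicates and is monotone in alpha", {
  de <- tibble::tibble(
    comparison = "AS_vs_RAD",
    replicate = rep(c("R1", "R2", "R3"), times = 3),
    tag = rep(c("up3", "mixed", "up2"), each = 3),
    direction = c("up", "up", "up",
                  "up", "up", "down",
                  "up", "up", "up"),
    p = c(0.001, 0.02, 0.04,
          0.001, 0.001, 0.001,
          0.01, 0.02, 0.2)
  )
  cons <- consistent_de(de, replicates = c("R1", "R2", "R3"))
  at05 <- cons$detail[cons$detail$alpha == 0.05, ]
  expect_setequal(at05$tag, "up3")  # mixed excluded, up2 ns in R3
  expect_equal(at05$direction, "up")

  cell <- cons$summary |>
    filter(comparison == "AS_vs_RAD", direction == "up") |>
    arrange(alpha)
  expect_true(all(diff(cell$n_tags) >= 0))
  expect_error(consistent_de(de, replicates = c("R1", "R4")), "R4")
})

test_that("consistency counts are monotone across thresholds on simulated data", {
  a <- generate_atlas(atlas_config(seed = 8, n_tag_types = 250,
                                   library_size = 8000))
  cons <- consistent_de(stagewise_de(a$libraries))
  by_cell <- cons$summary |>
    arrange(comparison, direction, alpha) |>
    group_by(comparison, direction) |>
    summarise(mono = all(diff(n_tags) >= 0), .groups = "drop")
  expect_true(all(by_cell$mono))
})

test_that("trend labels follow the signed significance pattern of the steps", {
  prof <- tibble::tibble(
    tag = c("acpp_like", "flat", "valley"),
    replicate = "R1",
    cpm_1 = c(12, 100, 500),
    cpm_2 = c(79, 100, 100),
    cpm_3 = c(382, 100, 480),
    p_step1 = c(0.001, 1, 0.001),
    p_step2 = c(0.001, 1, 0.001)
  )
  tl <- classify_trend(prof)
  expect_equal(tl$label, c("A", "M", "G"))
  expect_equal(tl$group, c(1L, 4L, 5L))

  # net-change refinement: up-then-flat is group 1 only with a net rise
  prof2 <- tibble::tibble(tag = "upflat", replicate = "R1",
                          cpm_1 = 10, cpm_2 = 40, cpm_3 = 38,
                          p_step1 = 0.001, p_step2 = 0.5,
                          p_net = c(0.001))
  expect_equal(classify_trend(prof2)$group, 1L)
  prof2$p_net <- 1
  expect_equal(classify_trend(prof2)$group, 4L)
  expect_error(classify_trend(prof[, 1:4]), "three cpm stages")
})

test_that("the candidate funnel separates known from novel genes", {
  known <- readLines(system.file("extdata", "known_cr_genes.txt",
                                 package = "sagetrend"))
  expect_length(known, 18)
  fm <- synthetic_funnel_map(n_tags = 193, n_ambiguous = 48, n_host = 10,
                             n_no_map = 7, n_genomic = 5,
                             n_multi_tag_genes = 9, gene_names = known)
  out <- candidate_gene_summary(fm$tags, fm$map, known)
  expect_equal(out$n_relevant, 135)
  expect_equal(out$n_candidate_genes, 114)
  expect_equal(out$n_known, 18)
  expect_equal(out$n_novel, 96)
  expect_lte(out$n_novel, out$n_candidate_genes)
})
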