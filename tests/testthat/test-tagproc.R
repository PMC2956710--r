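make_read <- function(tag1, tag2, q = rep(40L, 42), id = "r1", lib = "L1") {
  tibble::tibble(
    read_id = id, library_id = lib,
    sequence = paste0("CATG", tag1, revcomp(tag2), "CATG"),
    quality = vapply(list(q), function(v) rawToChar(as.raw(v + 33L)),
                     character(1))
  )
}

test_that("a ditag yields two tag observations with correct orientation", {
  t1 <- "ACGTACGTACGTACGTA"
  t2 <- "TTTTGGGGCCCCAAAAT"
  ex <- extract_tags(make_read(t1, t2))
  expect_equal(nrow(ex$observations), 2)
  expect_setequal(ex$observations$tag, c(t1, t2))
  expect_equal(nrow(ex$ditags), 1)
  expect_equal(ex$ditags$ditag, paste0(t1, revcomp(t2)))

  # too-short reads are skipped, not fatal
  short <- tibble::tibble(read_id = "s", library_id = "L1",
                          sequence = "CATGACGTACGTCATG",
                          quality = strrep("I", 16))
  ex2 <- extract_tags(dplyr::bind_rows(make_read(t1, t2), short))
  expect_equal(ex2$n_skipped, 1)
  expect_equal(nrow(ex2$observations), 2)
})

test_that("bad-tag filter removes tags with any N call", {
  obs <- tibble::tibble(library_id = "L1", read_id = c("a", "b"), slot = 1L,
                        tag = c("ACGTACGTACGTACGTA", "ACGTNCGTACGTACGTA"),
                        qf = 1)
  f <- filter_bad_tags(obs)
  expect_equal(nrow(f$kept), 1)
  expect_equal(f$n_removed, 1)
  expect_equal(f$kept$tag, "ACGTACGTACGTACGTA")
})

test_that("quality factor follows the Phred product and gates at 0.95", {
  expect_equal(quality_factor(rep(40L, 17)), (1 - 1e-4)^17, tolerance = 1e-12)
  expect_equal(quality_factor(rep(20L, 17)), 0.99^17, tolerance = 1e-12)
  expect_gt(quality_factor(rep(40L, 17)), 0.95)
  expect_lt(quality_factor(rep(20L, 17)), 0.95)

  obs <- tibble::tibble(library_id = "L1", read_id = c("a", "b"), slot = 1L,
                        tag = "ACGTACGTACGTACGTA",
                        qf = c(quality_factor(rep(40L, 17)),
                               quality_factor(rep(20L, 17))))
  qf <- quality_filter(obs)
  expect_equal(nrow(qf$kept), 1)
  expect_equal(qf$n_removed, 1)
  expect_equal(qf$removed$mean_qf, mean(obs$qf))
  # QF is monotone non-increasing when any base quality decreases
  q <- rep(30L, 17)
  for (i in c(1, 9, 17)) {
    q2 <- q; q2[i] <- 10L
    expect_lt(quality_factor(q2), quality_factor(q))
  }
  expect_error(quality_filter(dplyr::mutate(obs, qf = NA_real_)), "quality")
})

test_that("duplicate ditags are counted beyond the first occurrence", {
  led <- tibble::tibble(library_id = "L1", read_id = paste0("r", 1:5),
                        ditag = rep("AAA", 5))
  expect_equal(count_duplicate_ditags(led)$n_duplicate_ditags, 4)

  set.seed(1)
  base <- replicate(90, paste0(sample(c("A", "C", "G", "T"), 34,
                                      replace = TRUE), collapse = ""))
  led2 <- tibble::tibble(library_id = "L1", read_id = paste0("r", 1:100),
                         ditag = c(base, base[1:10]))
  expect_equal(count_duplicate_ditags(led2)$n_duplicate_ditags, 10)
  expect_equal(count_duplicate_ditags(led2, c(L1 = 200))$pct_duplicate_ditags,
               5)

  led3 <- tibble::tibble(library_id = "L1", read_id = paste0("r", 1:3),
                         ditag = c("A", "B", "C"))
  d3 <- count_duplicate_ditags(led3, c(L1 = 6))
  expect_equal(d3$n_duplicate_ditags, 0)
  expect_equal(d3$pct_duplicate_ditags, 0)
})

test_that("published per-library accounting is reproduced by the cascade arithmetic", {
  tab <- readr::read_tsv(system.file("extdata", "table1_composition.tsv",
                                     package = "sagetrend"),
                         show_col_types = FALSE)
  comp <- library_composition(tab)
  s1885 <- comp[comp$library_id == "S1885", ]
  expect_equal(s1885$total_minus_bad, 309561)
  expect_equal(s1885$pct_duplicate_ditags, 6.38)
  expect_equal(s1885$total_q95, 246504)
  expect_equal(s1885$final_total, 246361)
  expect_equal(sum(comp$final_total), 2305589)
  # accounting identity for every library
  expect_equal(comp$unfiltered_total,
               comp$final_total + comp$n_bad + comp$n_below_qf +
                 comp$n_ldt_type1 + comp$n_ldt_type2)
})

test_that("cpm normalisation is exact and invertible", {
  counts <- tibble::tibble(library_id = "L1",
                           tag = c("A", "B", "C"),
                           count = c(100L, 150000L, 99900L))
  cpm <- normalize_cpm(counts)
  expect_equal(cpm$cpm[1], 400)  # 100 in 250,000
  expect_equal(sum(cpm$cpm), 1e6)
  expect_equal(cpm$cpm * sum(counts$count) / 1e6, as.numeric(counts$count))
  one <- normalize_cpm(tibble::tibble(library_id = "L1", tag = "A",
                                      count = 7L))
  expect_equal(one$cpm, 1e6)
  expect_error(normalize_cpm(counts[0, ]), "empty")
})

test_that("linker-derived tags are removed by exact match with per-type tallies", {
  counts <- tibble::tibble(
    library_id = "L1",
    tag = c("AAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCC", "GGGGGGGGGGGGGGGGG"),
    count = c(10L, 4L, 3L))
  r <- remove_ldts(counts, "CCCCCCCCCCCCCCCCC", "GGGGGGGGGGGGGGGGG")
  expect_equal(nrow(r$counts), 1)
  expect_equal(r$removed$n_ldt_type1, 4)
  expect_equal(r$removed$n_ldt_type2, 3)
  none <- remove_ldts(counts, "TTTTTTTTTTTTTTTTT", "TATATATATATATATAT")
  expect_equal(none$counts, counts)
  expect_equal(none$removed$n_ldt_type1, 0)
})

test_that("contaminant-free synthetic reads reproduce the generating counts", {
  cfg <- clean_config()
  a <- generate_atlas(cfg)
  r <- generate_raw_ditags(a)
  pr <- process_reads(r, cfg$linker_type1, cfg$linker_type2)
  expect_equal(
    pr$counts |> arrange(library_id, tag),
    a$libraries |> select(library_id, tag, count) |> arrange(library_id, tag)
  )
  expect_true(all(pr$composition$final_total == cfg$library_size))
})

test_that("the accounting identity holds on contaminated synthetic reads", {
  cfg <- atlas_config(seed = 31, n_tag_types = 150, library_size = 4000,
                      frac_bad = 0.01, frac_low_qf = 0.2, frac_ldt = 0.005,
                      frac_duplicate_ditags = 0.05)
  a <- generate_atlas(cfg)
  pr <- process_reads(generate_raw_ditags(a), cfg$linker_type1,
                      cfg$linker_type2)
  comp <- pr$composition
  expect_equal(comp$unfiltered_total,
               comp$final_total + comp$n_bad + comp$n_below_qf +
                 comp$n_ldt_type1 + comp$n_ldt_type2)
  # all LDT injections were removed
  expect_false(any(pr$counts$tag %in% c(cfg$linker_type1, cfg$linker_type2)))
})

test_that("bad-tag and QF filters commute on the observations they pass", {
  a <- generate_atlas(atlas_config(seed = 17, n_tag_types = 100,
                                   library_size = 1500, frac_bad = 0.02,
                                   frac_low_qf = 0.3))
  obs <- extract_tags(generate_raw_ditags(a))$observations
  ab <- quality_filter(filter_bad_tags(obs)$kept)$kept
  ba <- filter_bad_tags(quality_filter(obs)$kept)$kept
  expect_equal(ab |> arrange(read_id, slot), ba |> arrange(read_id, slot))
})

test_that("canonical tags derive from the 3'-most CATG site", {
  tx <- tibble::tibble(
    gene = c("GENE1", "GENE2"),
    sequence = c("AAACATGTTTTTTTTTTTTTTTTTG",
                 "CATGAAAACATGCCCCCCCCCCCCCCCCCTTT"))
  tm <- build_tag_map(tx)
  g1 <- tm$map[tm$map$gene %in% "GENE1", ]
  expect_equal(g1$tag, strrep("T", 17))  # 17 bases after final CATG
  g2 <- tm$map[tm$map$gene %in% "GENE2", ]
  expect_equal(g2$tag, "CCCCCCCCCCCCCCCCC")
  expect_true(all(c(g1$class, g2$class) == "unique_sense"))

  # a transcript without a CATG site contributes no tag
  tm2 <- build_tag_map(tibble::tibble(gene = "NOSITE",
                                      sequence = "AAAAAAAAAACCCCCCCCCCCCCCCCCCCC"))
  expect_true("NOSITE" %in% tm2$no_site_genes)
})

test_that("tag mapping classes follow the ambiguity rules", {
  shared <- "GGGGGGGGGGGGGGGGG"
  tx <- tibble::tibble(
    gene = c("GENEA", "GENEB"),
    sequence = paste0("CATG", shared, "AA"))
  tm <- build_tag_map(tx)
  expect_equal(tm$map$class[tm$map$tag == shared], "ambiguous")

  host <- tibble::tibble(gene = "MmGene",
                         sequence = "TTCATGACACACACACACACACAAA")
  tm2 <- build_tag_map(tibble::tibble(gene = "GENEC",
                                      sequence = "AACATGTGTGTGTGTGTGTGTGTGG"),
                       host_transcripts = host)
  host_tag <- "ACACACACACACACACA"
  expect_equal(tm2$map$class[tm2$map$tag == host_tag], "host")
})

test_that("the mapping funnel reproduces published-style marginal counts", {
  fm <- synthetic_funnel_map(n_tags = 193, n_ambiguous = 48, n_host = 10,
                             n_no_map = 7, n_genomic = 5,
                             n_multi_tag_genes = 9)
  cl <- classify_tag_mapping(fm$tags, fm$map)
  expect_equal(cl$funnel$n_relevant, 135)
  expect_equal(cl$funnel$n_candidate_genes, 114)
  expect_equal(cl$funnel$n_multi_tag_genes, 9)

  empty <- classify_tag_mapping(character(), fm$map)
  expect_true(all(unlist(empty$funnel) == 0))
})
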