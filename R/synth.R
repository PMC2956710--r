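## Synthetic LongSAGE atlas generator.
##
## Emulates a three-stage (androgen-sensitive -> responsive-to-androgen-
## deprivation -> castration-recurrent) progression experiment with three
## biological replicates: Poisson/multinomial tag counts around planted
## stage trends, ditag reads with Phred qualities, filter contaminants
## (N-base tags, low-QF tags, linker-derived ditags, duplicate ditags) and a
## tag-to-gene map with ambiguity classes. Every injection is ground-truthed
## so downstream stages can be validated end to end.

#' Stage-trend pattern table
#'
#' The five major expression-trend groups (1 up during progression, 2 down,
#' 3 peak at the middle stage, 4 constant, 5 valley at the middle stage) are
#' realised as eleven concrete patterns of relative stage weights; the
#' non-extreme weight of skewed patterns is `sqrt(effect_size)`.
#'
#' @param effect_size Fold change between the low and high stage of a
#'   non-constant pattern (> 1).
#' @param stages Character vector of three ordered stage labels.
#' @return Tibble with columns `group`, `pattern` and one weight column per
#'   stage.
#' @export
trend_patterns <- function(effect_size = 4, stages = c("AS", "RAD", "CR")) {
  stopifnot(length(stages) == 3, effect_size > 1)
  e <- effect_size
  s <- sqrt(e)
  pat <- tibble::tribble(
    ~group, ~pattern,        ~w1, ~w2, ~w3,
    1L,     "up_up",           1,   s,   e,
    1L,     "up_flat",         1,   e,   e,
    1L,     "flat_up",         1,   1,   e,
    2L,     "down_down",       e,   s,   1,
    2L,     "down_flat",       e,   1,   1,
    2L,     "flat_down",       e,   e,   1,
    3L,     "peak",            1,   e,   1,
    3L,     "peak_skewed",     1,   e,   s,
    4L,     "constant",        1,   1,   1,
    5L,     "valley",          e,   1,   e,
    5L,     "valley_skewed",   e,   1,   s
  )
  names(pat)[3:5] <- paste0("w_", stages)
  pat
}

#' Configuration for a synthetic LongSAGE atlas
#'
#' Defaults describe a realistic nine-library progression experiment:
#' contaminant fractions are in the range observed in deep LongSAGE
#' sequencing (a few per-mille N-base tags, ~20% of tags below the 0.95
#' quality factor, linker-derived ditags at a few per ten thousand), and the
#' trend mix leaves most tags constant with balanced up/down regulation so
#' that the fixed-total multinomial draw does not tilt constant tags.
#'
#' @param seed Integer seed controlling every random draw of the atlas.
#' @param n_replicates Number of biological replicates.
#' @param stages Ordered stage labels (length 3 for the trend taxonomy).
#' @param n_tag_types Number of distinct 17-base tag types to simulate.
#' @param library_size Tags per library (kept exact under the multinomial
#'   count model; must be even if ditag reads are generated).
#' @param trend_mix Proportions of tags in trend groups 1..5; must sum to 1.
#' @param effect_size Fold change of non-constant trends.
#' @param subpatterns If `TRUE` each group is spread over its concrete
#'   patterns (eleven in total); if `FALSE` only the canonical pattern of each
#'   group is used (five well-separated profiles).
#' @param count_model `"multinomial"` (totals exactly `library_size`) or
#'   `"poisson"` (independent Poisson counts with the same means).
#' @param abundance_sdlog Log-normal spread of baseline tag abundance.
#' @param replicate_sdlog Log-normal biological noise applied per
#'   (tag, replicate).
#' @param frac_bad Fraction of sequenced tags carrying an N base call.
#' @param frac_low_qf Fraction of sequenced tags with quality factor below
#'   0.95.
#' @param frac_ldt Fraction of ditags that are linker self-ligation artifacts.
#' @param frac_duplicate_ditags Fraction of ditags duplicated by PCR.
#' @param frac_ambiguous_map,frac_antisense,frac_nomap,frac_genomic,frac_host
#'   Mapping-class proportions for the simulated tag-to-gene map; the
#'   remainder maps uniquely sense to one gene.
#' @param frac_multi_tag Fraction of gene-mapped tags sharing their gene with
#'   a second tag (3'-most site ambiguity).
#' @param linker_type1,linker_type2 The two linker-derived 17-base sequences.
#' @return An `atlas_config` list, validated.
#' @export
atlas_config <- function(seed = 1L,
                         n_replicates = 3L,
                         stages = c("AS", "RAD", "CR"),
                         n_tag_types = 2000L,
                         library_size = 50000L,
                         trend_mix = c(0.10, 0.10, 0.05, 0.70, 0.05),
                         effect_size = 4,
                         subpatterns = TRUE,
                         count_model = c("multinomial", "poisson"),
                         abundance_sdlog = 1,
                         replicate_sdlog = 0.05,
                         frac_bad = 0.003,
                         frac_low_qf = 0.20,
                         frac_ldt = 6e-4,
                         frac_duplicate_ditags = 0.04,
                         frac_ambiguous_map = 0.05,
                         frac_antisense = 0.04,
                         frac_nomap = 0.04,
                         frac_genomic = 0.02,
                         frac_host = 0.01,
                         frac_multi_tag = 0.08,
                         linker_type1 = "TCCCCGTACATCAGTCA",
                         linker_type2 = "TCCCTATTAAGGCAGTC") {
  count_model <- match.arg(count_model)
  if (length(stages) < 2) stop("`stages` must have length >= 2", call. = FALSE)
  if (n_tag_types <= 0 || library_size <= 0) {
    stop("`n_tag_types` and `library_size` must be positive", call. = FALSE)
  }
  for (f in c("frac_bad", "frac_low_qf", "frac_ldt", "frac_duplicate_ditags",
              "frac_ambiguous_map", "frac_antisense", "frac_nomap",
              "frac_genomic", "frac_host", "frac_multi_tag")) {
    assert_fraction(get(f), f)
  }
  if (length(trend_mix) != 5 || any(trend_mix < 0) ||
      abs(sum(trend_mix) - 1) > 1e-8) {
    stop("`trend_mix` must be 5 nonnegative proportions summing to 1",
         call. = FALSE)
  }
  map_total <- frac_ambiguous_map + frac_antisense + frac_nomap +
    frac_genomic + frac_host
  if (map_total > 1) stop("mapping-class fractions exceed 1", call. = FALSE)
  if (effect_size <= 1) stop("`effect_size` must exceed 1", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
         stages = stages, n_tag_types = as.integer(n_tag_types),
         library_size = as.integer(library_size), trend_mix = trend_mix,
         effect_size = effect_size, subpatterns = subpatterns,
         count_model = count_model, abundance_sdlog = abundance_sdlog,
         replicate_sdlog = replicate_sdlog, frac_bad = frac_bad,
         frac_low_qf = frac_low_qf, frac_ldt = frac_ldt,
         frac_duplicate_ditags = frac_duplicate_ditags,
         frac_ambiguous_map = frac_ambiguous_map,
         frac_antisense = frac_antisense, frac_nomap = frac_nomap,
         frac_genomic = frac_genomic, frac_host = frac_host,
         frac_multi_tag = frac_multi_tag,
         linker_type1 = linker_type1, linker_type2 = linker_type2),
    class = "atlas_config"
  )
}

#' Generate a ground-truthed synthetic LongSAGE atlas
#'
#' Draws per-library tag counts around planted stage trends. Baseline
#' abundances are log-normal; each tag's stage means follow its planted
#' pattern scaled by `effect_size`, with mild per-replicate log-normal
#' biological noise. Under the default multinomial model each library's
#' total is exactly `library_size`.
#'
#' @param config An [atlas_config()].
#' @return A `sage_atlas` list with elements `libraries` (tibble:
#'   `library_id`, `replicate`, `stage`, `tag`, `count`), `truth_trends`
#'   (tibble: `tag`, `group`, `pattern` and normalised stage weights),
#'   `tag_map` (tibble: `tag`, `gene`, `class`), `annotations` (tibble:
#'   `gene`, `term`) and `config`.
#' @examples
#' atlas <- generate_atlas(atlas_config(seed = 7, n_tag_types = 200,
#'                                      library_size = 5000))
#' head(atlas$libraries)
#' @export
generate_atlas <- function(config = atlas_config()) {
  if (!inherits(config, "atlas_config")) {
    stop("`config` must come from atlas_config()", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_tag_types
  stages <- config$stages

  tags <- random_tags(n)
  # keep linker sequences out of the transcript tag space
  tags[tags %in% c(config$linker_type1, config$linker_type2)] <- random_tags(1)

  groups <- sample(1:5, n, replace = TRUE, prob = config$trend_mix)
  pat <- trend_patterns(config$effect_size, stages)
  pattern <- character(n)
  for (g in 1:5) {
    pool <- pat$pattern[pat$group == g]
    if (!config$subpatterns) pool <- pool[1]
    idx <- which(groups == g)
    pattern[idx] <- sample(pool, length(idx), replace = TRUE)
  }
  w <- as.matrix(pat[match(pattern, pat$pattern), paste0("w_", stages)])
  rownames(w) <- tags

  base <- rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
  rep_ids <- paste0("R", seq_len(config$n_replicates))
  jitter <- matrix(rlnorm(n * config$n_replicates, 0, config$replicate_sdlog),
                   nrow = n)

  libs <- purrr::map_dfr(seq_along(rep_ids), function(r) {
    purrr::map_dfr(seq_along(stages), function(s) {
      lam <- base * jitter[, r] * w[, s]
      prob <- lam / sum(lam)
      cnt <- if (config$count_model == "multinomial") {
        as.integer(rmultinom(1, config$library_size, prob))
      } else {
        as.integer(rpois(n, config$library_size * prob))
      }
      tibble(library_id = paste0(rep_ids[r], "_", stages[s]),
             replicate = rep_ids[r], stage = stages[s],
             tag = tags, count = cnt) |>
        filter(.data$count > 0)
    })
  })

  truth <- tibble(tag = tags, group = as.integer(groups), pattern = pattern)
  wn <- sweep(w, 1, rowSums(w), "/")
  colnames(wn) <- paste0("w_", stages)
  truth <- dplyr::bind_cols(truth, as_tibble(wn))

  tag_map <- simulate_tag_map(tags, config)
  annotations <- simulate_annotations(tag_map, truth)

  structure(list(config = config, libraries = libs, truth_trends = truth,
                 tag_map = tag_map, annotations = annotations),
            class = "sage_atlas")
}

## mapping classes with configured proportions; the remainder is unique_sense
simulate_tag_map <- function(tags, config) {
  n <- length(tags)
  probs <- c(ambiguous = config$frac_ambiguous_map,
             antisense = config$frac_antisense,
             no_map = config$frac_nomap,
             genomic_only = config$frac_genomic,
             host = config$frac_host)
  probs <- c(probs, unique_sense = 1 - sum(probs))
  class <- sample(names(probs), n, replace = TRUE, prob = probs)

  gene <- rep(NA_character_, n)
  mapped <- class %in% c("unique_sense", "antisense")
  idx <- which(mapped)
  n_multi <- floor(length(idx) * config$frac_multi_tag / 2)
  gene_ids <- sprintf("G%05d", seq_len(length(idx) - n_multi))
  assign <- c(gene_ids,
              if (n_multi > 0) sample(gene_ids, n_multi))  # second tag on a gene
  gene[idx] <- sample(assign)
  gene[class == "host"] <- sprintf("MMU_G%05d", seq_len(sum(class == "host")))
  tibble(tag = tags, gene = gene, class = class)
}

## gene -> term table with one planted term per trend group plus background
simulate_annotations <- function(tag_map, truth, p_in = 0.6, p_out = 0.05,
                                 n_background = 20) {
  genes <- tag_map |>
    filter(.data$class == "unique_sense", !is.na(.data$gene)) |>
    left_join(truth[, c("tag", "group")], by = "tag") |>
    group_by(.data$gene) |>
    summarise(group = .data$group[1], .groups = "drop")
  bg_terms <- sprintf("BG%02d", seq_len(n_background))
  ann <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    terms <- bg_terms[runif(n_background) < 0.08]
    for (g in 1:5) {
      p <- if (genes$group[i] == g) p_in else p_out
      if (runif(1) < p) terms <- c(terms, sprintf("TREND%d", g))
    }
    if (!length(terms)) return(NULL)
    tibble(gene = genes$gene[i], term = terms)
  })
  ann
}

#' Generate raw ditag reads with per-base qualities from an atlas
#'
#' Pairs each library's tag occurrences into ditags
#' `CATG + tag1 + revcomp(tag2) + CATG` (42 bp), assigns Sanger-scale Phred
#' qualities, and injects the configured contaminants: N-base ("bad") tags,
#' low-quality-factor tags, linker-derived ditags (types I and II) and
#' duplicate ditags. Every injection is recorded in the returned ground
#' truth.
#'
#' @param atlas A `sage_atlas`.
#' @param base_error_rate Per-base substitution rate applied to tag bases
#'   (default 0, i.e. error-free apart from the explicit injections).
#' @param q_good,q_low Integer Phred ranges for ordinary and
#'   low-quality-factor tags. The defaults give QF above / below the 0.95
#'   threshold respectively.
#' @param seed Seed (defaults to the atlas seed offset by one).
#' @return A `sage_reads` list: `reads` (tibble: `read_id`, `library_id`,
#'   `sequence`, `quality` in Phred+33) and `truth` (tibbles `bad`, `low_qf`,
#'   `ldt`, `duplicates`, `dropped`).
#' @export
generate_raw_ditags <- function(atlas, base_error_rate = 0,
                                q_good = 35:40, q_low = 12:22,
                                seed = NULL) {
  stopifnot(inherits(atlas, "sage_atlas"))
  if (base_error_rate < 0) stop("`base_error_rate` must be >= 0", call. = FALSE)
  cfg <- atlas$config
  if (is.null(seed)) seed <- derive_seed(cfg$seed, 1L)
  set.seed(seed)

  out_reads <- vector("list", 0)
  truth <- list(bad = list(), low_qf = list(), ldt = list(),
                duplicates = list(), dropped = list())

  for (lib in unique(atlas$libraries$library_id)) {
    tab <- atlas$libraries[atlas$libraries$library_id == lib, ]
    pool <- rep(tab$tag, tab$count)
    pool <- sample(pool)
    if (length(pool) %% 2 == 1) {
      truth$dropped[[lib]] <- tibble(library_id = lib, tag = pool[length(pool)])
      pool <- pool[-length(pool)]
    }
    n_ditag <- length(pool) / 2
    t1 <- pool[seq(1, length(pool), by = 2)]
    t2 <- pool[seq(2, length(pool), by = 2)]

    # per-slot contaminant assignment (disjoint: bad wins over low-QF)
    n_slot <- 2L * n_ditag
    u <- runif(n_slot)
    bad_slot <- u < cfg$frac_bad
    low_slot <- !bad_slot & u < cfg$frac_bad + cfg$frac_low_qf

    tagmat <- cbind(t1, t2)
    if (base_error_rate > 0) {
      hit <- which(runif(n_slot) < 1 - (1 - base_error_rate)^17)
      for (i in hit) {
        s <- strsplit(tagmat[i], "")[[1]]
        j <- sample.int(17, 1)
        s[j] <- sample(setdiff(DNA_BASES, s[j]), 1)
        tagmat[i] <- paste0(s, collapse = "")
      }
    }
    qual <- matrix(sample(q_good, 17L * n_slot, replace = TRUE),
                   ncol = 17L, byrow = TRUE)
    if (any(low_slot)) {
      qual[low_slot, ] <- sample(q_low, 17L * sum(low_slot), replace = TRUE)
    }
    if (any(bad_slot)) {
      for (i in which(bad_slot)) {
        s <- strsplit(tagmat[i], "")[[1]]
        j <- sample.int(17, 1)
        s[j] <- "N"
        tagmat[i] <- paste0(s, collapse = "")
        qual[i, j] <- 2L
      }
    }
    t1 <- tagmat[seq_len(n_ditag)]
    t2 <- tagmat[n_ditag + seq_len(n_ditag)]
    q1 <- qual[seq_len(n_ditag), , drop = FALSE]
    q2 <- qual[n_ditag + seq_len(n_ditag), , drop = FALSE]
    ids <- sprintf("%s_d%06d", lib, seq_len(n_ditag))

    # linker-derived ditags: self-ligated linkers of type I or II
    n_ldt <- stats::rbinom(1, n_ditag, cfg$frac_ldt)
    if (n_ldt > 0) {
      type <- sample(1:2, n_ldt, replace = TRUE)
      lseq <- ifelse(type == 1, cfg$linker_type1, cfg$linker_type2)
      t1 <- c(t1, lseq); t2 <- c(t2, lseq)
      q1 <- rbind(q1, matrix(sample(q_good, 17L * n_ldt, replace = TRUE),
                             ncol = 17L))
      q2 <- rbind(q2, matrix(sample(q_good, 17L * n_ldt, replace = TRUE),
                             ncol = 17L))
      ldt_ids <- sprintf("%s_ldt%04d", lib, seq_len(n_ldt))
      ids <- c(ids, ldt_ids)
      truth$ldt[[lib]] <- tibble(library_id = lib, read_id = ldt_ids,
                                 type = as.integer(type))
    }

    # PCR duplicates: exact copies of existing ditags
    n_all <- length(ids)
    n_dup <- stats::rbinom(1, n_ditag, cfg$frac_duplicate_ditags)
    if (n_dup > 0) {
      src <- sample.int(n_all, n_dup, replace = TRUE)
      dup_ids <- sprintf("%s_dup%05d", lib, seq_len(n_dup))
      truth$duplicates[[lib]] <- tibble(library_id = lib, read_id = dup_ids,
                                        source_read_id = ids[src])
      t1 <- c(t1, t1[src]); t2 <- c(t2, t2[src])
      q1 <- rbind(q1, q1[src, , drop = FALSE])
      q2 <- rbind(q2, q2[src, , drop = FALSE])
      ids <- c(ids, dup_ids)
    }

    seqs <- paste0("CATG", t1, revcomp(t2), "CATG")
    anchor_q <- function(m) matrix(sample(q_good, 4L * m, replace = TRUE),
                                   ncol = 4L)
    m <- length(ids)
    qmat <- cbind(anchor_q(m), q1,
                  t(apply(q2, 1, rev)), anchor_q(m))
    quals <- apply(qmat, 1, function(q) phred_to_char(list(q)))

    slot_truth <- tibble(
      library_id = lib,
      read_id = sprintf("%s_d%06d", lib, rep(seq_len(n_ditag), 2)),
      slot = rep(1:2, each = n_ditag)
    )
    if (any(bad_slot)) {
      truth$bad[[lib]] <- slot_truth[which(bad_slot), ] |>
        mutate(tag = tagmat[which(bad_slot)])
    }
    if (any(low_slot)) {
      truth$low_qf[[lib]] <- slot_truth[which(low_slot), ] |>
        mutate(tag = tagmat[which(low_slot)])
    }
    out_reads[[lib]] <- tibble(read_id = ids, library_id = lib,
                               sequence = seqs, quality = quals)
  }

  structure(
    list(reads = bind_rows(out_reads),
         truth = purrr::map(truth, bind_rows)),
    class = "sage_reads"
  )
}

#' Synthetic tag map matching a published funnel composition
#'
#' Builds a tag map (and the tag list) whose marginal class counts match a
#' mapping funnel reported for a set of differentially expressed tags:
#' `n_ambiguous` ambiguously mapped tags, `n_host` host-species tags,
#' `n_no_map` unmapped and `n_genomic` unannotated-genomic tags, with the
#' remaining tags mapped to genes of which `n_multi_tag_genes` carry two
#' tags each. Gene names are drawn from `gene_names` first (so a known-gene
#' list can be represented), then padded with synthetic ids. Per-tag
#' identities are synthetic; only the marginal counts are meaningful.
#'
#' @param n_tags Total tag types entering the funnel.
#' @param n_ambiguous,n_host,n_no_map,n_genomic Class counts.
#' @param n_multi_tag_genes Genes represented by two tags each.
#' @param gene_names Optional character vector of gene names to use first.
#' @param seed Seed for the synthetic tag sequences.
#' @return List with `tags` (character) and `map` (tibble `tag`, `gene`,
#'   `class`).
#' @export
synthetic_funnel_map <- function(n_tags, n_ambiguous, n_host, n_no_map,
                                 n_genomic, n_multi_tag_genes,
                                 gene_names = character(), seed = 1L) {
  set.seed(as.integer(seed))
  n_gene_tags <- n_tags - n_ambiguous - n_host - n_no_map - n_genomic
  n_genes <- n_gene_tags - n_multi_tag_genes
  stopifnot(n_gene_tags >= 0, n_genes >= n_multi_tag_genes,
            length(gene_names) <= n_genes)
  genes <- c(gene_names,
             sprintf("SYNGENE%04d", seq_len(n_genes - length(gene_names))))
  gene_col <- c(genes, genes[seq_len(n_multi_tag_genes)])
  tags <- random_tags(n_tags)
  class <- c(rep("ambiguous", n_ambiguous), rep("host", n_host),
             rep("no_map", n_no_map), rep("genomic_only", n_genomic),
             rep("unique_sense", n_gene_tags))
  gene <- c(rep(NA_character_, n_ambiguous + n_host + n_no_map + n_genomic),
            gene_col)
  list(tags = tags, map = tibble(tag = tags, gene = gene, class = class))
}

#' Simulate a gene-expression matrix with planted group separation
#'
#' Stand-in for a clinical microarray compendium: genes x samples Gaussian
#' noise, with a random subset of "signature" genes shifted between sample
#' groups by `separation` standard deviations.
#'
#' @param n_genes Number of genes (>= 2).
#' @param groups Named integer vector of per-group sample counts (>= 2
#'   groups whenever `separation > 0`).
#' @param separation Between-group mean distance for signature genes, in SD
#'   units; 0 plants no structure.
#' @param seed Integer seed.
#' @param frac_signature Fraction of genes carrying the group shift.
#' @param sd Residual standard deviation.
#' @return List with `matrix` (genes x samples), `groups` (factor per
#'   sample) and `signature_genes`.
#' @export
generate_signature_matrix <- function(n_genes, groups, separation, seed = 1L,
                                      frac_signature = 0.3, sd = 1) {
  if (n_genes < 2) stop("`n_genes` must be >= 2", call. = FALSE)
  if (separation < 0) stop("`separation` must be >= 0", call. = FALSE)
  k <- length(groups)
  if (k < 2 && separation > 0) {
    stop("a single group cannot carry a nonzero separation", call. = FALSE)
  }
  set.seed(as.integer(seed))
  if (is.null(names(groups))) names(groups) <- paste0("grp", seq_len(k))
  samples <- rep(names(groups), groups)
  n_s <- length(samples)
  m <- matrix(rnorm(n_genes * n_s, sd = sd), nrow = n_genes,
              dimnames = list(sprintf("G%05d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_s))))
  sig <- sort(sample.int(n_genes, max(2, round(frac_signature * n_genes))))
  if (separation > 0) {
    offsets <- separation * sd * ((seq_len(k) - 1) / (k - 1) - 0.5)
    sign <- sample(c(-1, 1), length(sig), replace = TRUE)
    for (g in seq_len(k)) {
      cols <- which(samples == names(groups)[g])
      m[sig, cols] <- m[sig, cols] + sign * offsets[g]
    }
  }
  list(matrix = m, groups = factor(samples, levels = names(groups)),
       signature_genes = rownames(m)[sig])
}
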