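## Exact count-based differential expression between SAGE libraries.
##
## The Audic-Claverie test conditions on the count x observed in the first
## library and evaluates the second count y against its conditional
## distribution P(k | x) = (N2/N1)^k (x+k)! / (x! k! (1 + N2/N1)^(x+k+1)),
## i.e. a negative binomial with size x+1 and success probability
## N1/(N1+N2). All terms are accumulated in log space via log-gamma.

ac_logpmf <- function(k, x, log_r, log1p_r) {
  k * log_r + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1p_r
}

logsumexp <- function(lp) {
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

## two-sided p conditioning on x, minimum-likelihood convention: sum of
## P(k | x) over every k whose conditional probability does not exceed
## P(y | x). P(k | x) is unimodal in k, so the acceptance region is the two
## tails {k <= k_lo} and {k >= k_hi} around the conditional mode; both are
## summed directly in log space (never as 1 - other tail, which would lose
## deep tails to cancellation). At the mode the p-value is 1, so equal
## evidence (e.g. x = y = 0) is never called significant for any library
## sizes.
ac_cond_pvalue <- function(x, y, n1, n2) {
  r <- n2 / n1
  log_r <- log(r)
  log1p_r <- log1p(r)
  lp <- function(k) ac_logpmf(k, x, log_r, log1p_r)
  mode <- floor(x * r)  # pmf(k)/pmf(k-1) = r (x + k) / (k (1 + r)) >= 1
  while (lp(mode + 1) > lp(mode)) mode <- mode + 1
  target <- lp(y) + 1e-9

  # k_lo: largest k <= mode with lp(k) <= target (lp increasing there)
  k_lo <- -1L
  if (lp(0) <= target) {
    lo <- 0; hi <- mode
    while (lo < hi) {
      mid <- ceiling((lo + hi) / 2)
      if (lp(mid) <= target) lo <- mid else hi <- mid - 1
    }
    k_lo <- lo
  }
  # k_hi: smallest k >= mode with lp(k) <= target (lp decreasing there)
  lo <- mode; hi <- mode + 1
  while (lp(hi) > target) {
    lo <- hi
    hi <- 2 * hi - mode + 1
  }
  while (lo < hi) {
    mid <- floor((lo + hi) / 2)
    if (lp(mid) <= target) hi <- mid else lo <- mid + 1
  }
  k_hi <- hi

  p <- 0
  if (k_lo >= 0) p <- p + exp(logsumexp(lp(0:k_lo)))
  # upper tail from k_hi in chunks until the remaining terms are negligible
  acc <- lp(k_hi)
  from <- k_hi + 1
  repeat {
    ks <- from:(from + 255L)
    lpk <- lp(ks)
    acc <- logsumexp(c(acc, lpk))
    if (max(lpk) - acc < log(1e-18) || from > k_hi + 1e6) break
    from <- from + 256L
  }
  min(1, p + exp(acc))
}

## symmetrised: the choice of conditioning library is arbitrary, so the
## reported p averages the two conditionings, making
## p(x, y, N1, N2) = p(y, x, N2, N1) exactly
ac_pvalue_one <- function(x, y, n1, n2) {
  (ac_cond_pvalue(x, y, n1, n2) + ac_cond_pvalue(y, x, n2, n1)) / 2
}

#' Audic-Claverie exact two-sided p-value
#'
#' Tests whether a tag's counts `x` and `y` in two libraries of sizes `n1`
#' and `n2` are compatible with equal concentration. Conditioning on the
#' first count, the two-sided p-value follows the minimum-likelihood
#' convention: the sum of `P(k | x)` over every outcome no more probable
#' than the observed `y` (so the conditional mode scores 1, and equal
#' evidence such as `x = y = 0` is never significant for any sizes).
#' Because the choice of conditioning library is arbitrary, the reported p
#' averages the two directions, which makes the test exactly
#' exchange-symmetric: `p(x, y, n1, n2) = p(y, x, n2, n1)`.
#'
#' @param x,y Nonnegative integer counts in libraries 1 and 2 (vectorised).
#' @param n1,n2 Positive library sizes (totals after filtering).
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' ac_pvalue(0, 12, 250000, 250000)
#' @export
ac_pvalue <- function(x, y, n1, n2) {
  k <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(as.numeric(x), k); y <- rep_len(as.numeric(y), k)
  n1 <- rep_len(as.numeric(n1), k); n2 <- rep_len(as.numeric(n2), k)
  if (any(n1 <= 0) || any(n2 <= 0)) {
    stop("library sizes must be positive", call. = FALSE)
  }
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0", call. = FALSE)
  vapply(seq_len(k), function(i) ac_pvalue_one(x[i], y[i], n1[i], n2[i]),
         numeric(1))
}

#' Pairwise differential expression between two libraries
#'
#' Every tag present in either library is tested with the Audic-Claverie
#' statistic on raw counts (absent tags count 0) using the libraries' final
#' filtered totals; direction is the sign of the counts-per-million
#' difference (second minus first library).
#'
#' @param lib_a,lib_b Tag-count tibbles (`library_id`, `tag`, `count`) for a
#'   single library each.
#' @param n1,n2 Optional library sizes; default is each table's count sum.
#' @return Tibble `tag`, `x`, `y`, `n1`, `n2`, `cpm_a`, `cpm_b`, `direction`
#'   (`"up"`, `"down"`, `"none"`), `p`.
#' @export
pairwise_de <- function(lib_a, lib_b, n1 = NULL, n2 = NULL) {
  ida <- unique(lib_a$library_id); idb <- unique(lib_b$library_id)
  stopifnot(length(ida) == 1, length(idb) == 1)
  if (identical(ida, idb)) {
    stop("cannot compare a library with itself", call. = FALSE)
  }
  n1 <- n1 %||% sum(lib_a$count)
  n2 <- n2 %||% sum(lib_b$count)
  joined <- full_join(
    lib_a |> select(tag = "tag", x = "count"),
    lib_b |> select(tag = "tag", y = "count"),
    by = "tag"
  ) |>
    mutate(x = dplyr::coalesce(.data$x, 0L),
           y = dplyr::coalesce(.data$y, 0L),
           n1 = n1, n2 = n2,
           cpm_a = 1e6 * .data$x / n1,
           cpm_b = 1e6 * .data$y / n2,
           direction = dplyr::case_when(
             .data$cpm_b > .data$cpm_a ~ "up",
             .data$cpm_b < .data$cpm_a ~ "down",
             TRUE ~ "none"
           ))
  joined$p <- ac_pvalue(joined$x, joined$y, n1, n2)
  joined
}

#' Differential expression for all stage pairs in every replicate
#'
#' @param libraries Atlas-style count tibble (`library_id`, `replicate`,
#'   `stage`, `tag`, `count`).
#' @param stage_pairs List of 2-vectors of stage labels; default consecutive
#'   pairs plus first-vs-last for three stages.
#' @return Tibble of [pairwise_de()] results with `comparison` (e.g.
#'   `"AS_vs_RAD"`) and `replicate` columns.
#' @export
stagewise_de <- function(libraries, stage_pairs = NULL) {
  stages <- unique(libraries$stage)
  if (is.null(stage_pairs)) {
    stage_pairs <- utils::combn(stages, 2, simplify = FALSE)
  }
  purrr::map_dfr(unique(libraries$replicate), function(r) {
    purrr::map_dfr(stage_pairs, function(pr) {
      a <- libraries |> filter(.data$replicate == r, .data$stage == pr[1])
      b <- libraries |> filter(.data$replicate == r, .data$stage == pr[2])
      pairwise_de(a |> select("library_id", "tag", "count"),
                  b |> select("library_id", "tag", "count")) |>
        mutate(comparison = paste0(pr[1], "_vs_", pr[2]), replicate = r)
    })
  })
}

#' Cross-replicate consistent differential expression
#'
#' A tag counts as consistently up (down) in a comparison at level `alpha`
#' iff it is significant at `alpha` with the same non-tied direction in
#' every replicate. Tags absent from a replicate's result table are treated
#' as not significant there.
#'
#' @param de Tibble from [stagewise_de()] (columns `comparison`,
#'   `replicate`, `tag`, `direction`, `p`).
#' @param alphas Significance thresholds (default 0.05, 0.01, 0.001).
#' @param replicates Optional expected replicate ids; an expected replicate
#'   missing from `de` is an error naming it.
#' @return List with `summary` (tibble `comparison`, `direction`, `alpha`,
#'   `n_tags`) and `detail` (per tag/comparison/alpha consistent calls).
#' @export
consistent_de <- function(de, alphas = c(0.05, 0.01, 0.001),
                          replicates = NULL) {
  reps <- unique(de$replicate)
  if (!is.null(replicates)) {
    miss <- setdiff(replicates, reps)
    if (length(miss)) {
      stop("missing replicate: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    reps <- replicates
  }
  n_rep <- length(reps)
  detail <- purrr::map_dfr(alphas, function(a) {
    de |>
      filter(.data$p <= a, .data$direction != "none",
             .data$replicate %in% reps) |>
      group_by(.data$comparison, .data$tag, .data$direction) |>
      summarise(n_rep_sig = dplyr::n_distinct(.data$replicate),
                .groups = "drop") |>
      filter(.data$n_rep_sig == n_rep) |>
      mutate(alpha = a)
  })
  cells <- tidyr::expand_grid(comparison = unique(de$comparison),
                              direction = c("up", "down"), alpha = alphas)
  summary <- cells |>
    left_join(count(detail, .data$comparison, .data$direction, .data$alpha,
                    name = "n_tags"),
              by = c("comparison", "direction", "alpha")) |>
    mutate(n_tags = dplyr::coalesce(.data$n_tags, 0L))
  list(summary = summary, detail = detail, n_replicates = n_rep)
}

#' Default trend-label rule table
#'
#' Trend labels are assigned from the signed significance pattern of the two
#' progression steps (stage1 -> stage2, stage2 -> stage3), refined by the
#' net stage1 -> stage3 change; rows are matched first to last and `"any"`
#' is a wildcard. Major groups follow the five-trend taxonomy: 1 up during
#' progression, 2 down, 3 peak at the middle stage, 4 constant, 5 valley at
#' the middle stage.
#'
#' @return Tibble with columns `step1`, `step2`, `net`, `label`, `group`.
#' @export
trend_rules <- function() {
  tibble::tribble(
    ~step1, ~step2, ~net,   ~label, ~group,
    "up",   "up",   "any",  "A",    1L,
    "up",   "flat", "up",   "B",    1L,
    "up",   "flat", "any",  "C",    4L,
    "flat", "up",   "up",   "D",    1L,
    "flat", "up",   "any",  "E",    4L,
    "up",   "down", "any",  "F",    3L,
    "down", "up",   "any",  "G",    5L,
    "down", "down", "any",  "H",    2L,
    "down", "flat", "down", "I",    2L,
    "down", "flat", "any",  "J",    4L,
    "flat", "down", "down", "K",    2L,
    "flat", "down", "any",  "L",    4L,
    "flat", "flat", "any",  "M",    4L
  )
}

step_call <- function(cpm_from, cpm_to, p, alpha) {
  dplyr::case_when(
    p <= alpha & cpm_to > cpm_from ~ "up",
    p <= alpha & cpm_to < cpm_from ~ "down",
    TRUE ~ "flat"
  )
}

#' Classify three-stage expression trends
#'
#' Assigns each (tag, replicate) profile a letter label and a major trend
#' group from the signed significance pattern of the two consecutive stage
#' steps and the net first-to-last change, using a configurable rule table.
#'
#' @param profiles Tibble with columns `tag`, `replicate`, `cpm_1`, `cpm_2`,
#'   `cpm_3` (ordered stages), `p_step1` (stage1 vs 2), `p_step2`
#'   (stage2 vs 3) and optionally `p_net` (stage1 vs 3; defaults to 1,
#'   i.e. flat).
#' @param alpha Step significance threshold (default 0.05).
#' @param rules Rule table as from [trend_rules()].
#' @return Input with `step1`, `step2`, `net`, `label`, `group` columns.
#' @export
classify_trend <- function(profiles, alpha = 0.05, rules = trend_rules()) {
  need <- c("cpm_1", "cpm_2", "cpm_3", "p_step1", "p_step2")
  if (!all(need %in% names(profiles))) {
    stop("profiles need three cpm stages and two step p-values",
         call. = FALSE)
  }
  if (!"p_net" %in% names(profiles)) profiles$p_net <- 1
  out <- profiles |>
    mutate(step1 = step_call(.data$cpm_1, .data$cpm_2, .data$p_step1, alpha),
           step2 = step_call(.data$cpm_2, .data$cpm_3, .data$p_step2, alpha),
           net = step_call(.data$cpm_1, .data$cpm_3, .data$p_net, alpha))
  match_rule <- function(s1, s2, nt) {
    hit <- which((rules$step1 == s1 | rules$step1 == "any") &
                   (rules$step2 == s2 | rules$step2 == "any") &
                   (rules$net == nt | rules$net == "any"))[1]
    if (is.na(hit)) hit <- nrow(rules)
    hit
  }
  idx <- vapply(seq_len(nrow(out)), function(i) {
    match_rule(out$step1[i], out$step2[i], out$net[i])
  }, integer(1))
  out$label <- rules$label[idx]
  out$group <- rules$group[idx]
  out
}

#' Candidate-gene funnel with novelty against a known-gene list
#'
#' Applies [classify_tag_mapping()] to a set of consistently differentially
#' expressed tags and reports how many map non-ambiguously to the target
#' species ("relevant"), how many distinct candidate genes they represent,
#' and how many candidates are absent from a user-supplied list of genes
#' already associated with the phenotype.
#'
#' @param tags Character vector of tag sequences.
#' @param map Tag map (tibble or [build_tag_map()] output).
#' @param known_genes Character vector of known phenotype-associated genes.
#' @return One-row tibble: the [classify_tag_mapping()] funnel plus
#'   `n_known` and `n_novel`, with attribute `"candidate_genes"`.
#' @export
candidate_gene_summary <- function(tags, map, known_genes = character()) {
  cl <- classify_tag_mapping(tags, map)
  genes <- cl$classes |>
    filter(!.data$class %in% c("ambiguous", "host"), !is.na(.data$gene)) |>
    pull("gene") |>
    unique()
  out <- cl$funnel |>
    mutate(n_known = sum(genes %in% known_genes),
           n_novel = sum(!genes %in% known_genes))
  attr(out, "candidate_genes") <- genes
  out
}
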