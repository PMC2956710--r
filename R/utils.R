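#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join full_join anti_join bind_rows n n_distinct distinct
#'   count rename pull across if_else row_number
#' @importFrom stats cor dnbinom phyper pnbinom rlnorm rmultinom rnorm rpois
#'   runif sd setNames kmeans dist
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over the alphabet `{A,C,G,T,N}`.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("CATG")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

## Phred (Sanger, +33) helpers ------------------------------------------------

phred_to_char <- function(q) {
  vapply(q, function(qs) rawToChar(as.raw(qs + 33L)), character(1))
}

char_to_phred <- function(s) {
  lapply(s, function(x) as.integer(charToRaw(x)) - 33L)
}

#' Tag quality factor from per-base Phred scores
#'
#' The quality factor (QF) of a tag is the probability that every base of the
#' tag was called correctly, `prod(1 - 10^(-Q/10))` over its per-base Phred
#' scores.
#'
#' @param q Integer vector of Phred scores, or a list of such vectors.
#' @return Numeric QF in `[0, 1]` (one value per vector).
#' @examples
#' quality_factor(rep(40L, 17)) # ~0.9983
#' @export
quality_factor <- function(q) {
  if (!is.list(q)) q <- list(q)
  vapply(q, function(qs) prod(1 - 10^(-qs / 10)), numeric(1))
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index, used to score recovery of planted
#' cluster structure. 1 means identical partitions, 0 is the chance level.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}

## seed handling: derive independent sub-seeds below 2^31 from a base seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% .Machine$integer.max
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

random_tags <- function(n, width = 17L) {
  draw <- function(m) {
    mat <- matrix(sample(DNA_BASES, m * width, replace = TRUE), nrow = m)
    apply(mat, 1, paste0, collapse = "")
  }
  tags <- unique(draw(n))
  while (length(tags) < n) {
    tags <- unique(c(tags, draw(n - length(tags))))
  }
  tags[seq_len(n)]
}
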