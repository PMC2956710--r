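suppressMessages(library(dplyr))

# small clean atlas shared across tests (memoised per session)
small_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_atlas(atlas_config(
        seed = 42, n_tag_types = 300, library_size = 6000))
    }
    cache
  }
})

# a clean (contaminant-free) tiny atlas + reads for round-trip checks
clean_config <- function(seed = 11, n_tag_types = 150, library_size = 3000) {
  atlas_config(seed = seed, n_tag_types = n_tag_types,
               library_size = library_size,
               frac_bad = 0, frac_low_qf = 0, frac_ldt = 0,
               frac_duplicate_ditags = 0)
}

# independent negative-binomial route for the Audic-Claverie p-value:
# P(y | x) is NB(size = x + 1, prob = N1 / (N1 + N2)); the reported p is
# the average of the two conditioning directions (exchange-symmetric)
ac_cond_oracle <- function(x, y, n1, n2) {
  pr <- n1 / (n1 + n2)
  size <- x + 1
  target <- dnbinom(y, size, pr) * (1 + 1e-9)
  mode <- which.max(dnbinom(0:(10 * (x + 1) / pr), size, pr)) - 1L
  k_low <- 0:mode
  low_ok <- k_low[dnbinom(k_low, size, pr) <= target]
  p_low <- if (length(low_ok)) pnbinom(max(low_ok), size, pr) else 0
  k <- mode
  while (dnbinom(k, size, pr) > target) k <- k + 1L
  p_high <- pnbinom(k - 1, size, pr, lower.tail = FALSE)
  min(1, p_low + p_high)
}
ac_oracle <- function(x, y, n1, n2) {
  (ac_cond_oracle(x, y, n1, n2) + ac_cond_oracle(y, x, n2, n1)) / 2
}

# straight transcription of the Poisson-deviance definition
deviance_oracle <- function(x, centroid) {
  lam <- sum(x) * centroid
  s <- 0
  for (j in seq_along(x)) {
    s <- s + lam[j] - x[j] + if (x[j] > 0) x[j] * log(x[j] / lam[j]) else 0
  }
  s
}

# exact hypergeometric upper tail by enumeration with choose()
fisher_enum <- function(a, b, c, d) {
  K <- a + c; N <- a + b + c + d; n <- a + b
  ks <- max(0, n - (N - K)):min(K, n)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pmf[ks >= a])
}

# counts for two planted profile groups with high depth
planted_two_groups <- function(n_per = 100, total = 100, seed = 5) {
  set.seed(seed)
  w <- rbind(c(0.9, 0.05, 0.05), c(0.05, 0.05, 0.9))
  x <- rbind(
    t(rmultinom(n_per, total, w[1, ])),
    t(rmultinom(n_per, total, w[2, ]))
  )
  rownames(x) <- sprintf("t%03d", seq_len(2 * n_per))
  colnames(x) <- c("count_AS", "count_RAD", "count_CR")
  list(x = x, truth = rep(1:2, each = n_per))
}
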