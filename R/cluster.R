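## Poisson-deviance K-means ("PoissonC"-style) clustering of three-stage
## expression trends, K selection by within-cluster dispersion, random-restart
## consensus assignment, amalgamation into the five major trend groups, and
## Pearson 1-r library trees.
##
## A tag's profile is its raw count triple across the three stage libraries
## of one replicate; a centroid is a probability profile over stages. The
## distance is the Poisson deviance of the counts against stage means
## lambda_j = sum(x) * c_j, which is minimised (over c) by the
## maximum-likelihood centroid c_j proportional to the summed member counts.

CENTROID_FLOOR <- 1e-9

profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  stopifnot(is.data.frame(profiles))
  cols <- grep("^count_", names(profiles), value = TRUE)
  if (!length(cols)) {
    cols <- names(profiles)[vapply(profiles, is.numeric, logical(1))]
    cols <- setdiff(cols, c("sum", "total"))
    cols <- cols[!grepl("^pct_", cols)]
  }
  m <- as.matrix(profiles[, cols])
  if ("tag" %in% names(profiles)) rownames(m) <- profiles$tag
  m
}

floor_centroid <- function(c) {
  c <- pmax(c, CENTROID_FLOOR)
  c / sum(c)
}

#' Select tags for trend clustering
#'
#' Keeps tags whose summed raw count over the three stage libraries of one
#' replicate exceeds 10 and which map uniquely sense to a transcript, and
#' attaches the relative profile (per-stage percentage of the tag's summed
#' count).
#'
#' @param libraries Count tibble for one replicate (`library_id`, `stage`,
#'   `tag`, `count`).
#' @param map Tag map (`tag`, `gene`, `class`) or [build_tag_map()] output.
#' @param min_total Summed-count threshold; strictly greater-than (default
#'   10).
#' @param stages Ordered stage labels; default the order of appearance.
#' @return Tibble `tag`, `gene`, `count_<stage>` columns, `total`,
#'   `pct_<stage>` columns (each row's percentages sum to 100).
#' @export
select_clustering_tags <- function(libraries, map, min_total = 10,
                                   stages = NULL) {
  if (is.list(map) && !is.data.frame(map)) map <- map$map
  stages <- stages %||% unique(libraries$stage)
  wide <- libraries |>
    select("tag", "stage", "count") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "count",
                       values_fill = 0L, names_prefix = "count_")
  cols <- paste0("count_", stages)
  missing <- setdiff(cols, names(wide))
  for (mc in missing) wide[[mc]] <- 0L
  wide$total <- rowSums(wide[, cols])
  out <- wide |>
    inner_join(map |> filter(.data$class == "unique_sense") |>
                 select("tag", "gene"),
               by = "tag") |>
    filter(.data$total > min_total)
  for (s in stages) {
    out[[paste0("pct_", s)]] <- 100 * out[[paste0("count_", s)]] / out$total
  }
  out |> select("tag", "gene", dplyr::all_of(cols), "total",
                dplyr::all_of(paste0("pct_", stages)))
}

#' Poisson deviance between a count profile and a centroid
#'
#' `d = sum_j (lambda_j - x_j + x_j * log(x_j / lambda_j))` with
#' `lambda_j = sum(x) * c_j` and the convention `0 * log(0) = 0`; zero iff
#' the counts match the centroid's expected split exactly.
#'
#' @param x Nonnegative count vector (one profile) or matrix (profiles in
#'   rows), not all zero.
#' @param centroid Probability profile summing to 1 (floored at 1e-9).
#' @return Nonnegative deviance, one value per profile.
#' @examples
#' poissonc_distance(c(4, 0), c(0.5, 0.5)) # 4 * log(2)
#' @export
poissonc_distance <- function(x, centroid) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (any(rowSums(x) == 0)) stop("all-zero profile", call. = FALSE)
  centroid <- floor_centroid(centroid)
  lam <- rowSums(x) %o% centroid
  term <- lam - x + ifelse(x > 0, x * log(x / lam), 0)
  pmax(rowSums(term), 0)
}

## n x K deviance matrix via d_ik = const_i - X %*% log(c_k)
deviance_matrix <- function(x, centroids) {
  xlogx <- ifelse(x > 0, x * log(x), 0)
  s <- rowSums(x)
  const <- rowSums(xlogx) - s * log(s)
  a <- x %*% t(log(centroids))
  pmax(const - a, 0)
}

ml_centroids <- function(x, assign, K) {
  cen <- matrix(0, nrow = K, ncol = ncol(x))
  for (k in seq_len(K)) {
    members <- x[assign == k, , drop = FALSE]
    if (nrow(members) == 0) next
    cen[k, ] <- colSums(members)
  }
  t(apply(cen, 1, function(v) {
    if (sum(v) == 0) v <- rep(1, length(v))
    floor_centroid(v / sum(v))
  }))
}

#' Fit Poisson-deviance K-means
#'
#' Lloyd-style alternation: assign each tag to the centroid minimising the
#' Poisson deviance, then update each centroid to the maximum-likelihood
#' profile (normalised summed member counts), until the assignment reaches a
#' fixpoint. Deterministic given `seed`. Emptied clusters are re-seeded with
#' the currently worst-fit profile.
#'
#' @param profiles Count matrix (tags x stages) or a
#'   [select_clustering_tags()] tibble.
#' @param K Number of clusters, `1 <= K <= n`.
#' @param seed Integer seed for the random initial centroids.
#' @param max_iter Iteration cap.
#' @param init Optional K x stages matrix of starting centroid profiles
#'   (overrides the random initialisation).
#' @return A `poissonc_fit` object: `K`, `centroids` (K x stages, rows sum
#'   to 1), `assignment` (named integer vector), `dispersion` (total
#'   within-cluster deviance), `history` (dispersion after each assignment
#'   step, non-increasing), `seed`, `iterations`.
#' @export
poissonc_fit <- function(profiles, K, seed = 1L, max_iter = 100L,
                         init = NULL) {
  x <- profile_matrix(profiles)
  n <- nrow(x)
  if (K < 1 || K > n) stop("K must be between 1 and nrow(profiles)",
                           call. = FALSE)
  if (any(rowSums(x) == 0)) stop("all-zero profile", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(init)) {
    pick <- sample.int(n, K)
    centroids <- t(apply(x[pick, , drop = FALSE], 1,
                         function(v) floor_centroid(v / sum(v))))
  } else {
    stopifnot(is.matrix(init), nrow(init) == K, ncol(init) == ncol(x))
    centroids <- t(apply(init, 1, floor_centroid))
  }
  assign_old <- rep(0L, n)
  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    d <- deviance_matrix(x, centroids)
    assign <- max.col(-d, ties.method = "first")
    # re-seed empty clusters with the worst-fit profile
    for (k in which(tabulate(assign, K) == 0)) {
      worst <- which.max(d[cbind(seq_len(n), assign)])
      assign[worst] <- k
      d[worst, k] <- 0
    }
    history <- c(history, sum(d[cbind(seq_len(n), assign)]))
    if (identical(assign, assign_old)) break
    assign_old <- assign
    centroids <- ml_centroids(x, assign, K)
  }
  d <- deviance_matrix(x, centroids)
  dispersion <- sum(d[cbind(seq_len(n), assign)])
  names(assign) <- rownames(x)
  structure(list(K = K, centroids = centroids, assignment = assign,
                 dispersion = dispersion, history = history,
                 seed = as.integer(seed), iterations = it,
                 profiles = x),
            class = "poissonc_fit")
}

#' Within-cluster dispersion across a range of K
#'
#' Best-of-restarts total deviance for each K, with an elbow suggestion at
#' the K of maximum second difference of the dispersion curve. The choice of
#' K remains with the analyst; the curve only reports.
#'
#' @param profiles As for [poissonc_fit()].
#' @param K_range Integer vector of K values (default 2..20, clipped to n).
#' @param seed Base seed; restart r of K uses a derived sub-seed.
#' @param n_restarts Random restarts per K (default 5).
#' @return List with `curve` (tibble `K`, `dispersion`) and `elbow`
#'   (suggested K, `NA` if the range is too short).
#' @export
dispersion_curve <- function(profiles, K_range = 2:20, seed = 1L,
                             n_restarts = 5L) {
  x <- profile_matrix(profiles)
  K_range <- sort(K_range[K_range >= 1 & K_range <= nrow(x)])
  disp <- numeric(length(K_range))
  prev_fit <- NULL
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    fits <- lapply(seq_len(n_restarts), function(r) {
      poissonc_fit(x, K, seed = derive_seed(seed, i * 1000L + r))
    })
    # nested candidate: previous best solution plus a split at the
    # worst-fit profile, so dispersion is non-increasing in K
    if (!is.null(prev_fit) && K == prev_fit$K + 1L) {
      d <- deviance_matrix(x, prev_fit$centroids)
      worst <- which.max(d[cbind(seq_len(nrow(x)), prev_fit$assignment)])
      split_init <- rbind(prev_fit$centroids,
                          floor_centroid(x[worst, ] / sum(x[worst, ])))
      fits <- c(fits, list(poissonc_fit(x, K, seed = derive_seed(seed, i),
                                        init = split_init)))
    }
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "dispersion"))]]
    disp[i] <- best$dispersion
    prev_fit <- best
  }
  curve <- tibble(K = K_range, dispersion = disp)
  elbow <- NA_integer_
  if (length(K_range) >= 3) {
    # second difference on the log scale: dispersion spans orders of
    # magnitude, so the bend is where the *relative* decline stalls
    ld <- log(pmax(disp, .Machine$double.eps))
    d2 <- diff(ld, differences = 2)  # ld(K-1) - 2 ld(K) + ld(K+1)
    elbow <- K_range[which.max(d2) + 1L]
  }
  list(curve = curve, elbow = elbow)
}

## greedy alignment of run centroids to reference centroids by profile
## correlation; returns label map (run cluster -> reference cluster)
align_clusters <- function(ref, cen) {
  K <- nrow(ref)
  cors <- suppressWarnings(cor(t(cen), t(ref)))
  cors[!is.finite(cors)] <- -Inf
  map <- integer(K)
  used <- logical(K)
  for (step in seq_len(K)) {
    best <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    map[best[1]] <- best[2]
    cors[best[1], ] <- -Inf
    cors[, best[2]] <- -Inf
  }
  map
}

#' Consensus clustering over random restarts
#'
#' Runs `n_runs` independently seeded Poisson-deviance K-means fits, aligns
#' cluster labels across runs by greedy centroid-profile correlation
#' matching against the best (lowest-dispersion) run, and assigns each tag
#' its modal aligned cluster; stability is the fraction of runs agreeing
#' with the mode.
#'
#' @param profiles As for [poissonc_fit()].
#' @param K Number of clusters.
#' @param n_runs Number of restarts (default 100).
#' @param seed Base seed.
#' @return A `consensus_clustering` object: `assignment` (tibble `tag`,
#'   `cluster`, `stability`), `centroids` (ML profiles of the consensus
#'   clusters), `K`, `n_runs`, `best_dispersion`.
#' @export
consensus_cluster <- function(profiles, K, n_runs = 100L, seed = 1L) {
  stopifnot(n_runs >= 1)
  x <- profile_matrix(profiles)
  fits <- lapply(seq_len(n_runs), function(r) {
    poissonc_fit(x, K, seed = derive_seed(seed, r))
  })
  best <- which.min(vapply(fits, `[[`, numeric(1), "dispersion"))
  ref <- fits[[best]]$centroids
  labels <- vapply(fits, function(f) {
    map <- align_clusters(ref, f$centroids)
    map[f$assignment]
  }, integer(nrow(x)))
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = nrow(x))
  modal <- apply(labels, 1, function(l) {
    tb <- tabulate(l, K)
    k <- which.max(tb)
    c(k, tb[k] / length(l))
  })
  assignment <- tibble(tag = rownames(x) %||% as.character(seq_len(nrow(x))),
                       cluster = as.integer(modal[1, ]),
                       stability = modal[2, ])
  centroids <- ml_centroids(x, assignment$cluster, K)
  structure(list(assignment = assignment, centroids = centroids, K = K,
                 n_runs = n_runs,
                 best_dispersion = fits[[best]]$dispersion,
                 profiles = x),
            class = "consensus_clustering")
}

#' Amalgamate cluster centroids into the five major trend groups
#'
#' Rule on the centroid percentages `(a, r, c)` over the ordered stages with
#' tolerance `tau` (percentage points): group 3 if `r > max(a, c) + tau`
#' (peak at the middle stage); group 5 if `r < min(a, c) - tau` (valley);
#' group 1 if `c > a + tau` (up during progression); group 2 if
#' `c < a - tau` (down); otherwise group 4 (constant).
#'
#' @param centroids K x 3 matrix of centroid profiles (rows sum to 1 or to
#'   100), or a `poissonc_fit` / `consensus_clustering` object.
#' @param tau Tolerance in percentage points (default 5).
#' @return Integer vector of major groups (1..5), one per cluster.
#' @export
amalgamate_groups <- function(centroids, tau = 5) {
  if (inherits(centroids, c("poissonc_fit", "consensus_clustering"))) {
    centroids <- centroids$centroids
  }
  if (!is.matrix(centroids)) centroids <- matrix(centroids, nrow = 1)
  stopifnot(ncol(centroids) == 3)
  pct <- centroids / rowSums(centroids) * 100
  apply(pct, 1, function(p) {
    a <- p[1]; r <- p[2]; c <- p[3]
    if (r > max(a, c) + tau) return(3L)
    if (r < min(a, c) - tau) return(5L)
    if (c > a + tau) return(1L)
    if (c < a - tau) return(2L)
    4L
  })
}

#' Pearson 1-r library tree
#'
#' Computes pairwise Pearson correlations over the union tag set (absent
#' tags count 0), takes distance `1 - r`, infers the topology by neighbour
#' joining and refits nonnegative least-squares branch lengths to the
#' distance matrix.
#'
#' @param counts Count tibble over >= 3 libraries (`library_id`, `tag`,
#'   `count`).
#' @param use_cpm Correlate counts-per-million instead of raw counts.
#' @return A `sage_tree` object: `tree` (ape `phylo`), `dist` (matrix),
#'   `newick` (serialised tree).
#' @export
build_library_tree <- function(counts, use_cpm = FALSE) {
  if (use_cpm) {
    counts <- normalize_cpm(counts) |>
      mutate(count = .data$cpm)
  }
  wide <- counts |>
    select("library_id", "tag", "count") |>
    tidyr::pivot_wider(names_from = "library_id", values_from = "count",
                       values_fill = 0)
  m <- as.matrix(wide[, -1])
  if (ncol(m) < 3) stop("need at least 3 libraries", call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop("constant library vector: ", colnames(m)[which(sds == 0)[1]],
         call. = FALSE)
  }
  r <- cor(m)
  d <- 1 - r
  tree <- ape::nj(stats::as.dist(d))
  tree <- phangorn::nnls.tree(stats::as.dist(d), tree, method = "unrooted")
  tree$edge.length <- pmax(tree$edge.length, 0)
  structure(list(tree = tree, dist = d, newick = ape::write.tree(tree)),
            class = "sage_tree")
}

#' Test whether label groups form clades of a library tree
#'
#' For an unrooted tree, a group of tips forms a clade when the bipartition
#' separating it from the rest exists; checked by rooting at a tip outside
#' the group.
#'
#' @param tree A `sage_tree` or ape `phylo`.
#' @param groups Named character/factor vector mapping tip label to group.
#' @return Tibble `group`, `monophyletic`.
#' @export
stage_clades <- function(tree, groups) {
  phy <- if (inherits(tree, "sage_tree")) tree$tree else tree
  purrr::map_dfr(unique(groups), function(g) {
    tips <- names(groups)[groups == g]
    out_tip <- setdiff(phy$tip.label, tips)[1]
    rooted <- ape::root(phy, outgroup = out_tip, resolve.root = TRUE)
    tibble(group = g,
           monophyletic = ape::is.monophyletic(rooted, tips))
  })
}
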