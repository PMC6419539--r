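## Literature cohesion p-value (LPv): background cosine threshold T, sampled
## above/below-threshold counts A-D, right-tailed Fisher's exact test, and
## the -log10 transform.

#' Configuration for LPv calculation
#'
#' @param percentile background threshold percentile (default 95: T is the
#'   95th percentile of all background pairwise cosines).
#' @param k cosines per random draw (default 50; clamped down to the set's
#'   pair count for small sets).
#' @param n number of in-set draws (default 1000).
#' @param N number of background draws (default 1000).
#' @param background_pair_budget maximum background pairs enumerated or
#'   sampled to estimate T (default 1e6).
#' @param seed RNG seed.
#' @param point_mass if TRUE the p-value is the single-table hypergeometric
#'   point probability rather than the right tail sum.
#' @return validated `lpv_config` list.
#' @export
lpv_config <- function(percentile = 95, k = 50, n = 1000, N = 1000,
                       background_pair_budget = 1e6, seed = 1L,
                       point_mass = FALSE) {
  if (!(is.numeric(percentile) && percentile > 0 && percentile < 100)) {
    abort("percentile must be in (0, 100)", "litcohesion_config_error")
  }
  for (nm in c("k", "n", "N")) {
    v <- get(nm)
    if (!is_count(v)) abort(sprintf("%s must be an integer >= 1", nm), "litcohesion_config_error")
  }
  if (!is_count(background_pair_budget)) {
    abort("background_pair_budget must be an integer >= 1", "litcohesion_config_error")
  }
  structure(list(percentile = percentile, k = as.integer(k), n = as.integer(n),
                 N = as.integer(N), background_pair_budget = background_pair_budget,
                 seed = as.integer(seed), point_mass = isTRUE(point_mass)),
            class = "lpv_config")
}

## Percentile convention used for T: linear interpolation between order
## statistics (quantile type 7). Kept as its own function because percentile
## conventions differ across tools.
empirical_percentile <- function(x, percentile) {
  stats::quantile(x, percentile / 100, names = FALSE, type = 7)
}

decode_pair_rank <- function(r) {
  ## rank over pairs (i < j) enumerated (1,2),(1,3),(2,3),(1,4),...
  j <- floor((1 + sqrt(8 * r - 7)) / 2) + 1
  i <- r - (j - 1) * (j - 2) / 2
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Estimate the background cosine threshold T
#'
#' T is the configured percentile (linear interpolation between order
#' statistics) of background pairwise cosines. If the corpus has no more
#' than `background_pair_budget` pairs, all pairs are used (mode "exact");
#' otherwise that many unordered pairs are sampled uniformly without
#' replacement (mode "sampled"). The pool of background cosines is retained
#' for the background draws of [lpv()].
#'
#' @param space a `concept_space` with at least 2 genes.
#' @param config an [lpv_config()].
#' @return a `background_threshold`: `T`, `mode`, `pairs_used`, `percentile`,
#'   `seed`, and the cosine `pool`.
#' @export
estimate_threshold <- function(space, config = lpv_config()) {
  m <- length(space$genes)
  if (m < 2) abort("concept space has fewer than 2 genes", "litcohesion_config_error")
  npairs <- m * (m - 1) / 2
  v <- space_norms(space, space$genes)
  if (npairs <= config$background_pair_budget) {
    cc <- tcrossprod(v)
    pool <- cc[upper.tri(cc)]
    mode <- "exact"
  } else {
    if (npairs >= 2^31) {
      abort("corpus too large to sample pair ranks with 32-bit sampling",
            "litcohesion_numerical_error")
    }
    pool <- with_seed(derive_seed(config$seed, "threshold"), {
      ranks <- sample.int(npairs, config$background_pair_budget)
      ij <- decode_pair_rank(ranks)
      rowSums(v[ij[, "i"], , drop = FALSE] * v[ij[, "j"], , drop = FALSE])
    })
    mode <- "sampled"
  }
  structure(list(T = empirical_percentile(pool, config$percentile),
                 mode = mode, pairs_used = length(pool),
                 percentile = config$percentile, seed = config$seed, pool = pool),
            class = "background_threshold")
}

#' @export
print.background_threshold <- function(x, ...) {
  cat(sprintf("background_threshold: T = %.4f (%s, %d pairs, percentile %g)\n",
              x$T, x$mode, x$pairs_used, x$percentile))
  invisible(x)
}

#' Average above/below-threshold counts over random cosine draws
#'
#' Each draw samples `min(k, |cosines|)` cosines without replacement; counts
#' of values `>= T` and `< T` are averaged over draws. When the multiset has
#' at most k elements every draw is the full set and the averages are
#' deterministic.
#'
#' @param cosines numeric multiset of cosines.
#' @param T threshold.
#' @param k draw size.
#' @param n_draws number of draws.
#' @param seed RNG seed.
#' @return list `avg_above`, `avg_below`, `k_used`.
#' @export
sample_counts <- function(cosines, T, k, n_draws, seed = 1L) {
  P <- length(cosines)
  if (P < 1) abort("empty cosine multiset", "litcohesion_config_error")
  kk <- min(k, P)
  if (kk == P) {
    above <- sum(cosines >= T)
    return(list(avg_above = above, avg_below = P - above, k_used = kk))
  }
  ind <- cosines >= T
  counts <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) sum(ind[sample.int(P, kk)]), numeric(1))
  })
  avg <- mean(counts)
  list(avg_above = avg, avg_below = kk - avg, k_used = kk)
}

#' Right-tailed Fisher's exact test on a 2x2 table
#'
#' For the table (a, b | c, d), returns \eqn{P(X \ge a)} where X follows the
#' hypergeometric distribution with total a+b+c+d, a+c "successes", and a+b
#' draws. With `point_mass = TRUE` the single-table probability
#' \eqn{P(X = a)} is returned instead.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param point_mass return the point probability instead of the tail sum.
#' @return p-value in `(0, 1]`.
#' @export
fisher_right_tail <- function(a, b, c, d, point_mass = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    abort("cells must be non-negative integers", "litcohesion_domain_error")
  }
  if (point_mass) {
    p <- stats::dhyper(a, a + c, b + d, a + b)
  } else {
    p <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  }
  min(1, max(p, 0))
}

#' Literature cohesion p-value of a gene set
#'
#' Computes all pairwise cosines of the in-corpus genes, the averaged in-set
#' counts (A, B) over `n` draws, the averaged background counts (C, D) over
#' `N` draws from the background pool of `threshold`, rounds the averages to
#' the nearest integer (ties up), and applies the right-tailed Fisher's
#' exact test. Reported as both p and -log10(p); higher -log10(p) means
#' higher cohesion.
#'
#' @param space a `concept_space`.
#' @param gene_set character vector of gene ids (>= 2 in the corpus).
#' @param threshold a `background_threshold` from [estimate_threshold()].
#' @param config an [lpv_config()].
#' @return an `lpv_result`: rounded counts `A`-`D`, unrounded `raw` averages,
#'   `p`, `neg_log10`, `coverage`, `n_genes_used`, `k_used`, `significant`
#'   (p < 0.05).
#' @export
lpv <- function(space, gene_set, threshold, config = lpv_config()) {
  pc <- pairwise_cosines(space, gene_set)
  kk <- min(config$k, length(pc$cosines))
  ab <- sample_counts(pc$cosines, threshold$T, kk, config$n,
                      seed = derive_seed(config$seed, "inset"))
  cd <- sample_counts(threshold$pool, threshold$T, kk, config$N,
                      seed = derive_seed(config$seed, "background"))
  A <- round_half_up(ab$avg_above); B <- round_half_up(ab$avg_below)
  C <- round_half_up(cd$avg_above); D <- round_half_up(cd$avg_below)
  ## rounding can break the margin by one; rebalance the below cell
  B <- kk - A
  D <- kk - C
  p <- fisher_right_tail(A, B, C, D, point_mass = config$point_mass)
  structure(list(A = A, B = B, C = C, D = D,
                 raw = c(A = ab$avg_above, B = ab$avg_below,
                         C = cd$avg_above, D = cd$avg_below),
                 p = p, neg_log10 = -log10(p), coverage = pc$coverage,
                 n_genes_used = length(pc$genes_used), k_used = kk,
                 significant = p < 0.05),
            class = "lpv_result")
}

#' @export
print.lpv_result <- function(x, ...) {
  cat(sprintf("LPv: p = %.3g (-log10 = %.2f), table [%d %d; %d %d], coverage %.0f%%\n",
              x$p, x$neg_log10, x$A, x$B, x$C, x$D, 100 * x$coverage))
  invisible(x)
}
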