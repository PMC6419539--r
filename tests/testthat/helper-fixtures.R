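# Shared fixture builders. Everything is generated in code at test time.

# Small, fast synthetic world used by unit tests (the full-size defaults are
# exercised only by the acceptance suite).
tiny_config <- function(...) {
  defaults <- list(n_genes = 120, n_modules = 2, module_size = 20,
                   vocab_size = 400, module_vocab_size = 60,
                   doc_length_mean = 40, n_strains = 20,
                   n_signal_probes_per_module = 2, n_noise_probes = 2,
                   seed = 1L)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

tiny_space <- function(cfg = tiny_config()) {
  concept_space_from_corpus(generate_corpus(cfg)$corpus)
}

# Build a concept_space directly from a gene-vector matrix (genes x k), for
# closed-form cosine tests.
space_from_vectors <- function(vectors) {
  litcohesion:::new_concept_space(genes = rownames(vectors), k = ncol(vectors),
                                  d = rep(1, ncol(vectors)), vectors = vectors)
}

# Fabricated background threshold with a controlled cosine pool.
fake_threshold <- function(T, pool) {
  structure(list(T = T, mode = "exact", pairs_used = length(pool),
                 percentile = 95, seed = 1L, pool = pool),
            class = "background_threshold")
}

# Independent dense reimplementation of log-entropy weighting (loops only),
# used as the oracle against the sparse production path.
naive_log_entropy <- function(f) {
  n <- ncol(f)
  w <- matrix(0, nrow(f), ncol(f))
  for (i in seq_len(nrow(f))) {
    tot <- sum(f[i, ])
    g <- 1
    if (tot > 0) {
      s <- 0
      for (j in seq_len(n)) {
        if (f[i, j] > 0) {
          p <- f[i, j] / tot
          s <- s + p * log2(p)
        }
      }
      g <- 1 + s / log2(n)
    }
    for (j in seq_len(n)) w[i, j] <- g * log2(1 + f[i, j])
  }
  w
}

# Brute-force right-tail hypergeometric p via log-binomials (independent of
# phyper). Table (a, b, c, d): draws a+b from a+c successes in total.
enum_right_tail <- function(a, b, c, d) {
  K <- a + c; m1 <- a + b; tot <- a + b + c + d
  lo <- max(0, m1 + K - tot); hi <- min(m1, K)
  x <- a:hi
  if (a > hi) return(0)
  sum(exp(lchoose(K, x) + lchoose(tot - K, m1 - x) - lchoose(tot, m1)))
}

# Random count matrix whose last gene column duplicates the previous one, so
# the weighted matrix has rank <= min(dim) - 1 and truncation at that rank
# is lossless.
rank_deficient_counts <- function(nterm, ngene) {
  f <- matrix(rpois(nterm * ngene, 2), nterm, ngene)
  f[, ngene] <- f[, ngene - 1L]
  f + 1L  # strictly positive: no zero-norm columns
}

tgm_from_counts <- function(f) {
  if (is.null(rownames(f))) rownames(f) <- sprintf("t%03d", seq_len(nrow(f)))
  if (is.null(colnames(f))) colnames(f) <- sprintf("g%03d", seq_len(ncol(f)))
  structure(list(matrix = methods::as(Matrix::Matrix(f, sparse = TRUE), "CsparseMatrix"),
                 terms = rownames(f), genes = colnames(f), weighting = "raw"),
            class = "term_gene_matrix")
}

expect_lit_error <- function(expr, class) expect_error(expr, class = class)
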