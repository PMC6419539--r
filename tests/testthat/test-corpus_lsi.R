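test_that("gene2pubmed parsing collapses duplicates and reports bad rows by line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#tax_id\tGeneID\tPubMed_ID",
               "10090\t1\t101", "10090\t1\t101", "10090\t2\t102"), f)
  expect_identical(read_gene2pubmed(f), list(`1` = 101L, `2` = 102L))

  writeLines("#tax_id\tGeneID\tPubMed_ID", f)
  expect_identical(read_gene2pubmed(f), structure(list(), names = character(0)))

  writeLines(c("10090\t1\t101", "10090\t2\tabc"), f)
  err <- tryCatch(read_gene2pubmed(f), error = function(e) e)
  expect_s3_class(err, "litcohesion_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("documents concatenate available abstracts in ascending PMID order", {
  corpus <- suppressMessages(
    build_documents(list(g1 = c(102L, 101L)), c(`101` = "a b", `102` = "c")))
  expect_identical(unname(corpus$documents["g1"]), "a b c")

  # gene whose only PMID lacks text is excluded with a warning
  expect_warning(
    corpus2 <- suppressMessages(
      build_documents(list(g1 = 101L, g2 = 999L), c(`101` = "a b"))),
    "excluded")
  expect_identical(corpus2$genes, "g1")

  # shared citations appear in both documents
  shared <- suppressMessages(
    build_documents(list(g1 = 101L, g2 = c(101L, 102L)),
                    c(`101` = "shared text", `102` = "extra")))
  expect_match(shared$documents[["g1"]], "shared text")
  expect_match(shared$documents[["g2"]], "shared text")
})

test_that("tokenizer lowercases, splits, and drops short/numeric/stop tokens", {
  expect_identical(tokenize("Sirt3 regulates NAD+ metabolism"),
                   c("sirt3", "regulates", "nad", "metabolism"))
  expect_identical(tokenize("a an of 42"), character(0))
  expect_identical(tokenize(""), character(0))
})

test_that("term matrix applies the gene-frequency filter and count semantics", {
  corpus <- gene_corpus(c(g1 = "xxx yyy", g2 = "xxx zzz"),
                        list(g1 = 1L, g2 = 2L))
  tgm <- build_term_matrix(corpus, min_gene_frequency = 2)
  expect_identical(tgm$terms, "xxx")
  expect_equal(as.vector(tgm$matrix), c(1, 1))

  tgm1 <- build_term_matrix(corpus, min_gene_frequency = 1)
  expect_identical(tgm1$terms, c("xxx", "yyy", "zzz"))

  corpus3 <- gene_corpus(c(g1 = "abc abc abc", g2 = "abc"), list(g1 = 1L, g2 = 2L))
  tgm3 <- build_term_matrix(corpus3, min_gene_frequency = 1)
  expect_equal(tgm3$matrix["abc", "g1"], 3)

  expect_lit_error(build_term_matrix(corpus, min_gene_frequency = 5),
                   "litcohesion_pipeline_error")
})

test_that("log-entropy weighting matches hand-derived and oracle values", {
  # maximal entropy: a term in every document once -> weight 0
  f <- matrix(1, 1, 4)
  w <- log_entropy_weight(tgm_from_counts(rbind(f, c(2, 0, 0, 0))))
  expect_equal(unname(as.vector(w$matrix[1, ])), rep(0, 4), tolerance = 1e-12)
  # minimal entropy: a term in one document -> g = 1, w = log2(1 + f)
  expect_equal(w$matrix[2, 1], log2(3), tolerance = 1e-12)
  expect_equal(unname(w$global_weights[2]), 1)

  # hand-derived row: counts (2,1,1,0) over n = 4 genes
  w2 <- log_entropy_weight(tgm_from_counts(rbind(c(2, 1, 1, 0), c(1, 1, 1, 1))))
  expect_equal(unname(w2$global_weights[1]), 0.25, tolerance = 1e-12)
  expect_equal(unname(as.vector(w2$matrix[1, ])),
               0.25 * c(log2(3), 1, 1, 0), tolerance = 1e-12)

  # weighting oracle: naive dense reimplementation on random 50 x 20 counts
  for (seed in 1:3) {
    f <- with_seed(seed, matrix(rpois(50 * 20, 1.5), 50, 20))
    f[rowSums(f) == 0, 1] <- 1
    w <- log_entropy_weight(tgm_from_counts(f))
    expect_lt(max(abs(as.matrix(w$matrix) - naive_log_entropy(f))), 1e-10)
  }

  expect_lit_error(log_entropy_weight(tgm_from_counts(matrix(1, 2, 1))),
                   "litcohesion_config_error")
})

test_that("truncated SVD: rank-1 case, clamping, and energy against dense oracle", {
  # rank-1 outer product: one concept explains all of the Frobenius norm
  f <- outer(1:5, 1:3)
  tgm <- tgm_from_counts(f)
  expect_warning(space <- truncated_svd(tgm, k = 5), "clamped")
  expect_length(space$d, 2)
  expect_equal(space$d[1]^2, sum(f^2), tolerance = 1e-8)
  expect_lt(space$d[2], 1e-8)

  # random 200 x 100, k = 30: retained energy equals best rank-30
  # approximation energy from a dense full SVD oracle
  f <- with_seed(9, matrix(rpois(200 * 100, 2), 200, 100))
  space30 <- truncated_svd(tgm_from_counts(f), k = 30)
  oracle_d <- svd(f, nu = 0, nv = 0)$d
  expect_equal(sum(space30$d^2), sum(oracle_d[1:30]^2),
               tolerance = 1e-6 * sum(oracle_d[1:30]^2))
  expect_true(all(diff(space30$d) <= 1e-12))
})

test_that("SVD fidelity: lossless truncation preserves all pairwise cosines", {
  for (seed in 1:3) {
    f <- with_seed(seed, rank_deficient_counts(60, 40))
    w <- log_entropy_weight(tgm_from_counts(f))
    space <- truncated_svd(w, k = 39)
    v <- litcohesion:::space_norms(space, space$genes)
    red <- tcrossprod(v)
    dense <- as.matrix(w$matrix)
    dn <- sweep(dense, 2, sqrt(colSums(dense^2)), "/")
    direct <- crossprod(dn)
    expect_lt(max(abs(red[upper.tri(red)] - direct[upper.tri(direct)])), 1e-6)
  }
})

test_that("cosines follow closed forms and pair counting rules", {
  vec <- rbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0, 1, 0), d = c(1, 1, 0))
  space <- space_from_vectors(vec)
  expect_equal(cosine(space, "a", "b"), 1.0)
  expect_equal(cosine(space, "a", "c"), 0.0)
  expect_equal(cosine(space, "d", "a"), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cosine(space, "a", "d"), cosine(space, "d", "a"))
  expect_lit_error(cosine(space, "a", "zz"), "litcohesion_lookup_error")

  zspace <- space_from_vectors(rbind(a = c(1, 0), z = c(0, 0)))
  err <- tryCatch(cosine(zspace, "a", "z"), error = function(e) e)
  expect_s3_class(err, "litcohesion_similarity_error")
  expect_match(conditionMessage(err), "z")

  pc <- pairwise_cosines(space, c("a", "b", "c"))
  expect_length(pc$cosines, 3)
  expect_equal(pc$coverage, 1)

  pc2 <- pairwise_cosines(space, c(rownames(vec), "e1", "e2", "e3", "e4", "e5", "e6"))
  expect_length(pc2$cosines, choose(4, 2))
  expect_equal(pc2$coverage, 0.4)

  expect_lit_error(pairwise_cosines(space, c("a", "nope")),
                   "litcohesion_cohesion_undefined_error")
})

test_that("mean within-module cosine increases with planted signal", {
  fracs <- c(0, 0.25, 0.5, 0.75)
  means <- vapply(fracs, function(sf) {
    cfg <- synthetic_config(n_genes = 200, n_modules = 4, module_size = 25,
                            vocab_size = 600, module_vocab_size = 60,
                            doc_length_mean = 40, signal_term_fraction = sf,
                            n_strains = 10, n_signal_probes_per_module = 2,
                            n_noise_probes = 2, seed = 5)
    gen <- generate_corpus(cfg)
    space <- concept_space_from_corpus(gen$corpus)
    mean(vapply(gen$truth$modules,
                function(m) mean(pairwise_cosines(space, m)$cosines), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("corpus -> space pipeline is reproducible and archives round-trip", {
  cfg <- tiny_config(seed = 4)
  s1 <- tiny_space(cfg)
  s2 <- tiny_space(cfg)
  expect_identical(s1$vectors, s2$vectors)

  stem <- file.path(withr::local_tempdir(), "space")
  write_concept_space(s1, stem)
  s3 <- read_concept_space(stem)
  expect_equal(s3$d, s1$d, tolerance = 1e-9)
  expect_equal(cosine(s3, s1$genes[1], s1$genes[2]),
               cosine(s1, s1$genes[1], s1$genes[2]), tolerance = 1e-6)
})
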