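test_that("invalid configurations are rejected with the violated invariant named", {
  expect_lit_error(synthetic_config(n_genes = 10, n_modules = 2, module_size = 10),
                   "litcohesion_config_error")
  expect_lit_error(synthetic_config(vocab_size = 100, module_vocab_size = 50,
                                    n_modules = 4),
                   "litcohesion_config_error")
  expect_lit_error(synthetic_config(signal_term_fraction = 1.2),
                   "litcohesion_config_error")
  expect_lit_error(synthetic_config(n_strains = 0), "litcohesion_config_error")
  expect_error(synthetic_config(gold_dropout = -0.1), "gold_dropout")
})

test_that("corpus generation is deterministic and respects the token mixture", {
  cfg <- tiny_config(signal_term_fraction = 0.5, seed = 7)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(g1$corpus$documents, g2$corpus$documents)
  expect_identical(g1$truth$modules, g2$truth$modules)
  expect_identical(g1$truth$activity, g2$truth$activity)

  # signal_term_fraction = 0: module genes use background vocabulary only
  null_gen <- generate_corpus(tiny_config(signal_term_fraction = 0))
  mod_docs <- null_gen$corpus$documents[unlist(null_gen$truth$modules)]
  expect_false(any(grepl("mod[0-9]", mod_docs)))

  # signal_term_fraction = 1 with disjoint module vocabularies: genes from
  # different modules share zero terms
  pure <- generate_corpus(tiny_config(signal_term_fraction = 1))
  toks1 <- unlist(strsplit(pure$corpus$documents[pure$truth$modules[[1]]], " "))
  toks2 <- unlist(strsplit(pure$corpus$documents[pure$truth$modules[[2]]], " "))
  expect_length(intersect(toks1, toks2), 0)
})

test_that("corpus structure: one document per gene, non-empty PMID sets, disjoint modules", {
  gen <- generate_corpus(tiny_config())
  expect_setequal(names(gen$corpus$documents), gen$truth$genes)
  expect_true(all(lengths(gen$corpus$pmids) >= 1))
  expect_length(intersect(gen$truth$modules[[1]], gen$truth$modules[[2]]), 0)
  expect_true(all(gen$truth$probes$region %in% c("exon", "intron")))
})

test_that("expression generation: noiseless signal probes are perfectly correlated", {
  cfg <- tiny_config(probe_noise_sd = 0, expression_noise_sd = 0)
  gen <- generate_corpus(cfg)
  ds <- generate_expression(cfg, gen$truth)
  sig <- gen$truth$probes$probe_id[gen$truth$probes$region == "exon" &
                                     startsWith(gen$truth$probes$probe_id, "module01")]
  cc <- cor(t(ds$matrix[sig, ]))
  expect_equal(max(abs(cc - 1)), 0, tolerance = 1e-12)

  # determinism
  ds2 <- generate_expression(cfg, gen$truth)
  expect_identical(ds$matrix, ds2$matrix)

  # config/truth mismatch is a consistency error
  other <- tiny_config(seed = 99)
  expect_lit_error(generate_expression(other, gen$truth),
                   "litcohesion_consistency_error")
})

test_that("independent noise probes stay below |r| = 0.8 over 40 strains", {
  # Monte-Carlo over 1000 replicate pairs at a fixed seed; for n = 40 the
  # probability of |r| >= 0.8 is astronomically small.
  rs <- with_seed(42, {
    vapply(seq_len(1000), function(i) cor(rnorm(40), rnorm(40)), numeric(1))
  })
  expect_lt(max(abs(rs)), 0.8)
})

test_that("gold standards corrupt planted modules as configured", {
  gen <- generate_corpus(tiny_config(module_size = 50, n_genes = 120))
  members <- gen$truth$modules[["module01"]]

  exact <- generate_gold_standard(gen$truth, "module01", gold_dropout = 0,
                                  gold_contamination = 0)
  expect_setequal(exact, members)

  empty <- generate_gold_standard(gen$truth, "module01", gold_dropout = 1,
                                  gold_contamination = 0)
  expect_length(empty, 0)

  expect_lit_error(generate_gold_standard(gen$truth, "moduleXX"),
                   "litcohesion_lookup_error")

  # dropout = 0.2 on 50 members: mean retained over 200 seeds within 2 SE of 40
  kept <- vapply(seq_len(200), function(s) {
    g <- generate_gold_standard(gen$truth, "module01", gold_dropout = 0.2,
                                gold_contamination = 0, seed = s)
    length(g)
  }, numeric(1))
  expect_true(all(kept >= 0 & kept <= 50))
  se <- sqrt(50 * 0.8 * 0.2 / 200)
  expect_lt(abs(mean(kept) - 40), 2 * se + 1e-9)
})

test_that("null corpora have exchangeable module/background similarity distributions", {
  # scaled-down version of the null-fidelity invariant: 5 seeds, rank test on
  # sampled within-module vs background-gene cosine pairs
  ps <- vapply(c(3, 5, 8, 13, 21), function(seed) {
    cfg <- tiny_config(signal_term_fraction = 0, seed = seed)
    gen <- generate_corpus(cfg)
    space <- concept_space_from_corpus(gen$corpus)
    mod <- pairwise_cosines(space, gen$truth$modules[[1]])$cosines
    bg_genes <- setdiff(gen$truth$genes, unlist(gen$truth$modules))
    bg <- pairwise_cosines(space, bg_genes[1:20])$cosines
    suppressWarnings(wilcox.test(mod, bg)$p.value)
  }, numeric(1))
  expect_gt(median(ps), 0.01)
})

test_that("planted signal makes within-module cosines dominate between-module ones", {
  cfg <- tiny_config(signal_term_fraction = 0.5)
  gen <- generate_corpus(cfg)
  space <- concept_space_from_corpus(gen$corpus)
  within <- c(pairwise_cosines(space, gen$truth$modules[[1]])$cosines,
              pairwise_cosines(space, gen$truth$modules[[2]])$cosines)
  v1 <- litcohesion:::space_norms(space, gen$truth$modules[[1]])
  v2 <- litcohesion:::space_norms(space, gen$truth$modules[[2]])
  between <- as.vector(v1 %*% t(v2))
  expect_gt(mean(within), mean(between))
  expect_lt(suppressWarnings(wilcox.test(within, between, alternative = "greater")$p.value),
            0.001)
})

test_that("synthetic files round-trip through the plain-text formats", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config()
  paths <- write_synthetic_data(cfg, dir)
  g2p <- read_gene2pubmed(paths$gene2pubmed)
  txt <- read_abstracts(paths$abstracts)
  corpus <- build_documents(g2p, txt)
  gen <- generate_corpus(cfg)
  expect_identical(corpus$documents[gen$truth$genes], gen$corpus$documents)
  mat <- read_expression_matrix(paths$expression)
  ds <- generate_expression(cfg, gen$truth)
  expect_equal(mat, ds$matrix, tolerance = 1e-6)
  golds <- read_gmt(paths$gold)
  expect_named(golds, paste0("gold_", names(gen$truth$modules)))
})
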