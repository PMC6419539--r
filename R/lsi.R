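## Gene-document corpus construction and the LSI concept space:
## log-entropy weighted term-by-gene matrix, truncated SVD, cosines.

#' Construct a gene corpus
#'
#' @param documents named character vector: gene id -> document text.
#' @param pmids named list: gene id -> integer PMIDs (non-empty).
#' @param pmid_text optional named character vector pmid -> text (kept for
#'   round-tripping).
#' @return a `gene_corpus` with fields `documents`, `pmids`, `genes` (the
#'   ordered gene universe G), `pmid_text`.
#' @export
gene_corpus <- function(documents, pmids, pmid_text = NULL) {
  stopifnot(!is.null(names(documents)), identical(sort(names(documents)), sort(names(pmids))))
  if (any(lengths(pmids) == 0)) {
    abort("every gene must have a non-empty PMID set", "litcohesion_config_error")
  }
  structure(list(documents = documents, pmids = pmids[names(documents)],
                 genes = names(documents), pmid_text = pmid_text),
            class = "gene_corpus")
}

#' @export
print.gene_corpus <- function(x, ...) {
  cat(sprintf("gene_corpus: %d genes, %d citations\n",
              length(x$genes), length(unique(unlist(x$pmids)))))
  invisible(x)
}

#' Build per-gene documents from citation links and abstract texts
#'
#' Each gene's document is the concatenation (single-space joined) of the
#' texts of its PMIDs in ascending numeric order. PMIDs without text are
#' skipped (count reported); genes with no retrievable text at all are
#' excluded from the universe with a warning.
#'
#' @param gene_pmids named list gene -> integer PMIDs (as from
#'   [read_gene2pubmed()]).
#' @param pmid_text named character vector pmid -> text.
#' @return a `gene_corpus`.
#' @export
build_documents <- function(gene_pmids, pmid_text) {
  have <- names(pmid_text)
  n_missing <- 0L
  docs <- character(0)
  kept_pmids <- list()
  for (g in names(gene_pmids)) {
    p <- sort(unique(as.integer(gene_pmids[[g]])))
    avail <- p[as.character(p) %in% have]
    n_missing <- n_missing + (length(p) - length(avail))
    if (!length(avail)) next
    docs[g] <- paste(pmid_text[as.character(avail)], collapse = " ")
    kept_pmids[[g]] <- avail
  }
  if (n_missing > 0) log_stage("corpus", n_missing, " cited PMIDs had no text; skipped")
  dropped <- setdiff(names(gene_pmids), names(docs))
  if (length(dropped)) {
    warning(sprintf("%d gene(s) had no retrievable text and were excluded from the universe",
                    length(dropped)))
  }
  if (!length(docs)) abort("no gene has any retrievable text", "litcohesion_pipeline_error")
  gene_corpus(docs, kept_pmids, pmid_text)
}

.stopword_cache <- new.env(parent = emptyenv())

#' Default English stopword list
#' @return character vector of stopwords.
#' @export
default_stopwords <- function() {
  if (is.null(.stopword_cache$words)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "litcohesion")
    .stopword_cache$words <- readLines(path)
  }
  .stopword_cache$words
}

#' Tokenize text for the term-by-gene matrix
#'
#' Lowercases, splits on non-alphanumeric characters, and drops tokens
#' shorter than 3 characters, pure numbers, and stopwords.
#'
#' @param text a single character string.
#' @param stopwords character vector of terms to drop.
#' @return character vector of tokens (possibly empty).
#' @export
tokenize <- function(text, stopwords = default_stopwords()) {
  if (!nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nchar(toks) >= 3]
  toks <- toks[!grepl("^[0-9]+$", toks)]
  toks[!toks %in% stopwords]
}

#' Build the raw term-by-gene count matrix
#'
#' Vocabulary keeps terms occurring in at least `min_gene_frequency` distinct
#' gene-documents, sorted lexicographically (C locale). Genes left with no
#' tokens are dropped from the universe with a warning.
#'
#' @param corpus a `gene_corpus`.
#' @param min_gene_frequency minimum number of distinct documents a term must
#'   appear in.
#' @param stopwords passed to [tokenize()].
#' @return a `term_gene_matrix` list: sparse `matrix` (terms x genes),
#'   `terms`, `genes`, `weighting = "raw"`.
#' @export
build_term_matrix <- function(corpus, min_gene_frequency = 2,
                              stopwords = default_stopwords()) {
  toks <- lapply(corpus$documents, tokenize, stopwords = stopwords)
  empty <- lengths(toks) == 0
  if (any(empty)) {
    warning(sprintf("%d gene(s) had no tokens after tokenization and were dropped",
                    sum(empty)))
    toks <- toks[!empty]
  }
  if (!length(toks)) abort("no gene has any tokens", "litcohesion_pipeline_error")
  genes <- names(toks)
  gene_freq <- table(unlist(lapply(toks, unique), use.names = FALSE))
  vocab <- sort(names(gene_freq)[gene_freq >= min_gene_frequency], method = "radix")
  if (!length(vocab)) {
    abort("vocabulary is empty after the gene-frequency filter", "litcohesion_pipeline_error")
  }
  trip <- do.call(rbind, lapply(seq_along(toks), function(j) {
    tt <- table(toks[[j]])
    i <- match(names(tt), vocab)
    keep <- !is.na(i)
    cbind(i = i[keep], j = rep.int(j, sum(keep)), x = as.numeric(tt)[keep])
  }))
  mat <- Matrix::sparseMatrix(i = trip[, "i"], j = trip[, "j"], x = trip[, "x"],
                              dims = c(length(vocab), length(genes)),
                              dimnames = list(vocab, genes))
  structure(list(matrix = mat, terms = vocab, genes = genes, weighting = "raw"),
            class = "term_gene_matrix")
}

#' Apply log-entropy weighting to a raw count matrix
#'
#' Weighted entries are \eqn{w_{ij} = g_i \log_2(1 + f_{ij})} with the global
#' entropy weight \eqn{g_i = 1 + \sum_j p_{ij}\log_2 p_{ij} / \log_2 n},
#' \eqn{p_{ij} = f_{ij} / \sum_j f_{ij}}, and n the number of genes. Terms
#' spread evenly across all documents get weight 0, terms confined to one
#' document weight 1.
#'
#' @param tgm a raw `term_gene_matrix`.
#' @return the weighted `term_gene_matrix` with a `global_weights` field.
#' @export
log_entropy_weight <- function(tgm) {
  f <- tgm$matrix
  n <- ncol(f)
  if (n < 2) abort("log-entropy weighting needs at least 2 genes", "litcohesion_config_error")
  rs <- Matrix::rowSums(f)
  ft <- methods::as(f, "TsparseMatrix")
  p <- ft@x / rs[ft@i + 1L]
  contrib <- p * log2(p)            # 0 counts contribute 0 by omission
  ent <- numeric(nrow(f))
  agg <- rowsum(contrib, group = ft@i + 1L)
  ent[as.integer(rownames(agg))] <- agg[, 1]
  g <- 1 + ent / log2(n)
  w <- f
  w@x <- log2(1 + w@x)
  w <- Matrix::Diagonal(x = g) %*% w
  out <- tgm
  out$matrix <- methods::as(w, "CsparseMatrix")
  dimnames(out$matrix) <- dimnames(f)
  out$weighting <- "log-entropy"
  out$global_weights <- stats::setNames(g, tgm$terms)
  out
}

new_concept_space <- function(genes, k, d, vectors, params = list()) {
  structure(list(genes = genes, k = k, d = d, vectors = vectors, params = params),
            class = "concept_space")
}

#' @export
print.concept_space <- function(x, ...) {
  cat(sprintf("concept_space: %d genes x %d concepts (sigma_1 = %.3g)\n",
              length(x$genes), x$k, x$d[1]))
  invisible(x)
}

#' Truncated SVD of the weighted matrix: the concept space
#'
#' Gene vectors are the singular-value-scaled right singular vectors: gene j
#' maps to \eqn{(\sigma_1 v_{j1}, \ldots, \sigma_k v_{jk})}, the standard LSI
#' document representation. The dense LAPACK solver is deterministic; `seed`
#' is accepted for interface compatibility with randomized solvers and
#' ignored.
#'
#' @param tgm a (weighted) `term_gene_matrix`.
#' @param k number of concepts (default 500); clamped to `min(dim) - 1` with
#'   a warning when larger.
#' @param seed unused (see above).
#' @return a `concept_space`.
#' @export
truncated_svd <- function(tgm, k = 500, seed = NULL) {
  if (!is_count(k)) abort("k must be an integer >= 1", "litcohesion_config_error")
  dims <- dim(tgm$matrix)
  kmax <- min(dims) - 1L
  if (k > kmax) {
    warning(sprintf("k = %d exceeds min(dims) - 1 = %d; clamped", k, kmax))
    k <- kmax
  }
  s <- tryCatch(svd(as.matrix(tgm$matrix), nu = 0L),
                error = function(e) {
                  abort(sprintf("SVD failed on %d x %d matrix: %s",
                                dims[1], dims[2], conditionMessage(e)),
                        "litcohesion_numerical_error")
                })
  d <- s$d[seq_len(k)]
  vectors <- sweep(s$v[, seq_len(k), drop = FALSE], 2L, d, "*")
  rownames(vectors) <- tgm$genes
  new_concept_space(genes = tgm$genes, k = k, d = d, vectors = vectors,
                    params = list(weighting = tgm$weighting, n_terms = dims[1]))
}

#' Build a concept space straight from a corpus
#'
#' Convenience wrapper: [build_term_matrix()] then [log_entropy_weight()]
#' then [truncated_svd()].
#'
#' @inheritParams build_term_matrix
#' @inheritParams truncated_svd
#' @return a `concept_space`.
#' @export
concept_space_from_corpus <- function(corpus, k = 500, min_gene_frequency = 2,
                                      stopwords = default_stopwords(), seed = NULL) {
  tgm <- build_term_matrix(corpus, min_gene_frequency, stopwords)
  suppressWarnings(truncated_svd(log_entropy_weight(tgm), k = k, seed = seed))
}

space_norms <- function(space, genes) {
  v <- space$vectors[genes, , drop = FALSE]
  nrm <- sqrt(rowSums(v^2))
  zero <- nrm == 0
  if (any(zero)) {
    abort(sprintf("gene '%s' has a zero-norm concept vector; similarity undefined",
                  genes[which(zero)[1]]),
          "litcohesion_similarity_error")
  }
  v / nrm
}

#' Cosine similarity between two genes in the concept space
#'
#' @param space a `concept_space`.
#' @param gene_a,gene_b gene ids present in the space.
#' @return cosine in `[-1, 1]`.
#' @export
cosine <- function(space, gene_a, gene_b) {
  miss <- setdiff(c(gene_a, gene_b), space$genes)
  if (length(miss)) {
    abort(sprintf("gene '%s' is not in the concept space", miss[1]),
          "litcohesion_lookup_error")
  }
  v <- space_norms(space, c(gene_a, gene_b))
  min(1, max(-1, sum(v[1, ] * v[2, ])))
}

#' All pairwise cosines within a gene set
#'
#' Genes absent from the corpus universe are dropped and reported through the
#' coverage fraction.
#'
#' @param space a `concept_space`.
#' @param gene_set character vector of gene ids.
#' @return list with `cosines` (one value per unordered in-corpus pair),
#'   `coverage` (fraction of unique input genes found), `genes_used`.
#' @export
pairwise_cosines <- function(space, gene_set) {
  gene_set <- unique(gene_set)
  present <- intersect(gene_set, space$genes)
  coverage <- length(present) / length(gene_set)
  if (length(present) < 2) {
    abort("fewer than 2 genes are in the corpus; cohesion undefined",
          "litcohesion_cohesion_undefined_error")
  }
  v <- space_norms(space, present)
  cc <- tcrossprod(v)
  list(cosines = cc[upper.tri(cc)], coverage = coverage, genes_used = present)
}
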