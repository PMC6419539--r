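## Synthetic-data generator: corpora with planted functional modules,
## strain-panel expression with signal (exonic) and noise (intronic) probes,
## and corrupted gold standards. Every downstream stage can therefore be
## validated against known ground truth.

#' Configuration for the synthetic-data generator
#'
#' The defaults describe the stated benchmark world: 500 genes, four planted
#' 50-gene modules, a 2000-term vocabulary with 100 module-private terms per
#' module, 100-token documents with 75% module-vocabulary tokens for module
#' genes, a 40-strain panel, and 3 signal ("exon") plus 3 noise ("intron")
#' probes per module.
#'
#' @param n_genes number of genes in the universe.
#' @param n_modules number of planted functional modules.
#' @param module_size genes per module.
#' @param vocab_size total vocabulary size.
#' @param module_vocab_size module-private terms per module.
#' @param doc_length_mean expected tokens per gene-document (Poisson mean,
#'   truncated at >= 1).
#' @param signal_term_fraction probability that a module gene's token is
#'   drawn from its module-private vocabulary.
#' @param n_strains strains in the expression panel.
#' @param n_signal_probes_per_module signal ("exon") probes per module.
#' @param n_noise_probes noise ("intron") probes per module; they target the
#'   same member genes as the signal probes but carry no signal.
#' @param probe_noise_sd SD of probe-level noise on top of the unit-variance
#'   latent module activity.
#' @param expression_noise_sd SD of per-gene residual ("loading") noise.
#' @param gold_dropout probability a true module gene is omitted from a gold
#'   standard.
#' @param gold_contamination contaminant genes added to a gold standard, as a
#'   fraction of module size (`round(gold_contamination * module_size)`).
#' @param seed RNG seed.
#' @return validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 500, n_modules = 4, module_size = 50,
                             vocab_size = 2000, module_vocab_size = 100,
                             doc_length_mean = 100, signal_term_fraction = 0.75,
                             n_strains = 40, n_signal_probes_per_module = 3,
                             n_noise_probes = 3, probe_noise_sd = 0.2,
                             expression_noise_sd = 0.2, gold_dropout = 0.1,
                             gold_contamination = 0.1, seed = 1L) {
  cfg <- list(n_genes = n_genes, n_modules = n_modules, module_size = module_size,
              vocab_size = vocab_size, module_vocab_size = module_vocab_size,
              doc_length_mean = doc_length_mean,
              signal_term_fraction = signal_term_fraction, n_strains = n_strains,
              n_signal_probes_per_module = n_signal_probes_per_module,
              n_noise_probes = n_noise_probes, probe_noise_sd = probe_noise_sd,
              expression_noise_sd = expression_noise_sd, gold_dropout = gold_dropout,
              gold_contamination = gold_contamination, seed = as.integer(seed))
  counts <- c("n_genes", "n_modules", "module_size", "vocab_size",
              "module_vocab_size", "n_strains", "n_signal_probes_per_module",
              "n_noise_probes")
  for (nm in counts) {
    if (!is_count(cfg[[nm]])) {
      abort(sprintf("invalid config: %s must be an integer >= 1", nm),
            "litcohesion_config_error")
    }
  }
  for (nm in c("signal_term_fraction", "gold_dropout")) {
    if (!is_prob(cfg[[nm]])) {
      abort(sprintf("invalid config: %s must be a probability in [0,1]", nm),
            "litcohesion_config_error")
    }
  }
  for (nm in c("doc_length_mean", "probe_noise_sd", "expression_noise_sd",
               "gold_contamination")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0) {
      abort(sprintf("invalid config: %s must be non-negative", nm),
            "litcohesion_config_error")
    }
  }
  if (cfg$n_modules * cfg$module_size > cfg$n_genes) {
    abort("invalid config: n_modules * module_size must be <= n_genes",
          "litcohesion_config_error")
  }
  if (cfg$module_vocab_size * cfg$n_modules > cfg$vocab_size) {
    abort("invalid config: module_vocab_size * n_modules must be <= vocab_size",
          "litcohesion_config_error")
  }
  if (cfg$n_signal_probes_per_module > cfg$module_size ||
      cfg$n_noise_probes > cfg$module_size) {
    abort("invalid config: probes per module must be <= module_size",
          "litcohesion_config_error")
  }
  structure(cfg, class = "synthetic_config")
}

module_ids <- function(n) sprintf("module%02d", seq_len(n))

#' Generate a synthetic literature corpus with planted modules
#'
#' Builds one document per gene. Tokens of module genes are a mixture: with
#' probability `signal_term_fraction` a token is drawn uniformly from the
#' module's private vocabulary, otherwise from the shared background
#' vocabulary. Background genes use background terms only. Each document is
#' split across two synthetic PMIDs so the gene2pubmed round trip is
#' non-trivial.
#'
#' @param config a [synthetic_config()].
#' @return list with `corpus` (a `gene_corpus`) and `truth` (a `module_truth`
#'   list: module membership, latent strain activity, probe map, gene
#'   universe, and the generating config).
#' @export
generate_corpus <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  mods <- module_ids(config$n_modules)
  members <- split(genes[seq_len(config$n_modules * config$module_size)],
                   rep(mods, each = config$module_size))
  members <- members[mods]
  module_vocab <- lapply(seq_len(config$n_modules), function(m) {
    sprintf("mod%02dterm%03d", m, seq_len(config$module_vocab_size))
  })
  names(module_vocab) <- mods
  n_bg <- config$vocab_size - config$n_modules * config$module_vocab_size
  background_vocab <- sprintf("bgterm%05d", seq_len(max(n_bg, 1L)))

  gene_module <- rep(NA_character_, config$n_genes)
  names(gene_module) <- genes
  for (m in mods) gene_module[members[[m]]] <- m

  out <- with_seed(derive_seed(config$seed, "corpus"), {
    docs <- character(config$n_genes)
    for (i in seq_len(config$n_genes)) {
      len <- max(1L, stats::rpois(1L, config$doc_length_mean))
      m <- gene_module[i]
      if (!is.na(m) && config$signal_term_fraction > 0) {
        n_sig <- stats::rbinom(1L, len, config$signal_term_fraction)
        toks <- c(sample(module_vocab[[m]], n_sig, replace = TRUE),
                  sample(background_vocab, len - n_sig, replace = TRUE))
        toks <- sample(toks)
      } else {
        toks <- sample(background_vocab, len, replace = TRUE)
      }
      docs[i] <- paste(toks, collapse = " ")
    }
    ## latent module activity over strains, fixed at corpus birth so the
    ## whole ground truth lives in one object
    activity <- matrix(stats::rnorm(config$n_strains * config$n_modules),
                       nrow = config$n_strains, dimnames = list(NULL, mods))
    list(docs = docs, activity = activity)
  })

  ## two PMIDs per gene: split the document at the midpoint token
  pmids <- lapply(seq_len(config$n_genes), function(i) 100000L + c(2L * i - 1L, 2L * i))
  names(pmids) <- genes
  pmid_text <- character(0)
  documents <- out$docs
  names(documents) <- genes
  for (i in seq_len(config$n_genes)) {
    toks <- strsplit(documents[i], " ", fixed = TRUE)[[1]]
    half <- ceiling(length(toks) / 2)
    pmid_text[as.character(pmids[[i]][1])] <- paste(toks[seq_len(half)], collapse = " ")
    pmid_text[as.character(pmids[[i]][2])] <-
      if (length(toks) > half) paste(toks[(half + 1):length(toks)], collapse = " ") else ""
  }
  pmid_text <- pmid_text[nzchar(pmid_text)]
  pmids <- lapply(pmids, function(p) p[as.character(p) %in% names(pmid_text)])

  probes <- do.call(rbind, lapply(mods, function(m) {
    sig_genes <- members[[m]][seq_len(config$n_signal_probes_per_module)]
    noi_genes <- members[[m]][seq_len(config$n_noise_probes)]
    rbind(
      data.frame(probe_id = sprintf("%s_exon%02d", m, seq_along(sig_genes)),
                 gene_id = sig_genes, region = "exon", module = m,
                 stringsAsFactors = FALSE),
      data.frame(probe_id = sprintf("%s_intron%02d", m, seq_along(noi_genes)),
                 gene_id = noi_genes, region = "intron", module = "noise",
                 stringsAsFactors = FALSE)
    )
  }))

  corpus <- gene_corpus(documents = documents, pmids = pmids, pmid_text = pmid_text)
  truth <- structure(list(modules = members, activity = out$activity,
                          probes = probes, genes = genes,
                          gene_module = gene_module, config = config),
                     class = "module_truth")
  list(corpus = corpus, truth = truth)
}

#' Generate a synthetic strain-panel expression dataset
#'
#' A signal ("exon") probe for gene g in module m reports the module's latent
#' strain activity plus per-gene loading noise (`expression_noise_sd`) and
#' probe-level noise (`probe_noise_sd`). A noise ("intron") probe is i.i.d.
#' standard normal. Every gene additionally gets one gene-level row (region
#' `"gene"`): module genes track their module activity, background genes are
#' pure noise, so co-expression windows can recover module members.
#'
#' @param config the [synthetic_config()] used to make `truth`.
#' @param truth the `module_truth` from [generate_corpus()].
#' @return an `expression_dataset` (see [expression_dataset()]).
#' @export
generate_expression <- function(config, truth) {
  if (!inherits(truth, "module_truth")) {
    abort("truth must be a module_truth from generate_corpus()", "litcohesion_consistency_error")
  }
  if (!identical(unclass(truth$config), unclass(config))) {
    abort("config does not match the config that produced truth", "litcohesion_consistency_error")
  }
  ns <- config$n_strains
  strains <- sprintf("strain%03d", seq_len(ns))
  with_seed(derive_seed(config$seed, "expression"), {
    ## per-gene loading noise, shared by a gene's signal probes and gene row
    loading <- matrix(stats::rnorm(length(truth$genes) * ns, sd = config$expression_noise_sd),
                      nrow = length(truth$genes), dimnames = list(truth$genes, strains))
    probe_rows <- t(vapply(seq_len(nrow(truth$probes)), function(i) {
      p <- truth$probes[i, ]
      if (p$region == "exon") {
        truth$activity[, p$module] + loading[p$gene_id, ] +
          stats::rnorm(ns, sd = config$probe_noise_sd)
      } else {
        stats::rnorm(ns)
      }
    }, numeric(ns)))
    rownames(probe_rows) <- truth$probes$probe_id
    gene_rows <- t(vapply(truth$genes, function(g) {
      m <- truth$gene_module[g]
      if (!is.na(m)) truth$activity[, m] + loading[g, ] else stats::rnorm(ns)
    }, numeric(ns)))
    rownames(gene_rows) <- paste0("g_", truth$genes)
    mat <- rbind(probe_rows, gene_rows)
    colnames(mat) <- strains
    annotation <- rbind(
      truth$probes[, c("probe_id", "gene_id", "region")],
      data.frame(probe_id = rownames(gene_rows), gene_id = truth$genes,
                 region = "gene", stringsAsFactors = FALSE)
    )
    expression_dataset(mat, annotation)
  })
}

#' Generate a corrupted gold standard for one planted module
#'
#' Members are retained independently with probability `1 - gold_dropout`;
#' `round(gold_contamination * module_size)` contaminant genes sampled
#' uniformly from non-members are added.
#'
#' @param truth a `module_truth`.
#' @param module_id module to corrupt.
#' @param gold_dropout,gold_contamination corruption parameters (default from
#'   the generating config).
#' @param seed RNG seed (default derived from the config seed and module id).
#' @return character vector of gene ids.
#' @export
generate_gold_standard <- function(truth, module_id,
                                   gold_dropout = truth$config$gold_dropout,
                                   gold_contamination = truth$config$gold_contamination,
                                   seed = derive_seed(truth$config$seed, paste0("gold_", module_id))) {
  if (!module_id %in% names(truth$modules)) {
    abort(sprintf("unknown module_id '%s'", module_id), "litcohesion_lookup_error")
  }
  members <- truth$modules[[module_id]]
  non_members <- setdiff(truth$genes, members)
  with_seed(seed, {
    kept <- members[stats::runif(length(members)) > gold_dropout]
    n_cont <- round(gold_contamination * length(members))
    cont <- if (n_cont > 0) sample(non_members, min(n_cont, length(non_members))) else character(0)
    c(kept, cont)
  })
}

#' Write a full synthetic dataset to disk
#'
#' Writes the corpus (gene2pubmed TSV + abstracts TSV), expression matrix and
#' probe annotation TSVs, per-module gold standards and exact module
#' categories as GMT, and the ground truth as JSON. These are exactly the
#' file formats consumed by [run_workflow()].
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, a named list of the paths written.
#' @export
write_synthetic_data <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_corpus(config)
  ds <- generate_expression(config, gen$truth)
  paths <- list(
    gene2pubmed = file.path(dir, "gene2pubmed.tsv"),
    abstracts = file.path(dir, "abstracts.tsv"),
    expression = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "probes.tsv"),
    gold = file.path(dir, "gold_standards.gmt"),
    categories = file.path(dir, "categories.gmt"),
    truth = file.path(dir, "truth.json")
  )
  g2p <- unlist(lapply(names(gen$corpus$pmids), function(g) {
    sprintf("10090\t%s\t%d", g, gen$corpus$pmids[[g]])
  }))
  writeLines(c("#tax_id\tGeneID\tPubMed_ID", g2p), paths$gene2pubmed)
  writeLines(sprintf("%s\t%s", names(gen$corpus$pmid_text), gen$corpus$pmid_text),
             paths$abstracts)
  write_expression_matrix(ds$matrix, paths$expression)
  write_probe_annotation(ds$annotation, paths$annotation)
  golds <- lapply(names(gen$truth$modules), function(m) generate_gold_standard(gen$truth, m))
  names(golds) <- paste0("gold_", names(gen$truth$modules))
  write_gmt(golds, paths$gold, descriptions = "synthetic corrupted module")
  write_gmt(gen$truth$modules, paths$categories, descriptions = "synthetic planted module")
  jsonlite::write_json(
    list(modules = gen$truth$modules,
         probes = gen$truth$probes,
         config = unclass(config)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
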