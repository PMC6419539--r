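## Orchestration of the full workflow: concept space -> per-probe windows ->
## LPv + gold-standard F + enrichment -> dataset-level correlations, probe
## classification and report.

#' Smallest window size maximizing F
#'
#' @param sizes numeric window sizes.
#' @param f F-measures, same length.
#' @return the smallest size attaining the maximum finite F.
#' @export
peak_window <- function(sizes, f) {
  ok <- is.finite(f)
  if (!any(ok)) abort("all F values are undefined", "litcohesion_config_error")
  s <- sizes[ok]; f <- f[ok]
  min(s[f == max(f)])
}

#' Evaluate a set of seed probes end to end
#'
#' For every seed probe: nested co-expression windows, LPv per window,
#' precision/recall/F per gold standard per window, and enrichment p per
#' category per window (BH-adjusted within each probe x window). Dataset
#' summaries: LPv-F Pearson r per window size (each probe scored against its
#' matched gold standard), exon-vs-intron rank-sum p, probe quality flags,
#' and per-probe peak windows.
#'
#' @param space a `concept_space`.
#' @param threshold a `background_threshold`.
#' @param dataset an `expression_dataset`.
#' @param seed_probes probe ids to evaluate.
#' @param golds named list of gold-standard gene sets (may be empty).
#' @param categories named list of annotation-category gene sets (may be
#'   empty).
#' @param sizes strictly increasing window sizes.
#' @param config an [lpv_config()]; per-probe/window LPv seeds are derived
#'   from `config$seed`.
#' @param rank_by window ranking mode, see [top_window()].
#' @param probe_gold optional named character vector probe -> gold name used
#'   for the matched LPv-F correlation; defaults to the first gold for all
#'   probes.
#' @param reference_size window size for rank-sum comparison and probe
#'   classification (default: the first size).
#' @return list with `records` (LPv per probe x window), `gold_scores`
#'   (P/R/F per probe x window x gold), `enrichment` (p and BH-adjusted p
#'   per probe x window x category), and `summary`.
#' @export
evaluate_probes <- function(space, threshold, dataset, seed_probes, golds = list(),
                            categories = list(), sizes = seq(100, 1000, by = 100),
                            config = lpv_config(), rank_by = "abs",
                            probe_gold = NULL, reference_size = sizes[1]) {
  universe <- intersect(space$genes, unique(dataset$annotation$gene_id))
  records <- list(); gold_scores <- list(); enrich <- list()
  for (pr in seed_probes) {
    windows <- window_series(dataset, pr, sizes = sizes, rank_by = rank_by)
    region <- dataset$annotation$region[match(pr, dataset$annotation$probe_id)]
    for (s in names(windows)) {
      win <- windows[[s]]
      cfg <- config
      cfg$seed <- derive_seed(config$seed, paste0("lpv_", pr, "_", s))
      res <- lpv(space, win, threshold, cfg)
      records[[length(records) + 1L]] <- data.frame(
        probe_id = pr, region = region, size = as.integer(s),
        n_window = length(win), A = res$A, B = res$B, C = res$C, D = res$D,
        p = res$p, neg_log10 = res$neg_log10, coverage = res$coverage,
        significant = res$significant, stringsAsFactors = FALSE)
      for (gn in names(golds)) {
        prf <- precision_recall_f(win, golds[[gn]])
        gold_scores[[length(gold_scores) + 1L]] <- data.frame(
          probe_id = pr, region = region, size = as.integer(s), gold = gn,
          precision = prf[["precision"]], recall = prf[["recall"]],
          F = prf[["F"]], stringsAsFactors = FALSE)
      }
      if (length(categories)) {
        ps <- vapply(categories, function(cat) enrichment_pvalue(win, cat, universe),
                     numeric(1))
        enrich[[length(enrich) + 1L]] <- data.frame(
          probe_id = pr, region = region, size = as.integer(s),
          category = names(categories), p = unname(ps),
          p_adjusted = bh_adjust(unname(ps)), stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, records)
  gold_scores <- if (length(gold_scores)) do.call(rbind, gold_scores) else NULL
  enrich <- if (length(enrich)) do.call(rbind, enrich) else NULL

  summary <- list(threshold_T = threshold$T, reference_size = reference_size)

  if (!is.null(gold_scores)) {
    if (is.null(probe_gold)) {
      probe_gold <- stats::setNames(rep(names(golds)[1], length(seed_probes)), seed_probes)
    }
    matched <- gold_scores[gold_scores$gold == probe_gold[gold_scores$probe_id], ]
    lpv_f_r <- lapply(sizes, function(s) {
      rec <- records[records$size == s, ]
      ms <- matched[matched$size == s, ]
      f <- ms$F[match(rec$probe_id, ms$probe_id)]
      tryCatch(correlate_lpv_f(rec$neg_log10, f), litcohesion_error = function(e) NA_real_)
    })
    summary$lpv_f_r <- stats::setNames(unlist(lpv_f_r), as.character(sizes))
    peak <- vapply(unique(matched$probe_id), function(pr) {
      mm <- matched[matched$probe_id == pr, ]
      peak_window(mm$size, mm$F)
    }, numeric(1))
    summary$peak_window <- peak
    summary$mean_peak_window <- mean(peak)
  } else {
    log_stage("benchmark", "no gold standards supplied; F and correlation stages skipped")
  }

  ref <- records[records$size == reference_size, ]
  exon <- ref$neg_log10[ref$region == "exon"]
  intron <- ref$neg_log10[ref$region == "intron"]
  if (length(exon) >= 2 && length(intron) >= 2) {
    summary$rank_sum_p <- rank_sum_compare(exon, intron)
  }
  if (nrow(ref) >= 2) {
    flags <- classify_probes(stats::setNames(ref$neg_log10, ref$probe_id))
    summary$quality <- flags
    summary$quality_threshold <- attr(flags, "threshold")
  }
  list(records = records, gold_scores = gold_scores, enrichment = enrich,
       summary = summary)
}

#' Default synthetic benchmark configuration
#'
#' The stated benchmark world: four planted 50-gene modules, 3 signal + 3
#' noise probes each, 40 strains (see [synthetic_config()] for the rest).
#'
#' @param seed RNG seed.
#' @return a `synthetic_config`.
#' @export
default_benchmark_config <- function(seed = 1L) synthetic_config(seed = seed)

#' Run the complete synthetic benchmark in memory
#'
#' Generates a corpus with planted modules, strain-panel expression, one
#' corrupted gold standard per module, builds the concept space and the
#' background threshold, and evaluates every assay probe. Each probe is
#' matched to the gold standard of its target gene's module.
#'
#' @param syn_config a [synthetic_config()].
#' @param config an [lpv_config()].
#' @param sizes window sizes (default `c(module_size, 100, 200)`).
#' @param k concept-space rank passed to [concept_space_from_corpus()].
#' @return the [evaluate_probes()] result plus `truth`.
#' @export
run_synthetic_benchmark <- function(syn_config = default_benchmark_config(),
                                    config = lpv_config(seed = syn_config$seed),
                                    sizes = NULL, k = 500) {
  gen <- generate_corpus(syn_config)
  ds <- generate_expression(syn_config, gen$truth)
  space <- concept_space_from_corpus(gen$corpus, k = k)
  threshold <- estimate_threshold(space, config)
  golds <- lapply(names(gen$truth$modules), function(m) generate_gold_standard(gen$truth, m))
  names(golds) <- paste0("gold_", names(gen$truth$modules))
  if (is.null(sizes)) sizes <- unique(c(syn_config$module_size, 100, 200))
  probes <- gen$truth$probes
  gene_mod <- gen$truth$gene_module
  probe_gold <- stats::setNames(paste0("gold_", gene_mod[probes$gene_id]), probes$probe_id)
  out <- evaluate_probes(space, threshold, ds, probes$probe_id,
                         golds = golds, categories = gen$truth$modules,
                         sizes = sizes, config = config,
                         probe_gold = probe_gold,
                         reference_size = syn_config$module_size)
  out$truth <- gen$truth
  out
}

hash_file <- function(path) unname(tools::md5sum(path))

#' Run the file-based workflow from a single configuration
#'
#' Configuration fields: `gene2pubmed`, `abstracts` (or `space`, a concept
#' space archive stem), `expression`, `annotation`, `gold` (GMT, optional),
#' `categories` (GMT, optional), `sizes`, `rank_by`, `reference_size`,
#' `lpv` (a list of [lpv_config()] fields), `seed_probes` (optional; default
#' all exon/intron probes), `out` (output directory), `rank` (concept count).
#' All outputs are written to `out`: `lpv_records.tsv`, `gold_scores.tsv`,
#' `enrichment.tsv`, `summary.json`, and `manifest.json` (config echo, input
#' hashes, timestamp — the only file with a timestamp).
#'
#' @param config a named list or path to a JSON file with those fields.
#' @return invisibly, the [evaluate_probes()] result.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stage <- "config"
  result <- tryCatch({
    for (f in c("expression", "annotation")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        abort(sprintf("config field '%s' must name an existing file", f),
              "litcohesion_config_error")
      }
    }
    lcfg <- do.call(lpv_config, as.list(config$lpv %||% list()))
    sizes <- as.integer(config$sizes %||% seq(100, 1000, by = 100))

    stage <- "space"
    if (!is.null(config$space)) {
      space <- read_concept_space(config$space)
    } else {
      log_stage("space", "building concept space from ", config$gene2pubmed)
      g2p <- read_gene2pubmed(config$gene2pubmed)
      txt <- read_abstracts(config$abstracts)
      corpus <- build_documents(g2p, txt)
      space <- concept_space_from_corpus(corpus, k = config$rank %||% 500,
                                         min_gene_frequency = config$min_gene_freq %||% 2)
    }
    stage <- "threshold"
    threshold <- estimate_threshold(space, lcfg)
    log_stage("threshold", sprintf("T = %.4f (%s)", threshold$T, threshold$mode))

    stage <- "expression"
    mat <- read_expression_matrix(config$expression)
    annot <- read_probe_annotation(config$annotation)
    ds <- expression_dataset(mat, annot)
    seed_probes <- config$seed_probes %||%
      annot$probe_id[annot$region %in% c("exon", "intron")]

    golds <- if (!is.null(config$gold)) read_gmt(config$gold) else list()
    categories <- if (!is.null(config$categories)) read_gmt(config$categories) else list()

    stage <- "benchmark"
    evaluate_probes(space, threshold, ds, seed_probes, golds = golds,
                    categories = categories, sizes = sizes, config = lcfg,
                    rank_by = config$rank_by %||% "abs",
                    reference_size = config$reference_size %||% sizes[1])
  }, litcohesion_error = function(e) {
    out_dir <- config$out %||% "."
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(sprintf("stage: %s\n%s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(sprintf("workflow failed at stage '%s': %s", stage, conditionMessage(e)),
          "litcohesion_pipeline_error")
  })

  out_dir <- config$out %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  write_tsv(result$records, "lpv_records.tsv")
  write_tsv(result$gold_scores, "gold_scores.tsv")
  write_tsv(result$enrichment, "enrichment.tsv")
  summ <- result$summary
  summ$quality <- as.list(summ$quality)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  inputs <- Filter(function(p) is.character(p) && length(p) == 1 && file.exists(p),
                   config[c("gene2pubmed", "abstracts", "expression", "annotation",
                            "gold", "categories")])
  manifest <- list(config = config,
                   input_md5 = lapply(inputs, hash_file),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log_stage("done", "outputs written to ", out_dir)
  invisible(result)
}
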