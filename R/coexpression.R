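## Probe-seeded co-expression windows: Pearson correlation of every probe to
## a seed probe over a strain panel, collapse to gene level, and nested
## top-N windows.

#' Construct an expression dataset
#'
#' @param mat numeric matrix, probes x strains, with rownames and colnames;
#'   `NA` marks missing values.
#' @param annotation data.frame with columns `probe_id`, `gene_id`, `region`
#'   covering every row of `mat`; region is `exon`/`intron` for assay probes
#'   and `gene` for gene-level rows.
#' @param min_present minimum fraction of non-missing strains for a probe to
#'   be usable (default 0.8).
#' @return an `expression_dataset`: `matrix`, `annotation`, `usable` flags.
#' @export
expression_dataset <- function(mat, annotation, min_present = 0.8) {
  if (ncol(mat) < 3) abort("expression matrix needs >= 3 strains", "litcohesion_config_error")
  if (is.null(rownames(mat))) abort("expression matrix needs probe rownames", "litcohesion_config_error")
  if (!all(c("probe_id", "gene_id", "region") %in% names(annotation))) {
    abort("annotation must have probe_id, gene_id, region", "litcohesion_config_error")
  }
  missing_annot <- setdiff(rownames(mat), annotation$probe_id)
  if (length(missing_annot)) {
    abort(sprintf("probe '%s' has no annotation", missing_annot[1]),
          "litcohesion_config_error")
  }
  bad_region <- setdiff(unique(annotation$region), c("exon", "intron", "gene"))
  if (length(bad_region)) {
    abort(sprintf("unknown region label '%s'", bad_region[1]), "litcohesion_config_error")
  }
  annotation <- annotation[match(rownames(mat), annotation$probe_id), ]
  usable <- rowMeans(!is.na(mat)) >= min_present
  structure(list(matrix = mat, annotation = annotation,
                 usable = stats::setNames(usable, rownames(mat))),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d probes x %d strains (%d usable)\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$usable)))
  invisible(x)
}

probe_gene <- function(dataset, probe) {
  dataset$annotation$gene_id[match(probe, dataset$annotation$probe_id)]
}

#' Pearson correlation of every probe to a seed probe
#'
#' Correlations use pairwise-complete strains; probes with fewer than 3
#' complete pairs or zero variance on the complete subset are excluded (a
#' count is logged).
#'
#' @param dataset an `expression_dataset`.
#' @param seed_probe probe id of the seed.
#' @return named numeric vector of correlations (seed excluded).
#' @export
probe_correlations <- function(dataset, seed_probe) {
  if (!seed_probe %in% rownames(dataset$matrix)) {
    abort(sprintf("seed probe '%s' not in dataset", seed_probe), "litcohesion_lookup_error")
  }
  if (!dataset$usable[seed_probe]) {
    abort(sprintf("seed probe '%s' is unusable (too many missing values)", seed_probe),
          "litcohesion_config_error")
  }
  x <- dataset$matrix[seed_probe, ]
  others <- setdiff(rownames(dataset$matrix)[dataset$usable], seed_probe)
  M <- dataset$matrix[others, , drop = FALSE]
  ok <- !is.na(x)
  n_complete <- as.vector((!is.na(M)) %*% as.numeric(ok))
  r <- suppressWarnings(as.vector(stats::cor(x, t(M), use = "pairwise.complete.obs")))
  names(r) <- others
  bad <- n_complete < 3 | is.na(r)
  if (any(bad)) log_stage("coexpress", sum(bad), " probe(s) excluded (undefined correlation)")
  r[!bad]
}

#' Collapse probe-level correlations to gene level
#'
#' Per gene, keeps the probe with maximal absolute correlation (ties broken
#' by smaller probe id); the seed probe's own target gene is dropped.
#'
#' @param correlations named vector from [probe_correlations()].
#' @param annotation probe annotation data.frame.
#' @param exclude_gene gene id to drop (the seed's target), or NULL.
#' @return data.frame `gene_id`, `r`, `probe_id`, ordered by |r| descending
#'   with ties by gene id ascending.
#' @export
collapse_to_genes <- function(correlations, annotation, exclude_gene = NULL) {
  df <- data.frame(probe_id = names(correlations), r = unname(correlations),
                   stringsAsFactors = FALSE)
  df$gene_id <- annotation$gene_id[match(df$probe_id, annotation$probe_id)]
  if (!is.null(exclude_gene)) df <- df[!df$gene_id %in% exclude_gene, ]
  df <- df[order(df$gene_id, -abs(df$r), df$probe_id, method = "radix"), ]
  df <- df[!duplicated(df$gene_id), ]
  df <- df[order(-abs(df$r), df$gene_id, method = "radix"), ]
  rownames(df) <- NULL
  df[, c("gene_id", "r", "probe_id")]
}

#' Top-N co-expression window
#'
#' @param gene_correlations data.frame from [collapse_to_genes()].
#' @param size window size.
#' @param rank_by `"abs"` (default; two-sided connectivity) or `"positive"`.
#' @return character vector of gene ids (the window).
#' @export
top_window <- function(gene_correlations, size, rank_by = c("abs", "positive")) {
  rank_by <- match.arg(rank_by)
  if (!is_count(size)) abort("size must be an integer >= 1", "litcohesion_config_error")
  key <- if (rank_by == "abs") abs(gene_correlations$r) else gene_correlations$r
  ord <- order(-key, gene_correlations$gene_id, method = "radix")
  if (size > nrow(gene_correlations)) {
    warning(sprintf("requested window of %d but only %d genes available", size,
                    nrow(gene_correlations)))
    size <- nrow(gene_correlations)
  }
  gene_correlations$gene_id[ord[seq_len(size)]]
}

#' Nested series of co-expression windows for one seed probe
#'
#' Computes the gene-level ranking once and cuts it at each requested size,
#' so smaller windows are always subsets of larger ones.
#'
#' @param dataset an `expression_dataset`.
#' @param seed_probe seed probe id.
#' @param sizes strictly increasing window sizes (default 100..1000 by 100).
#' @param rank_by see [top_window()].
#' @return named list of gene-id vectors, one per size.
#' @export
window_series <- function(dataset, seed_probe, sizes = seq(100, 1000, by = 100),
                          rank_by = c("abs", "positive")) {
  rank_by <- match.arg(rank_by)
  if (any(diff(sizes) <= 0)) {
    abort("window sizes must be strictly increasing", "litcohesion_config_error")
  }
  corr <- probe_correlations(dataset, seed_probe)
  gc <- collapse_to_genes(corr, dataset$annotation,
                          exclude_gene = probe_gene(dataset, seed_probe))
  out <- lapply(sizes, function(s) top_window(gc, s, rank_by))
  names(out) <- as.character(sizes)
  out
}
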