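## Readers and writers for the plain-text interchange formats used across the
## workflow: gene2pubmed-dialect TSV, PMID->abstract TSV, expression matrix
## TSV, probe annotation TSV, GMT gene sets, and the concept-space archive.

#' Read a gene2pubmed-style TSV into a gene -> PMID-set map
#'
#' Expects at least three tab-separated columns (tax_id, GeneID, PubMed_ID);
#' lines starting with `#` are treated as comments. Duplicate (gene, pmid)
#' rows collapse to one entry.
#'
#' @param path file path.
#' @return named list mapping GeneID (character) to sorted integer PMIDs.
#' @export
read_gene2pubmed <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(keep)) return(structure(list(), names = character(0)))
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3)) {
    abort(sprintf("line %d: expected >= 3 tab-separated columns", idx[which(ncols < 3)[1]]),
          "litcohesion_parse_error")
  }
  gene <- vapply(parts, `[[`, "", 2L)
  pmid_chr <- vapply(parts, `[[`, "", 3L)
  bad <- !grepl("^[0-9]+$", pmid_chr)
  if (any(bad)) {
    abort(sprintf("line %d: PMID '%s' is not an integer", idx[which(bad)[1]], pmid_chr[which(bad)[1]]),
          "litcohesion_parse_error")
  }
  pmid <- as.integer(pmid_chr)
  out <- lapply(split(pmid, gene), function(p) sort(unique(p)))
  ## preserve first-appearance order of genes
  out[unique(gene)]
}

#' Read a PMID-to-text TSV
#'
#' Format: `pmid<TAB>text`, one record per line; `#` comment lines allowed.
#' Only the first tab separates the fields, so abstract text may contain
#' further tabs.
#'
#' @param path file path.
#' @return named character vector, names are PMIDs.
#' @export
read_abstracts <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(structure(character(0), names = character(0)))
  tab <- regexpr("\t", lines, fixed = TRUE)
  if (any(tab < 0)) {
    abort("abstract file has a line without a tab separator", "litcohesion_parse_error")
  }
  pmid <- substr(lines, 1L, tab - 1L)
  text <- substr(lines, tab + 1L, nchar(lines))
  structure(text, names = pmid)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (`name<TAB>description<TAB>gene1<TAB>gene2...`).
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of descriptions (recycled).
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Read an expression matrix TSV
#'
#' First column `probe_id`, remaining columns one per strain; empty cells are
#' missing values.
#'
#' @param path file path.
#' @return numeric matrix, probes in rows (rownames), strains in columns.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  mat <- as.matrix(df[, -1, drop = FALSE])
  mat[mat == ""] <- NA
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1]]
  mat
}

#' Write an expression matrix TSV
#'
#' @param mat numeric matrix with probe rownames and strain colnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
}

#' Read a probe annotation TSV
#'
#' Columns `probe_id`, `gene_id`, `region`; region is `exon` or `intron` for
#' assay probes, `gene` for gene-level summary rows.
#'
#' @param path file path.
#' @return data.frame with those three character columns.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("probe_id", "gene_id", "region")
  if (!all(need %in% names(df))) {
    abort("probe annotation must have columns probe_id, gene_id, region",
          "litcohesion_parse_error")
  }
  df[, need]
}

#' Write a probe annotation TSV
#' @param annotation data.frame with probe_id, gene_id, region.
#' @param path output path.
#' @export
write_probe_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a concept space as a portable text archive
#'
#' Writes `<path>.tsv` (gene id column plus k concept coordinates) and
#' `<path>.json` (rank, singular values, build parameters).
#'
#' @param space a `concept_space`.
#' @param path path stem (no extension).
#' @export
write_concept_space <- function(space, path) {
  df <- data.frame(gene_id = space$genes, space$vectors, check.names = FALSE)
  colnames(df) <- c("gene_id", paste0("c", seq_len(space$k)))
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(k = space$k, singular_values = space$d, params = space$params %||% list())
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

#' Read a concept space archive written by [write_concept_space()]
#' @param path path stem (no extension).
#' @return a `concept_space`.
#' @export
read_concept_space <- function(path) {
  df <- utils::read.delim(paste0(path, ".tsv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vec <- as.matrix(df[, -1, drop = FALSE])
  rownames(vec) <- df[[1]]
  new_concept_space(genes = df[[1]], k = meta$k, d = as.numeric(meta$singular_values),
                    vectors = vec, params = meta$params)
}
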