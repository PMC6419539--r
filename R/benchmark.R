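## Benchmarking: gold-standard precision/recall/F, hypergeometric category
## enrichment with BH adjustment, LPv-vs-F correlation, exon/intron rank-sum
## separation, and the mean-neg-log10 probe quality classifier.

#' Precision, recall and F-measure of a window against a gold standard
#'
#' F is the balanced (F1) harmonic mean `2PR/(P+R)`, defined as 0 when the
#' overlap is empty.
#'
#' @param window character vector of gene ids (non-empty).
#' @param gold character vector of gold-standard gene ids (non-empty).
#' @return named numeric vector `precision`, `recall`, `F`.
#' @export
precision_recall_f <- function(window, gold) {
  window <- unique(window); gold <- unique(gold)
  if (!length(window) || !length(gold)) {
    abort("window and gold standard must be non-empty", "litcohesion_config_error")
  }
  ov <- length(intersect(window, gold))
  P <- ov / length(window)
  R <- ov / length(gold)
  F <- if (ov == 0) 0 else 2 * P * R / (P + R)
  c(precision = P, recall = R, F = F)
}

#' Right-tailed hypergeometric enrichment p-value
#'
#' Probability of observing at least the seen number of category genes when
#' drawing `|window|` genes from the universe.
#'
#' @param window gene ids (intersected with the universe; must stay
#'   non-empty).
#' @param category gene ids of the annotation category.
#' @param universe gene ids of the enrichment universe.
#' @return p-value in `(0, 1]`.
#' @export
enrichment_pvalue <- function(window, category, universe) {
  universe <- unique(universe)
  win <- intersect(unique(window), universe)
  if (!length(win)) abort("window does not intersect the universe", "litcohesion_config_error")
  cat_u <- intersect(unique(category), universe)
  if (!length(cat_u)) abort("category does not intersect the universe", "litcohesion_config_error")
  ov <- length(intersect(win, cat_u))
  p <- stats::phyper(ov - 1, length(cat_u), length(universe) - length(cat_u),
                     length(win), lower.tail = FALSE)
  min(1, max(p, 0))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]", "litcohesion_domain_error")
  }
  m <- length(p_values)
  if (m <= 1) return(p_values)
  o <- order(p_values)
  adj <- rev(cummin(rev(p_values[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Pearson correlation between -log10(LPv) and F-measure
#'
#' @param neg_log10 numeric vector of -log10(LPv) values (one per probe).
#' @param f numeric vector of F-measures, same length.
#' @return Pearson correlation coefficient.
#' @export
correlate_lpv_f <- function(neg_log10, f) {
  ok <- is.finite(neg_log10) & is.finite(f)
  if (sum(ok) < 3) abort("need >= 3 probes with finite values", "litcohesion_config_error")
  x <- neg_log10[ok]; y <- f[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("degenerate correlation: one variable is constant", "litcohesion_degenerate_error")
  }
  stats::cor(x, y)
}

#' Two-sided Wilcoxon rank-sum comparison of two LPv groups
#'
#' Exact when the combined sample size is at most 20 and there are no ties;
#' otherwise the normal approximation with tie correction is used.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return two-sided p-value.
#' @export
rank_sum_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs >= 2 values", "litcohesion_config_error")
  }
  exact <- (length(a) + length(b)) <= 20 && !anyDuplicated(c(a, b))
  stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                     correct = TRUE)$p.value
}

#' Classify probes as high or low quality from their LPv values
#'
#' In `mean_neglog` mode the threshold is the mean of -log10(LPv) over all
#' probes in the dataset (recomputed per dataset; the fixed published-style
#' cutoff is available via `fixed`). A probe is "high" iff its value is
#' strictly above the threshold.
#'
#' @param neg_log10 named numeric vector, probe -> -log10(LPv).
#' @param mode `"mean_neglog"` (default) or `"fixed"`.
#' @param threshold cutoff used when `mode = "fixed"`.
#' @return named character vector `"high"`/`"low"`, plus attribute
#'   `threshold`.
#' @export
classify_probes <- function(neg_log10, mode = c("mean_neglog", "fixed"),
                            threshold = NULL) {
  mode <- match.arg(mode)
  if (length(neg_log10) < 2) abort("need >= 2 probes", "litcohesion_config_error")
  thr <- if (mode == "mean_neglog") mean(neg_log10) else {
    if (is.null(threshold)) abort("fixed mode needs a threshold", "litcohesion_config_error")
    threshold
  }
  out <- ifelse(neg_log10 > thr, "high", "low")
  attr(out, "threshold") <- thr
  out
}
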