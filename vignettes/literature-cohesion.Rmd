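---
title: "Literature cohesion of co-expressed gene sets: model, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature cohesion of co-expressed gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Microarray platforms often carry several probes for the same transcript, and
those probes can disagree wildly: some report the gene's expression, others
(e.g. probes that in fact hybridize to intronic sequence or to off-target
loci) report noise. A practical way to audit a probe is to look at the genes
whose expression correlates with it across a panel of strains: if the probe
measures real biology, its top co-expressed genes should share function, and
shared function leaves a trace in the biomedical literature. This package
quantifies that trace and turns it into a probe-quality metric.

# The model

## Gene documents and the concept space

Each gene is represented by a *gene-document*: the concatenation of the
abstracts of all its linked publications (a gene2pubmed-style citation table
plus a PMID-to-text table). Documents are tokenized (lowercase, split on
non-alphanumerics, tokens shorter than 3 characters, pure numbers and
stopwords dropped) and assembled into a term-by-gene count matrix
$f_{ij}$, keeping terms that occur in at least 2 distinct documents.

Counts are log-entropy weighted:

$$w_{ij} = g_i \,\log_2(1 + f_{ij}), \qquad
  g_i = 1 + \frac{\sum_j p_{ij}\log_2 p_{ij}}{\log_2 n}, \qquad
  p_{ij} = \frac{f_{ij}}{\sum_j f_{ij}},$$

so a term spread evenly over all $n$ documents gets global weight 0 and a
term confined to one document gets weight 1. A truncated SVD of $W$ yields
the rank-$k$ *concept space* (default $k = 500$, clamped to
$\min(\mathrm{dim}) - 1$ for small corpora); gene $j$'s vector is the
singular-value-scaled right singular vector $(\sigma_1 v_{j1}, \ldots,
\sigma_k v_{jk})$, and gene–gene similarity is the cosine between vectors.
The base of the logarithm cancels in $g_i$; base 2 is fixed so the stored
weights themselves are reproducible. The dense LAPACK SVD is deterministic,
so the `seed` argument of `truncated_svd()` is accepted only for interface
compatibility.

## The literature cohesion p-value (LPv)

Let $S$ be the multiset of all background pairwise cosines and $T$ its 95th
percentile (linear interpolation between order statistics; the convention is
config-exposed because tools differ). For a query set with pairwise cosines
$S'$, draw $n$ random subsets of size $k \le 50$ from $S'$ and $N$ subsets
of the same size from $S$ (defaults $n = N = 1000$), and let

* $A$/$B$ = average counts of draws from $S'$ at or above / below $T$,
* $C$/$D$ = the same averages for the background draws.

The averages are rounded to the nearest integer (ties up; the unrounded
values are kept for audit) and the cohesion p-value is the right-tailed
Fisher's exact test $P(X \ge A)$ for the table $(A, B; C, D)$, reported as
$-\log_{10}(p)$ so that higher means more cohesive. A `point_mass` switch
reproduces the single-table hypergeometric term for comparison, since the
printed form of the statistic in the source literature is the point
probability while the surrounding text specifies the right tail. Draws are
without replacement within a draw and independent across draws; when a set
has fewer than $k$ cosines, $k' = |S'|$ is used and the counts become
deterministic.

The background pool used for the $C$/$D$ draws is the same budget-bounded
pool used to estimate $T$ (exact enumeration up to
`background_pair_budget = 1e6` pairs, uniform pair sampling beyond), so one
threshold object fixes the entire background model for a corpus.

## Windows, benchmarking and probe classification

For a seed probe, Pearson correlations to every other probe are computed
over pairwise-complete strains (pairs with fewer than 3 complete strains or
zero variance are excluded), collapsed to gene level by keeping each gene's
max-$|r|$ probe (ties to the smaller probe id), and the seed's own target
gene is removed so a probe cannot vouch for itself. Ranking by $|r|$ is the
default because co-expression connectivity is two-sided; a positive-only
mode is provided. Nested windows of the top $N$ genes
($N = 100, \ldots, 1000$ on real platforms) are then scored by:

* **Gold-standard F-measure**: precision $P$, recall $R$ and the balanced
  harmonic mean $F = 2PR/(P+R)$ ($F = 0$ for empty overlap). "Weighted
  harmonic mean" with no stated weight is taken as $F_1$.
* **Category enrichment**: right-tailed hypergeometric p against a universe
  of platform genes with corpus vectors, BH-adjusted within each
  probe-window.
* **LPv**, as above, with one shared $T$ per corpus.

Dataset-level summaries are the Pearson correlation between
$-\log_{10}(\mathrm{LPv})$ and $F$ at each window size, a two-sided Wilcoxon
rank-sum comparison of exonic vs intronic probe LPv (exact for combined
$n \le 20$ without ties, normal approximation with tie correction
otherwise), each probe's peak window (smallest argmax of $F$) and its mean,
and a probe quality flag: *high* iff a probe's $-\log_{10}(\mathrm{LPv})$
strictly exceeds the dataset mean. The mean cutoff is deliberately a
*dataset statistic*, recomputed per dataset rather than fixed at any
published value; `classify_probes(mode = "fixed")` reproduces a fixed
cutoff when wanted.

# The synthetic world

Real corpora and strain panels are large and proprietary-ish; validation
instead uses a generator with planted ground truth (`synthetic_config()`
defaults in parentheses):

* **Corpus**: `n_genes` (500) genes, `n_modules` (4) disjoint modules of
  `module_size` (50). Each module owns `module_vocab_size` (100) private
  terms out of `vocab_size` (2000). Document lengths are Poisson with mean
  `doc_length_mean` (100), truncated at 1 — the simplest count model, since
  nothing constrains document statistics. A module gene's token is private
  with probability `signal_term_fraction` (0.75, the level at which planted
  modules should be reliably detected); background genes use only shared
  vocabulary. With `signal_term_fraction = 0` module genes are exchangeable
  with background genes — the null world used for calibration tests.
* **Expression**: latent module activity is i.i.d. standard normal across
  `n_strains` (40). A signal ("exon") probe reports activity plus per-gene
  loading noise (`expression_noise_sd` = 0.2) plus probe noise
  (`probe_noise_sd` = 0.2); a noise ("intron") probe is i.i.d. N(0,1) and
  targets the *same* member genes, mirroring exonic/intronic probes on one
  transcript. Every gene also gets one gene-level row (region `"gene"`) so
  that windows range over genes rather than probes; background genes' rows
  are pure noise. Gaussian throughout, which makes Pearson correlation the
  natural recovery statistic.
* **Gold standards**: module members retained with probability
  `1 - gold_dropout` (0.1), plus `round(gold_contamination * module_size)`
  (5) uniformly-sampled non-members — emulating proteomics-derived target
  lists that miss true members and carry false positives.

What the generator does **not** emulate: realistic term frequency
distributions (Zipf tails, MeSH structure), citation-count skew across
genes, genetic structure of the strain panel (kinship, QTLs), overlapping
modules, or platform-specific normalization artifacts. A green test
establishes that the statistical machinery recovers planted structure under
Gaussian/multinomial assumptions — not that any particular biological
conclusion is correct.

# Numerical choices and degenerate inputs

* Averaged counts are rounded half-up before the exact test (the test is
  defined on integer tables); rounding can perturb a margin by one, so the
  below-threshold cells are rebalanced to keep $A+B = C+D = k'$.
* Genes with no retrievable text or no surviving tokens are excluded from
  the universe (with a warning) rather than embedded at the origin, since a
  zero vector has no cosine.
* Ties in window ranking break by gene id, and in probe collapse by probe
  id, making every ranking deterministic.
* Per-stage RNG seeds are derived deterministically from one master seed
  and a stage label, so any stage can be reproduced in isolation and two
  runs with one seed are byte-identical (timestamps live only in the run
  manifest).
* Truncating the SVD at the *effective* rank is lossless for cosines;
  truncating a full-rank matrix at $\min(\mathrm{dim}) - 1$ perturbs
  cosines at roughly $\sigma_{\min}^2/\sigma_1^2$, which is why the
  fidelity tests use rank-deficient matrices.

# Validation design

The test suite asserts, among others: exact agreement of the Fisher right
tail with log-binomial enumeration over every 2x2 table with total
$\le 120$; the hand-derived log-entropy row $(2,1,1,0) \mapsto g = 0.25$;
cosine preservation under lossless truncation; LPv calibration on null
corpora (no more than 15% of random 50-gene sets significant at 0.05); LPv
power of at least 95% on planted modules at `signal_term_fraction = 0.75`
(25 corpora x 4 modules); and end-to-end probe discrimination over 10
seeded benchmark runs — exon/intron LPv separation by rank-sum test, at
least 80% correct quality flags, and LPv–F correlation $\ge 0.7$ at the
module-size window. Benchmark windows are {50, 100, 200} rather than the
100–1000 used on real platforms because the synthetic universe holds 500
genes and all criteria are evaluated at the module-size window.

One property deliberately deviates from a naive reading: *recall* is
exactly non-decreasing over nested windows and is asserted for every probe,
but *precision* non-increase is not a theorem — for an unstructured window
it is a hypergeometric ratio that fluctuates — so it is asserted only for
signal probes against their matched gold standard at windows at or beyond
the module size, the regime where co-expression structure exists.

# Known limitations

* The background cosine distribution of a real Medline-scale corpus is not
  characterized here; synthetic defaults are not calibrated to it, and the
  95th-percentile threshold on a small synthetic corpus is a much coarser
  estimate than on 2x10^8 real pairs.
* LPv depends on corpus coverage: sets with many genes absent from the
  corpus are scored on the covered subset only (the coverage fraction is
  always reported).
* The sampled Fisher construction is conservative-to-anticonservative only
  within the limits explored by the calibration test; it is not an exact
  test after averaging and rounding.
* `peak_window()` reports the smallest argmax per probe and its mean across
  probes; other averaging conventions over datasets are possible and would
  give different "peak window" summaries.
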