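# litcohesion

Literature-cohesion scoring of gene sets and benchmarking of microarray
probe quality.

## The problem

Multiple probes targeting the same transcript on an expression platform
often disagree — some track the gene, others track noise (mis-annotated
intronic probes, cross-hybridizing probes). A useful audit is functional:
take the genes most co-expressed with a probe across a strain panel and ask
whether they *cohere* — whether the biomedical literature about them is
more mutually similar than chance. `litcohesion` implements that audit end
to end, for researchers evaluating probes, co-expression modules, or any
gene set against the literature.

## The method

1. **Concept space.** Per-gene documents (concatenated PubMed abstracts
   from a gene2pubmed-style table) are turned into a term-by-gene matrix
   with log-entropy weights
   `w_ij = g_i * log2(1 + f_ij)`, `g_i = 1 + sum_j p_ij log2(p_ij) / log2(n)`,
   then reduced by truncated SVD (default 500 concepts). Gene–gene
   similarity is the cosine between concept vectors.
2. **Literature cohesion p-value (LPv).** With `T` the 95th percentile of
   all background pairwise cosines, draw 1000 size-`k` (`k <= 50`) samples
   from the set's pairwise cosines and 1000 from the background; the
   averaged above/below-`T` counts `(A, B; C, D)` go into a right-tailed
   Fisher's exact test, reported as `-log10(p)` (higher = more cohesive).
3. **Windows and benchmarking.** For each seed probe, the top-N
   co-expressed genes (nested windows) are scored by LPv, by
   precision/recall/F1 against gold-standard gene sets, and by
   hypergeometric category enrichment (BH-adjusted). Dataset summaries:
   Pearson r between `-log10(LPv)` and F per window size, exon-vs-intron
   Wilcoxon rank-sum separation, per-probe peak windows, and a quality flag
   (`high` iff a probe's `-log10(LPv)` exceeds the dataset mean).
4. **Synthetic ground truth.** A generator plants functional modules in a
   corpus (module-private vocabulary), an expression panel (signal probes
   track latent module activity; noise probes are N(0,1)), and corrupted
   gold standards — so every claim the package makes is testable against
   known truth.

## Worked example

```r
library(litcohesion)

cfg   <- synthetic_config(seed = 1)            # 500 genes, 4 planted modules
gen   <- generate_corpus(cfg)
space <- concept_space_from_corpus(gen$corpus)
space
#> concept_space: 500 genes x 499 concepts (sigma_1 = 24.6)

thr <- estimate_threshold(space, lpv_config(seed = 1))
thr
#> background_threshold: T = 0.1060 (exact, 124750 pairs, percentile 95)

# a planted 50-gene module is massively cohesive ...
lpv(space, gen$truth$modules[["module01"]], thr, lpv_config(seed = 1))
#> LPv: p = 2.32e-25 (-log10 = 24.63), table [50 0; 3 47], coverage 100%

# ... a random 50-gene set is not
lpv(space, with_seed(99, sample(space$genes, 50)), thr, lpv_config(seed = 1))
#> LPv: p = 0.819 (-log10 = 0.09), table [2 48; 3 47], coverage 100%
```

Reading the output: all 50 sampled in-set cosine pairs of the planted
module exceed the background threshold versus 3/50 for background draws,
giving `-log10(LPv) = 24.6`; the random set is indistinguishable from
background (`p = 0.82`).

The full benchmark (windows, F-measures, probe flags) in one call:

```r
res <- run_synthetic_benchmark(default_benchmark_config(seed = 1))
res$summary$lpv_f_r
#>        50       100       200
#> 0.9434039 0.6588543 0.6152572
res$summary$rank_sum_p
#> [1] 2.475747e-05
table(res$summary$quality)
#> high  low
#>   12   12     # the 12 signal probes are "high", the 12 noise probes "low"
```

At the module-size window the correlation between `-log10(LPv)` and
gold-standard F across the 24 probes is 0.94, signal probes separate from
noise probes at rank-sum p = 2.5e-05, and the mean-`-log10(LPv)` classifier
flags every probe correctly.

The same workflow runs from files (TSV/GMT in, TSV/JSON out) via
`run_workflow()` or the CLI in `inst/scripts/litcohesion-cli.R`
(`simulate`, `build-space`, `lpv`, `coexpress`, `run` subcommands).

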