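Package: litcohesion
Title: Literature-Cohesion Evaluation of Co-Expressed Gene Sets and Probe Quality
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores the functional cohesion of gene sets against the
    biomedical literature and uses that score to benchmark microarray
    probes. Per-gene documents built from PubMed citations are embedded in
    a latent semantic indexing (LSI) concept space with log-entropy term
    weighting and truncated SVD; a sampled right-tailed Fisher's exact
    test turns pairwise cosine similarities into a literature cohesion
    p-value (LPv). Co-expression windows seeded from expression probes are
    scored with LPv, gold-standard precision/recall/F, and hypergeometric
    category enrichment, and probes are classified as high or low quality.
    Includes a synthetic-data generator with planted functional modules so
    the whole workflow can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
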