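Package: monosig
Title: Multicohort Discovery and Scoring of Monocyte-Subset Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates heterogeneous cohorts of sorted-cell gene expression
    profiles to discover parsimonious cell-subset signatures and score new
    samples with them. Provides per-dataset quantile normalization, probe to
    gene summarization, cross-study co-normalization, per-gene Hedges' g
    effect sizes with DerSimonian-Laird random-effects pooling and
    Benjamini-Hochberg correction, a four-rule parsimonious signature
    selector, geometric-mean signature scoring with AUROC and correlation
    based evaluation, pre-ranked gene-set enrichment on pooled effect-size
    vectors, and a synthetic multi-study data generator with planted markers
    and known mixture fractions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    limma,
    fgsea,
    pROC
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
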