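# monosig

Multicohort discovery and scoring of monocyte-subset gene expression
signatures.

## The problem

Human monocytes comprise three subsets — classical (CD14+CD16−, ~90%),
nonclassical (CD14−CD16+, ~5%) and intermediate (CD14+CD16+) — whose
proportions shift in infection, autoimmunity and under treatment. Most
transcriptome datasets profile bulk blood, so subset levels must be
estimated in silico. Single cohorts of sorted cells are small and
platform-specific; integrating many public cohorts of sorted subsets
yields markers that survive real-world technical and biological
heterogeneity. `monosig` implements that integration pipeline for anyone
who wants to derive a small, robust, cross-platform signature for a cell
subset and use it to score new samples: computational immunologists,
translational researchers mining public expression compendia, and method
developers who need a fully synthetic, ground-truthed test bed.

## The method

For each gene and each study, the package computes the standardized mean
difference between the subset of interest and all other sorted samples
as Hedges' *g* (on log2 expression):

    d = (x̄₁ − x̄₀) / s_p,   J = 1 − 3/(4(n₁+n₀) − 9),   g = J·d,
    var(g) = (n₁+n₀)/(n₁n₀) + g²/(2(n₁+n₀))

Study effects are pooled per gene under a random-effects model with the
DerSimonian–Laird moment estimator of between-study variance τ²
(fixed-effect weights wᵢ = 1/vᵢ give Cochran's Q; τ² = max(0, (Q −
(k−1))/(Σwᵢ − Σwᵢ²/Σwᵢ)); random-effects weights wᵢ* = 1/(vᵢ+τ²) give
the pooled effect μ̂ = Σwᵢ*gᵢ/Σwᵢ*, SE = √(1/Σwᵢ*), z and a two-sided
normal p), with Benjamini–Hochberg correction across genes. Before
meta-analysis, studies are quantile-normalized, probe-summarized and
co-normalized (per-gene, per-study location alignment on the log2 scale,
which provably leaves every within-study *g* unchanged).

Signatures come from a four-rule parsimonious selector: rank by pooled
*g*; keep up-regulated genes; keep genes with a pooled linear mean
difference ≥ 32 expression units; take the top 10. A sample's signature
score is the geometric mean of its signature-gene expression (cMSS for
classical, ncMSS for nonclassical), evaluated by AUROC with DeLong
confidence intervals, group tests, and Pearson correlation against
cytometry-measured fractions. Pre-ranked GSEA over the pooled
effect-size vector characterizes the biology a subset's ranking carries.
A synthetic multi-study generator with planted markers, per-study batch
shifts, platform-style gene dropout and known mixture fractions makes
every stage testable end to end.

## Worked example

```r
library(monosig)

sim <- simulate_sorted_studies(simulation_config(seed = 42))
fit <- meta_signature(sim$datasets, "classical")
fit
#> Multicohort subset-signature model
#>   subset: classical  (6 studies, 1000 genes meta-analyzed)
#>   significantly over-expressed (FDR <= 0.05): 10 genes
#> Signature 'classical_signature' (classical, 10 genes, up):
#>   G00066, G00284, G00004, G00412, G00967, G00396, G00923, G00813, G00367, G00223

length(intersect(fit$signature$genes,
                 sim$truth$marker_genes_by_subset$classical))
#> [1] 10        # all 10 planted markers recovered

scores <- predict(fit, sim$datasets)
auroc(scores$score, scores$subset == "classical")
#> AUROC = 0.924 (95% CI 0.880-0.968; 60 pos, 60 neg)
```

The fitted object reports, per signature gene, the pooled Hedges' *g*,
its standard error, τ², the number of contributing studies, the FDR and
the pooled linear-scale mean difference (`summary(fit)`); `plot(fit)`
draws the forest plot. Here the simulation planted 10 classical markers
at *g* = 2 across 6 studies with batch shifts and 10% gene dropout; the
selector recovers all of them, and the geometric-mean score separates
classical from other sorted samples with AUROC 0.92 at this noise level
(1.0 as noise shrinks). `run_pipeline()` (or
`Rscript inst/scripts/monosig.R pipeline.yaml`) chains
simulate → normalize → meta → select → score → evaluate → enrich from
one config and writes a manifest with checksums and seeds.

Published signature resources from the source study (the complete
10-gene intermediate-monocyte list and the main-text classical and
nonclassical marker genes) are available via `bundled_signatures()`.

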