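---
title: "Methods: multicohort signature discovery and scoring in monosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicohort signature discovery and scoring in monosig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monosig)
```

# Overview

`monosig` discovers small ("parsimonious") cell-subset gene signatures
by integrating many independent cohorts of sorted-cell expression
profiles, and scores new samples with them. The pipeline is: per-study
quantile normalization and probe-to-gene summarization; cross-study
co-normalization; per-gene Hedges' g effect sizes within each study and
DerSimonian–Laird (DL) random-effects pooling across studies with
Benjamini–Hochberg (BH) correction; a four-rule selector producing a
signature of over-expressed genes; geometric-mean scoring with
AUROC/correlation evaluation; and pre-ranked gene-set enrichment of the
pooled effect-size vector. The motivating application is human monocyte
subsets (classical, nonclassical, and the transitional intermediate),
but nothing in the machinery is monocyte-specific.

# The statistical model

## Within-study effect sizes

For a gene in one study, the case group is the subset of interest and
the control group is every other sorted sample in that study (samples
labelled `"mixed"` are never used for discovery). On log2 expression we
compute the bias-corrected standardized mean difference

$$d = \frac{\bar x_1 - \bar x_0}{s_p},\qquad
  J = 1 - \frac{3}{4(n_1+n_0)-9},\qquad g = J d,$$

with $s_p$ the df-weighted pooled standard deviation, and sampling
variance $\mathrm{var}(g) = (n_1+n_0)/(n_1 n_0) + g^2/(2(n_1+n_0))$.
Effect sizes are computed on the log2 scale because expression fold
changes are multiplicative and array intensities approximately
log-normal; the linear-scale case-minus-control mean difference is
tracked separately because the selection filter below is phrased in
linear expression units. A study contributes a gene only when both
groups have at least two non-missing values and $s_p > 0$; genes a
study does not measure are simply absent from its contribution — never
imputed.

## Random-effects pooling

Per gene, study effects $g_i$ with variances $v_i$ are pooled with the
DL moment estimator: fixed-effect weights $w_i = 1/v_i$ give Cochran's
$Q$; $\tau^2 = \max\{0, (Q-(k-1))/(\sum w_i - \sum w_i^2/\sum w_i)\}$;
random-effects weights $w_i^* = 1/(v_i+\tau^2)$ give the summary effect,
its standard error $\sqrt{1/\sum w_i^*}$, and a two-sided normal
p-value. With one study $\tau^2$ is defined as 0 and the single effect
passes through. The normal (not t) reference is the conventional
large-sample meta-analytic choice; REML-type $\tau^2$ estimators are
deliberately out of scope. BH correction runs across all reported
genes. The implementation is vectorized across genes; the test suite
checks it against hand-computed toys and against `metafor::rma(method
= "DL")` on random instances to 1e-8.

## Assumptions

Approximate normality of log2 expression within groups; independence of
studies; exchangeability of study effects around a common mean
(random-effects); missingness of a gene in a study is platform
coverage, unrelated to its expression level. Violations mostly inflate
$\tau^2$, which the pooling absorbs as wider intervals.

# Normalization

Quantile normalization forces each sample of a study onto the per-rank
mean distribution (delegated to `limma::normalizeQuantiles`, ties
averaged, interpolation at a sample's own quantile grid when missing
values shorten it). Probe summarization is the arithmetic mean of a
gene's probes per sample, a probe annotated to several genes counting
for each; the mean is the simplest deterministic, order-independent
convention and alternatives (variance-weighted collapses) are
intentionally not offered. Co-normalization then aligns study
locations: per gene, each study's log2 values are shifted so its mean
over sorted samples equals the unweighted cross-study mean of those
study means. A per-study location shift is the minimal transform that
equalizes locations, and it preserves every within-study contrast and
standardized effect size exactly — the test suite asserts a planted +1
log2 batch shift is removed to 1e-9 while every within-study g is
unchanged to machine precision. Richer co-normalization strategies
(e.g. scale adjustment) could replace it behind the same function
without touching the meta-analysis. Pipeline order is quantile
normalize, then summarize, then co-normalize.

# Signature selection

Four rules, applied to the meta-analysis table: (a) rank genes by
pooled g descending (ties: smaller FDR, then alphabetical symbol, for
determinism); (b) keep up-regulated genes (pooled g > 0, FDR ≤ 0.05 —
the significance cutoff behind "significantly over-expressed" is a
package default, as discovery reports rarely print it); (c) keep genes
with pooled linear mean difference ≥ `min_mean_diff` (default 32
expression units); (d) take the top `top_k` (default 10). The 32-unit
filter is interpreted on the **linear** intensity scale: a threshold of
32 is meaningless on log2 data (few log2 values exceed 16), and its
purpose — guaranteeing a signal large enough for independent
experimental validation — only makes sense on intensities. Both the
threshold and its scale are configurable. The "mean difference" is the
inverse-variance-weighted (fixed-effect) combination of per-study
linear differences; a per-study minimum was considered and rejected as
too sensitive to single noisy studies. If fewer than `top_k` genes
survive, all survivors are returned with a shortfall flag rather than
an error; zero survivors is an error that names how many candidates
each rule eliminated.

`bundled_signatures()` ships the published resource lists: the complete
10-gene intermediate-monocyte signature (verbatim as printed, including
the symbols `ATP50` and `DX39A`, with corrected aliases `ATP5O` and
`DDX39A` carried alongside — fidelity to the printed resource plus
usability), and the main-text-verifiable classical (CSF3R, FCGR2A,
CD36, IL17RA) and nonclassical (SIGLEC10, IER2, CTSA) genes. The
complete discovery signatures live in the source study's supplementary
material and are not re-distributed here.

# Scoring and evaluation

A sample's signature score is the geometric mean of its linear
expression over the signature genes present in the dataset. Values are
floored at 1 linear unit so a zero cannot annihilate the product (the
choice of floor only matters for near-background values and is
configurable); genes missing from a platform reduce the exponent $1/k$
rather than invalidating the score, with a minimum-coverage guard
(default 50%) because cross-platform application is the central use
case. Geometric-mean scoring on linear values equals the anti-log of
the mean of log values, so score *rankings* are identical under either
convention; only the reported units differ, and linear units are used
throughout.

Evaluation: AUROC as the normalized Mann–Whitney U (ties one half)
with DeLong 95% intervals via pROC (the CI method in discovery reports
is typically unstated; DeLong is the standard analytic choice and a
bootstrap is easy to add by the caller); Welch's t-test as the default
"t-test" flavour (robust to unequal variances, reduces to Student
under equality) and Wilcoxon rank-sum/signed-rank for non-parametric
and paired comparisons; Pearson correlation with t-distribution
p-values against measured cell fractions; and a three-group ordering
check that the putative transitional subset's mean score lies strictly
between the two pure subsets' means.

# Enrichment

Pre-ranked GSEA over the pooled effect-size vector: the classic
weighted running-sum statistic (hit increments proportional to
$|g|^{p}$ with $p=1$, uniform miss decrements, ES = the extremum of the
running sum), permutation p-values from random gene sets of matching
size, NES normalized by the mean magnitude of same-sign permutation
scores, BH across gene sets. The engine is `fgsea::fgseaSimple` under a
fixed seed (10⁴ permutations by default); the test suite pins the ES to
an exhaustive running-sum enumeration on small rankings, so the fgsea
conventions are verified rather than assumed. Sets intersecting the
ranking in fewer than 3 genes or more than half the ranking are skipped
(standard practice; configurable); a set covering the whole ranking is
degenerate — the running sum has no decrement — and is reported with
ES = 0 and no p-value.

# The synthetic generator

`simulate_sorted_studies()` emulates the structure of a public
sorted-cell compendium: multiple independent studies, each with two (or
three) sorted subsets; per-gene log2-normal expression; a per-study
additive log2 batch shift shared across genes; gene-wise uniform
dropout per study (platform coverage); and disjoint planted marker
sets whose log2 means are shifted by `planted_effect_size` within-group
standard deviations, so realized Hedges' g targets the planted value.
Defaults — 6 studies, 10 samples per subset per study, 1000 genes, 10
markers per subset, g = 2, baseline mean 256 and sd 128 linear units,
batch sd 0.5 log2 units, 10% dropout — are the package's canonical
study conditions: enough studies and samples for a discovery cohort in
miniature, marker effects of the size a real subset marker shows, and a
batch spread (a typical ~1.4-fold study offset; no canonical literature
value exists) that is large relative to the planted effects'
per-study noise, so co-normalization is genuinely exercised. Per-gene
baseline log2 means get a fixed 0.5 log2-unit spread around the global
baseline so genes are not interchangeable. The linear moments are
matched exactly to the log2-normal, and with these defaults a g = 2
marker's linear mean difference (~400 units at baseline 256) comfortably
clears the 32-unit filter — as real subset markers must to be selected.

One global seed drives a hierarchical stream (gene baselines and marker
identities first, then one derived seed per study), so output is
bit-reproducible and studies are mutually independent.
`simulate_intermediate_profiles()` draws samples around the log2-scale
λ-mixture of two pure mean profiles (the transitional-state model of
intermediate monocytes); `simulate_mixtures()` builds PBMC-like samples
as linear-scale convex combinations of pure profiles with Dirichlet (or
caller-fixed) fractions recorded as ground truth.

What the generator does **not** emulate: probe-level structure,
count-based RNA-seq noise (the log-normal stands in for both array
intensities and log-transformed RNA-seq), correlated gene modules,
disease effects, gene-specific dropout bias, or study-varying sample
sizes. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, and calibration/recovery
under idealized heterogeneity — not performance on any real compendium,
which also contends with annotation error and platform-specific
distortions the model omits.

# Numerical choices and degenerate inputs

- Zeros: log2 is taken after flooring at $2^{-20}$ inside the
  meta-analysis (simulated and normalized intensities are positive;
  the floor only guards exact zeros), and at 1 linear unit inside
  scoring.
- A gene with zero pooled variance in a study (all values tied)
  contributes no effect there; a gene under `min_studies` coverage is
  reported in a skipped list, not dropped silently.
- Ties in AUROC count one half by construction of the U statistic;
  Wilcoxon tests use the normal approximation so tied inputs return
  exact p = 1 rather than an error.
- All orderings use deterministic tie-breaks (effect, then FDR, then
  symbol), so every pipeline output is reproducible byte for byte; the
  manifest records seeds and md5 checksums.
- Gene symbols are matched case-insensitively and reported
  case-preserved.

# Problem sizes in the validation suite

The shipped checks run at deliberately modest scale, chosen as the
smallest sizes at which each property is sharply testable: worked toys
of 2–6 observations for closed forms; 100 random instances for
reference-implementation agreement; 20 replicates of the default
6-study × 20-sample × 1000-gene null for FDR calibration; the default
study conditions for end-to-end marker recovery; 30-sample noise-free
mixtures for score–fraction correlation; rankings of ≤ 12 genes for
exhaustive enrichment enumeration and 20 × 5 null sets at 1000
permutations for p-value uniformity.

# Known limitations

The co-normalization is location-only; multiplicative (scale) batch
distortion would pass through (though standardized effects are
insensitive to per-study scaling applied uniformly on log2 values).
DL is known to underestimate $\tau^2$ when study effects are few and
heterogeneous; with ≥ 4 studies per subset (the discovery convention)
this mainly affects interval width, not ranking. The selector optimizes
nothing jointly — it is a transparent filter, and correlated top genes
can make the signature less diverse than an optimized set. Permutation
GSEA p-values are bounded below by 1/(n_perm+1); very small printed
enrichment p-values from analytic or multilevel methods are outside its
resolution.
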