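---
title: "Methods: locus mapping, prior weighting and boosted gene scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus mapping, prior weighting and boosted gene scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(locusboost)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite
and `scripts/acceptance.R` do not themselves compute.

## The problem

A GWAS associates a tag SNP — a proxy for a block of correlated variants
— with a trait. The causal gene is usually one of many inside or near
the block. `locusboost` scores every annotated gene for disease
association by learning, from unbiased binary genomic features, what the
probable causal genes at the trait's loci have in common. "Unbiased"
matters: the features (expression percentile indicators, binding-site
copy counts, domain memberships, ...) are built without reference to the
trait, so a high score reflects shared functional genomics rather than
annotation circularity.

## Locus mapping

Coordinates are 0-based half-open throughout (BED compatibility; the
readers document this). For each tag SNP:

1. **LD block**: the minimal interval covering the tag and every partner
   SNP with r² ≥ 0.5. The threshold is inclusive — "within r² of 0.5" is
   read as ≥ — and configurable (`r2_min`).
2. **Hotspot extension**: each end moves outward to the nearest
   recombination hotspot at or beyond it. Hotspots strictly inside the
   interval are ignored; with no flanking hotspot an end is left
   unchanged. The behaviour without a flanking hotspot is not dictated
   by the procedure being implemented, so the conservative identity was
   chosen.
3. **Flank**: 250 kb on each side, clipped to the chromosome.
4. **Gene assignment**: genes with a TSS in the interval, plus any gene
   whose body `[tx_start, tx_end)` contains the tag. If the locus is
   empty, the interval is widened once (not iteratively) by 50 kb per
   side; a still-empty locus is kept but flagged and excluded from
   training.

An alternative reading of the mapping rule — an interval extending
250 kb to either side of each TSS — coincides with the above for point
intervals and was not implemented separately. Overlapping loci of one
trait are never merged: per-locus positive sampling (below) is defined
locus by locus, and a gene at several loci is simply sampled and scored
per locus.

## Prior weighting

Candidates at a multi-gene locus score +5 for a TSS within 50 kb of the
index variant (TSS-to-SNP distance, not gene-boundary distance) and +5
per evidence source: membership in an OMIM-like disease gene list, and
membership in GO-like or mouse-phenotype-like terms found enriched among
the trait's locus genes. The per-source weight of 5 is deliberately not
optimized, but is configurable. The single gene of a one-gene locus is
overridden to a total of 1 — a weak but non-zero vote, since locus
membership alone is modest evidence.

Enrichment replaces an external annotation service with an internal
one-sided hypergeometric test, Benjamini–Hochberg adjusted within each
collection, selecting terms with adjusted p < 0.05 and log odds > 1. The
log odds is the natural log of the sample odds ratio of the 2×2 table
with a 0.5 continuity correction on zero cells (whether the original
service corrected is unknown; the correction only matters for degenerate
tables). Relaxing the thresholds is an explicit argument
(`adj_p_max`, `lod_min`), not an automated judgement.

Scores become sampling probabilities by per-locus normalization to 1. An
all-zero locus becomes uniform so that every locus can still contribute
a positive training example. Genes with a total ≥ 10 are *likely
positives*, the surrogate truth used by the evaluation module.

## The boosting engine

The classifier is least-absolute-deviation (LAD) gradient boosting on
0/1 class targets. Each tree is a four-leaf binary tree over binary
features, grown best-first: the (leaf, feature) split that most reduces
the summed absolute deviation of residuals from their per-side medians
is taken, and leaf values are residual medians. The initial constant f₀
is the median of a first batch's targets (0.5 for balanced batches), and
trees enter with shrinkage ν (default 0.1; the original procedure names
the parameter but not its value, so the conventional default is used and
recorded in run logs). The final score is the logit of the ensemble
output clamped to [ε, 1−ε], ε = 1e-3: the "absolute loss" fit and the
"log-odds output" are reconciled by fitting in probability space and
transforming at the end.

Stochasticity: each tree sees ⌈0.7·L⌉ loci chosen uniformly, one
positive drawn per chosen locus by its probabilities, and an equal
number of negatives drawn uniformly without replacement from the pool of
genes belonging to no locus of the trait (in Mendelian mode, genes not
on the positive list). All features are candidates at every split — no
per-split subsampling — so overfitting is controlled only by batch
subsampling, tree size, shrinkage and tree count.

**Burn-in.** In GWA mode, before the main fit, 20 trees are grown the
same way while a tally runs: after each tree, the gene with the highest
current ensemble score at *every* training locus (not only the sampled
ones — "at each locus" is read literally) gains one point. After 20
trees each locus's tally total T is the sum of initial prior scores plus
increments (the alternative, increments only, sits behind
`burnin_tally_initial = FALSE`; the text is ambiguous), and only genes
whose running score exceeds 0.25·T keep their — renormalized — sampling
probability. Single-gene loci always survive; a locus the filter would
empty keeps its top-scoring gene so it remains usable. The burn-in trees
are then discarded and 60 fresh trees trained from the refined weights:
"the process repeated" is read as re-sampling, not model reuse, since
the refined scores are described as fixed *for* the subsequent trees.

Ties — in split gains, in burn-in top genes — break deterministically
(lower feature index, lower gene id) so that a seed fully reproduces a
run. Missing feature values are imputed as 0, the natural absent state
for binary indicator features.

**Cross-validation.** Six rounds of eight-fold cross-validation,
partitioning loci (GWA) or positive genes (Mendelian; no burn-in there).
Fold partitions are uniform, unstratified. A locus gene's score comes
from the fold holding out its locus (mean over folds if it sits at
several loci); all other genes get the round's mean over fold models;
the final table averages rounds and keeps per-round columns. Every gene
in the annotation universe receives a finite score, including genes
never used in training.

## Evaluation statistics

* **AUROC**: rank-based Mann–Whitney form with midrank ties.
* **Precision at recall**: smallest top-k capturing the recall level;
  significance is the upper binomial tail P(X ≥ hits), X ~ Bin(k,
  prevalence).
* **Within-locus rank permutation test**: counts loci whose likely
  positive reaches the top window (top 3 for ≥ 4 genes, top 2 for 3,
  top 1 for 2). Loci without a likely positive cannot score under any
  permutation and single-gene loci always would; both are excluded.
  The null is drawn from the exact within-locus permutation law
  (hypergeometric window counts), and the empirical p carries the +1
  correction so it is never exactly zero.
* **Top-score null**: per locus of n genes, the maximum of n draws from
  the genome-wide score pool, 10,000 iterations; sampling is without
  replacement within an iteration because a locus's genes are distinct
  (`replace = TRUE` recovers the closed form 1 − F(x)ⁿ for testing).
  Here the raw fraction is reported by default, as that is how this
  statistic is defined.
* **Fisher enrichment**: sample odds ratio ad/bc (0.5 correction on zero
  cells) — chosen over the conditional-MLE odds ratio because the
  published value equals ad/bc on the published counts — with a
  one-sided hypergeometric p by default.

## Motif features

The match score of a window against a PWM is an entropy-weighted mean
log-ratio: MMS = Σⱼ wⱼ log₂(f̃_{b(j),j}/p_{b(j)}) / Σⱼ wⱼ, with
wⱼ = 2 + Σ_b f̃ log₂ f̃ the information content of column j (range
[0, 2]). Two printed-form ambiguities are resolved as follows, each with
the literal variant behind a flag: the weight formula omitting the f
multiplier (`literal_weights`) would not be an information content and
can leave [0, 2], so standard information content is the default; and a
leading minus sign on the score would make strong matches maximally
*negative*, which is incompatible with thresholding the *highest*-mean
mixture component as "high confidence", so higher-is-better is the
default (`paper_sign` negates). A pseudocount of 0.01 per cell (then
renormalized) prevents log 0.

Per-motif thresholds come from a three-component 1-D Gaussian mixture
fit by EM — k-means++ initialization, best of 20 restarts, tolerance
1e-8, up to 500 iterations, a 1e-6 variance floor against degenerate
spikes — on an empirical score pool; the threshold is the smallest score
MAP-assigned to the highest-mean ("high confidence") component. The EM
is authored here because the mixture-threshold rule is integral to the
feature builder; an established mixture package serves as an independent
cross-check in the tests. Scanning covers both strands (reverse
complement), keeps overlapping hits without deduplication, and maps a
hit to every gene whose body ± window (10 kb experimental, 25 kb
conserved) contains the hit's start coordinate — a simple,
strand-independent convention. Counts discretize into nested indicators
(≥1, ≥2, ≥3, ≥4), and continuous per-sample values into strict
exceedance of the 75th/90th/99th linear-interpolation percentiles (a
gene exactly at a cutoff is 0; a constant sample gives an all-zero
column with a warning).

## The synthetic benchmark

The generator emulates the structure the engine assumes: causal genes at
separate loci share planted binary features. The default scenario — one
chromosome, 2,000 genes at ~80 kb mean spacing (uniform ±50% jitter),
15 loci, 200 features with 10 planted, carried by causal genes at rate
0.8 versus 0.05 background, evidence sets covering half the causal genes
per source, seed 20141203 — is small enough for minutes-scale
cross-validation and strong enough for stable recovery. The ~80 kb
spacing makes a hotspot-plus-250 kb-flank locus hold roughly 4–10 genes.
Tag SNPs land within 30 kb of their causal gene's TSS (so the causal
gene earns proximity points, as real index variants near causal genes
would); in-block LD partners draw r² from [0.55, 1] and decoys from
[0, 0.45], avoiding the threshold boundary; hotspots sit 5–20 kb outside
the block. The truth's intended locus membership is computed from the
inclusion rules by independent code in the generator, so the mapper's
recovery of it is a real check, not a tautology.

What the generator does *not* emulate: realistic LD decay, overlapping
or nested loci, feature correlation structure, class imbalance among
features, or annotation noise in the evidence sets. Passing the
benchmark therefore shows the machinery is correct and can recover a
planted signal of realistic strength; it does not certify performance on
real GWAS data, where feature signal is weaker and priors are noisier.

## Numerical and scale choices

Problem sizes in the test suite were chosen for a laptop-scale run: the
full benchmark (6×8-fold cross-validation on 2,000 genes × 200 features)
runs in a few minutes; unit tests use a 600-gene variant of the same
scenario. Probability normalization asserts to 1e-9; split gains must
exceed 1e-12 to count as improvements; EM likelihood traces are checked
non-decreasing to 1e-6. All stochastic entry points take a `seed` and
restore the caller's RNG state, and identical seeds give bit-identical
score tables.

## Known limitations

* Shrinkage, the one undocumented training constant, defaults to 0.1;
  different values change absolute log-odds (not usually rankings).
* The negatives pool is "everything outside the trait's loci", which on
  real data contains undiscovered positives; scores are therefore
  conservative.
* LAD trees on binary features can tie frequently; deterministic
  tie-breaking keeps runs reproducible but means feature order matters
  at exact ties.
* The permutation test conditions on the observed likely-positive
  placement; with very few contributing loci its resolution is limited.
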