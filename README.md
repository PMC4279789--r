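# locusboost

Genome-wide association studies (GWAS) report tag SNPs, not genes: each
associated locus typically spans dozens of genes in linkage
disequilibrium, and deciding which of them is causal is the central
interpretive bottleneck. `locusboost` implements a disease-gene
prioritization engine for this problem. It maps each tag SNP to a
candidate-gene locus, weights the candidates by prior evidence, and then
trains an adapted stochastic gradient-boosting classifier on *unbiased*
binary genomic features (expression percentiles, transcription-factor
binding-site counts, protein domains, and the like) to score **every gene
in the genome** with a log-odds of disease association.

## The method

**Locus mapping.** A tag SNP's locus is the minimal interval covering all
SNPs with r² ≥ 0.5, extended outward to the nearest flanking
recombination hotspots, plus a 250 kb flank on each side. Genes whose TSS
falls in the interval are candidates, as is any gene whose body contains
the tag SNP; an empty locus is widened once by 50 kb.

**Prior weighting.** Each candidate gene at a multi-gene locus starts at
0 and gains 5 points for a TSS within 50 kb of the index variant and 5
points per supporting annotation source — an OMIM-like disease gene list,
and GO-like / mouse-phenotype-like terms found over-represented among the
trait's locus genes (one-sided hypergeometric test, BH-adjusted p < 0.05
and log odds > 1) — to a maximum of 20. The sole gene of a single-gene
locus scores 1. Scores become per-locus sampling probabilities (total 1
per locus), and genes scoring ≥ 10 are flagged *likely positives* for
evaluation.

**Boosting.** The classifier is an additive expansion of four-leaf
regression trees fit under absolute (L1) loss, F(x) = f₀ + ν·Σₘ Tₘ(x),
with leaf values equal to median residuals and shrinkage ν = 0.1 by
default. Each tree sees a stochastic batch: 70% of loci, one positive
gene drawn per locus by its sampling probabilities, and as many negatives
drawn from genes outside all loci. A 20-tree *burn-in* phase refines the
positives — after each tree the top-scoring gene at every locus gains a
tally point, and genes holding more than 25% of their locus tally survive
— before 60 fresh trees are trained on the refined sampling weights.
Scoring uses six rounds of eight-fold cross-validation with loci (or, in
Mendelian mode, positive genes) held out, and the final per-gene output
is the clamped logit of F(x), a genome-wide log-odds of association.

**Evaluation and features.** The package includes AUROC, precision at
fixed recall with a binomial significance, a within-locus rank
permutation test, a top-score-at-locus empirical null, and Fisher
enrichment. A motif module builds binding-site features from scratch:
entropy-weighted PWM match scores (MMS), per-motif thresholds from a
three-component Gaussian mixture fit by EM, hit-to-gene count mapping,
and nested copy-number / percentile discretizers. A synthetic-data
generator with planted causal structure makes the whole pipeline testable
end to end.

## A worked example

```r
library(locusboost)

cfg    <- sim_config()                 # 2,000 genes, 15 loci, 10 planted features
genome <- make_genome(cfg)
trait  <- make_trait(genome, cfg)

loci <- map_loci(trait$tags, trait$ld, trait$hotspots, genome)
enr  <- term_enrichment(unique(unlist(loci$member_genes)),
                        trait$go_sets, genome$gene_id)
enr[, c("term_id", "n_overlap", "adj_p", "log_odds")]
#> # A tibble: 1 × 4
#>   term_id   n_overlap   adj_p log_odds
#>   <chr>         <int>   <dbl>    <dbl>
#> 1 go_term_1         8 0.00843     1.40

weighted <- weigh_loci(loci, genome,
                       omim_genes = trait$omim_genes,
                       go_genes = unique(unlist(enr$member_genes)))
scores <- cross_validate(weighted, trait$features, genome$gene_id,
                         training_config(), seed = 7)

lg <- scores$gene_id[scores$is_locus_gene]
auroc(setNames(scores$log_odds[match(lg, scores$gene_id)], lg),
      trait$truth$causal_genes)
#> [1] 0.984
```

The enrichment table shows the generator's planted evidence term being
rediscovered among the locus genes (8 of its members sit at loci,
adjusted p = 0.0084, log odds = 1.40), so its genes earn prior points.
The final AUROC of 0.984 says that after cross-validated training on the
binary features alone, planted causal genes outrank their locus
neighbours almost perfectly.

A thin command-line wrapper over the same functions ships in
`inst/cli/locusboost.R` (subcommands `map-loci`, `prioritize`,
`motif-scan`, `simulate`).

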