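# coexdiff

Differential gene-coexpression analysis for two-condition transcriptome
studies.

Gene-expression experiments that contrast two conditions — the motivating
case is *Drosophila* reared gnotobiotically (with a defined gut microbiota)
versus axenically (microbe-free), one sample per genetic line in each
condition — usually ask which genes change in *level*. `coexdiff` asks a
different question: which groups of genes change in how tightly they are
*co-expressed*, i.e. whether the conditions restructure the transcriptional
network itself. It is aimed at computational biologists analysing bulk (or
pseudo-bulked single-cell) RNA-seq with a handful of replicates per
condition.

## Method

Coexpression of a gene pair in one condition is the unsigned squared
Spearman correlation ρ² (the *coexpression index*, 0 = no co-regulation,
1 = perfect co-regulation irrespective of sign). The pipeline:

1. per-condition signed squared Spearman adjacency
   `a⁽ᶜ⁾ᵢⱼ = sign(ρᵢⱼ) ρᵢⱼ²`;
2. coexpression-change dissimilarity
   `dᵢⱼ = ( √(½ |a⁽¹⁾ᵢⱼ − a⁽²⁾ᵢⱼ|) )^β`;
3. topological overlap of the change network,
   `Tᵢⱼ = (ℓᵢⱼ + dᵢⱼ) / (min(kᵢ, kⱼ) + 1 − dᵢⱼ)`,
   `ℓᵢⱼ = Σᵤ dᵢᵤ dᵤⱼ`, `kᵢ = Σᵤ dᵢᵤ`;
4. average-linkage clustering of `1 − T`, a static cut at 71.2 % of the
   tree height range with a minimum module size, and merging of modules
   whose (unit-norm, sign-aligned) eigengenes lie within Euclidean
   distance 0.2;
5. permutation significance per module and module pair: the dispersion
   statistic `√(mean dᵢⱼ²)` over the module's pairs against B random
   sample-to-condition reassignments, `p = (1 + #{null ≥ obs}) / (B + 1)`,
   with Benjamini–Hochberg adjustment per test family;
6. strength contrasts of differentially coexpressed (DC) modules against
   the pooled non-DC modules — the organism's intrinsic coexpression
   baseline — per condition, plus transcriptome-wide Kolmogorov–Smirnov and
   rank-sum comparisons of the coexpression index, hypergeometric gene-set
   enrichment, and thresholded network export.

A seeded synthetic-data generator plants condition-dependent modules
(single latent factor per module, condition-specific loadings, negative
binomial counts) and returns the ground truth, so every stage is testable
against a known answer. See the methods vignette
(`vignettes/differential-coexpression.Rmd`) for the model, parameter
defaults and design rationale.

## Worked example

```r
library(coexdiff)

sim  <- simulate_expression(default_study_config(seed = 1))
expr <- vst_transform(filter_genes(sim$data, min_count = 5))
expr
#> coex_expr: 950 genes x 34 samples
#> conditions: axenic=17, gnotobiotic=17

corr <- lapply(conditions_of(expr), function(cc) spearman_matrix(expr, cc))
names(corr) <- conditions_of(expr)
compare_distributions(coexpression_index(corr[[1]]),
                      coexpression_index(corr[[2]]))
#> Coexpression-index distribution comparison (450775 pairs)
#>   KS D = 0.02604 (p = 0)
#>   rank-sum W = 1.052e+11 (p = 2.03e-185)
#>   medians: gnotobiotic = 0.03562, axenic = 0.03114 (gnotobiotic > axenic)

d   <- difference_dissimilarity(signed_adjacency(corr[[1]]),
                                signed_adjacency(corr[[2]]), beta = 4)
asg <- merge_similar_modules(expr,
         cut_tree(cluster_genes(topological_overlap(d)), min_size = 30))
asg
#> module_assignment: 2 module(s), 107/950 genes assigned
#>  1  2
#> 59 48
module_recovery_ari(asg, sim$truth)
#> [1] 0.89

permutation_test(expr, asg, B = 499, seed = 2)
#> Differential-coexpression permutation test (B = 499, alpha = 0.05)
#> within-module:
#>   module size statistic     p  padj   dc
#> 1      1   59    0.4667 0.002 0.002 TRUE
#> 2      2   48    0.4775 0.002 0.002 TRUE
#> between-module pairs flagged DC: 0/1
```

Reading the output: transcriptome-wide coexpression is higher in the
gnotobiotic-like condition (median index 0.0356 vs 0.0311, rank-sum
p ≈ 2e-185) — the direction expected when the planted modules are stronger
there. Module detection recovers the planted structure with adjusted Rand
index 0.89 over assigned genes (detected modules are conservative cores of
the planted ones), and both detected modules are flagged differentially
coexpressed at the permutation floor p = 1/(B+1) = 0.002. One call runs
everything and writes TSV tables plus a manifest:

```r
res <- run_pipeline(list(simulate = list(seed = 1)), out_dir = "out")
```

A thin command-line wrapper with subcommands (`simulate`, `preprocess`,
`coexpr`, `modules`, `permtest`, `export`, `enrich`, `run`) is installed at
`inst/scripts/coexdiff.R`.

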