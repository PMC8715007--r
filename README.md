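# microrev

**Drug-responsive gut microbes and their mediating metabolites from
longitudinal multi-omics.**

Many intervention studies profile three groups — healthy controls (WT), a
disease model (Tg), and treated disease animals (TgR) — at several ages,
with 16S taxon counts, untargeted fecal metabolomics, and a panel of
physiological indicators. `microrev` turns the discovery chain of such
studies into one tested, seed-reproducible pipeline:

| stage | method |
|---|---|
| diversity | Chao1 (bias-corrected), Shannon (nats), Gini–Simpson, evenness; Bray–Curtis & unweighted UniFrac; PCoA |
| screening | per-timepoint two-class PLS-DA (NIPALS) with VIP scores + Wilcoxon rank-sum + BH FDR |
| longitudinal filters | trend consistency across all timepoints; strict treatment-reversal toward control |
| validation | qPCR standard curves, absolute quantification, disease-vs-treated responsiveness |
| taxon network | CoNet-style ensemble: Pearson/Spearman/Bray–Curtis/symmetrised-KL, 1000 top + 1000 bottom candidate edges per measure, renormalized permutation null (1000 iterations) + bootstrap stability, per-measure BH, sign-consistent multi-measure merge |
| integration | tripartite taxon–metabolite–indicator network (Pearson ∧ Spearman, joint BH) and bridge-metabolite ranking |

The central screening statistic is the PLS-DA variable importance in
projection,

    VIP_j = sqrt( p * Σ_a SSY_a (w_aj / ||w_a||)² / Σ_a SSY_a ),

with `Σ_j VIP_j² = p`; taxa are screened at VIP > 0.7 per timepoint,
metabolites at VIP > 1 with p < 0.05. A **bridge metabolite** is one with
significant edges to both a taxon and an indicator in the tripartite
network — the pipeline's candidate mediator between microbiome and host
physiology.

A synthetic-data generator (`generate_study()`) plants known responsive
taxa (age-dependent multiplicative disease effects, partially reversed by
treatment), mediating metabolites tied to those taxa, and indicators tied
to those metabolites — with multinomial compositional counts — so every
stage can be checked against ground truth.

## Worked example

```r
library(microrev)

cfg <- pipeline_config(simulate = study_config(seed = 42), seed = 42,
                       out_dir = "run42")
res <- run_pipeline(cfg)

str(res$recovery)
#> List of 5
#>  $ taxa_trend_recall         : num 1
#>  $ taxa_trend_false          : int 30
#>  $ metabolite_reversed_recall: num 1
#>  $ bridge_top10_recall       : num 1
#>  $ bridge_top10_false        : int 0

res$bridges
#> # A tibble: 5 × 6
#>   metabolite degree taxon_degree indicator_degree sum_abs_rho  rank
#>   <chr>       <int>        <int>            <int>       <dbl> <int>
#> 1 met_235        41           35                6        25.5     1
#> 2 met_146        40           35                5        26.6     2
#> 3 met_083        40           35                5        25.8     3
#> 4 met_041        40           35                5        25.3     4
#> 5 met_125        40           35                5        24.8     5
```

All five planted responsive taxa were trend-consistent, all five planted
mediating metabolites passed the reversal filter and occupy the top of
the bridge ranking with no false bridges. (`taxa_trend_false = 30`
reflects a real property of compositional data, not a bug: when planted
taxa grow ~15-fold, every other relative abundance genuinely shrinks, and
a VIP-only screen picks that up — the reversal, validation and bridge
stages supply the specificity. See the methods vignette.)

Every run writes its stage outputs (TSV/GraphML/JSON) plus a
checksummed, fully deterministic `manifest.json` under `out_dir`;
re-running with the same seed reproduces every file byte-identically.

Individual stages are ordinary pipe-friendly functions if you prefer to
drive them yourself: `alpha_diversity()`, `beta_diversity()`, `pcoa()`,
`differential_screen()`, `trend_consistency()`, `reversal_screen()`,
`fit_standard_curve()`, `conet()`, `tripartite_network()`,
`rank_bridge_metabolites()`, with `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` graphics.

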