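---
title: "Methods: screening drug-responsive microbes and their mediating metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening drug-responsive microbes and their mediating metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A recurring design in gut–brain and pharmacomicrobiomics studies is a
three-group longitudinal experiment: healthy controls (WT), a disease
model (Tg), and treated disease animals (TgR), each profiled at several
ages with 16S amplicon sequencing, untargeted fecal metabolomics, and a
panel of physiological/biochemical indicators. The scientific question is
causal-chain-shaped: *which bacteria respond to the drug, which
metabolites do those bacteria produce or consume, and which host
indicators do those metabolites track?*

`microrev` implements that discovery chain as a reproducible pipeline:

1. **Diversity profiling** — Chao1, Shannon, Gini–Simpson, Shannon
   evenness; Bray–Curtis and unweighted UniFrac distances; PCoA.
2. **Differential screening** — per-timepoint two-class PLS-DA with VIP
   scoring, plus a two-sided Wilcoxon rank-sum test and BH correction.
3. **Trend consistency** — features must be selected with the same
   nonzero direction at every timepoint.
4. **Treatment reversal** — the treated group's median must move strictly
   back toward the control median at every post-treatment timepoint.
5. **qPCR-style validation** — absolute quantification against a standard
   curve; a taxon is responsive if disease vs treated differ significantly
   *and* treatment moves it toward control.
6. **Ensemble co-occurrence network** — four association measures,
   top/bottom candidate edges, renormalized permutation nulls with
   bootstrap stability, per-measure BH, sign-consistent multi-measure
   merge.
7. **Tripartite network and bridge ranking** — taxon–metabolite–indicator
   correlations (Pearson *and* Spearman, jointly BH-corrected); metabolites
   connected to both a taxon and an indicator are "bridges", the
   candidate mediators.

Because real studies rarely come with ground truth, the package ships a
synthetic-data generator that plants known responsive taxa, mediating
metabolites and linked indicators, so every stage of the pipeline can be
validated against what was planted.

# The synthetic study generator

`study_config()` / `generate_study()` emulate the processed data layer of
such a study (not raw reads or spectra). The generative model, fully
deterministic given one seed:

* Per-taxon baseline log-abundances are Normal(0, `taxon_base_logmean_sd`).
* A planted responsive taxon's expected abundance in the disease group is
  multiplied by `disease_effect^(t+1)` at timepoint index `t` ∈ {0, 1, 2},
  in the planted direction — a monotone, age-dependent dysbiosis.
* Treatment starts after the first sampling: the treated group carries the
  full disease effect at the first timepoint and `(1 − reversal_fraction)`
  of it afterwards.
* Expected abundances are closed to proportions and counts drawn
  **multinomially** at a per-sample log-normal library size. Closure is
  deliberate: it reproduces the compositionality of real amplicon data,
  which is exactly the artifact the network stage's renormalized
  permutation null exists to combat.
* A mediating metabolite's log-intensity is `link_strength` times its
  source taxon's latent log-abundance plus Gaussian noise; unplanted
  metabolites are independent log-normals.
* A linked indicator is the exponential of a signed sum of its mediators'
  latent log-values plus noise. The exponential keeps indicator values
  positive; downstream association tests are rank-based or applied on
  both scales, so this monotone transform changes nothing of substance.

Defaults (6 subjects/group, 3 groups, timepoints 8/9/10 months, 100 taxa,
300 metabolites, 11 indicators, 5 responsive taxa, 5 mediating
metabolites, `disease_effect = 2.5`, `reversal_fraction = 0.8`, mean
library 20 000) are sized to the study design this pipeline targets and
to minutes-scale runtime. They were chosen once, as the package's study
conditions, not tuned per analysis.

What the generator does **not** emulate: sequencing error, chimeras,
batch effects, chromatographic drift, zero-inflation beyond what the
multinomial induces, and subject-level autocorrelation (samples are drawn
independently across timepoints). Passing recovery tests therefore shows
the pipeline's logic is sound under the stated model, not that it is
robust to every real-data pathology.

# Screening model

PLS-DA is fit per timepoint on control vs disease, as PLS1 via NIPALS on
autoscaled predictors and a centered ±1 class code, two components by
default. The VIP score of feature $j$ is

$$\mathrm{VIP}_j=\sqrt{\,p\;\frac{\sum_a \mathrm{SSY}_a\,(w_{aj}/\lVert w_a\rVert)^2}{\sum_a \mathrm{SSY}_a}\,}$$

with $\mathrm{SSY}_a$ the response sum of squares explained by component
$a$; $\sum_j \mathrm{VIP}_j^2 = p$ always, so VIP ≈ 1 marks average
importance. Taxa are screened at VIP > 0.7 (no p cut), metabolites at
VIP > 1 together with rank-sum p < 0.05 — the conventional thresholds of
this workflow. The rank-sum test uses the exact null when both groups
have ≤ 10 samples without ties (the n = 6 design sits in this regime) and
the tie-corrected normal approximation otherwise.

Two facts about this screen are worth stating plainly:

* **Exact rank-based p-values are discrete.** At n = 6 vs 6 there are
  only ~20 attainable two-sided p-values, so the p distribution under the
  null is a step function, not continuous-uniform; its type-I error is
  calibrated (slightly conservative, ≈ 0.041 at nominal 0.05) but a
  Kolmogorov–Smirnov test against the continuous uniform will always
  reject, for any number of features. The package's tests assert
  calibration at several α levels rather than continuous uniformity.
* **Compositional closure couples taxa.** When planted taxa grow
  ~15-fold, all other relative abundances must shrink. With a VIP-only
  cut (no p threshold, per the genus screen convention) many unplanted
  taxa become genuinely — not spuriously — trend-consistent. The
  pipeline's specificity therefore comes from the later reversal,
  validation and bridge stages, not from the screen alone; the
  false-positive control of the screen itself is meaningful (and tested)
  only on null studies with `disease_effect = 1`.

Direction is taken from group medians (robust to heavy-tailed
abundances); ties give direction 0 and can never be trend-consistent.
Trend consistency requires selection at *every* timepoint with one
nonzero direction. Reversal requires strict shrinkage of
|median(treated) − median(control)| below
|median(disease) − median(control)| at *every* post-treatment timepoint.

# Ensemble co-occurrence network

Following the CoNet recipe: taxa are filtered (kept iff count sum ≥ 120
and occurrence ≥ 12 within at least one condition), closed to relative
abundances, and scored by four measures — Pearson, Spearman, Bray–Curtis
and symmetrised Kullback–Leibler divergence
$\tfrac12[KL(p\|q)+KL(q\|p)]$ (pseudocount $10^{-6}$, renormalised). Per
measure, the 1000 top and 1000 bottom pairs become candidates (ties broken
lexicographically for determinism); for correlations the top tail is
co-presence, for dissimilarities the bottom tail is.

Significance is a permutation test: one feature of the pair is shuffled
per iteration, and — by default for taxon–taxon edges — every sample is
re-closed to proportions after the shuffle, so the null *retains* the
compositional coupling and only destroys the pair-specific association
(the ReBoot idea). The two-sided p is $(1+\#\text{extreme})/(N+1)$.
Correlation nulls are centered at zero by construction; the nonnegative
dissimilarity nulls are not, so for Bray/KL both the observed and null
scores are centered at the null mean before the extremeness comparison —
applying the raw absolute-value formula to a nonnegative score would make
co-presence (small-dissimilarity) edges undetectable by construction.
Bootstrap resampling of samples yields a 2.5–97.5% score interval; edges
whose interval covers the null expectation are flagged `unstable` but not
removed — stability flagging and significance are reported separately
rather than silently blended.

One permutation index set and one bootstrap index set (drawn from R's RNG
at the stage seed) are shared by all edges of a call. This makes the run
deterministic and fast; per-edge p-values remain individually valid, and
since each simulated dataset in the calibration tests draws fresh
indices, calibration is unaffected.

Per measure, BH is applied across that measure's candidates; an edge
enters the final network iff it passes q < 0.05 in ≥ 2 measures with one
sign. The merge rule is deliberately transparent (support counting +
Fisher's combined p over supporting measures) rather than a reimplementation
of any particular historical tool default, which is not publicly specified;
`min_support = 1` recovers the simple union.

The hot loop (≈ 8000 candidate edges × 2000 null/bootstrap evaluations)
is implemented in C++; all randomness is drawn in R so a single seed
governs everything.

# Tripartite network and bridges

The taxon layer (trend-consistent taxa, as relative abundances), the
metabolite layer (reversed metabolites, total-ion normalised) and the
indicator layer are correlated across shared samples with both Pearson
and Spearman; analytic two-sided p-values come from the t transform
$r\sqrt{(n-2)/(1-r^2)}$. BH runs jointly over *all* cross-layer tests of
both methods, and an edge is kept only when both methods pass q < 0.05
with agreeing sign — a conservative consensus rule. Edge weight is the
Spearman rho.

A **bridge metabolite** has at least one significant taxon edge and at
least one significant indicator edge; bridges are ranked by total degree,
ties by summed |rho|, then id. These are the pipeline's nominated
mediators.

# Numerical and design choices

* Shannon uses natural log; Simpson is reported as Gini–Simpson
  $1-\sum p_i^2$ (values near 1 for diverse communities). Chao1 is the
  bias-corrected form $S_{obs}+F_1(F_1-1)/(2(F_2+1))$, defined also when
  no doubletons exist. No rarefaction is applied — depth normalisation is
  the caller's decision via proportions.
* PCoA retains negative eigenvalues in the report but builds axes from
  positive ones only (no Lingoes/Cailliez correction); proportions
  explained are over positive eigenvalues.
* Unweighted UniFrac is delegated to `picante::unifrac` behind the
  package's pairwise interface; star-like basal polytomies are resolved to
  zero-length branches first, which leaves the distance unchanged.
* NIPALS uses tolerance 1e-10 with a 500-iteration cap (one pass suffices
  for a univariate response); zero-variance predictors keep zero weight.
  Degenerate screens (e.g. the two groups are literally identical, so no
  response variance is explainable) yield VIP 0 for all features rather
  than an error, so a null screen returns "nothing selected".
* All stage randomness derives from one seed through fixed per-stage
  substreams, so any stage can be re-run in isolation and two runs of
  `run_pipeline()` are byte-identical — wall-clock timings are therefore
  written to a separate `run.log`, not the checksummed manifest.
* The qPCR validation stage of `run_pipeline()` on synthetic studies has
  no instrument Ct values to read, so it simulates a dilution-series
  standard curve (slope −3.32, intercept 38, small Gaussian noise) and
  derives per-sample Ct values from the counts before quantifying and
  testing — a synthetic stand-in exercising the same code path a wet-lab
  table would take via `fit_standard_curve()` / `quantify_copies()` /
  `validate_responsive()`.

# Problem sizes used in the test-suite

The packaged tests run the default study (54 samples, 100 taxa, 300
metabolites, 11 indicators) across 10 seeds for planted-structure
recovery, 2000 simulations each for the two null calibrations, 50 random
datasets for the VIP oracle, and 2000 random vectors for the BH oracle —
sizes chosen to make the suite complete in minutes on one CPU while
keeping Monte-Carlo error well inside the asserted bands.

# Known limitations

* Trend screens treat timepoints as independent cross-sections; subject
  identity is carried in the metadata but no mixed-effects structure is
  modelled.
* The ensemble merge is a transparent stand-in, not a replica of any
  specific legacy tool's (undocumented) merge; exact numerical parity
  with such tools is a non-goal.
* Indicator layers measured per subject endpoint rather than per sample
  must be joined by the caller before `tripartite_network()`.
* The generator's independence assumptions (above) mean recovery results
  bound what the pipeline can do under clean conditions; they are not a
  field-data benchmark.
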