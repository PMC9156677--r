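# sigomics

An integrated R pipeline for two-cohort microbiome–metabolome studies,
built for the common design where ~10 animals (or subjects) per cohort
yield a species-level 16S abundance table and an NMR-quantified stool
metabolite table, and the question is whether the cohorts differ, which
species and metabolites drive the difference, and how the species organize
into co-varying consortia — *species-interacting groups* (SIGs).

It is written for microbiome researchers who want the whole analysis —
diversity, supervised discrimination, network inference, cross-omics
correlation — as composable, tested R functions rather than a fixed
script, plus a synthetic-data generator that plants known structure so
every stage can be validated against ground truth.

## What it computes

**Diversity and ordination.** Per-sample richness and Shannon entropy
(H = −Σ pᵢ log pᵢ, nats); Bray–Curtis dissimilarity
d(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ); principal coordinate analysis with negative
eigenvalues reported, not corrected; one-way PERMANOVA (distance-based
pseudo-F) and ANOSIM (R = (r̄_B − r̄_W)/(M/2) on ranked distances), both
with permutation p = (#{stat_perm ≥ stat_obs}+1)/(n_perm+1) at 999
permutations by default; complete-linkage clustering with a Fisher-exact
test of the 2×2 cluster-by-cohort table.

**Discriminant analysis.** Two-class PLS-DA by NIPALS with VIP scores
VIP_j = √( p · Σ_a SSY_a w²_aj / Σ_a SSY_a ), normalized so Σ VIP² = p;
classification reliability by *double cross-validation* (inner 5-fold loop
selects the component count, outer stratified 5-fold loop estimates
per-class rates, 50 repeats); Mann–Whitney / Kruskal–Wallis univariate
tests; fold ratios of group means; volcano tables.

**Correlation network and SIGs.** Pearson correlations on
quantile-normalized, standardized abundances of species with prevalence
≥ 5%; per edge a leave-one-out *averaged* p-value (mean of the n
jackknife p-values); edges pruned by the adaptive two-stage
Benjamini–Hochberg procedure at FDR 10%; eight thickness categories from
q-quantile bins; consensus SIG detection from 100 Louvain runs under
randomized node order (co-classification > 0.5), with per-species
stability; degree, normalized betweenness ("keystonness"); Fisher tests
of cohort opposition between SIGs.

**Cross-omics.** Species × metabolite Pearson matrices within a cohort,
Fisher z = atanh(r)·√(n−3), two-stage-FDR flagging, clustered heatmap
export.

**Derived metrics.** NMR quantification against internal standards
(TSP for stool µmol/g, creatine for serum mol/mol), 2^−ΔΔCt qPCR fold
changes, novel-object discrimination index, paired-pulse ratio, and
baseline-normalized fEPSP time courses.

**Synthetic data.** A logistic-normal/multinomial generator that plants
correlated species blocks (the SIGs to be recovered), cohort shifts on
block species, and metabolite fold changes (defaults: formate ×2.81,
acetate ×1.35), with full ground-truth bookkeeping and a null variant for
calibration.

## Worked example

```r
library(sigomics)

sim   <- simulate_cohort_study(simulation_params(n_species = 40), seed = 7)
study <- sim$study        # 20 samples (10 SE, 10 EE), 40 species, 37 metabolites
res   <- run_sig_pipeline(study, run_config(seed = 7))

tidy(res$permanova)
#>   method    statistic p_value n_permutations
#> 1 PERMANOVA      2.95   0.038            999

glance(res$network)
#>   n_nodes n_edges n_sigs prop_positive
#> 1      40      69     23         0.623

res$network$partition$membership[1:14, ]
#>    species   sig stability
#>  1 sp001       1         1     <- planted block 1, recovered as SIG 1
#>  ...
#>  8 sp008       2         1     <- planted block 2, recovered as SIG 2
#>  ...

tidy(res$sig_tests[["1-2"]])
#>   method                        statistic  p_value
#> 1 Fisher exact (SIG x affinity)       Inf 0.000583
```

The two planted 7-species blocks come back as two SIGs with stability 1,
and their cohort affinities oppose exactly (Fisher p = 2/C(14,7) ≈
0.000583). The planted metabolite effect is recovered too:

```r
fold_ratio(metabolite_matrix(study)[, "formate"], cohort_labels(study))
#>      fr higher_cohort fr_infinite mean_higher mean_lower
#> 1  2.81 EE            FALSE              40.1       14.3

head(res$volcano[, 1:3], 2)
#>   metabolite log2_fr   p_value
#> 1 formate     -1.49  0.0000108     # direction SE/EE by default
#> 2 acetate     -0.382 0.000325
```

Networks export to Gephi-ready files with all node and edge attributes:

```r
write_network(res$network, "network.gexf", format = "gexf")
write_report(list(permanova = res$permanova, anosim = res$anosim),
             "report.json", config = run_config(seed = 7))
```

## Documentation

The methods vignette (`vignettes/sigomics-methods.Rmd`) describes the
statistical models, the synthetic-data generator and its calibration, the
numerical choices, and known limitations. Every exported function carries
roxygen documentation with its formula and defaults.
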