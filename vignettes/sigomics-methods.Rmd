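---
title: "Methods: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigomics)
```

This vignette is the package's account of its statistics: what each stage
assumes, which tunables matter and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and where the
design was genuinely open and a choice had to be made.

## The study design the pipeline assumes

One two-level cohort factor (the canonical labels are `SE` and `EE`, a
standard versus enriched housing environment, but any two labels work),
roughly ten samples per cohort, a species-level abundance table derived
from 16S sequencing, and optionally a metabolite concentration table in
µmol per g stool. All tables are samples-as-rows with a `sample_id`
column; sample order is taken from the metadata and misalignments are
errors, never silent drops. The analysis is cross-sectional: each sample
is treated as an independent draw from its cohort.

## Normalization

Counts become relative abundances by row division. For multivariate and
network analysis each feature is then *gaussianized*: ranks are mapped to
standard-normal quantiles at plotting positions $(r - 0.5)/n$ (ties share
average ranks) and the result is centered and scaled to population
variance one. The transform is monotone within each feature and invariant
to any strictly monotone per-feature distortion of the input, which makes
correlations comparable between features with wildly different dynamic
ranges — a dominant species versus a rare one, an abundance versus a
concentration. The plotting position $(r-0.5)/n$ is symmetric and keeps
the extreme quantiles finite; average-rank tie handling keeps the
transform deterministic. Constant features cannot be ranked and pass
through as zeros with a warning. The prevalence filter (strict positivity
in at least 5% of samples, inclusive) runs *before* gaussianization, so
the transform sees only the features that can become network nodes.
Standardization uses the population divisor $n$, so "variance one" holds
exactly on the transformed columns.

## Diversity and permutation tests

Richness counts detected species; Shannon entropy uses natural logs
(ecology convention; the base is an argument). Bray–Curtis dissimilarity,
computed through `vegan`, feeds three downstream consumers:

* **PCoA** by classical scaling (Gower double-centering of $-d^2/2$).
  Bray–Curtis is not Euclidean-embeddable in general, so negative
  eigenvalues can appear; they are reported untouched and the proportion
  explained is taken over the positive part of the spectrum only.
* **PERMANOVA** with the one-way distance-based pseudo-F
  ($SS_{total}=\sum_{i<j} d_{ij}^2/n$, within-group sums with divisor
  $n_g$), and **ANOSIM** on ranked distances. Both use free relabeling
  (no strata) and the estimator $p=(\#\{stat_{perm}\ge stat_{obs}\}+1)/
  (n_{perm}+1)$, which counts ties as exceedances; at the default 999
  permutations the smallest attainable p is $1/1000$. ANOSIM, being
  rank-based, is invariant to monotone transformation of the
  dissimilarities; PERMANOVA is not — the test suite asserts exactly this
  asymmetry. With very small groups a random relabeling occasionally
  recreates the observed split, so even infinitely separated clusters can
  report $p = 2/1000$; this is a property of permutation inference, not a
  defect.
* **Cluster–cohort concordance**: complete-linkage agglomeration, cut at
  two clusters, tested by a two-sided Fisher's exact test
  (table-probability method). Merge ties are resolved by `hclust`'s
  deterministic order. With more than two cohorts the dendrogram is
  returned and the test is skipped.

## PLS-DA, VIP and double cross-validation

The two classes are encoded as a single centered ±1 response and
components are extracted by NIPALS (weights $w_a \propto X'y$ normalized,
scores $t_a = Xw_a$, deflation by $t_a p_a'$). This is the PLS1 special
case, exact for a two-level factor; multi-class fitting is out of scope
and three-or-more-group univariate questions go to Kruskal–Wallis.

VIP scores use
$\mathrm{VIP}_j=\sqrt{p\,\sum_a SSY_a w_{aj}^2 / \sum_a SSY_a}$ with
$SSY_a = q_a^2\, t_a' t_a$, so $\sum_j \mathrm{VIP}_j^2 = p$ identically —
the suite checks this to $10^{-9}$ on every fitted model — and the
conventional "VIP > 1" threshold marks features contributing more than an
average share.

Classification reliability uses *double* cross-validation: an inner
stratified 5-fold loop on each outer training split picks the component
count (1–5) minimizing classification error, an outer stratified 5-fold
loop scores held-out samples by the nearest class centroid in latent-score
space, and the whole procedure repeats 50 times with reshuffled folds.
Per-class correct-classification rates are reported as mean ± sd over
repeats. Neither the fold counts nor the prediction rule is canonical in
the literature; 5×5×50 and nearest-centroid are this package's fixed,
documented choices. On label-permuted data the procedure sits at chance
(the suite checks the 50% ± 15 percentage-point envelope and a binomial
test on one repeat's held-out predictions).

## The correlation network and SIG detection

Edges start from all species pairs surviving the 5% prevalence filter.
The correlation coefficient is the full-sample Pearson r on gaussianized
data; its p-value is the *leave-one-out average*: for each left-out
subject the two-sided Pearson p (t statistic, $n-3$ df) is computed on
the remaining $n-1$ samples, and the $n$ values are averaged. The mean is
dominated by the largest jackknife p, i.e. by the deletion that most
weakens the correlation, so an edge must not hinge on a single subject.
This is deliberately conservative. The literature sometimes wraps this in
a "5-fold cross-validated" scheme whose mechanics are not operationally
defined; plain leave-one-out is the reproducible core and is what this
package implements.

Pruning uses the adaptive **two-stage Benjamini–Hochberg** step-up: a
first BH pass at $q'=q/(1+q)$ estimates the true-null count
$m_0 = m - r_1$, then a second BH pass runs at $q'm/m_0$ (all rejected if
$m_0=0$). The reported q-values are the second-stage adjusted values
rescaled by $m_0/m$ and floored at p. Surviving edges carry their sign
and a 1–8 thickness category from equal-count q-quantile bins (8 =
smallest q); the category count is fixed at eight, the binning rule is
this package's choice.

**SIG detection** runs Louvain modularity optimization 100 times at
resolution 1, each under a randomized node processing order, and takes
the consensus: species pairs co-classified in more than half of the runs
form the SIG graph, whose connected components are the SIGs. Per-species
stability (mean co-classification with SIG partners) is reported so users
can recompute any dispersion-based grouping they prefer. One choice here
deserves emphasis: community attraction uses **positive edges only**
(weighted by r). In a signed correlation network a negative edge is
evidence that two species belong to *opposing* groups; weighting Louvain
by |r| lets the magnitude of an anti-correlation pull opposed blocks into
one community, which is exactly backwards. On synthetic data with two
planted anti-correlated blocks, |r|-weighted consensus merges them in
roughly a quarter of runs, while positive-edge consensus recovers them
cleanly. Negative edges remain in the network, are exported, and drive
the SIG-opposition Fisher test (2×2 SIG × cohort-affinity table,
two-sided).

Node centralities are degree and shortest-path betweenness on the
unweighted pruned graph, normalized by $(n-1)(n-2)/2$. "Keystonness" —
the display quantity that scales node labels in the conventional network
figure — is the normalized betweenness; whether it should instead be a
composite of degree and betweenness is unsettled, and betweenness alone
is the simplest defensible reading.

## Cross-omics correlation

Within a chosen cohort (or all samples), every species–metabolite pair
gets the Pearson r, its two-sided p ($n-2$ df), and the Fisher
variance-stabilized z-score $z=\mathrm{atanh}(r)\sqrt{n-3}$ — the "z"
displayed in cross-correlation heatmaps; an alternative reading
(matrix-wide standardization of r) exists, but the Fisher transform is
the one with a sampling-theory justification. The leave-one-out averaged
p is computed alongside the plain p for every cell, since published
correlation p-values in this design are sometimes one and sometimes the
other. Two-stage BH at 10% across all cells flags the associations;
heatmap rows are ordered by complete-linkage clustering of the z
profiles.

## The synthetic-data generator

`simulate_cohort_study()` draws, per sample, a latent Gaussian vector
over species: per-species baselines $\mu_j \sim N(0, 1)$, a shared
factor per planted block giving within-block latent correlation
$\rho$ (default 0.8) via $z_j = \mu_j + \sqrt{\rho}\,f_b +
\sqrt{1-\rho}\,\varepsilon_j$, and a cohort mean shift (default 1 log
unit) on block species in their enriched cohort — odd blocks enriched in
the second cohort, even in the first, so consecutive blocks oppose. The
latent vector passes through a softmax to a composition; counts are
multinomial at Poisson-distributed depth (mean 28123); zero-inflation
(default 0.3) then hits non-block species with below-median baselines.
Metabolites are log-normal with planted enriched/reference mean ratios
(defaults: formate 2.81, acetate 1.35) and noise CV 20%
($\sigma_{\log} = \sqrt{\log(1+0.2^2)} \approx 0.198$), matching the
SEM-to-mean ratios typical of NMR quantification at this sample size.

The logistic-normal/multinomial route was chosen over a Dirichlet because
a Dirichlet cannot carry a planted correlation structure. Zero-inflation
deliberately spares the planted blocks: the generator's purpose is to
provide ground truth for recovery experiments, and corrupting the planted
structure itself would conflate generator noise with detector failure;
non-block species still exercise the prevalence-filter code path. The
baseline spread (sd 1) was calibrated once against the requirement that
CLR-transformed observed data recover the latent within-block correlation
to ±0.15 at n = 200 (measured ≈ 0.72–0.77 for a latent 0.8, across 30 and
145 species) — the residual attenuation comes from multinomial counting
noise on rare species, which is exactly what real 16S data do.

What the generator does **not** emulate: taxonomic correlation beyond
the planted blocks, depth-dependent taxon detection bias, batch and cage
effects, longitudinal dependence, and compositional effects of a few
hyper-dominant taxa. Passing recovery tests on these simulations
therefore shows the *machinery* is correct and calibrated, not that real
data meet its assumptions.

`simulate_null_study()` zeroes every cohort effect, block correlation and
metabolite fold, making the cohort labels exchangeable — the reference
distribution behind the size and FDR calibration checks.

## Calibration results and problem sizes

The experiments the test suite and `scripts/acceptance.R` run, at the
sizes they use (chosen to exercise the study's own dimensions while
keeping a full run in tens of seconds):

* PERMANOVA (999 permutations) and Mann–Whitney on 200 null simulations
  at n = 10 per cohort: rejection counts within the exact binomial 95%
  envelope of a nominal 5% test.
* Two-stage BH on 200 × 100 uniform p-values: mean false-discovery
  proportion at or below the 10% level.
* Planted-SIG recovery: 2 blocks × 7 species at latent r 0.8, n = 20,
  30 species total, generator defaults otherwise; adjusted-Rand-index-1
  rate over 50 seeds. Measured per-seed recovery probability is ≈
  0.93–0.95: every failure is a species whose *realized* sample
  correlation with its block at n = 20 leaves it without a single
  FDR-surviving edge — its six within-block edge statistics co-move
  through the species' own noise vector, so they fail together with
  probability of order 1% per species. This is an information limit of
  n = 20 under a conservative edge p-value and 10% FDR, not a detector
  property; recovery is essentially perfect at n ≥ 40 or r ≥ 0.9.
* Double-CV PLS-DA on a strongly shifted simulation (shift 3): per-class
  rates ≥ 95%; on permuted labels: chance.
* Exact oracles: betweenness against exhaustive path enumeration on all
  random graphs up to 7 nodes; Fisher's exact against full hypergeometric
  enumeration of every 2×2 table with total up to 20; PCoA distance
  reconstruction to $10^{-8}$ on Euclidean-embeddable input.

## Numerical and degenerate-input policy

Permutation p-values never report zero (the +1 estimator). Correlation
p-values are clamped away from 0 before FDR adjustment. Jackknife
replicates with a zero-variance column contribute p = 1 with a warning.
Constant features are dropped (PLS-DA) or passed through as zeros
(gaussianize) or marked undefined (cross-correlation), always with a
warning. A fold ratio over a zero mean reports `Inf` with an explicit
flag rather than failing. All randomized procedures take an explicit
seed, restore the caller's RNG state, and are bit-reproducible; reports
embed the seed and thresholds that produced them.

## Known limitations

Pearson-on-gaussianized-data is not a compositionally aware association
measure; with few dominant taxa, shared-denominator effects can induce
spurious correlation (SparCC-style corrections are out of scope by
design). The PLS-DA is strictly two-class. The double-CV fold structure
and the consensus threshold 0.5 are conventions, not estimates. The
discrimination index defaults to the (novel − familiar)/total form; the
novel/total variant is available via `method = "ratio"` since both
appear in the behavioral literature, and they differ by an affine map.
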