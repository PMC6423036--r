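---
title: "Methods and design of the dexnet pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the dexnet pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dexnet)
```

`dexnet` chains six statistical stages — cross-cohort meta-analysis of
differential expression, gene-set enrichment, drug connectivity, TF/kinase
network enrichment, seed-gene association signatures, and Bayesian
colocalization — into one pipeline that can be exercised end-to-end on
synthetic data with known ground truth. This vignette explains each model,
its assumptions, the tunable parameters, and the design decisions taken
where the methodology was genuinely open.

## Meta-analysis of differential expression

**Model.** Each cohort is a genes-by-samples matrix of log2-scale,
normalized expression with case/control labels. Per gene and study the
effect size is Hedges' g: the standardized mean difference
$d = (\bar x_{case} - \bar x_{ctrl}) / s_{pooled}$ corrected by
$J = 1 - 3/(4(n_1+n_2-2)-1)$, with sampling variance
$\mathrm{var}(g) = (n_1+n_2)/(n_1 n_2) + g^2/(2(n_1+n_2))$. Expression is
standardized per feature (mean 0, sd 1) first; since $g$ is invariant to
affine transforms this only fixes the scale convention. Probesets are
condensed to genes by keeping the feature with the largest $|g|$ — the
least likely by chance — with ties broken by feature id so the result does
not depend on row order.

Across studies we use the DerSimonian–Laird random-effects model: fixed
weights $w_i = 1/v_i$, heterogeneity $Q = \sum w_i (g_i - \bar g_w)^2$,
moment estimate $\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w))$,
random-effects weights $w_i^* = 1/(v_i + \tau^2)$, combined effect
$\hat\mu = \sum w^* g / \sum w^*$ and meta-Z $z = \hat\mu\sqrt{\sum w^*}$.
The gene universe defaults to genes present in every study
(`min_studies = NULL`), the convention for multi-platform microarray
meta-analyses; a smaller `min_studies` relaxes this.

**Permutation FDR.** Case/control labels are shuffled independently within
each study (preserving group sizes) and the entire effect-size-to-meta-Z
pipeline is recomputed; the FDR at threshold $|z_0|$ is the expected null
exceedance count divided by the observed count, clipped to $[0,1]$,
floored at $1/(n_{perm} \cdot n_{genes})$ so no FDR is exactly zero, and
made monotone non-increasing in $|z|$ (q-value style: each gene receives
the minimum raw FDR over thresholds at or below its own $|z|$). The
default 1000 permutations match common practice; the bundled recovery
experiments use 200, which is sufficient for FDR resolution at the 0.05
level on 2000 genes while keeping the suite fast.

**Covariate adjustment.** Known factor covariates (sex, batch) are
adjusted with the empirical-Bayes location/scale (ComBat) model from the
sva package, protecting the case/control effect via the model matrix.
Hidden covariates are estimated by residualizing expression on the group
label and taking right-singular vectors of the residual matrix; components
are retained while their variance explained exceeds the 95th percentile of
row-permuted residual matrices (parallel analysis, $\alpha = 0.05$, capped
at `n_max`); the permuted matrices are re-projected onto the residual
space of the design so that observed and null singular values share the
same rank structure — without this the null is deflated and pure noise
yields spurious surrogates. Candidate covariates are screened for *widespread*
effects: per-gene simple regressions, then a one-sample KS test of the P
value distribution against U(0,1); a candidate is selected when KS
$P < 0.01$ — under the null the P distribution is uniform, and a covariate
touching many genes drags it left. Selected covariates are removed per
gene by Huber IRLS (tuning constant 1.345, at most 50 iterations, OLS
fallback on non-convergence), keeping intercept + residuals.

**A calibration caveat, and why the recovery experiment skips adjustment.**
The estimated surrogates are, by construction, orthogonal to the group
label. Removing them strips variance from every direction *except* the
group direction, so whatever chance alignment the hidden covariate had
with the observed labels stays in the data while the permutation null —
built from re-randomized labels — no longer sees it. Empirically this
inflates the realized FDR of the label-permutation estimate (0.23 after
adjustment versus 0.09 without, in the bundled five-study experiment).
The recovery experiments therefore measure the meta-analysis applied to
the generated matrices directly; the adjustment operators are validated
by their own targeted checks (surrogate-truth correlation above 0.8,
selection behavior on planted versus noise covariates, robust-versus-OLS
slope behavior under gross outliers). On real data, where confounding is
not generated under the analyst's control, adjustment remains the right
default — but permutation FDRs after data-driven covariate removal should
be read as approximate.

**Per-study signatures.** Single-cohort datasets (e.g. perturbation
experiments) use the same machinery without combination:
`per_dataset_z()` returns $z = g/\sqrt{\mathrm{var}(g)}$ per condensed
gene as a ranked signature, with ties broken by gene symbol. We
deliberately use this one effect-size route throughout rather than a
moderated-variance (limma-style) fit for some datasets, keeping per-study
statistics comparable across the pipeline.

## Gene-set enrichment

**KS-like enrichment score.** For a set of size $t$ whose members sit at
ascending positions $V(1) \le \dots \le V(t)$ in a ranked list of length
$n$, the score is the larger of
$a = \max_j (j/t - V(j)/n)$ and $b = \max_j (V(j)/n - (j-1)/t)$, signed
positive when the set concentrates at the top. The weighted variant
replaces $j/t$ by the cumulative $|score|^p$ fraction; exponent 1 is the
default for signature-versus-module tests and exponent 0 (classic,
rank-only) is used where scores are not meaningful, e.g. the compound
ranking. Choosing this single statistic for both the gene-set and the
drug-connectivity stages keeps the two enrichment notions identical, and
it satisfies the boundary property that the full universe as a set scores
$|ES| \le 1/n$.

**Permutation P values.** The null permutes gene labels: scores stay
fixed and set membership lands at uniformly random positions. Because of
that, the null ES distribution depends only on the overlap size $t$, and
one sample of $n_{perm}$ draws is shared across sets of equal $t$ —
exactly equivalent to per-set permutation and far faster. P values are
two-sided on $|ES|$ with the $+1$ correction
($P = (1 + \#\{|ES_{null}| \ge |ES_{obs}|\})/(1 + n_{perm})$), so the
smallest attainable P is $1/(1+n_{perm})$; the sign of the observed ES is
reported separately as the direction. Sets overlapping the signature in
fewer than 5 genes (2 for compound classes) are skipped.

**Set-vs-set enrichment** uses Fisher's exact test on the 2x2 table in a
stated universe, reporting both the sample odds ratio and the
conditional-MLE odds ratio with the exact P (one-sided "greater" for
enrichment, two-sided available). Multiple testing uses Benjamini-Hochberg
or Bonferroni as appropriate; P values from several ChIP sources for one
TF are combined with Fisher's method ($\chi^2 = -2\sum\ln p$, $df = 2k$).

## Drug connectivity

Replicate rankings of one compound are merged into a prototype ranked
list (PRL): repeatedly take the two lists at smallest Spearman footrule
distance $\sum_g |r_a(g) - r_b(g)|$ and replace them by their Borda merge
(re-rank of the mean rank, ties by gene symbol) until one list remains.
Distance ties are broken on a canonical key of the rank vectors, making
the result invariant to replicate order. The connectivity of a module in
a PRL is the unweighted KS statistic above; positive scores mean the
module sits at the up-regulated end (rank 1).

The permutation null shuffles the PRL's gene labels and rescores — the
documented choice over regenerating replicate sets, which would be
computationally unbounded; as with GSEA the null depends only on
$(n, t)$ and is shared across compounds. P values are two-sided with the
$+1$ correction and BH-adjusted across compounds. Target-class
(chemogenomic) enrichment ranks compounds by connectivity score and runs
the exponent-0 KS test of each class over that ranking with a
compound-label permutation null.

## TF and kinase networks

Regulons follow the `TF::source` naming convention (one ChIP experiment
per source set). Each source set is tested against the module by one-sided
Fisher exact in the gene universe; sources of one TF are Fisher-combined;
BH runs across TFs with a default significance threshold of FDR < 0.01.
The TF-PPI network is the significant TFs plus their direct interaction
partners, trimmed uniformly to an expression filter — seed TFs failing the
filter are dropped too, the simplest consistent reading of trimming "the
combined network"; the filter itself is caller-provided, with
`expressed_genes()` offering a detection-quantile helper since no
universal low-expression cutoff exists. Kinase-substrate sets are then
tested against the network node set (Fisher exact, greater) with both BH
and Bonferroni reported and an explicit rank column, and
`network_module_overlap()` reports which fraction of the module is
recaptured by its own regulatory network.

## Association signatures

For a seed gene, Pearson r against every other gene across samples is
transformed to $z = \mathrm{atanh}(r)\sqrt{n-3}$, a standard-normal score
under the null — the scaled form is used precisely so that downstream
consumers can treat it as a Z statistic. Correlations are clipped at
$\pm(1 - 10^{-12})$ before `atanh` so a perfectly correlated gene yields a
large finite z rather than infinity. Consensus across contexts (cell
lines) is unweighted Stouffer, $\sum z_i/\sqrt{k}$, over the genes present
in all contexts; correlations are computed across all samples of a study
without conditioning on treatment group.

## Colocalization

Per variant and trait the Wakefield log approximate Bayes factor is
$\tfrac12\ln(1-r) + \tfrac12 r z^2$ with $r = W/(V+W)$, $V = se^2$ and
prior effect variance $W$. Prior effect sd defaults to 0.15 for
quantitative traits (0.2 on the log-odds scale is conventional for
case/control), and per-hypothesis priors to
$p_1 = p_2 = 10^{-4}, p_{12} = 10^{-5}$ per variant. The five hypothesis
sums are assembled entirely in log space with log-sum-exp; the H3
cross-term over distinct variant pairs is computed exactly pairwise for
loci up to 200 variants and by the product-minus-diagonal identity with a
`log1p` cancellation guard above that (the two paths agree to $10^{-6}$
in tests). A single shared variant leaves H3 as an empty sum
(probability 0), not an error. Genes are called per tissue at
PP4 $\ge 0.75$ and the cross-tissue intersection is reported as the
high-confidence set.

When only $(p, maf, n)$ are available, $|z|$ is recovered from the
two-sided P and the standard error from
$1/\sqrt{2\,maf(1-maf)\,n}$ (times $1/\sqrt{cf(1-cf)}$ for case/control
traits); the sign is unrecoverable but the ABF depends only on $z^2$.
Rescaling one trait's beta and se by a common factor changes $V$ relative
to the fixed prior $W$ and therefore the posteriors; with
`scale = "z"` the ABF is computed from z statistics alone ($V = 1$,
prior on the z scale) and posteriors become exactly scale-invariant.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of (parameters, seed) and write/read
cleanly through the package's TSV/GMT formats.

* `sim_multistudy_expression`: Gaussian noise (sd 1) on the log2 scale —
  matching log2-transformed normalized arrays — around N(7, 1) gene
  baselines; DE genes (10% by default) shifted in cases by ±0.8 with
  per-study attenuation U(0.8, 1); a balanced two-level batch with
  N(0, 0.5) per-gene offsets; one standard-normal hidden covariate
  loading on 30% of genes with N(0, 1) loadings; 20% of genes duplicated
  as two probesets to exercise condensation. Five studies of 25 vs 25.
  Not emulated: probe-level effects, heavy-tailed noise,
  platform-specific missingness, gene-gene correlation beyond the single
  hidden factor.
* `sim_compound_profiles`: 200 compounds x 3 replicate rank permutations
  of 1000 genes; perturbing compounds (10%) pull their target set's ranks
  toward an extreme by n/2 rank units with sd n/10 replicate noise,
  clamped to the valid range. By default the perturbing compounds form
  one directionally coherent class on one target set — the planted
  condition the recovery experiments quantify — with decoy sets and decoy
  compound classes alongside; mixed directions and multi-set assignment
  are available via `directions` and `active_sets`.
* `sim_regulon_ppi`: 100 TFs with 1-3 ChIP source sets of 100 genes;
  enriched TFs (10) draw module genes at 3.5x the background rate; a
  TF-partner PPI graph with Poisson(5) degree; the planted kinase's
  substrates cover 60% of the enriched TFs and their neighbors. TFs and
  partner proteins are namespaced apart from target genes, so
  module-in-network overlap is exercised on constructed fixtures instead.
  Not emulated: realistic PPI topology (hubs, clustering), regulon size
  heterogeneity.
* `sim_coloc_locus`: 500 independent variants (no LD — the
  single-causal-variant assumption of the model holds exactly, a
  documented simplification), maf U(0.05, 0.5), se from
  $1/\sqrt{2\,maf(1-maf)\,n}$ at n = 5000, causal effect 0.35 under
  scenarios H0-H4.

Because these generators satisfy the analysis models' assumptions by
construction, passing recovery tests demonstrates correctness of the
statistics and code, not robustness to real-data pathologies (LD,
correlated probes, heavy tails, annotation errors).

## Numerical choices and edge cases

* Ranked signatures break score ties by gene symbol; all orderings use
  radix sort for platform-independent determinism.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state, so results are bit-reproducible and independent of
  call order.
* Zero-variance features are dropped (with counts logged) wherever a
  standardized statistic would be undefined; a zero-variance seed gene is
  an error.
* Permutation P values never return exactly zero (+1 correction);
  permutation FDRs never return exactly zero (floor at
  $1/(n_{perm} n_{genes})$).
* The exhaustive Fisher checks compare P values and conditional-MLE odds
  ratios against full hypergeometric enumeration on all 2x2 tables with
  total at most 12.

## Problem sizes used in the bundled experiments

The recovery experiments run at 5 studies x 2000 genes with 200
permutations, 200 compounds x 1000 genes with 1000 permutations, 100 TFs
x 2000 genes, and 100 loci x 500 variants per scenario — sizes chosen so
the full suite exercises every stage at meaningful power while remaining
quick to run on a laptop. All reported numbers in the README are produced
by the code in this repository; none are transcribed from elsewhere.

## Known limitations

* Label-permutation FDR after data-driven covariate removal is
  approximate (see above).
* The PRL merge is $O(k^2)$ in replicates per compound — fine for the
  handful of replicates typical of compound screens.
* Colocalization assumes one causal variant per trait per locus and
  independent variants; with LD or allelic heterogeneity PP4 is biased in
  ways the no-LD generator cannot reveal.
* The homolog mapping default (symbol uppercasing) is a convention, not
  orthology; supply an explicit mapping table for anything beyond
  mouse-human symbol pairs.
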