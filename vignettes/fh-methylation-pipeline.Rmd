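---
title: "Tiered differential methylation and machine-learning discrimination for FH cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered differential methylation and machine-learning discrimination for FH cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhmethyl)
```

## The problem this package addresses

A substantial fraction of patients with a clinical diagnosis of familial
hypercholesterolemia (FH) carry no identifiable pathogenic variant in the
major FH genes (*LDLR*, *APOB*, *PCSK9*). One hypothesis is that such
"mutation-negative" patients differ from mutation-positive patients in
their blood DNA methylation. Testing that hypothesis on methylation-array
data takes two complementary analyses:

1. **Candidate-gene differential methylation**: per-CpG linear models over
   a tiered set of candidate loci, with cell-composition and age
   adjustment, variance moderation, empirical-null inflation correction
   and false-discovery-rate control.
2. **Genome-wide discrimination**: a stability-selected gradient-boosted
   classifier whose repeated-split test AUC, label-permutation p-value and
   relative feature importances summarize whether the two groups differ in
   aggregate, even when no single CpG does.

`fhmethyl` implements both arms as composable, tibble-returning functions,
together with a synthetic cohort generator that emulates the statistical
structure of such a study, so every stage is testable without access to
patient data.

## The synthetic cohort generator

`generate_cohort()` draws a two-group cohort in which each sample's beta
value at probe $j$ is a leukocyte-mixture mean perturbed on the logit
scale:

$$
\mu_{ij} = \sum_k w_{ik}\, P_{jk}, \qquad
\beta_{ij} = \operatorname{expit}\!\big(\operatorname{logit}(\mu_{ij} + s_{ij}) + \varepsilon_{ij}\big),
\quad \varepsilon_{ij} \sim N(0, \sigma_\ell^2),
$$

clipped to $[0.001, 0.999]$. Here $w_i$ are per-sample cell proportions
drawn from a Dirichlet, $P$ the per-probe cell-type methylation profiles,
and $s_{ij}$ optional spiked effects (a group difference on the beta
scale, added to the mutation-negative group, plus an optional age slope).
The defaults encode the study design the package targets:

* **78 mutation-negative and 58 mutation-positive samples**, ages
  truncated-normal with mean 50.7 (SD 12.3) and 38.1 (SD 12.0) years
  respectively, truncated to 18–90 years (an adult referral cohort).
* **Six leukocyte types** (CD8T, CD4T, NK, B cells, monocytes,
  granulocytes) with Dirichlet concentrations (10, 10, 2, 2, 2, 30) in
  that order, so granulocytes dominate as in whole blood — a deliberate
  collinearity stress for the cell-composition covariates.
* **Logit-scale noise SD 0.15**, which at mid-range betas corresponds to a
  per-observation beta SD of roughly 0.035, a realistic scale of
  between-replicate variation for normalized array betas. Noise is placed
  on the logit scale because additive beta-scale noise would violate the
  $[0,1]$ range.
* Probe baselines are drawn from a stretched Beta(0.4, 0.4), giving the
  bimodal beta distribution characteristic of methylation arrays; every
  non-marker probe also receives small ($\mathrm{SD}=0.02$) cell-type
  deviations, so cell composition is a genuine confounder genome-wide.

The generator also plants the artifacts the analysis must cope with:
`spike_spec()` group effects (a spike that would push a mean beta outside
$[0,1]$ is an error, not a silent clip), and `apply_snp_artifact()`
probes whose apparent methylation is a Hardy–Weinberg mixture of two or
three genotype levels — the trimodal pattern an undetected SNP produces.
All hidden truth (cell proportions, spikes, genotypes, the reference
panel) is stored in `dataset$truth` for parameter-recovery testing.

What the generator does **not** emulate: raw-intensity (IDAT) artifacts,
batch/slide effects, probe-type chemistry differences, genomic
correlation between neighbouring CpGs, or genome-scale probe counts.
Passing tests on synthetic cohorts therefore demonstrate the statistical
machinery is correct and calibrated — not that any particular biological
finding will replicate on real arrays.

## Quality control

`filter_probes()` applies the standard exclusions in a fixed order, each
probe counted once under the first rule it matches: cross-reactive
probes; probes with a SNP of minor-allele frequency strictly above 0.01
at the CpG itself or the single-base-extension position; probes with such
a SNP in the probe body. The body rule reuses the same threshold as the
CpG/SBE rule (no separate convention is established for it) but is
counted separately in the report. Missing MAF annotation is treated as
"no known SNP" and logged. Sex-chromosome probes are **retained** by
default — the intended design is an all-male cohort, and X-linked CpGs
can be genuinely informative there — with `drop_sex = TRUE` available.

`pca_summary()` computes an SVD of the probe-centered (unscaled) beta
matrix; `pca_correlate()` correlates the leading scores with known
sample-level variables, the usual check for which variables drive the
main axes of variation.

## Cell-type deconvolution

`estimate_cell_proportions()` is a reference-based constrained
projection: for each sample, minimize $\|y - Xw\|^2$ subject to
$w \ge 0,\ \sum_k w_k \le 1$, where $X$ holds the reference profiles at
the marker probes. The solver is a Lawson–Hanson active-set NNLS with the
simplex inequality handled by an explicit slack variable (weighted
pseudo-observation, weight $10^3$), followed by an exact KKT polish on
the recovered active set — noise-free mixtures are reproduced to
machine precision, and the feasibility constraints hold to $10^{-8}$.
Proportions are renormalized to sum to one for reporting and for use as
covariates (set `renormalize = FALSE` for the raw solution; which of the
two a downstream model should use is a genuine convention choice, and
renormalized is the default here because the six fractions are then on
the interpretable compositional scale).

## Per-CpG differential methylation

`fit_dmp()` fits, per probe, ordinary least squares of methylation on
group, age and five of the six cell proportions. The granulocyte fraction
is dropped: the six proportions sum to one, and removing the dominant
component keeps the design well-conditioned. The group coefficient is
coded mutation-negative minus mutation-positive. The default modeling
scale is **beta values**, so an effect of $-0.013$ reads directly as a
1.3-percentage-point lower methylation; M-values (`scale = "m"`) are
available when variance stabilization matters more than effect
interpretability.

`moderate_variances()` shrinks the per-probe residual variances toward a
scaled inverse-chi-square prior fitted by method of moments on the log
variances, exactly the empirical-Bayes scheme of the moderated
t-statistic; the moderated t with $d_0 + d$ degrees of freedom is the
default reported statistic, with the ordinary t retained alongside. In
tests the estimates agree with `limma::eBayes` to $10^{-6}$, and the
estimator recovers simulated prior parameters ($d_0$ within a factor of
two, $s_0^2$ within 20%).

`correct_inflation()` estimates an empirical null for the moderated
z-scores: a three-component Gaussian mixture — null $N(\mu_0,
\sigma_0^2)$ plus two symmetric tail components at $\mu_0 \pm \mu_1$ —
fitted by EM (at most 200 iterations, relative log-likelihood tolerance
$10^{-6}$, median/MAD initialization). Corrected statistics are
$(z-\mu_0)/\sigma_0$; the genomic inflation factor
$\lambda = \mathrm{median}(z^2)/0.4549$ is reported alongside. Three
numerical safeguards keep the fit honest: the tail means are constrained
at least $3\sigma_0$ from the null, the tail SD at least $\sigma_0$, and
the weights carry weak Dirichlet pseudo-counts (90, 5, 5). Without them
the flanks of a *purely null* input leak into the tail components and
$\sigma_0$ is biased a few percent low; with them the null SD is
recovered within 0.5% at $n = 10{,}000$ for true SDs 0.8–1.5, while a
5% planted tail at $z = 4$ is still absorbed by the non-null components.
Inputs with fewer than 1000 finite z-scores get an identity correction
with a warning; EM non-convergence falls back to a median/MAD null.
Inflation correction is applied genome-wide, before any tier subsetting,
because the empirical null is a statement about the full test-statistic
distribution.

`bh_fdr()` is the Benjamini–Hochberg step-up (delegated to
`stats::p.adjust` and verified against the hand computation).

## Candidate tiers

`tier_registry()` fixes tier 1 (*LDLR*, *APOB*, *PCSK9*) and tier 2
(*LDLRAP*, *STAP1*, *ABCG5*, *ABCG8*, *APOE*, *LIPA*) and takes tier 3
(GWAS lipid genes) and tier 4 (individual candidate CpG ids) as
configuration — these lists are data, not algorithm, and
`default_tier_registry()` ships a small worked example (five
well-established GWAS lipid genes; cg00574958 in *CPT1A* plus three other
lipid-associated CpGs) with approximate hg19 gene intervals. Probe
selection takes every probe within 3000 bp of a tier gene on either side,
both endpoints inclusive, left edge clamped at 1; tier 4 matches CpG ids
exactly. Genes present in multiple tiers are analysed independently per
tier.

`run_candidate_analysis()` runs **one** genome-wide fit (OLS, moderation,
inflation correction) and subsets it per tier — tier tables are row
subsets, never refits. FDR is computed within each tier's probe set by
default (`fdr_scope = "genome"` carries the genome-wide q-values over
instead). Whether FDR should be scoped within-tier or genome-wide is a
genuine ambiguity in this kind of design; within-tier is the default
because each tier is reported as a self-contained analysis, and the
choice is recorded in the output's `fdr_scope` attribute.

## The classifier arm

`train_evaluate()` repeats, `n_repeats` times: a stratified 80/20
train/test split; stability selection on the training partition; a small
cross-validated hyperparameter search restricted to the stable set; and
evaluation on the untouched test split. Defaults are 50 repeats, 5-fold
stratified CV, and a 1000-fold label permutation test.

Stability selection draws `n_stability_subsamples` class-stratified
half-subsamples of the training data, fits a boosted-tree model to each,
and scores each probe by the fraction of subsamples in which it receives
nonzero gain importance; probes at or above $\pi = 0.6$ form the stable
set. Two design points deserve note:

* **Randomized base learners.** Each stability fit offers every tree a
  random half of the probes (`stability_colsample = 0.5`, seeded per
  subsample, so runs are reproducible). With a fully deterministic
  learner, greedy boosting reuses the same few strong probes in every
  subsample and systematically under-counts the rest of a planted signal;
  randomizing the feature pool is the standard companion of subsampling
  in stability selection and restores sensitivity without inflating the
  null (noise-only data still rarely puts any probe above $\pi$).
* **Fallback.** When the stable set is empty — the typical outcome on
  label-permuted or null data — the repeat falls back to all probes, with
  a message.

The "combination of multiple gradient boosting classifiers" is realized
as a fold-model ensemble: the CV fold models' predicted probabilities on
the test split are averaged (`ensemble = "refit"` switches to a single
model refit on the full training partition). The hyperparameter grid is
deliberately small — depth {2, 3}, learning rate {0.05, 0.1} — because
$n \approx 136 \ll p$; importance is total split gain, averaged over
folds and repeats, then rescaled so the top probe scores 100
(`rescale_importances()`, ties broken lexicographically).
`annotate_directions()` labels each probe hyper- or hypomethylated in the
mutation-negative group by the difference in group medians, withholding
the label on exact ties.

`permutation_test()` reshuffles the labels, reruns the evaluation at a
reduced number of outer repeats per permutation (`perm_repeats`, default
5 — the full 50 per permutation being three orders of magnitude more
compute for the same null), and reports the add-one p-value
$p = (1 + \#\{\mathrm{AUC}_{perm} \ge \mathrm{AUC}_{obs}\})/(1 + B)$,
which can never be exactly zero. Seed discipline throughout: the master
seed spawns independent substreams for splits, subsamples, folds,
stability randomization and permutations, so a report is reproducible
end to end and invariant to sample order.

## In-silico validation

`correlate_with_table()` replaces web-database lookups with a local
operation: Pearson and Spearman correlations (two-sided p from the t
approximation on $n-2$ df, average ranks for ties) of probe betas
against any expression or phenotype table keyed by sample id.
`filter_biological()` flags pairs with $p < 0.05$ and $|r| > 0.1$;
the absolute value is deliberate — a strong negative
methylation–expression correlation is at least as interesting as a
positive one — and a pair is flagged when either correlation method
passes both thresholds.

## Problem sizes used in the shipped tests

The package's own test suite and `scripts/acceptance.R` run entirely on
synthetic cohorts, at sizes chosen to make each statistical property
measurable while keeping a full run in minutes: 136-sample cohorts
throughout; 250-probe arrays for effect-recovery replicates (100
replicates for the 1.3-point spike); 10,000 probes for null calibration
and empirical-null recovery; 5,000 probes with 30 spiked CpGs for
classifier detection (5 outer repeats, 99 permutations at 1 repeat each,
stability off during permutations since permuted labels never yield a
stable set); 2,000 probes with 10 strongly spiked CpGs for stable-set
recovery. The boosting configuration in these runs is a single
hyperparameter point (depth 2, learning rate 0.1, 50–60 rounds) rather
than the full default grid.

## Known limitations

* The empirical-null EM is a lightweight surrogate for a full Bayesian
  (Gibbs-sampled) mixture fit; its point estimates are accurate in the
  regimes tested but it reports no posterior uncertainty.
* The generator draws probes independently; methods that exploit genomic
  correlation between CpGs (region detection) are out of scope, as are
  surrogate-variable adjustment and mixed models.
* Tier 3/4 default lists are worked examples, not curated panels;
  supply your own registry for real analyses.
* With `n_permutations` at its default of 1000 and full-size repeats the
  permutation test is compute-intensive; `perm_repeats` trades permutation
  granularity against per-permutation fidelity.
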