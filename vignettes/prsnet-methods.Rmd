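---
title: "Polygenic risk modeling with prsnet: models, simulation design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic risk modeling with prsnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Common late-onset Alzheimer's disease is polygenic: one large-effect
locus (the *APOE* region) and dozens of small-effect variants jointly
shift an individual's liability. A polygenic score condenses a person's
genotype at a chosen variant panel into a single number that predicts
case status. `prsnet` implements four score families over a shared data
model, together with the surrounding machinery — per-variant logistic
GWAS, fixed-effects meta-analysis, LD clumping, evaluation, Gaussian-
mixture risk stratification, and endophenotype interpretation — and a
synthetic-cohort generator so the whole pipeline can be exercised and
validated without restricted genotype data.

# Score models

**Weighted PRS.** `weighted_prs()` computes the classical score
$s_j = \sum_i w_i d_{ji}$ from allele dosages $d \in [0,2]$ and log-odds
weights $w_i$ taken from GWAS summary statistics, with no
normalization. It is exactly linear, so it cannot represent epistasis
(interaction) between variants; this limitation motivates the network
models.

**L1-logistic (lasso).** `fit_lasso()` wraps a penalized logistic
regression over a descending 100-point log-spaced $\lambda$ grid
(down to $10^{-3}\lambda_{max}$) with five-fold cross-validation.
Following the convention of retaining as many variants as possible, the
chosen $\lambda$ is the CV-grid value with the largest number of
nonzero variant coefficients. Covariates (age, sex, five genotype PCs)
enter either unpenalized alongside the dosages (default) or are
regressed out first via a covariate-only logistic fit whose linear
predictor becomes a fixed offset (`covariate_mode = "offset"`). The
original description of the procedure is ambiguous between these two
readings, so both are provided and neither is asserted as canonical.

**Dense sigmoid network.** `build_nn()` constructs one of two
seven-layer layouts. The locus-structured layout takes dropout on the
input, a dense layer of width $3L$ (allowing up to three risk
haplotypes per locus), dropout, then dense layers of width $L$
(loci), 22 (chromosomes), 5 (putative pathways) and 1 (the risk
score). The compact layout is dense(50), dropout, dense(30), dropout,
dense(10), dense(5), dense(1). All dense activations are sigmoid.
Dropout placement for "first and third layers" is resolved as input
dropout plus dropout after the first dense block; both the rate (0.2 or
0.3 by default depending on layout) and placement are configurable.
Training (`train_nn()`) is plain mini-batch SGD on mean binary
cross-entropy — the optimizer is our choice; only the schedule and
learning rate are inherited — with a staircase exponential decay
`lr0 * 0.96^floor(step/100000)` and optional early stopping (patience
in epochs, best weights restored). Weight initialization is a seeded
symmetric-uniform scheme with fan-based scaling, so a seed fully
determines the fit. Gradients are analytic and verified against central
finite differences in the test suite.

**Graph-convolutional classifier.** `build_graphs()` turns each sample
into a graph on the variant panel: edges connect variants with LD
$r^2 > 0.6$, node features are the sample's dosage plus functional
annotation counts (coding, UTR, histone, open-chromatin, polymerase and
TF-binding events), normalized dimension-wise over the dataset.
`train_gnn()` stacks three symmetric-normalized graph convolutions
($\hat A = D^{-1/2}(A+I)D^{-1/2}$, rectifier, width 128), global max
pooling, and a two-layer width-64 rectifier classifier head, trained
with Adam and early stopping (patience 20). Because all samples share
the node set and adjacency, a batch is processed as a single
(batch·nodes) × width matrix; applying the adjacency block-wise and
applying weights are then two plain matrix products.

**Module extraction.** `penultimate_outputs()` returns the activations
of the dense layer feeding the output node (width 5 in both stock
layouts). These "modules" summarize the genetic input into a few latent
components; `multivariate_module_assoc()` fits an endophenotype on all
modules jointly by robust regression and returns the per-module
t-statistics used for downstream clustering.

# Surrounding statistics

- `logistic_assoc()`: per-variant IRLS logistic fits of status on
  dosage + covariates, Wald two-sided p (the standard GWAS choice),
  EAF = mean dosage / 2; non-converged, separated or constant variants
  are flagged with missing p rather than dropped.
- `fixed_effects_meta()`: inverse-variance pooling, Cochran's Q and
  $I^2 = \max(0, (Q-(k-1))/Q)\cdot 100$ (floored at zero, matching the
  convention of printing 0 for homogeneous variants).
- `ld_clump()`: greedy best-p-first clumping with defaults $r^2 > 0.1$
  within 1000 kb (the source method names no parameters; these are
  standard) and a deterministic (p, chrom, pos, id) tie-break.
- `select_replicated()`: the two-cohort recipe — nominally significant
  in either cohort, kept when meta-significant, rescued when the effect
  direction is concordant in both.
- `auroc()` (Mann-Whitney pair counting), `auprc()` (non-interpolated
  step area with ties grouped — the convention must be pinned down
  because different packages interpolate differently), stratified
  percentile bootstrap intervals (B = 2000) and a paired bootstrap
  auROC comparison with a normal approximation. Threshold-based
  "accuracy" is deliberately not reported: its threshold is not
  identified by the source description.
- `fit_gmm()`: univariate K-component EM with k-means initialization,
  relative log-likelihood tolerance $10^{-8}$, at most 200 iterations,
  restart-on-collapse (up to 3 fresh seeds), components sorted by mean.
  Plain EM is used rather than an ECM variant: for a one-dimensional
  three-component mixture the fixed points coincide.
- `membership_probs()`: the default returns posterior responsibilities,
  which satisfy the "medium = 1 − low − high" identity exactly; a
  "literal" mode evaluates outer-component tail probabilities and
  derives the medium probability by subtraction, clipping into [0, 1]
  with a warning — the published description is ambiguous between
  these readings, so both ship and the coherent one is the default.
- `robust_linear_fit()`: M-estimation via `MASS::rlm` — Huber start,
  bisquare refinement (c = 4.685, 95% Gaussian efficiency), MAD scale —
  with Wald t and p. Raw p-values are the default throughout the
  endophenotype layer; BH adjustment is available behind a flag.
- `rank_inverse_normal()`: Blom offset 3/8 by default (configurable);
  average ranks for ties.
- `spearman_partial_correlation()`: rank-transform, then read partial
  correlations off the inverse joint correlation matrix; p from the
  t-approximation with df = n − (p−1) − 2.
- `kmeans_cluster()`: best-of-25 restarts per candidate k; the elbow is
  operationalized as the maximizer of the second difference of the WSS
  curve, because an automated rule is needed where the cited tooling
  draws a plot. All-identical inputs resolve to k = 1 by tie-break.
- `cell_type_specific_genes()`: a gene is specific to the cell type
  where its FPKM is ≥ 5 and ≥ 1.5× every other type — the strict first
  tier of the cited tool's three-tier scheme; the laxer tiers are out
  of scope. `enrichment_test()` is an upper-tail hypergeometric with BH
  across cell types within a cluster.
- `group_mean_comparison()`: one-way ANOVA plus pairwise Welch t-tests
  Bonferroni-multiplied by the number of pairs.

# The synthetic cohort generator

`sim_spec()` + `simulate_cohort()` emulate the statistical structure the
analyses assume, not a population-genetic process:

- **Genotypes.** Two latent haplotypes per sample are drawn from
  block-wise equicorrelated Gaussians and thresholded at the
  allele-frequency quantile; dosage is their sum. Thresholding
  attenuates correlation, so the latent correlation is calibrated
  numerically per block to hit the target dosage r. Variants within a
  block share one allele frequency (drawn uniformly from `maf_range`),
  which keeps that calibration exact in expectation. This is a
  Gaussian-copula approximation — there is no recombination, mutation
  or coalescent realism, and no population structure.
- **Liability.** $L = \sum_i \beta_i g_i + \sum_{jk} \gamma_{jk}
  (g_j-\bar g_j)(g_k-\bar g_k) + \beta_{age}(age-72) + \beta_{sex} sex
  + \varepsilon$, centered and shifted to the logit of the target case
  fraction; status is Bernoulli(logistic(L)). Epistatic terms use
  centered dosages so that at symmetric allele frequencies the marginal
  (linear) association of each pair member vanishes — this is what
  makes "networks beat the linear PRS under epistasis" a fair test.
  Among non-cases, an `mci_fraction` (default 10%) is drawn with
  liability-proportional weights and labelled MCI — a noisy
  intermediate state rather than a deterministic top slice, which
  would otherwise remove every high-liability control from the NC
  pool.
- **Case-control sampling** subsets to the requested AD fraction among
  AD + NC; if the simulated prevalence leaves fewer than 80% of the
  requested cohort achievable at that fraction, the request is treated
  as unreachable and an error reports the bound.
- **Endophenotypes.** Each variant belongs to one of K pathways
  (default K = 5, mirroring the width of the module layer); pathway
  burdens $B_k = \sum_{i \in k} \beta_i g_i$ are recorded as ground
  truth, and biomarkers are linear combinations $\Lambda B + noise$.
- **Demographics** are deliberately simple: age uniform on [55, 90],
  sex Bernoulli(1/2), PCs standard normal noise. Default covariate
  effects are mild (0.02/year, 0.2 for sex).
- **Seeding.** One master seed; every stage derives its own sub-stream
  seed through a fixed affine map (`split_seed()`), so the draws of one
  stage do not depend on whether another ran first, and identical seeds
  give bit-identical cohorts.

What passing tests on these cohorts do *not* show: performance on real
genotype data with realistic LD, population structure, genotyping
error, phenotype misclassification or ascertainment. The generator
validates the machinery and the qualitative model ordering, not
clinical accuracy.

# Validation scenarios and problem sizes

The `benchmark_*` functions fix the study conditions used by the test
suite and the acceptance script:

- **Epistasis** (`benchmark_epistasis`): n = 6000, 50 variants, five
  interaction pairs (γ = 2) in two-variant LD blocks (target dosage
  r = 0.8, so pair members are connected at the graph model's
  $r^2 > 0.6$ threshold) at allele frequencies in (0.45, 0.5), where
  centered products carry no marginal signal; five seeds; two thirds
  train, one third held out. A marginal-GWAS weighted PRS sits near
  chance here while the dense and graph networks learn the
  interactions. The dense network shows a long loss plateau before the
  interaction structure is found (with no first-order signal, learning
  must bootstrap through higher-order effects), so this scenario trains
  with a higher initial rate (lr0 = 2) for a fixed 500 epochs and no
  early stopping; the graph model trains on a 2000-sample subset for 15
  epochs. These budgets are fixed design choices of the benchmark.
- **Additivity** (`benchmark_additive`): ten β = 0.35 variants plus one
  APOE-like β = 1.1 locus, no interactions, no covariate effects. The
  Bayes-optimal score is then the true linear predictor itself, so the
  true-beta weighted PRS sits at the oracle and a well-trained network
  should match — not beat — it (lr0 = 0.5 here; the plateau is short
  on additive signal and a gentler rate tracks the optimum more
  closely).
- **Pathways** (`benchmark_pathways`): all 50 variants causal
  (β = 0.4) in five disjoint pathways; one biomarker loads on pathway 1
  only. Checks that each pathway burden is tracked by some module
  (Spearman), and that the joint robust fit of the noisy biomarker
  assigns its maximal |t| to the module that an ordinary least-squares
  fit of the *true* burden on the modules identifies — a conditional
  (not marginal) reference is required because the modules are
  inter-correlated, and the OLS route is an independent computation of
  the same conditioning.
- **Stratification** (`benchmark_stratification`): n = 2000 cohorts
  with a dominant major locus (beta = 1.6) over a mild polygenic
  background, so the true-beta PRS is genuinely trimodal and the three
  mixture components are well occupied; the AD fraction must rise
  strictly from the low to the high group, with an elevated
  high-vs-low odds ratio.
- **Calibration**: 200 null cohorts (n = 5000, 100 variants) pool
  ~20000 per-variant p-values for the type-I error; 100 outer
  replicates check coverage of the bootstrap auROC interval; robust
  regression and ANOVA null p-values are tested for uniformity.
- **Recovery**: three-component mixture means from n = 3000 scores;
  lasso support recovery (20 causal variants, |β| = 0.25, n = 8000);
  single-variant effect recovery (β = ln 3, n = 8000 — case-control
  sampling shifts only the intercept, not the slope).

These sizes are the package's chosen validation conditions; they keep
each scenario's full five-seed run in the minutes range on a single
core while leaving the statistical conclusions stable across seeds.

# Numerical choices and degenerate inputs

- Missing dosages stay `NA` through I/O and are mean-imputed per
  variant only at model input, keeping file round trips lossless.
- Harmonization matches by rsID only (warning, not error, on
  chrom/pos disagreement), flips dosages to the summary-statistic
  effect allele, drops strand-ambiguous A/T and G/C pairs by default,
  and rejects multi-allelic sites with a count.
- Posterior membership probabilities are computed in log space, so
  scores far outside the mixture's support still normalize exactly.
- Constant dosage columns yield a defined LD of 0 off-diagonal; in the
  GWAS they are flagged rather than fitted.
- The GNN's argmax pooling breaks ties toward the first node; mixture
  component collapse (σ → 0) triggers a seeded restart, then an error.
- 32-bit seed arithmetic: all derived seeds stay below 2^31.

# Known limitations

- The LD construction cannot represent long-range or asymmetric LD,
  and calibration targets a single within-block correlation.
- The European-style network layout assumes the input is SNP-level
  dosages feeding the 3L-wide layer; locus-level feature pooling is
  not implemented.
- No GPU path and no hyperparameter search: training budgets are fixed
  presets. The graph model supports one adjacency per graph set; a
  multi-ancestry analysis builds one graph set per ancestry group and
  scores them separately.
- The bootstrap model comparison uses a normal approximation; exact
  permutation is only advisable at small n and is not the default.
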