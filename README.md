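# prsnet

Polygenic risk modeling for case-control disease genetics, built around
Alzheimer's disease: classical weighted polygenic risk scores, an
L1-logistic model, a structured multilayer sigmoid neural network with
interpretable penultimate-layer "modules", and a graph-convolutional
classifier over the variant LD graph — plus the GWAS, meta-analysis,
LD-clumping, evaluation, risk-stratification and endophenotype-
association machinery around them, and a synthetic-cohort simulator
that makes the whole pipeline testable without restricted genotype
data.

## Who this is for

Statistical geneticists and method developers who want to (i) build and
compare polygenic score models beyond the weighted sum — in particular
models that can exploit epistasis, (ii) stratify individuals into
low/medium/high genetic risk groups, and (iii) interpret a network's
latent risk components against endophenotypes such as plasma
biomarkers.

## The models

For dosages `d_ji ∈ [0,2]` (sample j, variant i) and GWAS log-odds
weights `w_i`, the weighted PRS is the plain sum

    s_j = Σ_i w_i · d_ji          (no normalization)

The lasso model is an L1-penalized logistic regression over the variant
panel with unpenalized covariates (age, sex, five genotype PCs), tuned
by five-fold cross-validation with the lambda that retains the most
variants. The dense network stacks sigmoid layers — e.g. widths
50, 30, 10, 5, 1 with dropout after the first and second dense blocks —
trained by mini-batch SGD on binary cross-entropy with a staircase
exponential learning-rate decay (`lr0 · 0.96^⌊step/100000⌋`). The
five-node layer feeding the output is the *module* layer: its
activations decompose a sample's polygenic risk into latent components.
The graph model connects variants with LD `r² > 0.6`, attaches dosage
plus functional annotation counts as node features, and classifies each
sample's graph with three symmetric-normalized graph convolutions
(width 128), global max pooling and a width-64 dense head, trained with
Adam.

Risk scores are stratified by a three-component univariate Gaussian
mixture (EM, k-means start, components sorted by mean) into low /
medium / high groups with posterior membership probabilities.

## Worked example

Simulate a 2000-sample case-control cohort with ten causal variants and
an APOE-like major locus, run a covariate-adjusted GWAS, score with a
weighted PRS, and stratify:

```r
library(prsnet)

beta <- c(rep(0.35, 10), rep(0, 40))
spec <- sim_spec(n_samples = 2000, n_variants = 50,
                 additive_effects = beta,
                 large_effect = list(variant = 11, beta = 1.1),
                 seed = 42)
cohort <- simulate_cohort(spec)

gwas  <- logistic_assoc(cohort$genotypes, cohort$phenotypes)
prs   <- weighted_prs(cohort$genotypes, wprs_model(gwas))
y     <- cohort$phenotypes$status == "AD"
keep  <- cohort$phenotypes$status != "MCI"

auroc(prs[keep], y[keep])
#> [1] 0.7972704
bootstrap_ci_auroc(prs[keep], y[keep], seed = 1)[1:2]
#> [1] 0.7756923 0.8162295

gmm    <- fit_gmm(prs, K = 3, seed = 1)
groups <- assign_risk_groups(gmm, prs)
tapply(y[keep], groups$label[keep], mean)
#>       low    medium      high
#> 0.2629482 0.6162403 1.0000000
```

The auROC of ~0.80 is the discrimination the simulated architecture
supports (in-sample, with GWAS weights estimated on the same cohort);
the bootstrap interval is a stratified percentile interval (B = 2000).
The case fraction rising from 0.26 in the low-risk group to 1.00 in the
(small) high-risk group is the mixture stratification recovering the
built-in risk gradient.

Training the dense network on the same cohort and extracting its
modules:

```r
X  <- impute_dosage_means(cohort$genotypes$dosage)
nn <- build_nn("chinese", n_features = 50, init_seed = 1)
nn <- train_nn(nn, X[keep, ], as.integer(y[keep]),
               train_config(epochs = 500, lr0 = 0.5, seed = 1))
modules <- penultimate_outputs(nn, X)   # samples x 5 latent components
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/prsnet.R` (subcommands `simulate`, `assoc`, `meta`, `clump`,
`select`, `score`, `stratify`, `evaluate`).

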