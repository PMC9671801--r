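---
title: "Models and methods behind metabotyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metabotyper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabotyper)
```

# Scope and design

`metabotyper` implements the statistical core of a two-stage untargeted
metabolomics GWAS: metabolite preprocessing, per-cohort association with
fixed-effect meta-analysis, LD-based region definition, exact forward
stepwise conditional analysis on pooled individual-level data, the greedy
matrix.ref/matrix.out partitioning of regional variant–metabolite
associations into genetically influenced metabotypes (GIMs), candidate
causal-gene evidence scoring, metabolite genetic-score PheWAS with
MR follow-up, and Gaussian-graphical-model network reconstruction. A
synthetic-data module generates two discovery cohorts plus a validation
cohort with a planted genetic architecture, so that every downstream
stage can be tested against a known truth.

# The synthetic-data generator

**Genotypes.** Hard-call dosages in {0, 1, 2} arise from two latent
Gaussian haplotype vectors with within-chromosome correlation
`exp(-ldDecay * distance)`, each thresholded at the normal quantile of the
target minor allele frequency. This latent-threshold construction was
chosen over coalescent simulation deliberately: the downstream pipeline
consumes exactly two genotype properties — a tunable MAF spectrum
(supported down to MAF 0.1%) and exponentially decaying LD — and the
latent model provides both with two parameters. The default
`ldDecay = 1e-4` (per bp, used by `simulateStudy()`) puts substantial LD
inside a 5 kb block and near-zero dosage correlation beyond ~40 kb, which
is compressed relative to human genome-wide decay but preserves the
qualitative structure (tight proxy blocks, independent blocks, independent
loci) at a size that keeps whole-pipeline simulations fast. What the
generator does **not** emulate: recombination hotspots, population
structure and relatedness (hence ordinary least squares downstream),
imputation uncertainty, and allele-frequency/LD coupling. Passing tests
therefore demonstrate correctness of the statistical machinery, not
robustness to confounding or cryptic relatedness.

**Metabolites.** On a standardized latent scale each causal variant
contributes `beta` per allele copy; residual noise brings the latent
variance to 1 (so `beta^2 * 2 maf (1-maf)` is the variance explained), and
the latent is exponentiated to a positive, log-normal abundance scale with
covariate main effects. Missingness is missing-completely-at-random by
default, with a per-entry probability matrix exposed as a
missing-at-random hook; the imputation stage assumes missingness
explainable by observed metabolite values, which MCAR satisfies trivially.
Each generator operation draws from its own seed-derived stream, so one
master seed can drive genotypes, metabolites, phecodes and cohort splits
without reusing random numbers across stages.

**Planted architecture.** `plantedArchitecture()` lays loci 5 Mb apart
(far beyond the LD decay length, so loci are independent); within a locus
each planted GIM occupies its own 5 kb variant block, blocks 40 kb apart
so inter-GIM dosage r-squared is negligible (< 0.01) while intra-block
proxies remain correlated with the causal variant. Effect signs alternate
across a GIM's metabolites, and effect sizes derive from the
variance-explained target. The study-scale defaults of `simulateStudy()`
(8,455 + 5,841 discovery, 5,698 validation samples) mirror a realistic
two-cohort discovery design; the test suite uses 2 x 8,000 discovery
samples for the recovery experiments and 1,200–1,500 per cohort for unit
tests, sizes chosen so planted effects of 1.5–3% variance explained are
comfortably powered at the genome-wide thresholds.

# Preprocessing

Per metabolite: natural log, winsorization at mean ± 5 s.d., covariate
residualization, standardization (sample s.d., n−1). Three deliberate
choices:

* winsorization bounds are computed **once** on the pre-winsorization log
  values and not iterated;
* residualization is complete-case per metabolite, but samples missing a
  covariate are excluded from all metabolites (one consistent analysis
  population);
* covariate lists are per-cohort — cohorts are preprocessed independently
  and only the standardized residuals are pooled, so cohort-specific batch
  structure never needs harmonizing.

Metabolites seen in fewer than `minN` samples are dropped
(default 200, scaled down in small simulations), as are metabolites that
are constant after the log transform.

# Association, meta-analysis and regions

Ordinary least squares replaces mixed-model association engines: simulated
individuals are unrelated and unstructured, so the random effect would be
estimating zero. This is the single largest simplification relative to a
production GWAS stack and is the reason the generator excludes relatedness
by design. Two-sided P values come from the t distribution with n−2 df;
the meta-analysis uses the normal approximation, to which the t converges
at these sample sizes. Cohorts failing MAC > 10 are dropped from a pair's
pooling rather than failing it.

Region definition follows a peel-and-merge scheme: per metabolite,
iteratively take the remaining candidate with the largest −log10(P) as
sentinel, span the positions of candidates in LD (r² ≥ 0.1) with it (± 500
kb when isolated), remove covered candidates, repeat — this iterative
reading guarantees every candidate is covered by some interval. Pooled
sentinel intervals merge when sentinels share LD (r² > 0.6), gain 250 kb
padding per side, and overlapping intervals merge to a fixpoint. Intervals
are 1-based closed; abutting-but-not-overlapping regions stay separate;
endpoints clip at 1 with no chromosome-length clipping (synthetic
chromosomes are unbounded). Ties in −log10(P) break by smaller position,
then allele order, for bit-reproducibility.

# Conditional analysis

Forward selection is exact (individual-level refits, via the
Frisch–Waugh–Lovell partial-regression identity for speed) with a cohort
indicator as fixed effect. Eligibility — per-cohort conditional
direction consistency at P < 0.01 — is re-checked at **every step** in the
conditional model, and an ineligible top candidate is skipped in favor of
the next best rather than terminating selection. The stop and joint-model
threshold is 0.05/(39,297 × 102) ≈ 1.25e−8, the Bonferroni correction for
the maximal regional variant and metabolite counts. When no selected
variant survives the joint model, the lead variant alone is retained with
a fallback flag; the threshold in that branch applies to the joint (not
marginal) P, one of two defensible readings.

Variance explained: the grand total is the joint-model R² over all
retained variants; per-variant contributions are leave-one-out decreases
in R², with any shared R² allocated proportionally. This partition is a
design choice — it is symmetric in the variants, exact for orthogonal
predictors, and sums to the grand total by construction — since no unique
decomposition exists under LD. Bins: rare MAF ≤ 1%, low-frequency
(1%, 5%], common > 5%.

# GIMs

`gimSelect()` keeps a matrix.ref of conditional −log10(P) values (rows:
the union of conditionally independent variants over regional metabolites;
columns: regional metabolites), each entry refit exactly from
individual-level data conditioning on the already selected (matrix.out)
variants. The top pair must also show same-direction P < 0.01 in both
cohorts conditionally; a failing **pair** (not the variant) is masked and
the next-largest entry considered — masks reset once matrix.out changes,
which guarantees termination. Selection stops below −log10(5e−8).
matrix.out rows store signed −log10(P) conditional on lower marker orders
only. GIMs are the connected components of the bipartite
significant-pair graph, enumerated by ascending marker order.

"Adjacent" regions for the merge pass are consecutive same-chromosome
regions with a gap ≤ 1 Mb (configurable) sharing at least one associated
metabolite; merged regions are re-analyzed (conditional + GIM selection +
clustering) and the pass iterates to a fixpoint. A quantitative adjacency
rule is needed because the merge is automated here rather than manual.

# Gene annotation

The fuzzy matcher is defined explicitly so results are reproducible:
case-folding, removal of non-alphanumerics, then the Dice coefficient over
character trigrams, with hits above 0.5. Disease names are cleansed of a
fixed stop-word list removed as whole tokens and as word suffixes (the
list contains suffixes such as "uria" and "emia"); GO biological-process
names are cleansed of stop phrases as substrings, and terms with ≥ 500
member genes are excluded. Pathway evidence is bare co-occurrence on a
shared map. The two-tailed binomial enrichment P uses the
minimum-likelihood convention (sum of outcome probabilities no larger than
the observed outcome's). Causal-gene flagging itself is a manual review
step and is deliberately not automated; the package emits the evidence
table that review would consume. Both gene-set constructions (manually
flagged causal genes, or nearest genes to conditionally independent
variants) can feed the enrichment test.

# PheWAS and MR

Scores are standardized before the logistic regression, so odds ratios are
per 1 s.d. of the genetic score. A minimum of 50 cases (and controls) per
phecode is required by default — a floor has to exist for the asymptotics
to be trusted, and 50 is conventional. Separation is flagged
(non-convergence or extreme coefficients) and the P value withheld. MR
uses first-order Wald-ratio standard errors (`se_out / |beta_exp|`) in
Cochran's Q; the modified second-order weights would change little at the
simulated instrument strength. Because the simulation draws exposure and
outcome associations in one sample, the two-sample design is emulated by
cohort splitting; weak-instrument bias is negligible at the planted
instrument strength and checked in tests. The strong-evidence flag
requires ≥ 3 instruments and heterogeneity P > 0.05.

# Network reconstruction

Imputation is chained equations with Bayesian normal linear models
("norm": posterior draws of coefficients and residual variance, then
posterior-predictive draws), each metabolite regressed on all other
eligible (< 30% missing) metabolites, 30 imputations × 50 iterations by
default (tests use 5 × 8, which suffices at the simulated missingness of
5–10%). Partial correlations use a correlation matrix shrunk toward the
identity with the analytic Schäfer–Strimmer intensity
`lambda = sum Var(r_ij) / sum r_ij^2`, then inversion and rescaling.
Fisher-z pooling uses Rubin's rules with within-imputation variance
`1/(n − k − 3)` for partial correlations of order k — the complete-sample
n is used, with the between-imputation term carrying the missing-data
uncertainty. Cohorts are imputed and pooled separately, then meta-analyzed
by fixed-effect IVW on the z scale and back-transformed with `tanh`.
Edge inclusion is strict (`|r| > cutoff`) at 0.10/0.12/0.15.

# Numerical choices and degenerate inputs

* Latent correlation matrices get a 1e−10 ridge before Cholesky.
* Zero-variance dosages: marginal tests are excluded and flagged; LD rows
  are set NA and listed in an attribute.
* Perfectly collinear selected variants: the later-selected member is
  dropped with a warning.
* An empty conditional model yields an all-zero variance report; an empty
  significant set yields zero GIMs.
* All thresholds are strict inequalities exactly as stated above
  (candidate P < 5e−8, GIM edge −log10 P > −log10(5e−8), network
  |r| > cutoff).

# Known limitations

Everything is validated on synthetic data with unrelated individuals and
simplified LD; the OLS engine, the MCAR default, and the compressed LD
scale mean that population structure, informative missingness, and
fine-scale fine-mapping behavior are out of scope. The variance partition
is one defensible convention among several under LD. Genotype calling and
imputation, colocalization, functional annotation and druggability
tiering are outside the package entirely; annotation resources arrive as
flat tables.
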