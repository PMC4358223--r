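---
title: "Pedigree and genomic prediction of hip-score traits: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree and genomic prediction of hip-score traits: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caninegp)
```

# Scope

`caninegp` compares pedigree-based and genomic prediction of canine
hip-dysplasia traits. The UK screening scheme scores nine radiographic
components per hip; their sum over both hips is the hip score HS in 0–106
(0 = perfect). HS is strongly right-skewed, so analyses usually work with
THS = log(1 + HS), with the laxity components (Norberg angle, subluxation,
cranial acetabular edge) and with a weighted selection index over the nine
component totals. The package provides:

* a synthetic-cohort generator (pedigree, gene-dropped SNP genotypes,
  hip-score-like phenotypes) so every downstream stage is testable without
  access to any proprietary dog data;
* marker QC for PLINK PED/MAP panels;
* the three relationship structures used by mixed-model predictors —
  pedigree \(A\) (and its sparse-rule inverse), genomic \(G\), and the
  combined single-step \(H^{-1}\);
* single-random-effect animal-model REML for variance components;
* four predictors — BLUP, GBLUP, Bayes C, single-step BLUP — behind one
  front end, `gp_fit()`;
* a cross-validation harness with the predictive-ability statistic, a
  single-marker GWAS ranking, and marker-density/pre-selection experiments.

# Models

## Animal model and REML

Variance components come from the animal model

\[ y = X b + a + \varepsilon, \qquad
   a \sim N(0, \sigma^2_a A), \quad \varepsilon \sim N(0, \sigma^2_e I), \]

with fixed effects sex (1 d.f.), daily-exercise category (4 levels) and a
smooth age trend, and heritability \(h^2 = \sigma^2_a/(\sigma^2_a +
\sigma^2_e)\). Because the model has a single structured random effect,
REML is implemented exactly by eigendecomposition: rotating \(y\) and
\(X\) by the eigenvectors of \(A\) diagonalizes the covariance, the
restricted likelihood is profiled over the ratio
\(\gamma = \sigma^2_a/\sigma^2_e\), and a bounded 1-D search
(\(\gamma \in [10^{-6}, 10^6]\), tolerance \(10^{-8}\) on
\(\log\gamma\)) finds the optimum. Each likelihood evaluation after the
one-off eigendecomposition costs \(O(np)\). Standard errors come from a
finite-difference observed-information matrix in
\((\sigma^2_a,\sigma^2_e)\) with the delta method for \(h^2\). A grid
search over \(\gamma\) with dense linear algebra serves as the test
oracle.

The smooth age trend is a natural cubic spline with four interior knots at
the age quantiles (`age_spline()`). A penalized smoothing spline would be
an alternative; the basis-spline approximation was chosen because age
trends within the 1–5-year scoring window are weak, and it keeps the fixed
effects inside ordinary least-squares machinery.

## Relationship matrices

* `a_matrix()` builds Wright's numerator relationship matrix by the
  tabular method; the diagonal is \(1 + F\). `a_inverse()` builds the
  inverse directly from Henderson's rules with Meuwissen–Luo inbreeding
  coefficients, and dense inversion of the tabular matrix is kept as a test
  oracle.
* `g_matrix()` uses standardized allele doses: the dose of the reference
  allele is centred by \(2p_i\) and scaled by \(1/\sqrt{2p_i(1-p_i)}\),
  with \(p_i\) always recomputed from the analysis sample, and
  \(G = Z'Z/n\) over \(n\) SNPs. Missing doses are mean-imputed to
  \(2p_i\) (i.e. to zero after centring), which preserves centring.
  Monomorphic SNPs are a hard error — they carry no information and break
  the scaling — so marker QC must run first.
* `h_inverse()` combines the two for single-step evaluation. The default
  (`mode = "misztal"`) is the standard construction
  \(H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{*-1} - A_{22}^{-1}
  \end{bmatrix}\) over the genotyped block. A literal element-replacement
  variant (`mode = "paper"`), which overwrites genotyped-block elements of
  \(A^{-1}\) with elements of \(G^{*-1}\), is retained for sensitivity
  analysis; the two agree when every animal is genotyped. Before
  inversion \(G\) is stabilized by blending with the pedigree block:
  \(G^* = 0.95\,G + 0.05\,A_{22}\). The weight 0.05 is common practice;
  it guarantees positive definiteness whenever \(A_{22}\) is positive
  definite and perturbs well-conditioned \(G\) only slightly.

## Predictors

All predictors consume *adjusted phenotypes*: residuals from a
least-squares fit of the fixed effects (`adjust_phenotypes()`). BLUP,
GBLUP and Bayes C adjust for sex and age; single-step adjusts for sex
alone, because sex is the only covariate one can assume available for
ancestor records. By default the adjustment is estimated on the full
phenotyped sample — the conventional adjusted-phenotype workflow — and a
strict train-only mode (`adjust_scope = "train"`) is provided to quantify
the (small) leakage that convention admits.

BLUP, GBLUP and single-step all solve the same mixed-model equations with
\(\lambda = \sigma^2_e/\sigma^2_a\) and differ only in the covariance
structure (\(A\), \(G\), \(H\)); `mixed_model_solve()` accepts either a
covariance matrix (solved in its training block) or a precision matrix
(Henderson's equations — the only option for single-step, where just
\(H^{-1}\) is available). GBLUP is algebraically identical to ridge
regression on standardized doses, which the tests verify to \(10^{-8}\).

Bayes C is a spike-and-slab SNP model: a proportion \(\pi\) of SNPs have
effects drawn from \(N(0, \sigma^2_{SNP})\) and the rest have none. Doses
are centred by \(2p_i\) but *not* scaled. The Gibbs sampler (compiled
code, driven by R's RNG so `set.seed()` governs it) updates, per cycle: an
explicit intercept \(\mu\); each SNP's (indicator, effect) pair jointly
from its marginal odds; \(\sigma^2_{SNP}\) from its full conditional under
a bounded flat prior (scaled inverse-chi-square draw when at least three
SNPs are in the model, otherwise a grid sampler on the bounded support,
where the bounded prior keeps the density proper); \(\pi\) from
\(\mathrm{Beta}(2 + k,\; 2 + m - k)\) under its Beta(2, 2) prior; and
\(\sigma^2_e\) from its flat-prior full conditional. The bounds of the
flat prior on \(\sigma^2_{SNP}\) default to \((0, 10\,\mathrm{var}(y))\),
a deliberately loose envelope. Posterior means over the recorded draws
give the reported effects and GEBV = centred doses × posterior-mean
effects. With \(\pi\) fixed at 1 the model collapses to ridge regression
and the GEBVs track GBLUP, a key cross-method check. The production chain
length is 40,000 burn-in plus 30,000 draws recorded every 10 cycles
(340,000 total); tests and examples use proportionally scaled-down chains.
No formal convergence diagnostic is applied; an autocorrelation-based
effective sample size of the genetic-variance trace is reported as a
diagnostic output only.

## Cross-validation and evaluation

`make_folds()` shuffles animals under a seed and deals round-robin, so
fold sizes differ by at most one (1,179 animals in 5 folds gives
236×4 + 235; the largest training set has 944 animals).
`cross_validate()` withholds each fold's phenotypes, trains the requested
predictor, and reports the per-fold Pearson correlation \(r\) between
validation EBVs and validation adjusted phenotypes plus the predictive
ability \(PA = r/\sqrt{h^2}\), averaged over folds (plain averaging, no
Fisher transform). The \(h^2\) in PA is the full-sample REML estimate, not
re-estimated per fold. Pedigree methods additionally train on phenotyped
but ungenotyped animals; genomic methods use only genotyped training
animals, with \(G\) built over training plus validation animals (their
*genotypes* are legitimately available at prediction time; their
phenotypes never enter).

`gwas_rank()` is deliberately plain single-marker least squares on
adjusted phenotypes with a two-sided t-test — no relatedness correction —
because its only role is to *rank* markers for pre-selection; under family
structure its p-values are anticonservative, and the output warns
accordingly. `select_snps()` sizes subsets as
`ceiling(fraction × total)`, the only rounding rule consistent with all
the standard thinning proportions. `density_experiment()` rebuilds \(G\)
from each subset and reruns GBLUP cross-validation; its `"biased"` mode
ranks markers on training *plus validation* data — a deliberately leaky
design included only to measure the upward bias of full-data marker
pre-selection, and flagged as such in the output.

# The synthetic-cohort generator

The generator emulates the statistical structure the analysis assumes,
not any particular dog population.

**Pedigree.** Discrete cohorts; per-cohort sire and dam counts are set
from the target family sizes (defaults 1.63 offspring per sire, 1.10 per
dam — small half-sib families), every used parent receives at least one
offspring and the rest are dealt at random. When the previous cohort
cannot supply enough parents of a sex, unrelated "immigrant" parents are
created, mirroring how a screened cohort is drawn from a far wider
registered population; this also produces the key data structure of
phenotyped-but-ungenotyped ancestors surrounding a genotyped youngest
cohort.

**Genotypes.** Gene dropping with phased haplotypes: founder haplotypes
are drawn at frequencies sampled from the minor-allele-frequency range,
optionally with first-order (AR(1)) dependence between adjacent loci
(haplotype blocks); gametes recombine along each chromosome under a
Haldane map (default one Morgan per chromosome, 38 autosomes). Per-locus
marginals are Hardy–Weinberg in founders and Mendelian in offspring
regardless of the LD settings. The block mode (adjacent-locus correlation
0.95–0.98 in the shipped experiments) is what makes marker thinning
plateau: a thinned panel still tags every genomic segment. There is no
breed-specific LD map, no mutation, and no selection.

**Phenotypes.** A latent log-scale liability
\(L = \mu + \mathrm{sex} + \mathrm{exercise} + f(\mathrm{age}) + a + e\)
with \(\mathrm{var}(a) = \sigma^2_a\) and \(\mathrm{var}(e) = \sigma^2_e\)
on the THS scale (defaults 0.11 and 0.29, i.e. \(h^2 = 0.275\); latent
mean 2.35 puts the median HS near 10). Breeding values are either
infinitesimal — founder draws plus Mendelian-sampling deviates with exact
inbreeding-adjusted variances, so \(\mathrm{cov}(a) = \sigma^2_a A\) holds
by construction — or, with `n_qtl > 0`, linear in causal SNP doses with
effects rescaled so the expected additive variance equals \(\sigma^2_a\)
exactly. The hip score is \(HS = \mathrm{round}(e^L - 1)\) clamped to
0–106, which reproduces the right skew that motivates the log transform,
and THS = log(1 + HS) differs from \(L\) only by quantization noise (small
relative to \(\sigma^2_e\), so realized heritability sits within
Monte-Carlo error of the target). Component scores allocate each animal's
HS across the 18 side-by-component cells by a capped multinomial draw:
cells are capped at the scheme maxima (6 per component per hip, 5 for the
caudal acetabular edge) with overflow reallocated to open cells. A
component's allocation weight controls its share of the heritable signal,
so the default weights give CrAE the smallest share and hence the lowest
component heritability, matching its rank in published estimates. This
mechanism was chosen for transparency — any generative model meeting the
skewness and heritability contracts would do — and it does not model
radiographic measurement error or age trends beyond the scoring window.
Age at scoring is uniform on [365, 1825] days; sex effects and weak age
trends are configurable in `trait_architecture()`.

All randomness flows through one explicit seed; internal stages use fixed
offsets of it, and replicate \(k\) of any experiment uses seed + \(k\).

# What passing tests do and do not show

The simulations validate *internal* correctness — estimator equivalences,
parameter recovery under the generative model, and the qualitative
orderings the study design predicts (genomic methods beating a shallow
pedigree, single-step gaining from ancestor records, thinning plateaus,
full-data GWAS pre-selection inflating accuracy). They cannot certify
accuracies on real dog data: real LD structure, genotyping artefacts,
non-random ascertainment of scored dogs, and selection in the pedigree are
all absent from the generator.

# Numerical choices and degenerate inputs

* REML clips negative relationship-matrix eigenvalues at zero (tolerance
  \(10^{-8}\) relative) and errors on clearly indefinite inputs; an
  unstructured (identity) relationship triggers a non-identifiability
  warning.
* `mixed_model_solve()` requires \(\lambda > 0\); the covariance path
  solves an \(n_{train}\)-dimensional system, the precision path one
  equation per animal in the structure.
* Bayes C skips zero-variance (monomorphic-after-centring) SNPs; an
  all-zero phenotype vector degenerates gracefully to null effects.
* The HWE filter tests a 1-d.f. chi-square against expected counts at the
  estimated allele frequency; monomorphic markers return p = 1 and are
  left to the MAF filter. The Bonferroni denominator defaults to the
  number of SNPs tested and is configurable.
* Fold assignment, marker thinning and the Gibbs sampler are all
  deterministic given their seeds.

# Problem sizes in the shipped experiments

The packaged tests and the acceptance script run at desk scale, chosen so
each statistical check has adequate power: heritability recovery uses 20
replicate cohorts of ~2,000 phenotyped animals on a five-cohort pedigree;
the marker-density experiment uses ~1,200 genotyped animals and 10,000
SNPs in haplotype-block mode; oracle equivalences use instances from 2 to
a few hundred animals. The full-length Bayes C chain (340,000 cycles) is
the default only for production fits; scaled-down chains with the same
structure are used everywhere results are compared across methods.

# Limitations

* Single-trait analyses only; no genetic correlations between sides, no
  multi-trait REML, no dominance or epistasis.
* The single-step construction is the classic blended form; bias
  corrections and large-scale approximations (APY and relatives) are out
  of scope.
* The GWAS step is a ranking device, not an association study; no
  genome-wide significance machinery is provided.
* The generator's LD model is a one-parameter block structure, not a
  breed LD map; absolute accuracies from simulations should not be read
  as forecasts for any real population.
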