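---
title: "Multi-trait genomic prediction and phenotyping resource allocation: models and methods"
author: "mtgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait genomic prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Some of the traits a wheat breeding program selects on — dough strength and
extensibility from the alveograph, mixing stability from the mixograph — are
expensive and labour-intensive to phenotype, while genetically correlated
traits such as sedimentation volume, wet gluten or protein content are cheap.
A multi-trait genomic prediction model can exploit those genetic correlations:
lines phenotyped only for the cheap traits can still be predicted accurately
for the expensive one, so the phenotyping budget for the expensive trait can
be cut. `mtgp` implements the full chain needed to study this trade-off —
trial-data adjustment, marker-based kinship, single- and multi-trait Bayesian
whole-genome regression, and the cross-validation designs that mimic
different phenotyping budgets — together with a synthetic-data generator so
every stage is testable without access to proprietary breeding data.

## Models

### Trial model and adjusted means

Raw records from a multi-environment trial network are adjusted per trait
with the linear mixed model

$$y_{ijk} = \mu + g_i + e_j + t_{k(j)} + \varepsilon_{ijk},$$

genotype $g_i$ and environment $e_j$ fixed, trial-within-environment
$t_{k(j)} \sim N(0, \sigma^2_t)$ random, fitted by REML (`lme4`). The
adjusted mean (BLUE) of line $i$ is its genotype estimate plus the average
environment effect. Broad-sense heritability on an adjusted-mean basis is

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \bar\nu / 2},$$

with $\bar\nu$ the mean variance of a difference of two adjusted means,
computed in closed form from the fixed-effect covariance block
($\bar\nu = 2\,[n\,\mathrm{tr}(C) - \mathbf{1}'C\mathbf{1}]/(n(n-1))$, exact
for any panel size). The fixed-genotype model carries no genotypic variance,
so $\sigma^2_g$ comes from a companion fit with genotype random — a
documented convention of this package, since the adjusted-means formulation
needs both parameterizations.

### Kinship

After quality control (markers with more than 20% missing calls, lines with
more than 50%, and markers below 5% minor allele frequency, with MAF always
recomputed last) and imputation, the realized additive relationship matrix is

$$K = \frac{WW'}{2\sum_m p_m q_m}, \qquad W_{im} = X_{im} + (1 - 2p_m),$$

with the same allele frequencies used for centering and for the denominator,
recomputed after imputation. Imputation is an iterative
expectation-maximisation under a multivariate-normal model with a low-rank
(truncated-SVD) covariance: missing entries start at marker means and are
repeatedly replaced by their rank-$r$ conditional reconstruction until the
largest change falls below `tol` (default 1e-3, ample for kinship purposes;
default rank 20). A dense marker-by-marker covariance would be intractable at
several thousand markers, and the leading principal components carry the
relatedness structure that drives genotype imputation. Imputed dosages are
kept real-valued in $W$ (rounding available by flag). A per-marker-mean
fallback (`imputeMean`) is provided.

### Single-trait model

Bayesian ridge regression,

$$y_i = \mu + \sum_j x_{ij}\beta_j + \varepsilon_i, \quad
\beta_j \sim N(0, \sigma^2_\beta), \quad \varepsilon_i \sim N(0, \sigma^2),$$

with scaled inverse-chi-square priors on both variances, degrees of freedom 5
and scale $S = \mathrm{var}(y) \times 0.5$. We read $\chi^{-2}(df, S)$ in the
"sum" parameterisation: the full conditional draw is
$\sigma^2 = (S + \mathrm{SS})/\chi^2_{df+n}$. The default fitting route is
the equivalent G-BLUP form $y = \mu + u + e$, $u \sim N(0, \sigma^2_u K)$,
which costs $O(n)$ per sweep after one eigendecomposition; the marker-effect
form (`fitBRR`) is exact but scales with $m$ and is mainly useful when marker
effects themselves are wanted. Lines with missing phenotype are excluded from
the likelihood; their genetic values are recovered by the projection
$\hat u_{\text{new}} = K_{no} K_{oo}^{-1}\hat u_{\text{obs}}$, which is exact
for posterior means because the conditional expectation of unobserved genetic
values given observed ones does not involve the variance components.

Both samplers accept frozen variance components (`fixSigma2U`, `fixSigma2E`);
in that regime the stationary mean of the chain is the joint ridge solution
$[\mu, \beta] = (Z'Z + \lambda D)^{-1}Z'y$, which the test suite verifies to
1e-3 relative error.

The default chain length of 3000 is read as the total (1500 draws retained
after the 1500 burn-in); both knobs are exposed.

### Multi-trait model

$$y = \mathbf{1}\mu' + u + \varepsilon, \qquad
\mathrm{vec}(u) \sim N(0, \Sigma \otimes K), \qquad
\varepsilon_i \sim N(0, R),$$

with $\Sigma$ unstructured and $R$ diagonal by default — in analyses of this
kind a diagonal residual covariance tends to predict better than an
unstructured one, and it is also what enables the fast sampler below.
The matrix prior $\chi^{-2}(df_\Sigma, S_\Sigma)$ is read as an
inverse-Wishart with the stated scale and degrees of freedom, defaults
$df_\Sigma = 4$,
$S_\Sigma = I_t$; residual variances have per-trait scaled inverse-chi-square
priors with $df = 1$, $S = 1$. Intercepts get flat priors.

Sampling exploits two diagonalisations. With the spectral decomposition
$K = VDV'$ (computed once per fit; eigenvalues below 1e-8 are dropped, which
restricts the genetic prior to the span of the retained eigenvectors and
reduces the inverse-Wishart degrees of freedom increment to the retained
rank), the rotated rows $\tilde y_i = (V'Y)_i$ are independent with prior
$\tilde u_i \sim N_t(0, d_i\Sigma)$ and noise $N_t(0, R)$. Within each sweep
the pair $(\Sigma, R)$ is simultaneously whitened —
$R^{-1/2}\Sigma R^{-1/2} = Q\Lambda Q'$ — after which every cell of the
rotated matrix has an independent scalar Gaussian posterior, so the entire
$n \times t$ genetic-value update is three dense multiplications and one
vectorised draw. $\Sigma$ is drawn from
$\mathrm{IW}(df_\Sigma + r,\, S_\Sigma + \tilde u' D^{-1} \tilde u)$ and each
$R_t$ from its scaled inverse-chi-square conditional.

Missing phenotype cells are handled by data augmentation: each sweep draws
them from $N(\mu_t + u_{it}, R_t)$, which leaves the observed-data posterior
invariant and preserves the complete-data diagonalisation above. The
alternative — conditioning the likelihood on observed cells only — has the
same stationary distribution but forces an $n \times n$ factorisation per
trait per sweep; augmentation makes a full fit on ~500 lines a few seconds
instead of minutes, which is what makes the cross-validation studies
tractable. This is the one place the package deliberately trades the simplest
formulation for speed.

### Cross-validation designs

All schemes mask cells of the adjusted-mean matrix and measure predictive
ability as the Pearson correlation between adjusted means and predicted
genetic values on the lines *not* phenotyped for the target trait:

* **ST-CV1 / MT-CV1** — a random training set is fully phenotyped; test
  lines have no phenotypes at all.
* **MT-CV2** — the target trait is observed on the training set only, the
  1-3 correlated traits on every line (2T/3T/4T designs). Traits outside the
  modelled subset are excluded from the model entirely.
* **MT-CV2-50%b / 50%u** — the correlated traits are phenotyped on only half
  the lines. Train and test sets are each split into four random quarters
  (remainders round-robin); every correlated trait masks two train quarters
  and two test quarters. Balanced: all traits mask the same quarters.
  Unbalanced: each trait gets a distinct pair of quarters, cycling through
  the six possible pairs in seeded random order (separately for train and
  test), which guarantees distinct pairs for up to three correlated traits.

Per-iteration masks and chain seeds derive from one master seed through a
dedicated sub-seed stream, so results are bit-reproducible and adding a
scheme never perturbs existing iterations. Predictive ability uses genetic
values without the intercept — Pearson correlation is location invariant, so
this is immaterial.

## The synthetic-data generator

The generator emulates the study conditions the package is designed around:
495 inbred lines, 6,655 SNPs (reduced in tests), eight traits with
heritabilities spanning 0.36-0.64 in two groups of four (within-group genetic
correlation 0.7 by default, mid-range for trait groups of this kind; zero
across groups), 82 trials in nine environments linked by five check lines
(breeding trial networks typically carry two to eight), fixed environment effects of
unit variance and trial variance 0.5 — moderate management variation relative
to a unit genetic variance.

Genotypes are drawn at Hardy-Weinberg proportions with allele frequencies
uniform on the MAF range; markers are independent (no linkage
disequilibrium — a deliberate simplification; predictive abilities here
reflect relationship information only, not marker-QTL LD, and are therefore
conservative relative to panels with strong LD). Marker effects are i.i.d.
across markers and multivariate-normal across traits (infinitesimal
architecture, appropriate for these highly polygenic quality traits; an
`nQTL` option provides a sparse architecture for robustness checks). Genetic
values are $u = WB$; residual variances are set from the *realized* genetic
variances so each trait's line-level heritability matches its target exactly
in expectation. Trial records are generated from the true genetic values with
per-record residual variance $R_t$, so the trial model's assumptions hold
exactly; each non-check line has a home trial and a third of the non-check
lines are also evaluated in two further environments, mirroring the
multi-location evaluation of advanced lines — this replication is what makes
adjusted-mean heritability estimable at a useful precision. Genotype
missingness is uniform at random (no mechanism was reported for the real
pipeline).

What the generator does *not* emulate: linkage disequilibrium and population
structure, genotype-by-environment interaction beyond additive environment
and trial effects (assumed low), non-Gaussian
trait distributions, and non-random missingness. Passing tests therefore
demonstrate correctness of the machinery and qualitative transferability of
the design comparisons, not quantitative predictive abilities for any real
panel.

## Numerical choices

* Degenerate genetic correlation matrices are repaired by clipping
  eigenvalues at 1e-8 and rescaling to unit diagonal (with a message).
* Kinship eigenvalues below 1e-8 are dropped rather than jittered inside the
  samplers; `KinshipMatrix` validity enforces symmetry to 1e-10.
* REML uses `lme4` with rank-deficiency warnings surfaced; a disconnected
  trial network (no checks linking trials) is an error listing the group
  sizes, since line contrasts across components are not estimable.
* The first environment is the implicit reference level; adjusted means add
  the average environment effect, whose uncertainty is included in the
  reported standard errors.
* With exactly zero residual variance REML is degenerate; tests use a
  whisper of noise instead.
* Sampler determinism is per-seed: each fit calls `set.seed` with its
  configured seed, and `subSeeds()` turns one master seed into per-stage and
  per-iteration seeds.

## Problem sizes used by the test suite

Fixture scales are the package's own choice of "small enough to iterate,
large enough to measure": sampler-correctness checks run at $n = 50$,
$m = 20$ with frozen variances; parameter recovery at $n = 300$, $t = 4$,
$m = 600$ over 20 datasets; the design-comparison study at $n = 495$,
$m = 2000$, $t = 4$, $r_g = 0.8$, $h^2 = 0.5$ with 20 paired CV iterations
per scheme (the full chain length of 3000 is kept; only the number of CV
iterations is reduced from the reference 100). The heritability-recovery
check runs at the full trial-network scale of 495 lines, 82 trials and nine
environments.

## Known limitations

* The marker-form BRR sampler is single-site and pure R; at $m \gg 10^3$ use
  the G-BLUP form (the default), which is exact for the same model.
* The EM imputation models relatedness through leading principal components;
  with very few markers or extreme missingness it degrades toward mean
  imputation.
* The residual covariance is diagonal by default;
  `mtConfig(unstructuredR = TRUE)` switches
  to a full inverse-Wishart residual covariance (missing cells are then
  augmented from their within-row conditional normals, grouped by
  missingness pattern).
* Training-set optimisation (e.g. CDmean) is out of scope; training sets are
  random, so reported predictive abilities are a baseline.
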