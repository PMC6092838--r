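---
title: "Genetic evaluation from group records: model, estimation and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic evaluation from group records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupbv)
```

## The problem

For traits such as feed intake in group-housed pigs, individual recording
requires expensive electronic feeders, while the *total* intake of a pen is
cheap to measure. `groupbv` implements genetic evaluation — variance-component
estimation and breeding-value prediction — when the only phenotype is such a
group total, with group sizes that vary from pen to pen.

## Model

At the individual level the trait follows a standard animal model with two
non-genetic random effects,

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Z}_l \mathbf{l} + \mathbf{Z}_c \mathbf{c}
  + \mathbf{Z}_a \mathbf{a} + \mathbf{e},$$

with litter effects $\mathbf{l} \sim N(0, \mathbf{I}\sigma^2_l)$ (shared
pre-weaning environment of full sibs), pen effects
$\mathbf{c} \sim N(0, \mathbf{I}\sigma^2_c)$ (shared grow–finish environment),
breeding values $\mathbf{a} \sim N(0, \mathbf{A}\sigma^2_a)$ with $\mathbf{A}$
the pedigree relationship matrix, and independent residuals.

Group records arise by premultiplying with an indicator matrix $\mathbf{T}$
(one row per group, `grouping_matrix()`): $\mathbf{y}^* = \mathbf{Ty}$ and all
incidence matrices aggregate the same way (`aggregate_design()`). The
aggregated model is again a linear mixed model, with one crucial change: the
residual covariance is $\mathbf{R}\sigma^2_e$ with $R_{ii} = n_{gi}$, the
group size. Summed over a group, each variance component contributes
according to its sharing structure (`pen_var_group()` and friends):

| component | group-level variance |
|---|---|
| pen        | $n_g^2\,\sigma^2_c$ |
| litter     | $\sum_k n_{lk}^2\,\sigma^2_l$ |
| additive   | $\sigma^2_a \sum_{jj'} A^*_{jj'}$ |
| residual   | $n_g\,\sigma^2_e$ |

The pen contribution is quadratic in group size while the residual is linear;
this contrast is exactly what makes $\sigma^2_c$ estimable from totals — but
only when group sizes vary. With constant $n_g$,
$\mathbf{Z}^*_c\mathbf{Z}^{*\prime}_c = n_g \mathbf{R}$ and pen and residual
variance are confounded; if every pen holds one whole litter,
$\mathbf{Z}^*_l\mathbf{Z}^{*\prime}_l = \mathbf{Z}^*_c\mathbf{Z}^{*\prime}_c$
and litter and pen are confounded. `check_identifiability()` detects both
patterns algebraically, and `fit_reml()` refuses such layouts unless forced.

Because a single-trait evaluation from group totals cannot distinguish
full sibs within a pen, they receive identical predictions; the information
loss relative to individual records is the central quantity the simulation
machinery measures.

### The reduced-weight formulation

The pen effect can be absorbed into the residual: the group residual variance
becomes $n_g^2 b\,\sigma^2_e + n_g \sigma^2_e = n_g(b\,n_g + 1)\sigma^2_e$
with $b = \sigma^2_c/\sigma^2_e$, i.e. diagonal weights
$R^*_{ii} = n_{gi}(b\,n_{gi}+1)$ (`reduced_weights()`). At the true $b$ this
model is exactly equivalent to the full pen model (same likelihood, same
predictions — tested to $10^{-8}$) while avoiding the notoriously unstable
explicit pen term; $b$ can be taken from individual-record analyses of a
correlated trait.

## Estimation

`fit_reml()` maximises the restricted likelihood by average-information (AI)
updates. The implementation keeps two exact evaluation routes:

* **Sparse route** (individual records): Henderson's mixed-model equations
  are factorised with a sparse Cholesky (Matrix/CHOLMOD). First derivatives
  need traces of blocks of the inverse coefficient matrix; these are computed
  *exactly* by a Takahashi selected inverse of the factor (compiled code),
  not by Monte-Carlo sampling. The average information matrix comes from
  working variates (one extra solve per component).
* **Dense route** (group records): with a few hundred group totals, the
  phenotypic covariance $\mathbf{V}$ fits in memory; likelihood, score and AI
  are direct matrix expressions, and the relationship part
  $\mathbf{Z}^*_a\mathbf{A}\mathbf{Z}^{*\prime}_a$ comes from one sparse
  solve against $\mathbf{A}^{-1}$. The mixed-model equations are solved once
  at convergence for the breeding values.

Both routes were verified against each other and against a dense textbook
implementation of the REML likelihood, score and GLS/BLUP solutions
(equality to $10^{-6}$ or better in the test suite).

Numerical safeguards, chosen once and fixed:

* starting values: the empirical phenotypic variance (for group totals,
  divided by the mean group size) split equally across components;
* step halving when an AI step leaves the parameter space or decreases the
  likelihood, then an EM step (written through the score,
  $\sigma^2 \mapsto \sigma^2 + 2\sigma^4 g/q$, which is uphill by
  construction);
* variances floored at $10^{-8}\times$ the phenotypic variance — REML
  estimates must stay positive — with an active set: a component pinned at
  the floor with a downhill score is held there, excluded from the update
  and from the convergence norms, and reported in `boundary`; components
  that EM drives below $10^{-4}\times$ the phenotypic variance are snapped
  onto the floor rather than allowed to decay geometrically forever;
* convergence when the relative parameter change is below $10^{-6}$ and the
  scaled score norm below $10^{-4}$; 200 iterations maximum.

Pen models on group records converge slowly or pin at the boundary in a
small fraction of replicates (the residual and pen variances are barely
separated when sizes vary little); the replicate runner records and excludes
such fits rather than failing.

## What the simulator emulates

`simulate_population()` reproduces the validation design: 30 sires each
mated to 20 dams, litters of six test candidates, eight non-overlapping
generations under random selection and random mating, phenotypes in the last
five generations, variances $(\sigma^2_a,\sigma^2_l,\sigma^2_c,\sigma^2_e) =
(120, 40, 40, 200)$ — heritability 0.3, total variance 400 — or
$(120, 280)$ for the phenotype without litter and pen effects. Breeding
values descend with Mendelian sampling variance
$\tfrac12(1 - (F_s+F_d)/2)\sigma^2_a$; inbreeding is accounted for exactly
(Meuwissen–Luo) even though it stays small under this design. Pens of 12 are
filled within generation from whole litters (`L_1x6`), random sub-litters of
three (`L_2x3`, the base design), or individuals at random (`L_ran`); 20%
of tested animals are deleted at random, so realised group sizes are
Binomial(12, 0.8) draws with mean 9.6. Breeders are drawn from the
survivors, which keeps every parent in the data and leaves the size
distribution intact.

Decisions the design left open, fixed here: breeders are sampled uniformly
without any within-litter quota; sex is assigned 50/50 at random; deletion
is i.i.d. per animal (not per pen); sub-litters may occasionally land in the
same pen under random allocation of sub-litters.

The simulator is deliberately idealised relative to real pig data: no
selection, no overlapping generations, one parity per sow, no genotyping,
single trait, homogeneous variances. Passing tests therefore demonstrate the
estimator's behaviour under the model's own assumptions, not robustness to
the many ways field data violate them.

## Problem sizes used in tests and the acceptance script

The reference population (30 sire families) gives roughly 29 000 pedigree
animals per replicate. The packaged experiments run a population with the
identical family structure — 20 dams per sire, litters of six, sub-litter
pens of 12, 20% attrition — but 10 sire families and 20 replicates, about
9 800 animals per replicate. Accuracy and the variance-component biases
depend on the family structure and the information per animal, which this
scaling preserves; replicate means simply carry larger Monte-Carlo error,
which the tests account for through their own replicate standard deviations.
Stochastic checks are asserted within three standard errors of the replicate
mean.

## Known limitations

* Single trait, single fixed effect (overall mean) in the packaged
  scenarios; the design machinery accepts general fixed effects but the
  runner does not exercise them.
* No genomic information: full sibs within a pen are not distinguishable.
* Groups are assumed disjoint; animals recorded in two pens are rejected.
* The dense group-level route assumes the number of groups is modest
  (thousands at most), which holds for pen-total data by construction.
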