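---
title: "Models and methods: testing panmixia and isolation by environment across elevational gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradientpanmixia)
```

## The scientific question

Organisms adapted to thermally stable environments are expected to evolve
narrow thermal tolerances, which should select against dispersal across
steep temperature gradients such as tropical mountainsides. If that
selection operates within a species' elevational range, neutral genetic
differentiation should correlate with environmental distance (elevation,
temperature, precipitation) over and above geographic distance — isolation
by environment (IBE) rather than plain isolation by distance (IBD). The
alternative outcome, panmixia across the gradient, predicts no
population structure, an IBE contribution near zero, effectively infinite
Wright's neighborhood sizes, and (if ranges are at equilibrium) no loss of
genetic diversity toward range limits and no signal of recent expansion.

`gradientpanmixia` implements that whole inferential chain for
reduced-representation SNP data: a reproducible post-calling filter
cascade, population-structure summaries, a Bayesian model of
allele-frequency covariance decaying with geographic and environmental
distance, coalescent/ABC demographic model choice on the site frequency
spectrum, and range-limit diagnostics. A seeded synthetic-data generator
mirrors the generative assumptions of every stage so that each estimator
can be validated by parameter recovery rather than by eye.

## The filter cascade

Variant filtering follows a fixed ten-rule order (see
`?apply_filter_cascade`); order matters for the per-rule counts and is part
of the contract. Rules use strict inequalities exactly where their
conventional statements do (`QUAL < 30`, allelic balance `> 0.75` or
`< 0.25`). Three readings deserve comment:

* **"Quality more than a quarter below depth"** is implemented as
  `QUAL < 0.25 * site depth`, with the factor exposed in
  `filter_config(qual_depth_factor_low=)`; the alternative parse
  (`QUAL < 0.75 * depth`) is one configuration change.
* **High-depth outliers.** Sites are flagged when their *mean
  per-individual* depth exceeds `3 * (mean over sites)^2`. On the
  summed-depth scale this threshold is unreachable for any plausible
  dataset (the square term dominates), whereas on the mean-depth scale it
  corresponds to the familiar histogram-of-mean-depth cut; flagged sites
  survive only with quality exceeding twice their depth, and a
  reproducible 99.5th-percentile cut replaces a qualitative
  histogram-asymptote judgement.
* **Strand balance** is a drop rule keyed on an INFO annotation and
  disabled by default: single-end RAD data rarely carry one, and enabling
  the rule without the annotation is a configuration error rather than a
  silent no-op.

Re-applying the cascade to its own output is a fixed point in all tested
configurations; the one caveat is that masking low-depth genotypes (rule 5)
raises per-locus missingness, so a locus sitting exactly at the 25%
missingness boundary can fall out only on a second pass. The bundled
fixtures keep clear margins around every threshold.

## Core statistics

Distances are great-circle kilometres (radius 6,371 km) and Euclidean
distances over z-scored environmental variables; z-scoring makes the
environmental distance invariant to units and offsets, which matters when
elevation (metres) meets temperature (degrees). Both matrices are divided
by the standard deviation of their off-diagonal values before modelling,
and the constants are kept to back-transform parameters afterwards.

F\_ST between population pairs is the Weir–Cockerham (1984)
variance-component estimator for samples of alleles, combined across loci
as a ratio of sums. Negative estimates are legitimate (within-population
heterozygosity above its panmictic expectation) and are preserved; the
range-limit stage corrects them to zero only where the Rousset regression
requires it. The test suite checks the estimator against an independent
`anova()`-based variance-component oracle over all single-locus
two-population tables with up to six alleles per population, plus seeded
random multi-locus tables.

Per-locus diversity uses the unbiased expected heterozygosity
`H = n/(n-1) (1 - sum p^2)` and inverts the infinite-alleles equilibrium
`F = 1/(1+theta)` to `theta = H/(1-H)`. The folded SFS drops sites with
missing genotypes by default or projects each site down to a common even
haploid size by the hypergeometric expectation (`project_to=`); the
pipeline projects to the even floor of the median per-site allele count,
retaining roughly half the sites instead of the vanishing fraction that
complete cases leave at realistic missingness. PCA imputes missing dosages
to locus means and centres but does not scale (scaling is available via
`scale.`); replacing a visual outlier call, individuals more than 6 MADs
from the median on PC1 or PC2 are flagged.

## The isolation-by-environment model

Reference-allele counts `x_kl` of population `k` at locus `l` are binomial
draws from latent frequencies `f_kl`. Each locus has a mean
`mu_l ~ Uniform(0,1)` and latent vector
`f_l ~ N(mu_l 1, mu_l (1-mu_l) Omega)` truncated to `(0,1)^K`, with

```
Omega_ij = (1/alpha0) * exp(-(alphaD D*_ij + alphaE E*_ij)^alpha2) + delta 1[i=j]
```

on standardized distances. `alpha0` sets the marginal drift variance,
`alphaD` and `alphaE` are the decay rates per standardized kilometre and
environmental unit, and `alpha2 in (0,1]` shapes the kernel; restricting
`alpha2` to (0,1] and adding a fixed nugget `delta = 1e-6` keeps the
kernel positive definite on any metric design, and non-positive-definite
proposals are simply rejected during sampling. Priors are weakly
informative and exposed as arguments: half-normal(10) for `alpha0`,
Exponential(1) for the decay rates, Uniform(0,1] for `alpha2`. This is a
fresh implementation of the verbal model description (binomial likelihood
over a latent spatial Gaussian process), not a port of any existing tool;
truncation is approximated by bound-rejection of proposals, which spends a
negligible prior-mass correction for the usual frequency ranges.

Sampling is blockwise adaptive Metropolis–Hastings in compiled code: one
covariance parameter per iteration in rotation, all locus means, and all
latent frequency vectors (as per-locus joint proposals) per sweep. Step
sizes adapt toward the 20–70% acceptance band during the first quarter of
the run and are frozen afterwards, so the retained samples target the
exact posterior; acceptance rates per block are reported and the
prior-sampling diagnostic mode (`likelihood = FALSE`) is tested against
the analytic priors by Kolmogorov–Smirnov. Desk-scale defaults are 1e5
iterations thinned by 25 with a 25% burn-in at summary time;
production-scale runs (2e6 iterations, thinning 250) are plain argument
changes. At `K = 10` populations and 500 loci, 1e5 iterations take about
half a minute on one core.

The headline summary is the posterior of the IBE/IBD ratio in raw units,
`(alphaE/alphaD) * (sd_D/sd_E)`. Samples with `alphaD` below a
documented floor (1e-6) are floored and counted: when geography explains
nothing, the ratio is a quotient of two near-zero quantities and its
posterior is prior-dominated. This matters for interpretation. On data
that are *actually panmictic* (both decay rates near zero) the likelihood
constrains only the sum of the decay terms, the ratio reverts to its
prior, and its posterior mean can be arbitrarily large; a small mean ratio
is therefore evidence of IBD-without-IBE only when `alphaD` itself is
resolved away from zero. Note also that the raw-unit ratio depends on the
measurement units of both distances, so comparisons across studies using
raw (un-z-scored) environmental variables are not unit-free.

A related design observation: on a single linear transect, elevation and
geography are perfectly collinear (the distance correlation in such
designs approaches 1) and `alphaD` and `alphaE` are jointly unidentified.
The generator therefore offers a `"ridge"` elevation profile — rising to
the middle of the transect and falling again, as when sampling crosses a
ridge or combines elevational with constant-elevation transects — which
decouples the two distances. The recovery experiments use this design; on
it, data simulated with `(alphaD, alphaE) = (1, 0)` at `K = 10`, 500 loci
and 20 alleles per population yield posterior means around
`alphaD ≈ 1`, `alphaE ≈ 0.03`, and planting a raw ratio of 1 puts 1 well
inside the 90% interval.

## Demography: coalescent simulation and ABC

The demographic stage compares a constant-size ("null") single-population
model against exponential growth, on the folded SFS aggregated over
unlinked loci. The coalescent engine applies the standard time
transformation for a backward population size `N(t) = N0 e^(-alpha t)`:
with `k` lineages at time `t0` and `w ~ Exp(k(k-1)/2)`, the next
coalescence is at `t1 = log(exp(alpha t0) + alpha w)/alpha` (continuously
reducing to `t0 + w` as `alpha -> 0`, with an asymptotic guard against
overflow at large `alpha t`). Mutations fall as a Poisson process at rate
`theta/2` per unit branch under infinite sites; a "three-nucleotide" locus
is represented as an infinite-sites locus with per-locus `theta` equal to
three times the per-site value. The engine is validated against
Watterson's `E[xi_i] = theta/i` (within 3% at 50,000 loci), the analytic
mean total branch length `2 * sum_{i<n} 1/i`, and an independent
coalescent simulator through Python.

Reference tables draw `theta` log-uniform on [0.1, 20] per locus and,
under growth, `alpha ~ Uniform(0, 10)` (priors unstated in comparable
field studies; these are broad and config-exposed), storing normalized
folded-SFS proportions as summaries. Monomorphic simulated datasets keep
an all-zero summary rather than being resampled, to avoid distorting the
prior. Rejection ABC accepts the `ceiling(tolerance * n)` simulations
closest in Euclidean distance with per-coordinate MAD scaling
(zero-MAD coordinates get unit scale); model choice pools tables, takes
posterior model probabilities as acceptance shares, and reports Bayes
factors in both orientations (reciprocal by construction; zero-acceptance
models are flagged as bounds). Leave-one-out cross-validation tabulates
confusion matrices at tolerances 0.01 and 0.05 over 100 held-out datasets
per model — the conventional reading of a "tolerances 0.01, 0.05, and 100
simulations" protocol. Desk-scale reference tables of 10,000 simulations
per model build in seconds; 100,000 is a config change.

## Range limits

Two diagnostics ask whether elevational ranges behave like equilibrium
ranges. First, per-locus `theta` values are regressed on each locality's
absolute elevational distance from the individual-weighted mean sampling
elevation, with a random intercept per locus, and the covariate is tested
by a 1-df likelihood-ratio test (maximum likelihood fits via `lme4`). A
fixed population factor alongside a population-level covariate would be
unidentifiable, so the locus is the grouping factor; the test's type-I
error is verified by simulation to sit at its nominal 5%. Second,
Rousset's regression of `FST/(1-FST)` on log distance estimates Wright's
neighborhood size `Nw = 4 pi rho sigma^2` as the reciprocal slope, with
negative FST values and negative slopes corrected to zero so that
non-positive slopes report `Nw = Inf` — the panmixia signature. Only the
density-dispersal product is estimable. Note the sampling behaviour of
this estimator under true panmixia: the fitted slope is a zero-mean noise
variable, so roughly half of panmictic datasets return a finite (if
enormous) `Nw` and half return infinity; `Nw` is best read jointly with
the FST values themselves.

## The synthetic-data generator

The generator is the package's study-design stand-in: 4–10 localities
evenly spaced in elevation along a straight line (default spacing 1 km,
elevational spans of a few hundred metres, ten individuals per locality),
temperature and precipitation derived from elevation with a tropical
lapse rate, per-locus frequencies drawn from exactly the IBE covariance
model (`alpha0 = 5` by default, a moderate drift variance), binomial
diploid genotypes, independent missingness, negative-binomial depths
(mean 30, dispersion 5), binomially split allele depths, depth-scaled
site qualities, and FreeBayes-style mapping-quality annotations. Clamping
frequencies to [0.001, 0.999] substitutes for formal truncation. Because
generator and inference share one covariance, recovery tests close the
loop. What the generator does *not* emulate: linked sites and LD beyond
duplicated RAD SNPs, allele-dropout and paralog collapse, strand
artifacts, non-equilibrium spatial expansions, or selection — so passing
recovery tests demonstrates correctness of the estimators under the
model's own assumptions, not robustness to those real-data pathologies.

## Problem sizes and numerical choices

Default test-time workloads are chosen to make every check run on a
single core at desk scale: coalescent oracles at 40,000–50,000 loci,
ABC experiments at 10,000 simulations per model with 30 diploids, IBE
recovery at ten seeds per scenario of 1e5 iterations (`K = 10`, 500 loci),
the LRT calibration at 1,000 simulated null datasets, and ten end-to-end
pipeline runs at 2,000 loci with 30,000-iteration MCMC on at most 250
LD-pruned loci. Production-scale equivalents (2e6 iterations, 1e5
simulations) are configuration changes, not code changes. Ties and degenerate inputs
are handled explicitly: monomorphic loci give `theta = 0`, sites without
heterozygotes pass the balance rule, same-locality pairs are excluded
before the log-distance regression, all-missing loci are dropped with a
warning before PCA, and every stochastic function takes an integer seed
with fixed seeds giving byte-identical outputs.

## Known limitations

The IBE/IBD ratio is unidentified under true panmixia (above) and its raw
value is unit-dependent; the neighborhood-size estimator's infinity is a
one-sided event under the null; rejection ABC with MAD-scaled SFS
proportions is insensitive to overall diversity when only proportions are
kept (total segregating sites enter through the summaries' shape, not
their sum); and the filter cascade's single-pass semantics mean
rule-order, not joint optimisation, defines the retained set. These are
properties of the methods as defined, reproduced faithfully.
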