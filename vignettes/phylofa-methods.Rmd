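---
title: "Models and methods in phylofa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phylofa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phylofa studies how liver fatty-acid (FA) composition covaries with
life-history traits — maximum life span, annual fecundity, basal metabolic
rate (BMR) — across bird species, while controlling for body mass,
migration and shared ancestry. This vignette documents the statistical
models, the numerical choices behind them, and what the synthetic-data
machinery does and does not establish.

## The data model

The unit of observation is a species. Composition enters as a species ×
fatty-acid matrix of molar percentages (mol%) closing to 100 per row
within a tolerance (±0.5 mol% by default, because published species means
need not close exactly; optional renormalization restores exact closure).
Fatty-acid labels follow the `C<carbons>:<bonds>n<omega>` shorthand and
are parsed into chain length, double-bond count, omega class and
saturation class, from which the composition indices derive:

* class sums SFA/MUFA/PUFA and the n-3/total-PUFA ratio (kept as a
  fraction in [0, 1], which is what a beta likelihood needs; rendering as
  a percentage is a formatting concern);
* average chain length, ACL = Σ (mol fraction × chain length);
* double bond index, DBI = Σ (mol% × double bonds);
* peroxidizability index with the conventional susceptibility weights
  0.025, 1, 2, 4, 6, 8 for one to six double bonds — the monoenoic
  coefficient is 0.025 exactly and no coefficient is extrapolated beyond
  hexaenoic acids, which are an error if present;
* anti-inflammatory index, AI = 100 × (20:3n-6 + 20:5n-3 + 22:6n-3) /
  20:4n-6. The numerator is an explicit enumeration: acids outside it
  contribute nothing. Species with no arachidonic acid get `NA`.

Indices are computed on the mol% values as given; when rows do not close
exactly we do not renormalize first, since the published index
definitions operate on reported proportions.

## Phylogenetic covariance

A rooted Newick consensus tree with branch lengths is the contract; tree
inference and consensus building happen upstream. Under Brownian trait
evolution, the covariance of two tips is the root-to-tip path length they
share, assembled by `phylo_vcv()`. The regression models consume the
normalized (correlation) form — each entry divided by the geometric mean
of its two diagonals — so that the phylogenetic standard deviation
`sigma_p` is identifiable on a common scale and comparable across trees;
for an ultrametric tree this equals division by tree height. The raw
shared-path matrix remains available (`normalize = FALSE`) for
sensitivity work. Non-ultrametric trees are accepted with a warning and
normalized through their per-tip depths. Pruning preserves the basal path
to the subtree root, so the pruned covariance is exactly the submatrix of
the full one.

## Migration distance

Distance between a fixed origin and each species' non-breeding centroid
uses the spherical haversine formula with mean Earth radius 6371 km; both
the radius and the origin are configuration values rather than constants
(the origin of the source data is the centroid of the Jutland part of
Denmark, for which no canonical coordinates exist). Distances are
reported in thousands of kilometres, and sedentary species are zero by
definition. Whether the source distances were geodesic or spherical is
not recorded; we implement the spherical form as named.

## The regression model

For a proportion response `y` in (0, 1):

    y_i ~ Beta(mu_i * phi, (1 - mu_i) * phi)
    logit(mu_i) = x_i' beta + u_i

and for a non-proportional index (ACL, DBI, PI, log-AI), a Gaussian
response with identity link and residual sd `sigma_e`. In both cases
`u ~ MVN(0, sigma_p^2 C)` with `C` the normalized phylogenetic
correlation. Body mass, life span, annual fecundity, BMR and ring
recoveries are log-transformed; every predictor (and every Gaussian
response) is z-standardized after its transform, so coefficients are per
standard deviation. Life span is included among the log-transformed
variables: treatments of this vary, but life span is strongly
right-skewed and the log scale is the standard choice for allometric
covariates. Proportions are modelled on the (0, 1) scale — required by
the beta density — and marginal effects are reported on that scale.
Exact zeros or ones are compressed with `y' = (y(n-1) + 0.5)/n`, applied
only when boundary values occur and logged when they are; the beta
support is open, so some such rule is unavoidable, and this is the
standard one.

Priors are weakly informative and configurable: improper flat priors on
`beta`, half-Student-t(3, 0, 2.5) on `sigma_p` and `sigma_e`, and
Gamma(0.01, 0.01) on `phi` — mirroring the documented defaults of the
mixed-model software this class of analysis typically uses.

### Sampler

The posterior is explored by an adaptive Metropolis-within-Gibbs sampler
written in C++. Species effects are sampled explicitly rather than
integrated out, because no closed form exists under the beta likelihood.
Each iteration combines:

* univariate random-walk updates of each coefficient (three sweeps — they
  cost O(n) against the O(n²) species-effect cycle);
* two sweeps over species effects: a random-walk sweep plus an
  independence sweep that proposes from the prior full conditional
  `u_i | u_-i` and accepts on the likelihood ratio alone — essential for
  tips tied by very short branches, whose effects are almost perfectly
  coupled;
* a joint proposal along the prior correlation, `u' = u + s sigma_p Lz`,
  covering coherent directions single-site moves traverse slowly;
* likelihood-invariant translations trading `beta_j` against `u` (the
  flat-ridge direction between fixed and species effects);
* centered and non-centered (scale) moves on `sigma_p`, the standard pair
  for funnel geometry; and a log-scale walk on the dispersion.

Proposal scales adapt in batches of 50 during burn-in only, targeting
0.44 acceptance for scalar moves and 0.234 for the joint move; freezing
them afterwards preserves detailed balance. All randomness flows through
R's RNG: chain `k` runs under `seed + k − 1`, so fits are bit-for-bit
reproducible. Near-singular correlation matrices receive an escalating
diagonal jitter (up to 1e-6) before factorization.

### Diagnostics and summaries

Convergence uses the classic (non-split) Gelman–Rubin statistic,
`sqrt(((n-1)/n W + B/n)/W)`, with the 0/0 case of identical constant
chains defined as 1; a fit whose maximum R-hat across *all* sampled
parameters (coefficients, variances and every species effect) exceeds
1.01 is flagged but still returned. Intervals are equal-tailed posterior
quantiles with linear interpolation of order statistics (R's type 7), so
a sort-based oracle reproduces them bit-for-bit. An effect is "significant"
when its 95% interval excludes zero.

Average marginal effects are computed per draw: for the Gaussian family
the coefficient itself; for the beta family
`beta_j × mean_i[mu_i(1 − mu_i)]` with `mu_i` evaluated at that draw's
coefficients and species effects. Including the sampled `u_i` (rather
than setting them to zero) is the default because the reported effects
should average over the population the model actually describes; the
`include_random = FALSE` switch gives the alternative.

The default MCMC configuration — 4 chains × 4,000 iterations, 1,000
burn-in, thinning 2, i.e. 6,000 retained draws — is the package's
desk-scale working setting; the heavier 25 × 6,000/2,000/10 configuration
used in publication-scale analyses is one `mcmc_control()` call away.

## PGLS residual correlations

The descriptive correlation structure among indices and individual acids
is computed on residuals from phylogenetic generalized least squares on
log body mass: proportions are logit-transformed (after the same boundary
squeeze), AI is log-transformed, each variable is PGLS-regressed with the
Brownian `C` as-is (no Pagel's λ estimation — the analysis names plain
PGLS), and Pearson correlations are taken pairwise on the residuals.
Pearson rather than rank correlation because the variables are
pre-transformed toward normality.

## Synthetic data and what it shows

`simulate_dataset()` generates the study conditions: 106 species on a
unit-height Yule tree (the pure-birth growth is implemented directly from
its exponential waiting-time construction, so the lineage-growth
expectation 2e^{λt} is testable analytically); compositions as Dirichlet
draws whose log-concentrations are the published median profile shifted
by phylogenetically correlated noise (closure holds by construction);
life-history traits with allometric slopes on log mass (BMR 0.66, life
span 0.2, fecundity −0.15) plus phylogenetic and independent log-normal
noise; ring recoveries as log-normal counts; Bernoulli migration with
Africa/Europe-window centroids; and one focal beta response with
`beta = 0.3` per predictor sd, `sigma_p = 0.5`, `phi = 50` — effect sizes
chosen so that recovery studies run at desk scale with realistic
signal-to-noise. One master seed derives all component seeds.

Passing recovery tests on these data shows the estimator is correct and
calibrated *under the generating model*: beta-distributed proportions,
Brownian phylogenetic effects, exact closure, no measurement error. Real
compositions carry features the generator does not emulate — lipid-class
mixtures, diet-driven covariance between acids, ring-recovery effort
bias beyond a count covariate — so green tests here certify the
machinery, not any biological conclusion.

Two statistical subtleties in the validation are worth recording. The
phylogenetic concentration shifts are shared across related species, so
medians taken over a single large tree do not converge on the baseline
profile; profile-recovery checks therefore pool species across
independent replicate trees. And with 50 replicate fits, binomial noise
makes ±3 sd bands the honest envelope for coverage (0.86–1.00) and
false-positive rates (≤ 0.14 around the nominal 5%).

## Problem sizes

Validation runs use: exact index and covariance oracles at up to 500
species; sampler-versus-OLS and versus-ML checks at n = 80 and n = 500;
one thorough fit and 50 reduced-MCMC replicate fits at the study scale of
106 species; and 200 simulated trees for the positive-semidefiniteness
sweep. These sizes make the full suite run in about a minute while
leaving every check statistically decisive.

## Known limitations

* No Pagel's λ or Ornstein–Uhlenbeck transformations of the covariance;
  Brownian motion is assumed, as in the analysis the package implements.
* No model comparison (WAIC/LOO), multivariate responses or
  within-species replicate variance.
* The sampler is random-walk based; gradient-based samplers would scale
  better to many predictors, but at p ≤ 5 and n ≈ 100 the implemented
  moves mix to R-hat < 1.01 within the default budget.
* Consensus-tree construction and range-polygon centroids are consumed,
  not computed.
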