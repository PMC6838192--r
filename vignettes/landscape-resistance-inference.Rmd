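---
title: "Landscape resistance inference: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape resistance inference: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`landres` implements a complete isolation-by-resistance (IBR) inference
chain for population-based landscape genetics: pairwise genetic
differentiation from genotypes, candidate resistance surfaces from landscape
rasters, circuit-theory effective resistance between sampling localities,
genetic-algorithm optimization of surface parameters against the genetic
data, and bootstrap AICc model selection across competing surfaces. This
vignette explains the underlying models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does not
establish about real data.

## The isolation-by-resistance model

Under isolation by distance (IBD), genetic distance between populations
grows with geographic separation alone. IBR generalizes this: the landscape
is treated as an electrical network in which each raster cell has a
resistance to movement, and the predictor of genetic distance is the
*effective resistance* between two localities — a quantity that integrates
all possible paths simultaneously, not just the best one. A landscape
feature "matters" when assigning it non-uniform resistance values yields
effective-resistance distances that explain pairwise genetic distances
better than straight-line distance does.

### Genetic distance

Pairwise differentiation is the multi-locus, multi-allele Weir–Cockerham
theta: for each allele at each locus the among-population (a),
among-individual (b) and within-individual (c) variance components are
accumulated, and theta = sum(a) / sum(a + b + c). Negative estimates are
reported as-is; truncating them at zero would bias the downstream
regressions. Missing genotypes are handled locus-wise — an individual
missing a locus is dropped from that locus only. A locus monomorphic across
the populations being compared contributes nothing; if *all* loci are
monomorphic the estimate is undefined and the package raises an error
rather than silently returning 0.

### Circuit-theory effective resistance

A resistance surface (every cell >= 1) becomes a weighted graph using
8-neighbor connectivity with the average-resistance scheme: an orthogonal
edge between cells i, j has resistance (r_i + r_j)/2 and a diagonal edge
sqrt(2) times that, reflecting the longer span. Effective resistance
between two focal cells is obtained by grounding one, injecting unit
current at the other, and solving the reduced graph-Laplacian linear
system; the pairwise matrix over k localities reuses one sparse Cholesky
factorization per connected component with one triangular solve per focal
node, so the cost is one factorization plus k − 1 back-substitutions rather
than one solve per pair. Disconnected pairs are reported as an explicit
`Inf` marker; the MLPE fitter refuses matrices containing it rather than
imputing. Current maps accumulate, over all focal pairs, each node's
current (half the sum of absolute incident edge currents; the injected unit
at source and sink), giving the familiar corridor visualization.

The solver is validated in the test suite against a dense Laplacian
pseudoinverse oracle and against series/parallel closed forms, and its
solutions satisfy Kirchhoff conservation to ~1e-10.

## Resistance surfaces

*Categorical* layers (habitat class, rasterized rivers/roads) assign one
resistance per class. One reference class is held at exactly 1 and the free
classes are searched in [0.01, 3500]. The lower bound is 0.01 rather than
0 because a zero-resistance cell is a superconducting shortcut that
degenerates the circuit problem; values below the floor are clamped with a
warning.

*Continuous* layers (distance to village, topographic position index) are
first affinely rescaled to [0, 10] so that transformation parameters are
comparable across layers, then passed through one of two transformations
with shape and maximum parameters:

- Monomolecular: f(x) = maximum (1 − exp(−x/shape)) — saturating,
  monotone increasing;
- Ricker: f(x) = maximum · x · exp(−x/shape) — hump-shaped with mode at
  x = shape, able to express "resistance first falls then rises" patterns.

Outputs are re-anchored so the easiest cell has resistance exactly 1. This
is a gauge choice, not a modelling assumption: the MLPE slope absorbs
overall scale, and anchoring removes a flat direction from the optimization.
The shape bound of 14 on the [0, 10] domain keeps both transformations
numerically informative; beyond it the monomolecular curve is effectively
linear.

*Composites* are cellwise sums of component resistance surfaces, re-anchored
to minimum 1. Sum (rather than product) is the package's convention for
additive movement costs; it is isolated in one function
(`combine_composite()`) so it can be swapped.

## The MLPE mixed model

Pairwise distances are not independent: two pairs sharing a population are
correlated. The maximum-likelihood population effects (MLPE) model accounts
for this with a random effect per population entering every pair it belongs
to:

y_ij = beta0 + beta1 * x̃_ij + u_i + u_j + e_ij,
u ~ N(0, sigma_u²), e ~ N(0, sigma_e²),

where x̃ is the z-scored predictor (standardization is recomputed on every
fitted dataset, including bootstrap subsamples, so beta1 is per predictor
SD and invariant to affine rescaling of the raw predictor). The incidence
matrix Z has one row per pair with exactly two unit entries, inducing
Var(y) = 2 sigma_u² + sigma_e² and Cov = sigma_u² times the number of
shared populations.

Fitting is by maximum likelihood (not REML, since models with different
fixed-effect scalings are compared). Writing lambda = sigma_u²/sigma_e²,
beta and sigma_e² have closed-form profile solutions given lambda, so the
optimization is one-dimensional; a single symmetric eigendecomposition of
ZZᵀ makes each profile evaluation O(p). The lambda = 0 boundary — exactly
the OLS model — is always evaluated alongside the interior optimum and the
better kept, so the fitted likelihood can never fall below the OLS
likelihood. The likelihood surface is validated against a dense
multivariate-normal evaluation in the tests.

### AICc and the K convention

Surfaces are compared by AICc with **effective sample size = number of
populations**, not number of pairs — the pairs are pseudo-replicates of n
populations, and using p = n(n−1)/2 would wildly overstate the information
content. The parameter count K follows the model-table convention:
Euclidean null K = 2; categorical surface K = number of classes + 1;
continuous surface K = 3; composite K = sum of component Ks. Akaike weights
are the usual exp(−Delta/2) normalization.

## Genetic-algorithm optimization

Free surface parameters are optimized by a real-coded GA: tournament
selection (size 3), BLX-0.5 blend crossover, Gaussian mutation with SD 10%
of each gene's range, elitism of 2, population max(20, 10 × genes),
stagnation stop after 25 generations without a log-likelihood gain above
1e-6 (hard cap 200 generations). All settings are exposed in `ga_config()`;
they are conventional real-coded-GA defaults, chosen once. Fitness is the
MLPE log-likelihood: within one surface's search K is constant, so
log-likelihood and AICc rank candidates identically, and AICc is reserved
for between-surface comparison. Circuit solves dominate the cost, so
candidate resistance matrices are memoized on the gene vector rounded to 4
decimals, and the value-independent graph structure (node indexing, edge
list, connectivity) is computed once per landscape and re-weighted per
candidate. Every run is a pure function of its seed; `replicate_runs()`
reruns an optimization under several seeds and flags replicate best-surface
correlations below 0.95, encoding the convention of running every
optimization at least twice.

Because the MLPE slope absorbs scale, categorical class values are
identified only up to transformations that preserve the resistance
*distances*; recovery is therefore assessed by the correlation between
optimized and true resistance distances and by the recovered class order,
not by the raw class values.

## Bootstrap model selection

Each iteration samples floor(0.75 n) localities **without replacement**
(13 of 18 in the reference design), restricts every pre-optimized distance
matrix to the induced pairs, refits the MLPE per model (no re-optimization),
and records AICc ranks and Akaike weights. Aggregates over iterations are
the average rank, the average weight (omega-bar) and the top-model
frequency (pi-hat). AICc ties are broken deterministically — smaller K
first, then lexical model name — so pi-hat sums to exactly 1 and runs are
reproducible bit-for-bit under a fixed seed. The default is 10,000
iterations; the bundled demo and tests use 1,000, which is ample to
separate pi-hat values differing by more than a few percent. Composite
surfaces are built only from surfaces that beat the Euclidean null's pi-hat
and exceed the 1% floor.

## The synthetic-data generator

The generator produces studies with *exactly* the statistical structure the
inference assumes, making every stage testable end to end:

- **Landscapes**: i.i.d. Gaussian noise smoothed by a separable Gaussian
  kernel and thresholded at class-proportion quantiles — spatially
  autocorrelated patches resembling habitat maps. The kernel length scale
  is a constructor argument (default rows/8 cells in scenarios).
- **Localities**: placed only on cells of the reference (lowest-resistance)
  class, with a minimum pairwise separation of 3 cells, mimicking sampling
  restricted to primary-habitat sites and avoiding degenerate
  near-zero-distance pairs.
- **Genetic distances**: true resistance distances from the generating
  surface via the same circuit solver, standardized, then
  y = beta0 + beta1 R̃ + u_i + u_j + e — the exact generative inverse of
  the MLPE fit. Values are *not* clamped to [0, 1]; they are generic
  distances, which keeps the generative model exactly invertible.
- **Genotypes**: the Balding–Nichols model (ancestral frequency
  p ~ U(0.1, 0.9); population frequencies Beta-distributed with
  differentiation theta; binomial diploid draws), whose expected
  Weir–Cockerham estimate is theta — the estimator-validation workhorse.

Scenario defaults — beta0 = 0.2, beta1 = 0.8 per resistance-distance SD,
sigma_u = sigma_e = 0.05, categorical truth 1/50/300 on a 40 × 40 grid of
1 km cells with 18 localities — describe a strong, clean IBR signal with
F_ST-like magnitudes. They were chosen once as a realistic-but-favorable
regime and are deliberately not tuned: the point of the synthetic study is
to verify that the machinery recovers a truth it is theoretically able to
recover.

What passing synthetic tests does **not** show: real microsatellite F_ST
values are noisier than the Gaussian MLPE noise model; real landscapes
violate the stationarity of the smoothed-noise generator; real sampling is
not confined to one habitat class; and genotype-based F_ST is only
asymptotically linear in resistance distance. Synthetic recovery is a
necessary check of correctness, not evidence about any particular
empirical system.

## Numerical choices and degenerate inputs

- Sparse solves use a cached Cholesky factorization per connected
  component; solutions satisfy conservation to ~1e-10.
- The categorical value floor (0.01), the [0, 10] rescale, the min = 1
  re-anchoring and the shape <= 14 bound are all identifiability or
  conditioning gauges, documented above.
- Monomorphic loci, constant rasters, zero-variance predictors,
  disconnected focal pairs, localities on nodata, populations with one
  individual: all are explicit errors, never silent defaults.
- Bootstrap iterations whose MLPE fit fails are dropped and counted; more
  than 1% drops is a hard error.
- Checkpointing in `run_full_pipeline()` is per-stage output files with
  stage-specific derived seeds: deleting a stage's artifacts recomputes
  that stage, and determinism keeps downstream artifacts consistent.

## Problem sizes

The bundled demo and the test suite run 40 × 40 landscapes (1,600-node
graphs) with 18 localities and 1,000 bootstrap iterations; one GA surface
optimization takes seconds at this size. These sizes were chosen to make
the full chain routinely re-runnable during development; the algorithms
scale to larger rasters (sparse factorization) and to the 10,000-iteration
bootstrap default linearly.

## Known limitations

- Categorical class values are identified only up to the resistance-
  distance-preserving gauge discussed above.
- No least-cost-path module and no one-to-all / advanced injection modes;
  one focal cell per locality.
- Composites combine by sum only; the alternative product rule would
  require changing one function.
- The MLPE model is the two-variance-component formulation; variants with
  a free pair-correlation parameter are not implemented.
- No coalescent genotype simulation; Balding–Nichols suffices for
  estimator validation but does not model linkage or mutation processes.
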