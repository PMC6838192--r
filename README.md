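# landres

Landscape resistance optimization and isolation-by-resistance inference for
population-based landscape genetics.

## The problem

Landscape genetics asks which features of a landscape — habitat type,
rivers, roads, terrain, proximity to humans — impede or facilitate gene
flow. The workflow this package implements answers that question for
population-sampled data:

1. **Genetic distance.** Pairwise differentiation between sampling
   localities as multi-locus Weir–Cockerham *F*<sub>ST</sub> (θ):
   per allele and locus, variance components *a* (among populations),
   *b* (among individuals), *c* (within individuals) are accumulated and
   θ = Σa / Σ(a+b+c).
2. **Resistance surfaces.** Each landscape raster becomes a candidate
   resistance surface: categorical layers get one value per class (the
   reference class fixed at 1, free classes in [0.01, 3500]); continuous
   layers are rescaled to [0, 10] and transformed by a Monomolecular
   (`max·(1−e^{−x/shape})`) or Ricker (`max·x·e^{−x/shape}`)
   transformation.
3. **Effective resistance.** The surface is a conductive grid
   (8-neighbor, average-resistance edges, √2-scaled diagonals); the
   predictor for each pair of localities is the two-point effective
   resistance of the weighted graph Laplacian, which integrates all paths
   simultaneously.
4. **MLPE mixed model.** Genetic distance is regressed on
   effective-resistance distance with maximum-likelihood population
   effects: `y_ij = β₀ + β₁·x̃_ij + u_i + u_j + e_ij`, accounting for the
   non-independence of pairs that share a population.
5. **GA optimization.** Free surface parameters are searched by a
   real-coded genetic algorithm maximizing the MLPE log-likelihood.
6. **Bootstrap model selection.** Optimized surfaces (plus the Euclidean
   null) are compared by AICc (effective sample size = number of
   populations) over bootstrap subsamples of 75% of the localities drawn
   without replacement, aggregating average rank, mean Akaike weight ω̄
   and top-model frequency π̂; winning surfaces are combined into jointly
   optimized composites, and the best model's corridor structure is
   visualized as a cumulative current map.

A synthetic-data generator produces complete studies with exactly this
generative structure (autocorrelated landscapes, Balding–Nichols
genotypes, MLPE-structured genetic distances), so the whole chain is
testable without any field data.

## Worked example

Simulate an 18-locality study on a 40 × 40 landscape whose true habitat
resistances are 1 / 50 / 300, then recover the surface:

```r
library(landres)

scen <- synthetic_scenario(seed = 1)      # landscape, localities, truth
d <- gen_genetic_distances(scen)          # genetic + true resistance matrices

# isolation by distance alone
ibd_regression(d$genetic, euclidean_matrix(scen$localities))
#> Isolation-by-distance regression (153 pairs)
#>   slope = 6.657e-05 per m, intercept = -1.001
#>   Pearson r = 0.829, r^2 = 68.7% of variance explained

# GA-optimize the categorical habitat surface against the genetic data
opt <- optimize_surface(scen$landscape,
                        categorical_spec("habitat", c(`0` = 1, `1` = 100, `2` = 100)),
                        d$genetic, scen$localities, ga_config(seed = 7))
opt$spec
#> <resistance_spec> habitat (categorical): 0=1, 1=470.59, 2=2878.7 [0 fixed at 1]
cor(pair_vector(opt$resistance), pair_vector(d$resistance))
#> [1] 0.9999
summary(opt$fit)
#> MLPE fit: beta0 = 0.1286, beta1 = 0.7946
#>   var components: sigma_u^2 = 0.00152, sigma_e^2 = 0.00255 (pair ICC = 0.544)
#>   logLik = 218.330, K = 4, AICc = -425.583 (n = 18 populations, 153 pairs)

# bootstrap selection against the Euclidean null
bootstrap_select(list(habitat = opt$resistance,
                      euclidean = euclidean_matrix(scen$localities)),
                 d$genetic, c(habitat = 4L, euclidean = 2L),
                 n_iterations = 1000, seed = 5)
#> Bootstrap model selection: 1000 iterations, 13 localities per subsample (0 dropped)
#>    surface K avg_rank omega_bar pi_hat
#>    habitat 4    1.066    0.9352  0.934
#>  euclidean 2    1.934    0.0648  0.066
```

The class *order* and the resistance-distance structure are what the data
identify (the MLPE slope absorbs overall scale, so 1/470/2879 and 1/50/300
produce near-identical distance matrices — hence the 0.9999 correlation);
the optimized surface wins π̂ = 0.93 against straight-line distance. The
slope β₁ ≈ 0.79 per predictor SD recovers the generating β₁ = 0.8, and the
variance components recover σ² ≈ 0.05² split across population and pair
levels.

`make_demo()` writes a full study (five landscape layers, localities,
genetic distances) to disk, and `run_full_pipeline()` executes the entire
protocol — IBD, per-surface optimization, Spearman screening, composite
construction, final bootstrap table, current map — with per-stage
checkpointing.

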