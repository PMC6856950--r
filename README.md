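# schic3d

Three-dimensional chromosome structure estimation from single-cell Hi-C
contact matrices, with a bulk-Hi-C population prior, multiscale
quasi-Newton optimization, a study-condition simulator, and shape-space
tools for comparing solution ensembles. Intended for computational
biologists reconstructing chromatin conformations from sparse single-cell
contact maps.

## The model

A chromosome is an ordered curve `X = (x_1, …, x_n)` in 3-space, one point
per genomic bin. Contact counts follow a Poisson power-law link,

    C_ij ~ Poisson(b * ||x_i − x_j||^a),    a < 0 (default −3), b > 0,

and the curve is estimated as the minimizer of the penalized objective

    E(X) = g(X | C~, a, b~)/M + λ1·h1(X) + λ2·h2(X),

where `g` is the Poisson negative log-likelihood, `h1` the variance of the
rescaled adjacent-point gaps (0 iff equally spaced), `h2` the mean cosine
of the interior bend angles (−1 for a straight chain), and the bulk prior
with weight `λ3` is absorbed into the effective data
`C~ = C + (λ3 M/M′) C′`, `b~ = (1 + λ3 M/M′) b`. Optimization is
coarse-to-fine: the contact matrix is recursively merged-binned, the
smallest problem is solved from a random start with full BFGS and the
analytic gradient, and each solution is arc-length-upsampled to initialize
the next scale. Solutions are compared modulo scale, translation, rotation
and reflection via Procrustes-aligned RMSD and clustered in shape space.

## Worked example

Simulate a 100-bin chromosome, sample a sparse single-cell matrix and a
population matrix, and reconstruct:

```r
library(schic3d)

gt   <- generate_ground_truth_ensemble(n = 100, K = 50, variability = 0.2,
                                       seed = 7)
C    <- simulate_contact_matrix(gt$curves[[1]], a = -3, b = 10, seed = 7)
total_contacts(C)   # ~1500 contacts over 4950 bin pairs: sparse
#> [1] 1510
bulk <- sum_bulk(lapply(2:50, function(k)
          simulate_contact_matrix(gt$curves[[k]], a = -3, b = 10,
                                  seed = 7 + k)))

params <- model_params(lambda1 = 0.1, lambda2 = 0.1, lambda3 = 0.5)
fit <- estimate_structure(C, bulk, params = params, min_n = 25, seed = 1,
                          max_iter = 50000)
fit
#> structure_fit: n = 100, energy = -3.07757, scales = (25, 50, 100), seed = 1

truth <- gt$curves[[1]]
rmsd_to_reference(fit$curve, truth) / radius_of_gyration(truth)
#> [1] 0.4764313

no_prior <- estimate_structure(C, params = model_params(
              lambda1 = 0.1, lambda2 = 0.1, lambda3 = 0),
              min_n = 25, seed = 1, max_iter = 50000)
rmsd_to_reference(no_prior$curve, truth) / radius_of_gyration(truth)
#> [1] 0.5251398
```

The printed energy is the posterior objective at full resolution (lower is
better; comparable only across runs on the same matrix). The RMSD ratios
say the reconstruction deviates from the ground truth by ~48% of the
truth's radius of gyration after optimal similarity alignment, improving
on ~53% without the population prior — a matrix this sparse (about 0.3
contacts per bin pair) only constrains the large-scale fold, which is
exactly the regime the bulk prior is for; dense matrices recover the truth
to a few percent (see `run_dense_recovery()`). The scripted
experiments (`run_dense_recovery()`, `run_prior_sweep()`,
`run_multiscale_comparison()`) reproduce the package's three simulation
studies; `inst/cli/schic3d-cli` exposes `estimate`, `simulate`, `analyze`
and `reproduce` subcommands for shell use.

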