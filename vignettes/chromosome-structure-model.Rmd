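---
title: "Penalized Poisson modelling of single-cell Hi-C for 3D chromosome structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized Poisson modelling of single-cell Hi-C for 3D chromosome structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schic3d)
```

## The model

A chromosome is represented as an ordered curve $X = (x_1, \dots, x_n)$,
$x_i \in \mathbb{R}^3$, where $x_i$ is the spatial center of mass of the
$i$-th genomic bin. A single-cell Hi-C experiment yields a symmetric
$n \times n$ matrix $C$ of contact counts between bins. Counts are modelled
as independent Poisson draws whose means follow a power law in the pairwise
spatial distance,

$$C_{ij} \sim \mathrm{Poisson}\!\left(b\,\|x_i - x_j\|^{a}\right), \qquad
a < 0,\; b > 0,$$

so that loci close in space contact often. Polymer-physics arguments give
$a = -3$, which is the package default. The scale $b$ is non-identifiable
against the overall size of $X$ (rescaling $X$ by $\gamma$ is equivalent to
replacing $b$ by $\gamma^a b$), and since structures are only identified up
to scale we fix $b = 1$ during estimation. Dropping terms constant in $X$,
the negative log-likelihood is

$$g(X \mid C, a, b) = -\sum_{i<j}\left(a\,c_{ij}\log\|x_i - x_j\|
  - b\,\|x_i - x_j\|^{a}\right).$$

Note that zero-count pairs still contribute the repulsion term
$b\,d_{ij}^{a}$: absence of contacts is evidence of separation.

Single-cell matrices are extremely sparse, and the unpenalized maximum
likelihood estimate is then unstable or biologically absurd. Two geometric
penalties and one data-driven prior regularize it:

* **Uniform spacing** $h_1$: rescale the adjacent-point gaps so that the
  curve has length $n - 1$ (the rescaled gaps $u_i$ then average exactly 1)
  and take their variance, computed here with divisor $n-1$, the number of
  gaps. $h_1 \ge 0$, with 0 exactly at equal spacing, for every $n$.
* **Smoothness** $h_2$: the mean cosine of the interior bend angles,
  $\frac{1}{n-2}\sum_{i=2}^{n-1}\cos\theta_i$. A straight monotone chain
  attains the minimum $-1$; a hairpin fold-back contributes $+1$.
* **Bulk prior** $h_3$: the scaled negative log-likelihood of a bulk
  (population) Hi-C matrix $C'$, weight $\lambda_3$. Algebraically this is
  absorbed into the data: with $k = \lambda_3 M / M'$ (where $M$, $M'$ are
  the total upper-triangular counts) the objective equals the prior-free
  objective on $\tilde C = C + k C'$ and $\tilde b = (1+k)b$. The prior
  therefore costs nothing at optimization time, and a small $\lambda_3$
  replaces structural zeros of a sparse $C$ with small biologically
  plausible values.

The working objective is

$$E(X) = \frac{1}{M} g(X \mid \tilde C, a, \tilde b)
  + \lambda_1 h_1(X) + \lambda_2 h_2(X),$$

minimized over $X \in \mathbb{R}^{n\times 3}$. Both penalties and the
normalized likelihood are per-pair/per-gap averages, so the same
$\lambda$ vector is meaningful across problem sizes — and is therefore
also applied unchanged at every scale of the multiscale pipeline below.
The defaults $\lambda = (0.5, 1, 0.1)$ are a sensible operating point for
real sparse data; the simulation experiments use the values appropriate to
each regime (small $\lambda_1 = \lambda_2 = 0.001$ when data are dense,
$0.1$ when sparse).

## Optimization

$E$ is smooth but non-convex with many local optima. The gradient is
analytic: the likelihood differentiates by the chain rule over pairwise
distances, the spacing penalty by the quotient rule over gap lengths, and
the bend cosines by normalized-dot-product differentiation. The reference
implementations live in `energy()` and `energy_gradient()`; the optimizer
calls a fused compiled kernel that is tested to agree with them to
machine precision, and the gradient itself is validated against central
finite differences (max relative error below $10^{-5}$ at $n = 50$).

Minimization uses full BFGS (`stats::optim`). The objective is strongly
ill-conditioned — counts span many orders of magnitude — and in our
experience limited-memory variants stall on it, while the dense Hessian
approximation of full BFGS converges reliably; at $3n$ parameters for a
single chromosome the dense approximation is cheap. Convergence is declared
at a relative energy change below $10^{-14}$ (or 10,000 iterations); the
tight tolerance matters, because the energy basin flattens long before the
geometry has finished untangling.

**Multiscale scheme.** `estimate_structure()` repeatedly merges adjacent
bin pairs of the contact matrix (summing the four mapped entries; counts
landing on the coarse diagonal are dropped, and the bulk matrix is merged
with the identical bin map) until the size falls to `min_n` (default 64).
The smallest problem is initialized from standard normal coordinates and
solved; each solution is upsampled — points placed at uniform arc-length
along the piecewise-linear coarse solution — to initialize the next finer
scale. Coarse stages position the global fold cheaply, so the pipeline is
faster than a flat full-resolution run and reaches lower energies on
average. The choice of `min_n` trades run time against the diversity of
reachable solutions: a very small coarsest scale can have essentially one
solution, collapsing the ensemble across seeds.

Numerical guards: every pairwise distance is clamped at $10^{-10}$ inside
logarithms, negative powers and normalizations (coincident points otherwise
produce infinities; random initializations can place points arbitrarily
close), with a warning. A degenerate (zero-length) curve is an error for
$h_1$, as is an empty contact matrix ($M = 0$) at full resolution. Curves
are returned centered at the origin; scale is left as produced, since $b$
fixes it arbitrarily.

On upsampling and $h_1$: points at equal arc-length spacing along a
*bent* polyline have slightly unequal chord lengths (a chord crossing a
vertex is shorter than its arc step), so upsampled curves have small but
not exactly zero $h_1$ except on straight segments. This is invisible in
practice because upsampled curves only serve as initializations.

## Shape-space comparison

Structures are equivalence classes modulo scale, translation, rotation and
reflection, so comparisons use orthogonal Procrustes alignment over the
full orthogonal group with optimal scaling (via `vegan::procrustes`),
followed by RMSD, the root *mean* square distance per point. Against a
ground truth, the solution is scaled onto the truth. For ensemble
comparisons one-sided scaling would break symmetry, so both curves are
first rescaled to unit centered Frobenius norm (`pairwise_rmsd()`), giving
a symmetric premetric; the triangle inequality is not guaranteed and not
asserted. RMSD values are reported relative to the reference curve's
radius of gyration where a scale-free number is needed. Ensembles are
clustered by average-linkage agglomerative clustering on the pairwise RMSD
matrix (`cluster_solutions()`); linkage is configurable, and average
linkage is simply a robust default for the blocky matrices these ensembles
produce.

## The simulator

No real single-cell Hi-C data ship with the package; the simulator
generates the study conditions instead. `generate_ground_truth_ensemble()`
draws a smooth mean curve — each coordinate a sum of 3–6 low-frequency
random-phase sinusoids along the bin index, rescaled to unit mean gap —
and $K$ per-cell variants obtained by adding a smooth low-frequency
perturbation field scaled by `variability` times the mean curve's radius
of gyration (default 0.2). Coherent low-frequency deformation, rather than
i.i.d. per-node jitter, is what "cell-to-cell shape variability" means
physically: cells share a fold and differ in its large-scale geometry.
Per-cell seed substreams make curve $k$ independent of $K$.
`simulate_contact_matrix()` then draws the Poisson counts; $b = 10^6$
yields the dense regime, $b = 10$ the sparse single-cell regime, and bulk
matrices are leave-one-out sums over the ensemble
(`sum_bulk(..., exclude_index = k)`), so a cell's own data never enter its
prior.

What the simulator does *not* emulate: genomic distance-dependent coverage
biases, unmappable regions, translocations, homolog mixing, or any
polymer-physics excluded-volume constraint. Passing tests therefore
demonstrate correctness of the estimator under its own generative model,
not robustness to the artefacts of real Hi-C.

## The simulation experiments

Three scripted experiments probe the estimator; sizes are chosen to run on
a single CPU in minutes and are stated with each function.

* `run_dense_recovery()` ($n = 100$, $b = 10^6$,
  $\lambda_1 = \lambda_2 = 10^{-3}$, $\lambda_3 = 0$, 20 random
  initializations): with dense data the best-of-ensemble solution aligns
  to the truth within a few percent of its radius of gyration. Local
  optima differing by reflections of substructures can have nearly
  identical energies but large RMSD, which is why RMSD and energy orderings
  correlate only loosely — and why reconstruction quality must be judged in
  shape space, not by energy alone.
* `run_prior_sweep()` ($b = 10$, $\lambda_1 = \lambda_2 = 0.1$, leave-one-
  out bulk from $K$ cells): mean RMSD to truth as a function of
  $\lambda_3$ drops as soon as the prior is switched on, with an interior
  optimum; more bulk cells help more.
* `run_multiscale_comparison()` ($n = 128$, paired seeds): the mean paired
  difference energy(flat) − energy(multiscale) is positive.

## Limitations

* The Poisson link is the only likelihood; overdispersed or zero-inflated
  alternatives are out of scope, as is estimating $a$ or $b$ from data.
* Curves with different bin counts cannot be compared (no resampling).
* The optimizer is deterministic given a seed but, like any non-convex
  local method, returns one local solution; ensembles over seeds are the
  intended usage.
* Matrices are modelled one chromosome at a time; inter-chromosomal
  contacts are ignored.
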