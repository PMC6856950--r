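#' Generate a ground-truth ensemble of smooth chromosome-like curves
#'
#' Builds a smooth mean curve and `K` per-cell variants of it, emulating
#' cell-to-cell chromatin shape variability around a common underlying
#' conformation. Each coordinate of the mean curve is a sum of a few
#' low-frequency random-phase sinusoids along the bin index, rescaled so the
#' mean gap length is 1; this yields smooth, non-self-intersecting open
#' curves. Per-cell deviations are themselves smooth low-frequency sinusoid
#' fields (coherent shape changes rather than independent per-node jitter)
#' whose amplitude is `variability` times the mean curve's radius of
#' gyration.
#'
#' Cell `k` is drawn from its own seed substream derived from the master
#' seed, so curve `k` is identical regardless of `K`.
#'
#' @param n number of bins per curve (>= 10); default 100.
#' @param K number of cells (>= 1).
#' @param variability non-negative fraction of the mean curve's radius of
#'   gyration governing per-cell deviation; 0 makes every curve equal to the
#'   mean. Default 0.2.
#' @param seed master integer seed.
#' @return a list of class `"ground_truth_ensemble"` with fields `curves`
#'   (list of K n x 3 matrices), `mean_curve`, `n`, `K`, `variability`,
#'   `seed`.
#' @export
#' @examples
#' gt <- generate_ground_truth_ensemble(n = 50, K = 3, variability = 0.2,
#'                                      seed = 7)
#' penalty_smoothness(gt$mean_curve)  # well below 0: predominantly straight
generate_ground_truth_ensemble <- function(n = 100, K = 1,
                                           variability = 0.2, seed = 1) {
  if (n < 10) stop("n must be at least 10")
  if (K < 1) stop("K must be at least 1")
  if (variability < 0) stop("variability must be non-negative")
  mean_curve <- withr::with_seed(as.integer(seed), random_smooth_curve(n))
  rg <- radius_of_gyration(mean_curve)
  curves <- lapply(seq_len(K), function(k) {
    if (variability == 0) return(mean_curve)
    sub_seed <- cell_seed(seed, k)
    withr::with_seed(sub_seed, {
      mean_curve + variability * rg * random_smooth_field(n)
    })
  })
  structure(list(curves = curves, mean_curve = mean_curve, n = n, K = K,
                 variability = variability, seed = as.integer(seed)),
            class = "ground_truth_ensemble")
}

# Deterministic per-cell substream seed, kept within 32-bit integer range.
cell_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647)
}

# Smooth open curve: 3-6 low-frequency sinusoids per coordinate over the
# bin index, rescaled to unit mean gap.
random_smooth_curve <- function(n) {
  t <- seq(0, 1, length.out = n)
  n_modes <- sample(3:6, 1)
  X <- vapply(1:3, function(j) {
    freqs <- stats::runif(n_modes, 0.5, 3)
    phases <- stats::runif(n_modes, 0, 2 * pi)
    amps <- stats::runif(n_modes, 0.5, 1) / freqs
    rowSums(vapply(seq_len(n_modes), function(m) {
      amps[m] * sin(2 * pi * freqs[m] * t + phases[m])
    }, numeric(n)))
  }, numeric(n))
  X / mean(gap_lengths(X))
}

# Smooth zero-mean perturbation field with unit-order amplitude.
random_smooth_field <- function(n) {
  t <- seq(0, 1, length.out = n)
  P <- vapply(1:3, function(j) {
    freqs <- stats::runif(3, 0.5, 2.5)
    phases <- stats::runif(3, 0, 2 * pi)
    amps <- stats::rnorm(3, 0, 1) / sqrt(3)
    rowSums(vapply(1:3, function(m) {
      amps[m] * sin(2 * pi * freqs[m] * t + phases[m])
    }, numeric(n)))
  }, numeric(n))
  sweep(P, 2, colMeans(P))
}

#' Simulate a single-cell Hi-C contact matrix from a curve
#'
#' Draws independent Poisson counts `C_ij ~ Poisson(b * d_ij^a)` for every
#' pair `j > i`, mirrors them to the lower triangle, and zeroes the
#' diagonal. Large `b` (e.g. 1e6) produces a dense matrix; small `b` (e.g.
#' 10) the extreme sparsity typical of single-cell Hi-C.
#'
#' @param X n x 3 coordinate matrix with no coincident points.
#' @param a negative power-law exponent; default -3.
#' @param b positive Poisson scale.
#' @param seed integer seed; draws are deterministic given the seed.
#' @return a `contact_matrix` of integer counts.
#' @export
simulate_contact_matrix <- function(X, a = -3, b = 1, seed = 1) {
  X <- as_curve(X)
  if (a >= 0) stop("a must be negative")
  if (b <= 0) stop("b must be positive")
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  if (any(D[upper.tri(D)] < .DIST_EPS)) {
    stop("coincident points give an infinite Poisson mean")
  }
  ut <- upper.tri(D)
  mu <- b * D[ut]^a
  counts <- withr::with_seed(as.integer(seed),
                             stats::rpois(length(mu), mu))
  C <- matrix(0, n, n)
  C[ut] <- counts
  C <- C + t(C)
  contact_matrix(C, warn_diagonal = FALSE)
}
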