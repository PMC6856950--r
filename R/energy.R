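#' Model parameters for the Poisson distance-contact model
#'
#' Bundles the fixed model parameters: the power-law exponent `a` linking
#' spatial distance to expected contact count (polymer-physics arguments give
#' `a = -3`), the Poisson rate scale `b` (arbitrary up to curve scale, so 1
#' by default for estimation), and the non-negative penalty weights
#' `lambda1` (uniform spacing), `lambda2` (smoothness) and `lambda3` (bulk
#' prior).
#'
#' @param a power-law exponent, must be negative. Default -3.
#' @param b Poisson scale, must be positive. Default 1.
#' @param lambda1,lambda2,lambda3 non-negative penalty weights.
#'   Defaults (0.5, 1, 0.1).
#' @return a list of class `"model_params"`.
#' @export
model_params <- function(a = -3, b = 1,
                         lambda1 = 0.5, lambda2 = 1, lambda3 = 0.1) {
  if (!is.numeric(a) || length(a) != 1 || a >= 0) {
    stop("a must be a single negative number")
  }
  if (!is.numeric(b) || length(b) != 1 || b <= 0) {
    stop("b must be a single positive number")
  }
  lam <- c(lambda1, lambda2, lambda3)
  if (any(!is.finite(lam)) || any(lam < 0)) {
    stop("penalty weights must be finite and non-negative")
  }
  structure(list(a = a, b = b, lambda1 = lambda1, lambda2 = lambda2,
                 lambda3 = lambda3),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("model_params: a = %g, b = %g, lambda = (%g, %g, %g)\n",
              x$a, x$b, x$lambda1, x$lambda2, x$lambda3))
  invisible(x)
}

# Pairwise distances with coincident-point guard. Distances below `eps`
# diverge inside log() and negative powers, so they are clamped with a
# single warning per evaluation.
.DIST_EPS <- 1e-10

pairwise_distances <- function(X, warn = TRUE) {
  D <- as.matrix(stats::dist(X))
  off <- D[upper.tri(D)]
  if (any(off < .DIST_EPS)) {
    if (warn) warning("near-coincident points: distances clamped at ",
                      .DIST_EPS)
    D[D < .DIST_EPS] <- .DIST_EPS
  }
  D
}

#' Poisson negative log-likelihood of a contact matrix given a curve
#'
#' Under the model `C_ij ~ Poisson(b * d_ij^a)` with `d_ij` the distance
#' between points i and j, the negative log-likelihood (dropping terms
#' constant in the curve) is
#' `g = -sum_{i<j} ( a * c_ij * log(d_ij) - b * d_ij^a )`.
#' Pairs with zero count still contribute the repulsion term `b * d_ij^a`.
#' Real-valued counts are accepted so the same code evaluates `g` on
#' prior-absorbed effective matrices.
#'
#' @param X n x 3 coordinate matrix.
#' @param C symmetric non-negative matrix of (possibly real-valued) counts.
#' @param a negative power-law exponent.
#' @param b positive Poisson scale.
#' @return a finite number.
#' @export
#' @examples
#' X <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
#' C <- contact_matrix(rbind(c(0, 2, 1), c(2, 0, 0), c(1, 0, 0)))
#' neg_loglik(X, C, a = -1, b = 1)  # 2.5 + log(2)
neg_loglik <- function(X, C, a, b) {
  X <- as_curve(X)
  C <- as_contact_matrix(C)
  if (nrow(C) != nrow(X)) stop("curve and contact matrix sizes differ")
  if (a >= 0) stop("a must be negative")
  if (b <= 0) stop("b must be positive")
  D <- pairwise_distances(X)
  ut <- upper.tri(D)
  d <- D[ut]
  cc <- unclass(C)[ut]
  -sum(a * cc * log(d) - b * d^a)
}

#' Uniform-spacing penalty
#'
#' Rescale the gaps so the curve has total length `n - 1` (the rescaled gaps
#' `u_i` then average exactly 1) and return their variance, computed as the
#' mean of `(u_i - 1)^2` over the `n - 1` gaps. The penalty is 0 exactly when
#' all adjacent points are equally spaced, and is invariant to scale,
#' translation, rotation and reflection.
#'
#' @param X n x 3 coordinate matrix, n >= 2, with positive total length.
#' @return a non-negative number.
#' @export
penalty_spacing <- function(X) {
  g <- gap_lengths(X)
  L <- sum(g)
  if (L <= 0) stop("degenerate curve: total length is zero")
  u <- (length(g)) * g / L
  mean((u - 1)^2)
}

#' Smoothness penalty
#'
#' Mean cosine of the interior bend angles: for each interior point the
#' cosine of the angle between the back vector `x_{i-1} - x_i` and the
#' forward vector `x_{i+1} - x_i`. A straight monotone chain has all angles
#' pi, giving the minimum -1; an immediate fold-back gives +1. Invariant to
#' scale, translation, rotation and reflection.
#'
#' @param X n x 3 coordinate matrix, n >= 3.
#' @return a number in `[-1, 1]`.
#' @export
penalty_smoothness <- function(X) {
  X <- as_curve(X)
  n <- nrow(X)
  if (n < 3) stop("smoothness penalty needs at least 3 points")
  d <- diff(X)                       # row i: x_{i+1} - x_i
  g <- sqrt(rowSums(d^2))
  if (any(g < .DIST_EPS)) {
    warning("zero-length gap: clamped at ", .DIST_EPS)
    g[g < .DIST_EPS] <- .DIST_EPS
  }
  # cos(theta_i) for i = 2..n-1: back vector is -d[i-1, ], forward is d[i, ]
  num <- -rowSums(d[-(n - 1), , drop = FALSE] * d[-1, , drop = FALSE])
  mean(num / (g[-(n - 1)] * g[-1]))
}

#' Absorb a bulk Hi-C prior into the data
#'
#' The bulk-prior penalty is algebraically equivalent to replacing the data
#' with the effective matrix `C~ = C + k * C'` and scale `b~ = (1 + k) * b`,
#' where `k = lambda3 * M / M'` mixes the bulk matrix in proportion to the
#' information content of the single-cell data. With `lambda3 = 0` the data
#' are returned unchanged.
#'
#' @param C single-cell contact matrix.
#' @param C_bulk bulk contact matrix of the same dimension (may be `NULL`
#'   when `lambda3 = 0`).
#' @param lambda3 non-negative prior weight.
#' @param b positive Poisson scale.
#' @return a list of class `"effective_data"` with fields `C_tilde`,
#'   `b_tilde`, `k`, and `M` (the single-cell total count).
#' @export
effective_data <- function(C, C_bulk = NULL, lambda3 = 0, b = 1) {
  C <- as_contact_matrix(C)
  if (lambda3 < 0) stop("lambda3 must be non-negative")
  if (b <= 0) stop("b must be positive")
  M <- total_contacts(C)
  if (lambda3 == 0 || is.null(C_bulk)) {
    if (lambda3 > 0) stop("lambda3 > 0 requires a bulk matrix")
    out <- list(C_tilde = C, b_tilde = b, k = 0, M = M)
  } else {
    C_bulk <- as_contact_matrix(C_bulk)
    if (nrow(C_bulk) != nrow(C)) {
      stop("bulk matrix dimension does not match the single-cell matrix")
    }
    Mp <- total_contacts(C_bulk)
    if (Mp <= 0) stop("bulk matrix is empty (M' = 0) but lambda3 > 0")
    k <- lambda3 * M / Mp
    out <- list(
      C_tilde = contact_matrix(unclass(C) + k * unclass(C_bulk),
                               warn_diagonal = FALSE),
      b_tilde = (1 + k) * b,
      k = k, M = M)
  }
  class(out) <- "effective_data"
  out
}

#' Posterior energy of a curve
#'
#' The working objective minimized during structure estimation:
#' `E = g(X | C~, a, b~) / M + lambda1 * h1(X) + lambda2 * h2(X)`,
#' where `g` is the Poisson negative log-likelihood on the prior-absorbed
#' effective data, `h1` the uniform-spacing penalty and `h2` the smoothness
#' penalty. The bulk prior enters only through the effective data, so its
#' weight adds essentially nothing to the evaluation cost.
#'
#' @param X n x 3 coordinate matrix.
#' @param eff `effective_data` object (or a plain contact matrix, treated as
#'   prior-free data).
#' @param M total single-cell contact count; defaults to the count recorded
#'   in `eff`. Must be positive.
#' @param params `model_params` object.
#' @return a finite number.
#' @export
energy <- function(X, eff, M = NULL, params = model_params()) {
  if (!inherits(eff, "effective_data")) {
    eff <- effective_data(eff, lambda3 = 0, b = params$b)
  }
  if (is.null(M)) M <- eff$M
  if (M <= 0) stop("empty single-cell matrix: M must be positive")
  neg_loglik(X, eff$C_tilde, params$a, eff$b_tilde) / M +
    params$lambda1 * penalty_spacing(X) +
    params$lambda2 * penalty_smoothness(X)
}

#' Analytic gradient of the posterior energy
#'
#' Returns the n x 3 gradient `(1/M) grad g + lambda1 grad h1 +
#' lambda2 grad h2`, each component differentiated analytically (chain rule
#' over pairwise distances for the likelihood, quotient rule over gap
#' lengths for the spacing penalty, normalized-dot-product differentiation
#' for the bend cosines). Matches central finite differences to high
#' relative accuracy; feeding it to a quasi-Newton optimizer is what keeps
#' estimation tractable at the bin counts seen in real data.
#'
#' @inheritParams energy
#' @return an n x 3 numeric matrix.
#' @export
energy_gradient <- function(X, eff, M = NULL, params = model_params()) {
  if (!inherits(eff, "effective_data")) {
    eff <- effective_data(eff, lambda3 = 0, b = params$b)
  }
  if (is.null(M)) M <- eff$M
  if (M <= 0) stop("empty single-cell matrix: M must be positive")
  X <- as_curve(X)
  grad_neg_loglik(X, eff$C_tilde, params$a, eff$b_tilde) / M +
    params$lambda1 * grad_penalty_spacing(X) +
    params$lambda2 * grad_penalty_smoothness(X)
}

# d g / d x_i = sum_{j != i} a * (b * d_ij^(a-2) - c_ij * d_ij^(-2)) (x_i - x_j)
grad_neg_loglik <- function(X, C, a, b) {
  D <- pairwise_distances(X, warn = FALSE)
  diag(D) <- Inf                     # removes self-terms from the weights
  W <- a * (b * D^(a - 2) - unclass(as.matrix(C)) / D^2)
  unname(rowSums(W) * X - W %*% X)
}

# h1 = (1/(n-1)) sum_i (s g_i / L - 1)^2 with s = n - 1, L = sum g_i.
# d h1 / d g_k = (2 s / L^2) (g_k - Q / L), Q = sum g_i^2; the coordinate
# gradient distributes this along the unit gap vectors.
grad_penalty_spacing <- function(X) {
  n <- nrow(X)
  d <- diff(X)
  g <- sqrt(rowSums(d^2))
  L <- sum(g)
  if (L <= 0) stop("degenerate curve: total length is zero")
  s <- n - 1
  coef <- (2 * s / L^2) * (g - sum(g^2) / L)    # d h1 / d g_k
  gs <- pmax(g, .DIST_EPS)
  E <- d / gs                                    # unit gap vectors
  grad <- matrix(0, n, 3)
  grad[-1, ] <- grad[-1, ] + coef * E
  grad[-n, ] <- grad[-n, ] - coef * E
  grad
}

# h2 term i has v = x_{i-1} - x_i, w = x_{i+1} - x_i, c = v.w/(|v||w|);
# dc/dv = w/(|v||w|) - c v/|v|^2 and symmetrically for w.
grad_penalty_smoothness <- function(X) {
  n <- nrow(X)
  if (n < 3) stop("smoothness penalty needs at least 3 points")
  d <- diff(X)
  g <- pmax(sqrt(rowSums(d^2)), .DIST_EPS)
  v <- -d[-(n - 1), , drop = FALSE]   # rows i = 2..n-1
  w <- d[-1, , drop = FALSE]
  gv <- g[-(n - 1)]
  gw <- g[-1]
  cosq <- rowSums(v * w) / (gv * gw)
  dv <- w / (gv * gw) - cosq * v / gv^2
  dw <- v / (gv * gw) - cosq * w / gw^2
  grad <- matrix(0, n, 3)
  idx <- 2:(n - 1)
  grad[idx - 1, ] <- grad[idx - 1, ] + dv
  grad[idx + 1, ] <- grad[idx + 1, ] + dw
  grad[idx, ] <- grad[idx, ] - (dv + dw)
  grad / (n - 2)
}
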