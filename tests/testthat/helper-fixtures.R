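# Shared fixtures and independent oracles for the test suite.

# Straight-line curve with arbitrary (possibly unequal) gaps.
collinear_curve <- function(gaps, direction = c(1, 0, 0), origin = c(0, 0, 0)) {
  direction <- direction / sqrt(sum(direction^2))
  pos <- c(0, cumsum(gaps))
  sweep(outer(pos, direction), 2, origin, `+`)
}

# Random curve with all gaps equal to `gap` but random directions.
equal_gap_curve <- function(n, gap = 1) {
  steps <- matrix(stats::rnorm((n - 1) * 3), n - 1, 3)
  steps <- gap * steps / sqrt(rowSums(steps^2))
  rbind(c(0, 0, 0), apply(steps, 2, cumsum))
}

# Random similarity transform: positive scale, orthogonal matrix (rotation
# or reflection), translation.
random_similarity <- function(reflect = FALSE) {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (reflect && det(R) > 0) R[, 1] <- -R[, 1]
  if (!reflect && det(R) < 0) R[, 1] <- -R[, 1]
  list(scale = stats::runif(1, 0.3, 3), R = R,
       shift = stats::rnorm(3, sd = 5))
}

apply_similarity <- function(X, tr) {
  sweep(tr$scale * X %*% tr$R, 2, tr$shift, `+`)
}

# Independent slow oracle for the Poisson negative log-likelihood:
# term-by-term double loop, no shared code with the implementation.
neg_loglik_oracle <- function(X, C, a, b) {
  n <- nrow(X)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((X[i, ] - X[j, ])^2))
      total <- total - (a * C[i, j] * log(d) - b * d^a)
    }
  }
  total
}

# Central finite-difference gradient of a scalar function of a curve.
fd_gradient <- function(f, X, h = 1e-6) {
  G <- matrix(0, nrow(X), 3)
  for (i in seq_len(nrow(X))) {
    for (j in 1:3) {
      Xp <- X; Xp[i, j] <- Xp[i, j] + h
      Xm <- X; Xm[i, j] <- Xm[i, j] - h
      G[i, j] <- (f(Xp) - f(Xm)) / (2 * h)
    }
  }
  G
}

# Closed-form orthogonal Procrustes oracle (SVD over the full orthogonal
# group, one-sided scaling of X onto Y), independent of vegan.
procrustes_rmsd_oracle <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Yc, Xc))
  R <- sv$v %*% t(sv$u)
  s <- sum(sv$d) / sum(Xc^2)
  sqrt(mean(rowSums((s * Xc %*% R - Yc)^2)))
}

# Small deterministic test matrix with a known upper triangle.
fixture_contact_matrix <- function(n, seed = 99, density_b = 20) {
  schic3d::simulate_contact_matrix(schic3d::make_test_helix(n),
                                   a = -3, b = density_b, seed = seed)
}
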