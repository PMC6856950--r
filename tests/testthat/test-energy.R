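test_that("negative log-likelihood matches hand-computed and oracle values", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  C <- contact_matrix(rbind(c(0, 2, 1), c(2, 0, 0), c(1, 0, 0)))
  # a = -1, b = 1: pairs (1,2): d=1, c=2 -> 1; (1,3): d=2, c=1 -> log2 + 1/2;
  # (2,3): d=1, c=0 -> 1. Total 2.5 + log 2.
  expect_equal(neg_loglik(X, C, a = -1, b = 1), 2.5 + log(2))

  # zero counts: pure repulsion sum of d^a
  C0 <- contact_matrix(matrix(0, 3, 3))
  expect_equal(neg_loglik(X, C0, a = -3, b = 1), 1 + 1 / 8 + 1)

  # random instance against the independent double-loop oracle
  set.seed(5)
  Xr <- matrix(rnorm(36), 12, 3)
  Cr <- fixture_contact_matrix(12)
  expect_equal(neg_loglik(Xr, Cr, a = -3, b = 2),
               neg_loglik_oracle(Xr, Cr, a = -3, b = 2))
})

test_that("likelihood scale identity: rescaling X is equivalent to rescaling b", {
  set.seed(7)
  X <- matrix(rnorm(60), 20, 3)
  C <- fixture_contact_matrix(20)
  M <- total_contacts(C)
  a <- -3
  for (gam in c(0.5, 2, 3.7)) {
    diff <- neg_loglik(gam * X, C, a, 1) - neg_loglik(X, C, a, gam^a * 1)
    expect_equal(diff, -a * M * log(gam), tolerance = 1e-10)
  }
})

test_that("neg_loglik validates its inputs", {
  X <- matrix(rnorm(9), 3, 3)
  bad <- matrix(c(0, 1, 0, 2, 0, 0, 0, 0, 0), 3, 3)
  expect_error(neg_loglik(X, bad, -3, 1), "symmetric")
  C <- contact_matrix(matrix(0, 3, 3))
  expect_error(neg_loglik(X, C, a = 1, b = 1), "negative")
  expect_error(neg_loglik(X, C, a = -3, b = 0), "positive")
  # coincident points are clamped with a warning, not an error
  Xd <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_warning(neg_loglik(Xd, C, -3, 1), "clamped")
})

test_that("spacing penalty is zero iff gaps are equal, with hand value", {
  expect_equal(penalty_spacing(rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))),
               1 / 9)
  set.seed(11)
  for (rep in 1:5) {
    X <- equal_gap_curve(sample(5:40, 1), gap = runif(1, 0.2, 4))
    expect_equal(penalty_spacing(X), 0, tolerance = 1e-12)
  }
  expect_gt(penalty_spacing(rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))), 0)
  expect_error(penalty_spacing(matrix(1, 4, 3)), "zero")
})

test_that("smoothness penalty hits its extremes and stays within [-1, 1]", {
  set.seed(13)
  line <- collinear_curve(runif(9, 0.1, 3))
  expect_equal(penalty_smoothness(line), -1)
  # right angle at the middle point: single zero cosine
  expect_equal(penalty_smoothness(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))),
               0)
  # immediate fold-back: cosine +1
  fold <- rbind(c(0, 0, 0), c(1, 0, 0), c(1e-9, 1e-12, 0))
  expect_equal(penalty_smoothness(fold), 1, tolerance = 1e-6)
  for (rep in 1:10) {
    X <- matrix(rnorm(45), 15, 3)
    h2 <- penalty_smoothness(X)
    expect_gte(h2, -1)
    expect_lte(h2, 1)
  }
})

test_that("penalties are invariant under similarity transforms incl. reflection", {
  set.seed(17)
  for (rep in 1:10) {
    X <- matrix(rnorm(60), 20, 3)
    tr <- random_similarity(reflect = rep %% 2 == 0)
    Xt <- apply_similarity(X, tr)
    expect_equal(penalty_spacing(Xt), penalty_spacing(X), tolerance = 1e-10)
    expect_equal(penalty_smoothness(Xt), penalty_smoothness(X),
                 tolerance = 1e-10)
  }
})

test_that("bulk prior is absorbed exactly into the effective data", {
  C_small <- contact_matrix(rbind(c(0, 4, 6), c(4, 0, 0), c(6, 0, 0)))
  C_bulk <- contact_matrix(rbind(c(0, 60, 20), c(60, 0, 20), c(20, 20, 0)))
  # hand values: M = 10, M' = 100, lambda3 = 0.1 -> k = 0.01
  eff <- effective_data(C_small, C_bulk, lambda3 = 0.1, b = 1)
  expect_equal(eff$k, 0.01)
  expect_equal(eff$b_tilde, 1.01)
  expect_equal(unclass(eff$C_tilde),
               unclass(C_small) + 0.01 * unclass(C_bulk))

  # lambda3 = 0 returns the data unchanged
  eff0 <- effective_data(C_small, C_bulk, lambda3 = 0, b = 2)
  expect_identical(unclass(eff0$C_tilde), unclass(C_small))
  expect_equal(eff0$b_tilde, 2)

  expect_error(effective_data(C_small, contact_matrix(matrix(0, 3, 3)),
                              lambda3 = 0.5, b = 1), "empty")
  expect_error(effective_data(C_small, fixture_contact_matrix(5),
                              lambda3 = 0.5, b = 1), "dimension")
})

test_that("bulk-absorption identity holds on random instances", {
  set.seed(19)
  for (rep in 1:100) {
    n <- sample(5:15, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    C <- simulate_contact_matrix(make_test_helix(n), a = -3, b = 30,
                                 seed = rep)
    Cb <- simulate_contact_matrix(make_test_helix(n, turns = 2), a = -3,
                                  b = 200, seed = rep + 5000)
    M <- total_contacts(C)
    Mp <- total_contacts(Cb)
    if (M == 0 || Mp == 0) next
    lambda3 <- runif(1, 0.01, 2)
    a <- -3; b <- runif(1, 0.5, 2)
    eff <- effective_data(C, Cb, lambda3 = lambda3, b = b)
    lhs <- neg_loglik(X, C, a, b) / M + lambda3 * neg_loglik(X, Cb, a, b) / Mp
    rhs <- neg_loglik(X, eff$C_tilde, a, eff$b_tilde) / M
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("energy composes its terms and is monotone in the penalty weights", {
  set.seed(23)
  X <- matrix(rnorm(30), 10, 3)
  C <- fixture_contact_matrix(10)
  M <- total_contacts(C)
  p0 <- model_params(a = -3, b = 1, lambda1 = 0, lambda2 = 0, lambda3 = 0)
  expect_equal(energy(X, C, params = p0), neg_loglik(X, C, -3, 1) / M)

  h1 <- penalty_spacing(X)
  h2 <- penalty_smoothness(X)
  p1 <- model_params(a = -3, b = 1, lambda1 = 2, lambda2 = 3, lambda3 = 0)
  expect_equal(energy(X, C, params = p1),
               neg_loglik(X, C, -3, 1) / M + 2 * h1 + 3 * h2)
  # nondecreasing in lambda1 when h1 > 0 (true for a random curve)
  expect_gt(h1, 0)
  e_lo <- energy(X, C, params = model_params(lambda1 = 0.1, lambda2 = 0,
                                             lambda3 = 0))
  e_hi <- energy(X, C, params = model_params(lambda1 = 1, lambda2 = 0,
                                             lambda3 = 0))
  expect_gt(e_hi, e_lo)
  expect_error(energy(X, contact_matrix(matrix(0, 10, 10)), params = p0),
               "M must be positive|empty")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(29)
  n <- 50
  X <- matrix(rnorm(n * 3), n, 3)
  C <- fixture_contact_matrix(n)
  Cb <- simulate_contact_matrix(make_test_helix(n, turns = 2), a = -3,
                                b = 100, seed = 31)
  params <- model_params(a = -3, b = 1, lambda1 = 0.5, lambda2 = 1,
                         lambda3 = 0.2)
  eff <- effective_data(C, Cb, lambda3 = params$lambda3, b = params$b)
  G <- energy_gradient(X, eff, params = params)
  G_fd <- fd_gradient(function(x) energy(x, eff, params = params), X)
  expect_lt(max(abs(G - G_fd)) / max(abs(G_fd)), 1e-5)
})

test_that("penalty gradients are translation invariant (columns sum to zero)", {
  set.seed(31)
  X <- matrix(rnorm(60), 20, 3)
  C <- fixture_contact_matrix(20)
  eff <- effective_data(C, lambda3 = 0, b = 1)
  g_full <- energy_gradient(X, eff, params = model_params(
    lambda1 = 0.7, lambda2 = 1.3, lambda3 = 0))
  g_lik <- energy_gradient(X, eff, params = model_params(
    lambda1 = 0, lambda2 = 0, lambda3 = 0))
  pen_grad <- g_full - g_lik
  expect_equal(colSums(pen_grad), c(0, 0, 0), tolerance = 1e-12)
})

test_that("compiled energy kernel agrees with the reference implementation", {
  set.seed(37)
  for (rep in 1:5) {
    n <- sample(c(10, 25, 60), 1)
    X <- matrix(rnorm(n * 3), n, 3)
    C <- fixture_contact_matrix(n, seed = rep)
    params <- model_params(a = -2.5, b = 1.4, lambda1 = runif(1),
                           lambda2 = runif(1), lambda3 = 0)
    eff <- effective_data(C, lambda3 = 0, b = params$b)
    k <- schic3d:::energy_kernel(X, unclass(as.matrix(eff$C_tilde)),
                                 params$a, eff$b_tilde, eff$M,
                                 params$lambda1, params$lambda2)
    expect_equal(k$value, energy(X, eff, params = params),
                 tolerance = 1e-12)
    expect_equal(k$gradient, energy_gradient(X, eff, params = params),
                 tolerance = 1e-12)
  }
})

test_that("model_params enforces the parameter domain", {
  expect_error(model_params(a = 0), "negative")
  expect_error(model_params(b = -1), "positive")
  expect_error(model_params(lambda2 = -0.1), "non-negative")
  p <- model_params()
  expect_equal(c(p$a, p$b, p$lambda1, p$lambda2, p$lambda3),
               c(-3, 1, 0.5, 1, 0.1))
})
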