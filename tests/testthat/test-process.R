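test_that("branch moments reproduce the scalar closed form and the BM limit", {
  ## scalar a = sigma = 1, t = ln 2: F = 1/2, V = (1 - e^{-2t})/2 = 0.375
  bm <- branch_moments(matrix(1), matrix(1), 0, log(2))
  expect_equal(as.numeric(bm$F), 0.5, tolerance = 1e-12)
  expect_equal(as.numeric(bm$V), 0.375, tolerance = 1e-12)
  ## A = 0 is Brownian motion: F = I, w = 0, V = Sig Sig' t
  S <- matrix(c(1, 0.3, 0, 0.5), 2, 2)
  b0 <- branch_moments(matrix(0, 2, 2), S, c(1, 2), 0.7)
  expect_equal(b0$F, diag(2))
  expect_equal(b0$w, c(0, 0))
  expect_equal(b0$V, tcrossprod(S) * 0.7, tolerance = 1e-12)
  ## t = 0 degenerates exactly
  bz <- branch_moments(diag(2), S, c(1, 2), 0)
  expect_equal(bz$V, matrix(0, 2, 2))
  expect_error(branch_moments(diag(2), S, c(1, 2), -1), "nonnegative")
})

test_that("accumulated covariance matches independent numerical quadrature", {
  set.seed(5)
  for (i in 1:4) {
    A <- rand_stable_A(3)
    S <- rand_sigma_factor(3)
    t <- runif(1, 0.2, 2)
    V1 <- branch_moments(A, S, rep(0, 3), t)$V
    V2 <- quadrature_V(A, S, t)
    expect_lt(max(abs(V1 - V2)), 1e-8)
  }
  ## singular drift (one zero eigenvalue) still integrates correctly
  A <- matrix(c(1, -1, 0, 0), 2, 2)          # eigenvalues 1, 0
  S <- diag(c(1, 0.5))
  V1 <- branch_moments(A, S, c(0, 0), 1.3)$V
  V2 <- quadrature_V(A, S, 1.3)
  expect_lt(max(abs(V1 - V2)), 1e-8)
  ## non-diagonalizable drift falls back to the augmented exponential
  J <- matrix(c(1, 0, 1, 1), 2, 2)           # Jordan block
  V1 <- branch_moments(J, S, c(0, 0), 0.9)$V
  V2 <- quadrature_V(J, S, 0.9)
  expect_lt(max(abs(V1 - V2)), 1e-8)
})

test_that("branch covariance is symmetric PSD and monotone in t for diagonal drift", {
  set.seed(6)
  A <- diag(c(2, 0.5, 1))
  S <- rand_sigma_factor(3)
  prev <- matrix(0, 3, 3)
  for (t in c(0.1, 0.3, 0.8, 2, 5)) {
    V <- branch_moments(A, S, rep(0, 3), t)$V
    expect_equal(V, t(V), tolerance = 1e-12)
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
               -1e-12)
    d <- eigen(V - prev, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(d), -1e-10)
    prev <- V
  }
})

test_that("stationary covariance solves the Lyapunov equation and is the t -> Inf limit", {
  expect_equal(as.numeric(stationary_covariance(matrix(1), matrix(1))), 0.5)
  expect_equal(stationary_covariance(log(2) * diag(2), diag(2)),
               diag(2) / (2 * log(2)), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:5) {
    A <- rand_stable_A(4)
    S <- rand_sigma_factor(4)
    St <- stationary_covariance(A, S)
    resid <- A %*% St + St %*% t(A) - tcrossprod(S)
    expect_lt(max(abs(resid)), 1e-10)
    t_big <- 50 / min(Re(eigen(A, only.values = TRUE)$values))
    Vb <- branch_moments(A, S, rep(0, 4), t_big)$V
    expect_lt(max(abs(Vb - St)), 1e-6)
  }
  expect_error(stationary_covariance(matrix(c(0, 0, 0, 1), 2, 2), diag(2)),
               "stationary")
})

test_that("half-lives are ln2 over eigenvalue real parts, on both scales", {
  hl <- half_lives(diag(c(log(2), 2 * log(2))))
  expect_equal(sort(hl$half_life), c(0.5, 1.0))
  expect_equal(sort(hl$percent_tree_height), c(50, 100))
  ## triangular drift: eigenvalues are the diagonal
  A <- matrix(c(2, 0, 1.5, 3), 2, 2)
  expect_equal(sort(half_lives(A)$half_life),
               sort(log(2) / c(2, 3)), tolerance = 1e-12)
  ## half-life strictly decreasing in the eigenvalue real part
  hl3 <- half_lives(diag(c(0.5, 1, 4)))
  o <- order(Re(hl3$eigenvalues))
  expect_true(all(diff(hl3$half_life[o]) < 0))
  ## unstable directions are flagged, not errored
  h0 <- half_lives(diag(c(1, -0.2)))
  expect_true(h0$non_adaptive)
  expect_true(any(is.infinite(h0$half_life)))
  ## realized drift from the positive-eigenvalue parametrization is always
  ## adaptive
  m0 <- a_mask(3, "DecomposablePositive", positive_diagonal = FALSE)
  set.seed(8)
  for (i in 1:20) {
    A <- mvou:::unpack_a(rnorm(mvou:::n_pack_a(m0)), m0)
    hi <- half_lives(A)
    expect_false(hi$non_adaptive)
    expect_true(all(is.finite(hi$half_life) & hi$half_life > 0))
  }
})

test_that("the OUBM block embedding matches the printed layout and two-stage moments", {
  e <- embed_oubm(A = matrix(1), Q = matrix(2), psi = 0.3,
                  Sigma_yy = matrix(1), Sigma_xx = matrix(1))
  expect_equal(e$A, matrix(c(1, 0, -2, 0), 2, 2))
  expect_equal(as.vector(e$theta), c(0.3, 0))
  ## Q = 0 decouples responses from predictors in the drift
  e0 <- embed_oubm(diag(2), matrix(0, 2, 1), c(0, 0), diag(2), matrix(1))
  expect_equal(e0$A[1:2, 3], c(0, 0))
  ## propagator of the embedding has the closed two-stage form
  ## [[F, (I-F)Q], [0, I]] and its covariance matches quadrature
  A <- matrix(c(2, 0.3, -0.2, 1), 2, 2)
  Q <- matrix(c(0.5, -0.7), 2, 1)
  ej <- embed_oubm(A, Q, c(1, -1), rand_sigma_factor(2), matrix(0.9))
  t <- 0.8
  bm <- branch_moments(ej$A, ej$Sigma_factor, ej$theta[, 1], t)
  F_y <- branch_moments(A, diag(2), c(0, 0), t)$F
  expect_lt(max(abs(bm$F[1:2, 1:2] - F_y)), 1e-9)
  expect_lt(max(abs(bm$F[1:2, 3] - (diag(2) - F_y) %*% Q)), 1e-9)
  expect_equal(bm$F[3, ], c(0, 0, 1), tolerance = 1e-12)
  Vq <- quadrature_V(ej$A, ej$Sigma_factor, t)
  expect_lt(max(abs(bm$V - Vq)), 1e-8)
})

test_that("regressions and conditional correlations follow Gaussian theory", {
  ## independent traits: all cross-slopes vanish
  spec <- model_spec("OUOU", k = 3, a_mask = a_mask(3, "Diagonal"),
                     sigma_class = "Diagonal")
  p <- model_params(spec, A = diag(c(1, 2, 3)), Sigma_yy = diag(3),
                    theta = rep(0, 3))
  sl <- regressions(p, t = 1, response = 1:2, covariate = 3)
  expect_equal(as.vector(sl), c(0, 0), tolerance = 1e-12)
  ## equicorrelation rho = 0.5: partial correlation = 1/3
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  cc <- conditional_correlation(S, response = 1:2, covariate = 3)
  expect_equal(cc[1, 2], 1 / 3, tolerance = 1e-12)
  ## scalar OUBM evolutionary slope vs Monte-Carlo regression
  spec_b <- model_spec("OUBM", k = 2, ky = 1, kx = 1,
                       a_mask = a_mask(1, "Diagonal"))
  pb <- model_params(spec_b, A = matrix(2), Sigma_yy = matrix(0.6),
                     theta = 0.5, Q = matrix(1.2), Sigma_xx = matrix(1),
                     x0 = c(0.5, 0))
  t <- 0.9
  slope <- as.numeric(regressions(pb, t = t))
  ej <- joint <- mvou:::joint_system(pb)
  bm <- branch_moments(joint$A, joint$Sigma_factor, joint$theta[, 1], t)
  set.seed(9)
  n_mc <- 1e5
  eps <- matrix(rnorm(2 * n_mc), 2, n_mc)
  X <- as.vector(bm$F %*% c(0.5, 0) + bm$w) + mvou:::psd_sqrt(bm$V) %*% eps
  fit_mc <- stats::coef(stats::lm(X[1, ] ~ X[2, ]))[2]
  se <- sqrt(diag(stats::vcov(stats::lm(X[1, ] ~ X[2, ]))))[2]
  expect_lt(abs(fit_mc - slope), 3 * se + 1e-8)
  ## long-run evolutionary regression equals the optimal regression Q
  expect_equal(as.numeric(regressions(pb, t = "limit")), 1.2)
})
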