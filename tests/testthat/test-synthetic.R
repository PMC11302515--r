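test_that("trait simulation is deterministic and exact in the noiseless limit", {
  tr <- rescale_to_unit_height(simulate_pure_birth(10, seed = 2))
  spec <- model_spec("OUOU", k = 2, a_mask = a_mask(2, "Diagonal"),
                     sigma_class = "Diagonal")
  p <- model_params(spec, A = diag(c(1.5, 2.5)), Sigma_yy = diag(2),
                    theta = c(1, -1))
  d1 <- simulate_traits(tr, NULL, p, seed = 42)
  d2 <- simulate_traits(tr, NULL, p, seed = 42)
  expect_identical(d1, d2)
  expect_false(identical(d1, simulate_traits(tr, NULL, p, seed = 43)))
  ## zero diffusion: tips equal the deterministic mean propagation
  p0 <- model_params(spec, A = diag(c(1.5, 2.5)),
                     Sigma_yy = matrix(0, 2, 2), theta = c(1, -1))
  d0 <- simulate_traits(tr, NULL, p0, seed = 1)
  fj <- full_joint_moments(tr, NULL, p0)
  expect_lt(max(abs(as.vector(t(d0)) - fj$mean)), 1e-12)
  expect_lt(max(abs(fj$cov)), 1e-12)
})

test_that("empirical tip moments match the model-implied joint moments", {
  tr <- read_newick("((A:0.6,B:0.6):0.4,(C:0.5,D:0.5):0.5);")
  spec <- model_spec("OUOU", k = 2,
                     a_mask = a_mask(2, "Invertible",
                                     positive_diagonal = FALSE),
                     sigma_class = "UpperTriangular")
  A <- matrix(c(1.6, 0.4, -0.2, 0.9), 2, 2)
  S <- matrix(c(0.8, 0.2, 0, 0.6), 2, 2, byrow = TRUE)
  p <- model_params(spec, A = A, Sigma_yy = S, theta = c(1, -0.5))
  fj <- full_joint_moments(tr, NULL, p)
  n_mc <- 10000
  sims <- matrix(0, n_mc, 8)
  set.seed(77)
  for (i in seq_len(n_mc)) {
    sims[i, ] <- as.vector(t(simulate_traits(tr, NULL, p)))
  }
  mu_hat <- colMeans(sims)
  se_mu <- sqrt(diag(fj$cov) / n_mc)
  expect_true(all(abs(mu_hat - fj$mean) < 4 * se_mu))
  C_hat <- stats::cov(sims)
  ## covariance entries: MC standard error approx (Cii Cjj + Cij^2)/n
  se_C <- sqrt((outer(diag(fj$cov), diag(fj$cov)) + fj$cov^2) / n_mc)
  expect_true(all(abs(C_hat - fj$cov) < 4 * se_C + 1e-12))
})

test_that("joint OUBM simulation agrees with the embedded process in distribution", {
  tr <- read_newick("((A:0.6,B:0.6):0.4,(C:0.5,D:0.5):0.5);")
  spec <- model_spec("OUBM", k = 3, ky = 2, kx = 1,
                     a_mask = a_mask(2, "Diagonal"))
  p <- model_params(spec, A = diag(c(2, 1)), Sigma_yy = diag(c(0.7, 0.5)),
                    theta = c(1, -1), Q = matrix(c(0.8, -0.4), 2, 1),
                    Sigma_xx = matrix(0.9), x0 = c(1, -1, 0.3))
  ## expectations through the embedding equal the two-stage expectations
  fj <- full_joint_moments(tr, NULL, p)
  js <- mvou:::joint_system(p)
  spec_j <- model_spec("OUOU", k = 3,
                       a_mask = a_mask(3, "Invertible",
                                       positive_diagonal = FALSE),
                       root_policy = "free_root")
  ## build the same process explicitly as a 3-variate OU with singular drift
  x0_joint <- c(c(1, -1) + as.vector(p$Q %*% 0.3), 0.3)
  p_j <- list(spec = spec_j, A = js$A, Sigma_yy = js$Sigma_factor,
              theta = js$theta, x0 = x0_joint, Q = NULL,
              Sigma_xx = NULL)
  class(p_j) <- "model_params"
  fj2 <- full_joint_moments(tr, NULL, p_j)
  expect_lt(max(abs(fj$mean - fj2$mean)), 1e-9)
  expect_lt(max(abs(fj$cov - fj2$cov)), 1e-9)
})

test_that("measurement error adds the specified per-tip variance", {
  n <- 4000
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, n)
  tr$tip.label <- paste0("t", seq_len(n))
  d <- matrix(0, n, 1, dimnames = list(tr$tip.label, "x"))
  ## zero ME is the identity
  expect_identical(add_measurement_error(d, tr, 0, seed = 1), d)
  v <- 0.49
  d1 <- add_measurement_error(d, tr, v, seed = 5)
  s2 <- stats::var(d1[, 1])
  se <- v * sqrt(2 / (n - 1))
  expect_lt(abs(s2 - v), 4 * se)
  ## one tip at 10x variance has 10x replicate spread
  spec10 <- me_spec(shared = v, per_tip = list(t1 = 10 * v))
  reps <- replicate(800, add_measurement_error(d[1:2, , drop = FALSE],
                                               ape::keep.tip(tr, c("t1", "t2")),
                                               spec10)[, 1])
  r <- stats::var(reps[1, ]) / stats::var(reps[2, ])
  expect_gt(r, 5); expect_lt(r, 20)
  expect_error(add_measurement_error(d, tr, matrix(c(1, 2, 2, 1), 2, 2)),
               "length|dim|positive")
})

test_that("study dataset generation is reproducible and statistically coherent", {
  spec <- model_spec("BM", k = 4)
  p <- model_params(spec, Sigma_yy = diag(4), x0 = rep(0, 4))
  ds <- generate_study_dataset(list(spec = spec, params = p, n_tips = 32),
                               seed = 99)
  expect_equal(dim(ds$data), c(32L, 4L))
  expect_equal(tree_height(ds$tree), 1, tolerance = 1e-12)
  ds2 <- generate_study_dataset(list(spec = spec, params = p, n_tips = 32),
                                seed = 99)
  expect_identical(ds$data, ds2$data)
  expect_identical(write_newick(ds$tree), write_newick(ds2$tree))

  ## fast-adaptation diagonal model: per-trait tip variance approximates the
  ## stationary variance, and the tip sample oscillates around the optimum
  spec7 <- model_spec("OUOU", k = 5, a_mask = a_mask(5, "Diagonal"),
                      sigma_class = "Diagonal")
  lam <- c(60, 45, 80, 52, 70)          # half-lives < 1.7% of tree height
  p7 <- model_params(spec7, A = diag(lam),
                     Sigma_yy = diag(sqrt(2 * lam)),
                     theta = c(1, -1, 0.5, 2, 0))
  ds7 <- generate_study_dataset(list(spec = spec7, params = p7,
                                     n_tips = 256), seed = 4)
  sv <- diag(stationary_covariance(p7$A, p7$Sigma_yy))
  emp <- apply(ds7$data, 2, stats::var)
  expect_true(all(abs(emp - sv) < 0.35))
  ## exact variance of the tip sample mean from the model-implied joint
  ## covariance (tips near a cherry are correlated through short stems)
  fj <- full_joint_moments(ds7$tree, ds7$painting, p7)
  k <- 5; n <- 256
  var_mean <- vapply(seq_len(k), function(j) {
    idx <- seq(j, n * k, by = k)
    sum(fj$cov[idx, idx]) / n^2
  }, numeric(1))
  expect_true(all(abs(colMeans(ds7$data) - p7$theta[, 1]) <
                    4 * sqrt(var_mean)))
})
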