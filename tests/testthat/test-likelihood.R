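test_that("pruning reproduces textbook cases exactly", {
  ## single tip, BM sigma^2 = 1, branch 1, root 0, obs 0: standard normal
  t1 <- read_newick("(A:1);")
  spec <- model_spec("BM", k = 1)
  p <- model_params(spec, Sigma_yy = matrix(1), x0 = 0)
  d <- matrix(0, 1, 1, dimnames = list("A", "x"))
  expect_equal(loglik_pruning(t1, NULL, p, d), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  ## star tree: independent tips
  st <- read_newick("(A:1,B:1);")
  d2 <- matrix(c(0.4, -0.3), 2, 1, dimnames = list(c("A", "B"), "x"))
  expect_equal(loglik_pruning(st, NULL, p, d2),
               sum(stats::dnorm(d2, 0, 1, log = TRUE)), tolerance = 1e-10)
  ## shared stem: off-diagonal covariance sigma^2 * s
  tr <- read_newick("((A:1,B:1):0.5,C:1.5);")
  p3 <- model_params(spec, Sigma_yy = matrix(1), x0 = 0)
  fj <- full_joint_moments(tr, NULL, p3)
  expect_equal(fj$cov[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(fj$cov[1, 3], 0, tolerance = 1e-12)
  expect_equal(diag(fj$cov), rep(1.5, 3), tolerance = 1e-12)
})

test_that("an OU with zero drift equals the BM likelihood exactly", {
  tr <- rescale_to_unit_height(simulate_pure_birth(12, seed = 31))
  S <- rand_sigma_factor(2)
  spec_ou <- model_spec("OUOU", k = 2,
                        a_mask = a_mask(2, "Invertible",
                                        positive_diagonal = FALSE),
                        sigma_class = "UpperTriangular",
                        root_policy = "free_root")
  spec_bm <- model_spec("BM", k = 2, sigma_class = "UpperTriangular")
  x0 <- c(0.3, -0.2)
  p_ou <- model_params(spec_ou, A = matrix(0, 2, 2), Sigma_yy = S,
                       theta = c(5, 5), x0 = x0)
  p_bm <- model_params(spec_bm, Sigma_yy = S, x0 = x0)
  set.seed(8)
  d <- simulate_traits(tr, NULL, p_bm, seed = 12)
  expect_equal(loglik_pruning(tr, NULL, p_ou, d),
               loglik_pruning(tr, NULL, p_bm, d), tolerance = 1e-10)
})

test_that("pruning equals the dense Gaussian log-density on fuzzed models", {
  set.seed(123)
  n_cases <- 60
  for (i in seq_len(n_cases)) {
    n_tip <- sample(3:8, 1)
    k <- sample(2:4, 1)
    fam <- sample(c("BM", "OUOU", "OUBM"), 1)
    tr <- rescale_to_unit_height(simulate_pure_birth(n_tip, seed = 1000 + i))
    p <- rand_model(fam, k)
    d <- simulate_traits(tr, NULL, p, seed = 2000 + i)
    me <- if (i %% 2 == 0) runif(k, 0.01, 0.2) else NULL
    ll1 <- loglik_pruning(tr, NULL, p, d, me = me)
    ll2 <- dense_loglik(tr, NULL, p, d, me = me)
    expect_lt(abs(ll1 - ll2), 1e-8)
  }
})

test_that("likelihood is invariant to tip order and zero-length internal branches", {
  tr <- read_newick("((A:0.4,B:0.4):0.6,(C:0.7,D:0.7):0.3);")
  p <- rand_model("OUOU", 3)
  set.seed(41)
  d <- simulate_traits(tr, NULL, p, seed = 77)
  ll <- loglik_pruning(tr, NULL, p, d)
  ## permute data rows: matched by label, so unchanged
  d_perm <- d[c(3, 1, 4, 2), , drop = FALSE]
  expect_equal(loglik_pruning(tr, NULL, p, d_perm), ll, tolerance = 1e-12)
  ## insert a zero-length internal branch above the (A,B) clade
  tr0 <- read_newick("(((A:0.4,B:0.4):0):0.6,(C:0.7,D:0.7):0.3);")
  expect_equal(loglik_pruning(tr0, NULL, p, d), ll, tolerance = 1e-8)
  ## multifurcation handled natively: same density as its dichotomous
  ## resolution with a zero-length connector
  tr_poly <- read_newick("(A:1,B:1,C:1);")
  tr_reso <- read_newick("((A:1,B:1):0,C:1);")
  p1 <- rand_model("OUOU", 2)
  d3 <- simulate_traits(tr_poly, NULL, p1, seed = 5)
  expect_equal(loglik_pruning(tr_poly, NULL, p1, d3),
               loglik_pruning(tr_reso, NULL, p1, d3), tolerance = 1e-8)
})

test_that("singular tip covariance errors with measurement-error advice", {
  tr <- suppressWarnings(read_newick("((A:0,B:1):1,C:2);"))
  spec <- model_spec("BM", k = 1)
  p <- model_params(spec, Sigma_yy = matrix(1), x0 = 0)
  d <- matrix(rnorm(3), 3, 1, dimnames = list(c("A", "B", "C"), "x"))
  expect_error(suppressWarnings(loglik_pruning(tr, NULL, p, d)),
               "measurement error")
  ## adding measurement error removes the singularity
  expect_true(is.finite(suppressWarnings(
    loglik_pruning(tr, NULL, p, d, me = 0.1))))
})

test_that("GLS matches the dense oracle and known limits", {
  set.seed(55)
  tr <- rescale_to_unit_height(simulate_pure_birth(10, seed = 61))
  ## BM: root estimate equals classic GLS from the dense covariance
  spec_bm <- model_spec("BM", k = 2, sigma_class = "UpperTriangular")
  S <- rand_sigma_factor(2)
  p_bm <- model_params(spec_bm, Sigma_yy = S, x0 = c(1, -1))
  d <- simulate_traits(tr, NULL, p_bm, seed = 3)
  g <- gls_linear(tr, NULL, A = matrix(0, 2, 2), Sigma_yy = S, data = d,
                  spec = spec_bm)
  z_oracle <- dense_gls_oracle(tr, NULL, spec_bm,
                               list(A = NULL, Sigma_yy = S), d)
  expect_lt(max(abs(g$z - as.vector(z_oracle))), 1e-8)
  ## OUOU with regimes: oracle agreement
  spec_ou <- model_spec("OUOU", k = 2, a_mask = a_mask(2, "Diagonal"),
                        regimes = c("r1", "r2"))
  tr_paint <- paint_regimes(tr, stats::setNames(
    rep(c("r1", "r2"), length.out = ape::Ntip(tr)), tr$tip.label),
    labels = c("r1", "r2"), default = "r1")
  A <- diag(c(2, 1)); Sy <- diag(c(0.8, 0.6))
  p_ou <- model_params(spec_ou, A = A, Sigma_yy = Sy,
                       theta = matrix(c(1, -1, 2, 0), 2, 2))
  d2 <- simulate_traits(tr, tr_paint, p_ou, seed = 4)
  g2 <- gls_linear(tr, tr_paint, A = A, Sigma_yy = Sy, data = d2,
                   spec = spec_ou)
  z2 <- dense_gls_oracle(tr, tr_paint, spec_ou,
                         list(A = A, Sigma_yy = Sy), d2)
  expect_lt(max(abs(g2$z - as.vector(z2))), 1e-8)
  ## fast adaptation: optimum estimate approaches the tip sample mean
  spec_f <- model_spec("OUOU", k = 1, a_mask = a_mask(1, "Diagonal"))
  lam <- log(2) / 0.001           # half-life 0.1% of tree height
  trf <- rescale_to_unit_height(simulate_pure_birth(64, seed = 9))
  pf <- model_params(spec_f, A = matrix(lam), Sigma_yy = matrix(sqrt(lam)),
                     theta = 2)
  df <- simulate_traits(trf, NULL, pf, seed = 10)
  gf <- gls_linear(trf, NULL, A = pf$A, Sigma_yy = pf$Sigma_yy, data = df,
                   spec = spec_f)
  se <- stats::sd(df) / sqrt(64)
  expect_lt(abs(gf$theta[1, 1] - mean(df)), 3 * se)
  ## a regime painting touching no branch is rank deficient
  spec_r <- model_spec("OUOU", k = 1, a_mask = a_mask(1, "Diagonal"),
                       regimes = c("used", "unused"))
  pu <- uniform_painting(trf, "used")
  attr(pu, "labels") <- c("used", "unused")
  expect_error(gls_linear(trf, pu, A = matrix(1), Sigma_yy = matrix(1),
                          data = df, spec = spec_r), "rank deficient")
})

test_that("noiseless data recover the optimum exactly through GLS", {
  tr <- rescale_to_unit_height(simulate_pure_birth(40, seed = 13))
  spec <- model_spec("OUOU", k = 2, a_mask = a_mask(2, "Diagonal"))
  A <- diag(c(3, 2))
  p <- model_params(spec, A = A, Sigma_yy = diag(c(1e-4, 1e-4)),
                    theta = c(1, 2))
  d <- simulate_traits(tr, NULL, p, seed = 21)
  g <- gls_linear(tr, NULL, A = A, Sigma_yy = diag(c(1e-4, 1e-4)),
                  data = d, spec = spec)
  expect_lt(max(abs(g$theta[, 1] - c(1, 2))), 1e-2)
})
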