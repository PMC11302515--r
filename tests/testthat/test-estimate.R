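test_that("the small-sample information criterion follows its formula", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7, tolerance = 1e-12)
  ## published worked examples at n_obs = 78 tips x 5 traits = 390
  expect_lt(abs(aicc(-238.132, 20, 390) - 518.547), 0.01)
  expect_lt(abs(aicc(-291.323, 15, 390) - 613.933), 0.01)
  expect_error(aicc(-10, 20, 21), "undefined")
  expect_error(aicc(-10, 0, 100), "positive integer")
})

test_that("closed-form BM estimation matches ordinary ML on a star tree", {
  n <- 30
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, n)
  tr$tip.label <- paste0("t", seq_len(n))
  set.seed(3)
  d <- matrix(rnorm(n, 2, 1.3), n, 1, dimnames = list(tr$tip.label, "x"))
  f <- fit_bm(tr, d, sigma_class = "Diagonal")
  expect_equal(f$params$x0, mean(d), tolerance = 1e-10)
  ## ML variance (divisor n) about the estimated mean
  expect_equal(as.numeric(tcrossprod(f$params$Sigma_yy)),
               mean((d - mean(d))^2), tolerance = 1e-10)
  expect_equal(f$dof, 2)
})

test_that("closed-form BM equals the numerical optimizer on fuzzed data", {
  set.seed(19)
  for (i in 1:6) {
    tr <- rescale_to_unit_height(simulate_pure_birth(24, seed = 300 + i))
    p <- rand_model("BM", 2)
    d <- simulate_traits(tr, NULL, p, seed = 400 + i)
    f_closed <- fit_bm(tr, d, sigma_class = "UpperTriangular")
    spec <- model_spec("BM", k = 2, sigma_class = "UpperTriangular")
    ctx_fit <- suppressWarnings(
      fit(tr, NULL, d, spec, me = 1e-8, n_starts = 2, seed = i))
    expect_lt(abs(f_closed$loglik - ctx_fit$loglik), 1e-3)
    ## AICc is recomputable from the stored pieces exactly
    expect_equal(f_closed$aicc,
                 aicc(f_closed$loglik, f_closed$dof, f_closed$n_obs))
  }
})

test_that("the ML fit dominates the true parameters and is deterministic", {
  spec <- model_spec("OUOU", k = 3, a_mask = a_mask(3, "Diagonal"),
                     sigma_class = "Diagonal", name = "OUOUs1_k3")
  p <- model_params(spec, A = diag(c(2, 1, 3)), Sigma_yy = diag(3),
                    theta = c(1, -1, 0))
  tr <- rescale_to_unit_height(simulate_pure_birth(64, seed = 71))
  d <- simulate_traits(tr, NULL, p, seed = 72)
  f1 <- suppressWarnings(fit(tr, NULL, d, spec, n_starts = 3, seed = 5))
  expect_gte(f1$loglik, loglik_pruning(tr, NULL, p, d) - 1e-6)
  f2 <- suppressWarnings(fit(tr, NULL, d, spec, n_starts = 3, seed = 5))
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$params$A, f2$params$A)
  expect_equal(f1$aicc, aicc(f1$loglik, f1$dof, f1$n_obs))
  expect_equal(f1$dof, count_dof(spec))
})

test_that("richer masks never fit worse than their nested restriction", {
  tr <- rescale_to_unit_height(simulate_pure_birth(48, seed = 81))
  spec_d <- model_spec("OUOU", k = 2, a_mask = a_mask(2, "Diagonal"),
                       sigma_class = "Diagonal")
  spec_u <- model_spec("OUOU", k = 2, a_mask = a_mask(2, "UpperTriangular"),
                       sigma_class = "Diagonal")
  p <- model_params(spec_d, A = diag(c(2, 1)), Sigma_yy = diag(2),
                    theta = c(1, -1))
  d <- simulate_traits(tr, NULL, p, seed = 82)
  f_d <- suppressWarnings(fit(tr, NULL, d, spec_d, n_starts = 3, seed = 6))
  start_u <- model_params(spec_u, A = f_d$params$A,
                          Sigma_yy = f_d$params$Sigma_yy,
                          theta = f_d$params$theta)
  f_u <- suppressWarnings(fit(tr, NULL, d, spec_u, n_starts = 3, seed = 6,
                              start = start_u))
  ## superset mask must reach at least the subset optimum
  expect_gte(f_u$loglik, f_d$loglik - 1e-4)
})

test_that("the log-likelihood spread across starts is reported and warned about", {
  tr <- rescale_to_unit_height(simulate_pure_birth(24, seed = 91))
  spec <- model_spec("OUOU", k = 2, a_mask = a_mask(2, "Diagonal"),
                     sigma_class = "Diagonal")
  p <- model_params(spec, A = diag(c(2, 1)), Sigma_yy = diag(2),
                    theta = c(0.5, -0.5))
  d <- simulate_traits(tr, NULL, p, seed = 92)
  f <- suppressWarnings(fit(tr, NULL, d, spec, n_starts = 3, seed = 7))
  expect_length(f$starts$loglik, 3L)
  expect_true(is.finite(f$starts$spread))
})

test_that("parametric bootstrap intervals are ordered, cover the estimate, and track coverage", {
  spec <- model_spec("OUOU", k = 1, a_mask = a_mask(1, "Diagonal"),
                     sigma_class = "Diagonal", name = "scalar_OU")
  theta_true <- 1.5
  p <- model_params(spec, A = matrix(2), Sigma_yy = matrix(1),
                    theta = theta_true)
  tr <- rescale_to_unit_height(simulate_pure_birth(64, seed = 101))
  d <- simulate_traits(tr, NULL, p, seed = 102)
  f <- suppressWarnings(fit(tr, NULL, d, spec, n_starts = 2, seed = 8))
  bt <- parametric_bootstrap(f, tr, reps = 60, seed = 9)
  expect_true(all(bt$intervals[, "lower"] <= bt$intervals[, "upper"]))
  expect_lte(bt$n_failed, 6)
  ## the point estimate of theta sits inside its own marginal interval
  expect_gte(bt$estimates["theta_1"], bt$intervals["theta_1", "lower"])
  expect_lte(bt$estimates["theta_1"], bt$intervals["theta_1", "upper"])

  ## outer replication: the 95% interval for theta covers the truth at a
  ## rate consistent with its nominal level (binomial SE at 20 outer
  ## replicates is about 5 points; the band below is 3 SE wide)
  n_outer <- 20
  covered <- 0L
  for (r in seq_len(n_outer)) {
    dr <- simulate_traits(tr, NULL, p, seed = 500 + r)
    fr <- suppressWarnings(fit(tr, NULL, dr, spec, n_starts = 1,
                               seed = 600 + r))
    if (!is.finite(fr$loglik)) next
    br <- parametric_bootstrap(fr, tr, reps = 80, seed = 700 + r)
    ci <- br$intervals["theta_1", ]
    if (theta_true >= ci["lower"] && theta_true <= ci["upper"]) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered / n_outer, 0.80)
})
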