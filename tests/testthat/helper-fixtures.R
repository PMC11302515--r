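# Shared fixtures and independent oracles used across the suite.

## random stable drift matrix of dimension k (real eigenvalues not
## required); stability enforced by shifting the diagonal when needed
rand_stable_A <- function(k, min_rate = 0.3, max_rate = 3) {
  A <- diag(stats::runif(k, min_rate, max_rate), k) +
    matrix(stats::rnorm(k * k, 0, 0.15), k, k)
  gap <- min(Re(eigen(A, only.values = TRUE)$values))
  if (gap < 0.2) A <- A + (0.25 - gap) * diag(k)
  A
}

## random upper-triangular diffusion factor with positive diagonal
rand_sigma_factor <- function(k, diagonal = FALSE) {
  S <- diag(stats::runif(k, 0.4, 1.2), k)
  if (!diagonal && k > 1) S[upper.tri(S)] <- stats::rnorm(k * (k - 1) / 2, 0, 0.3)
  S
}

## random model of a given family, dimension-conforming, on free masks
rand_model <- function(family, k, sigma_class = "UpperTriangular",
                       root_policy = "root_equals_optimum") {
  if (family == "BM") {
    spec <- model_spec("BM", k = k, sigma_class = sigma_class)
    return(model_params(spec, Sigma_yy = rand_sigma_factor(
      k, sigma_class == "Diagonal"), x0 = stats::rnorm(k)))
  }
  if (family == "OUOU") {
    spec <- model_spec("OUOU", k = k,
                       a_mask = a_mask(k, "Invertible",
                                       positive_diagonal = FALSE),
                       sigma_class = sigma_class,
                       root_policy = root_policy)
    x0 <- if (root_policy == "free_root") stats::rnorm(k) else NULL
    return(model_params(spec, A = rand_stable_A(k),
                        Sigma_yy = rand_sigma_factor(
                          k, sigma_class == "Diagonal"),
                        theta = stats::rnorm(k), x0 = x0))
  }
  ky <- max(1L, k %/% 2L); kx <- k - ky
  spec <- model_spec("OUBM", k = k, ky = ky, kx = kx,
                     a_mask = a_mask(ky, "Invertible",
                                     positive_diagonal = FALSE),
                     sigma_class = sigma_class,
                     root_policy = root_policy)
  model_params(spec, A = rand_stable_A(ky),
               Sigma_yy = rand_sigma_factor(ky, sigma_class == "Diagonal"),
               theta = stats::rnorm(ky),
               Q = matrix(stats::rnorm(ky * kx, 0, 0.8), ky, kx),
               Sigma_xx = rand_sigma_factor(kx, TRUE),
               x0 = stats::rnorm(k))
}

## composite-Simpson quadrature of V(t) = int_0^t e^{-As} Sig Sig' e^{-A's} ds
## through Matrix::expm -- an integration route independent of the
## eigendecomposition formula used by branch_moments
quadrature_V <- function(A, Sigma_factor, t, n_panels = 200) {
  SS <- tcrossprod(Sigma_factor)
  f <- function(s) {
    E <- as.matrix(Matrix::expm(-A * s))
    E %*% SS %*% t(E)
  }
  h <- t / n_panels
  acc <- f(0) + f(t)
  for (i in seq_len(n_panels - 1)) {
    acc <- acc + (if (i %% 2 == 1) 4 else 2) * f(i * h)
  }
  acc * h / 3
}

## dense GLS of the linear mean parameters from the brute-force joint
## moments: mean is linear in z, design columns obtained by unit vectors
dense_gls_oracle <- function(tree, painting, spec, st, data, me = NULL) {
  k <- spec$k
  base <- model_params(spec, A = if (spec$family == "BM") NULL else st$A,
                       Sigma_yy = st$Sigma_yy, Q = st$Q,
                       Sigma_xx = st$Sigma_xx,
                       x0 = rep(0, k))
  lay <- mvou:::z_layout(spec)
  set_z <- function(z) {
    th <- base$theta
    if (spec$family != "BM") {
      th <- matrix(z[seq_len(lay$n_theta)], lay$ks, lay$R)
    }
    x0 <- NULL
    if (lay$n_root > 0L) {
      xr <- z[lay$n_theta + seq_len(lay$n_root)]
      if (spec$family == "OUBM" && spec$root_policy != "free_root") {
        x0 <- c(rep(0, spec$ky), xr)
      } else {
        x0 <- xr
      }
    }
    model_params(spec, A = if (spec$family == "BM") NULL else st$A,
                 Sigma_yy = st$Sigma_yy, theta = th, x0 = x0,
                 Q = st$Q, Sigma_xx = st$Sigma_xx)
  }
  D <- sapply(seq_len(lay$p), function(j) {
    z <- rep(0, lay$p); z[j] <- 1
    full_joint_moments(tree, painting, set_z(z), me = me)$mean
  })
  V <- full_joint_moments(tree, painting, set_z(rep(0, lay$p)), me = me)$cov
  y <- as.vector(t(trait_data(data, tree)))
  Vi <- solve(V)
  solve(t(D) %*% Vi %*% D, t(D) %*% Vi %*% y)
}

## small fixed trees used in closed-form checks
cherry_tree <- function(tip = 1) {
  read_newick(sprintf("(A:%g,B:%g);", tip, tip))
}
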