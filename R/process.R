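## Closed-form moments of the multivariate OU process
##   dy = -A (y - theta) dt + Sigma dW
## Conditional on the state at the start of a branch of length t:
##   y(t) | y(0) ~ N(F y(0) + w, V)
## with F = expm(-A t), w = (I - F) theta and
##   V(t) = int_0^t expm(-A s) Sigma Sigma' expm(-A' s) ds.
## When A = P diag(lambda) P^-1 is diagonalizable,
##   V(t) = P [ Stilde_ij (1 - e^{-(lambda_i+lambda_j) t})/(lambda_i+lambda_j) ] P',
##   Stilde = P^-1 Sigma Sigma' P^-T,
## with the limit Stilde_ij * t as lambda_i + lambda_j -> 0 (this covers
## singular A, hence the BM rows of the OUBM block embedding).  For
## non-diagonalizable or badly conditioned A the augmented 2k x 2k
## matrix-exponential (Van Loan) construction is used instead.

EIG_COND_MAX <- 1e8

## eigen "plan" reused across branches; complex eigensystems are handled
## in complex arithmetic (the results are real up to rounding, and the
## transpose in the V formula is the plain transpose, never the conjugate
## one); ok = FALSE routes to the matrix-exponential fallback
ou_eigen_plan <- function(A, SigSig) {
  k <- nrow(A)
  cplx <- function(x) {
    x <- as.matrix(x)
    if (!is.complex(x)) storage.mode(x) <- "complex"
    x
  }
  if (max(abs(A)) == 0) {
    return(list(ok = TRUE, P = cplx(diag(k)), Pinv = cplx(diag(k)),
                lambda = complex(real = rep(0, k)),
                Stilde = cplx(SigSig), A = A, SigSig = SigSig))
  }
  e <- tryCatch(eigen(A), error = function(err) NULL)
  if (is.null(e)) return(list(ok = FALSE, A = A, SigSig = SigSig))
  P <- cplx(e$vectors)
  sv <- tryCatch(svd(P, nu = 0, nv = 0)$d, error = function(err) NULL)
  if (is.null(sv) || min(sv) <= 0 || min(sv) / max(sv) < 1 / EIG_COND_MAX) {
    return(list(ok = FALSE, A = A, SigSig = SigSig))
  }
  Pinv <- solve(P)
  list(ok = TRUE, P = P, Pinv = Pinv,
       lambda = as.complex(e$values),
       Stilde = Pinv %*% cplx(SigSig) %*% t(Pinv), A = A, SigSig = SigSig)
}

## integral factor (1 - exp(-s t))/s with the s -> 0 limit t (complex s)
int_factor <- function(s, t) {
  ifelse(Mod(s) * t < 1e-10, complex(real = t), (1 - exp(-s * t)) / s)
}

plan_moments <- function(plan, t) {
  k <- nrow(plan$A)
  if (plan$ok) {
    El <- exp(-plan$lambda * t)
    F_ <- Re(plan$P %*% (El * plan$Pinv))
    ls <- outer(plan$lambda, plan$lambda, "+")
    V <- Re(plan$P %*% (plan$Stilde * int_factor(ls, t)) %*% t(plan$P))
  } else {
    ev <- eigen(plan$A, only.values = TRUE)$values
    if (all(Re(ev) > 1e-8)) {
      ## stable drift: V(t) = S - F S F' with S the Lyapunov solution;
      ## free of the overflow the augmented exponential suffers at large t
      F_ <- as.matrix(Matrix::expm(-plan$A * t))
      S <- stationary_covariance_raw(plan$A, plan$SigSig)
      V <- S - F_ %*% S %*% t(F_)
    } else {
      M <- rbind(cbind(-plan$A, plan$SigSig),
                 cbind(matrix(0, k, k), t(plan$A)))
      E <- as.matrix(Matrix::expm(M * t))
      F_ <- E[seq_len(k), seq_len(k), drop = FALSE]
      TR <- E[seq_len(k), k + seq_len(k), drop = FALSE]
      V <- TR %*% t(F_)
    }
  }
  V <- (V + t(V)) / 2
  list(F = F_, V = V)
}

## Lyapunov solve on a precomputed Sig Sig' (no factor involved)
stationary_covariance_raw <- function(A, SigSig) {
  k <- nrow(A)
  K <- diag(k) %x% A + A %x% diag(k)
  S <- matrix(solve(K, as.vector(SigSig)), k, k)
  (S + t(S)) / 2
}

#' Conditional moments of the OU transition along a branch
#'
#' @param A drift matrix (k x k); `A = 0` gives the Brownian limit
#'   `F = I`, `V = Sigma Sigma' t`.
#' @param Sigma_factor diffusion factor; the instantaneous covariance is
#'   `Sigma_factor %*% t(Sigma_factor)`.
#' @param theta optimum pulling the process along this branch.
#' @param t branch length (>= 0).
#' @return a list with `F` (the propagator `expm(-A t)`), `w` (the drift
#'   offset `(I - F) theta`) and `V` (the accumulated covariance, symmetric
#'   positive semidefinite).
#' @export
branch_moments <- function(A, Sigma_factor, theta, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("'t' must be a single nonnegative number")
  }
  A <- as.matrix(A)
  k <- nrow(A)
  if (ncol(A) != k) stop("'A' must be square")
  Sigma_factor <- as.matrix(Sigma_factor)
  if (!all(dim(Sigma_factor) == k)) stop("'Sigma_factor' must be k x k")
  theta <- as.numeric(theta)
  if (length(theta) != k) stop("'theta' must have length k")
  if (t == 0) {
    return(list(F = diag(k), w = rep(0, k), V = matrix(0, k, k)))
  }
  plan <- ou_eigen_plan(A, tcrossprod(Sigma_factor))
  fm <- plan_moments(plan, t)
  list(F = fm$F, w = as.vector((diag(k) - fm$F) %*% theta), V = fm$V)
}

#' Stationary covariance of a multivariate OU process
#'
#' Solves the Lyapunov equation `A S + S A' = Sigma Sigma'` via the
#' Kronecker-vectorized linear system; requires every eigenvalue of `A` to
#' have positive real part (otherwise no stationary distribution exists).
#'
#' @inheritParams branch_moments
#' @return the k x k stationary covariance `S`.
#' @export
stationary_covariance <- function(A, Sigma_factor) {
  A <- as.matrix(A)
  k <- nrow(A)
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) <= 0)) {
    stop("no stationary distribution: A has an eigenvalue with ",
         "nonpositive real part")
  }
  SigSig <- tcrossprod(as.matrix(Sigma_factor))
  K <- diag(k) %x% A + A %x% diag(k)
  S <- matrix(solve(K, as.vector(SigSig)), k, k)
  (S + t(S)) / 2
}

#' Phylogenetic half-lives of the drift matrix
#'
#' For each eigenvalue `lambda_i` of `A`, the half-life `ln 2 / Re(lambda_i)`
#' is the time needed to lose half of the ancestral deviation along the
#' corresponding eigenvector direction.  Reported both in tree-height units
#' and as a percentage of the (given) tree height; eigenvalues with
#' nonpositive real part yield `Inf` and raise the `non_adaptive` flag
#' (no decay toward the optimum along that direction).
#'
#' @param A drift matrix.
#' @param tree_height height used for the percentage scale (default 1, the
#'   convention after rescaling trees to unit height).
#' @return a list with `half_life`, `percent_tree_height`, `eigenvalues`,
#'   `eigenvectors` (columns paired with the half-lives) and the logical
#'   flag `non_adaptive`.
#' @export
half_lives <- function(A, tree_height = 1) {
  A <- as.matrix(A)
  e <- eigen(A)
  re <- Re(e$values)
  hl <- ifelse(re > 0, log(2) / re, Inf)
  list(half_life = hl,
       percent_tree_height = 100 * hl / tree_height,
       eigenvalues = e$values,
       eigenvectors = e$vectors,
       non_adaptive = any(re <= 0))
}

#' Embed an OUBM model into the joint OU form
#'
#' The hierarchical model in which responses `y` follow an OU pull toward
#' `psi + Q x` while the predictors `x` evolve as Brownian motion is a
#' single OU process on the stacked state `(y, x)` with the block drift
#' `A' = rbind(cbind(A, -A Q), 0)`, optimum `theta' = (psi, 0)` and
#' block-diagonal diffusion `diag(Sigma_yy, Sigma_xx)`.  The bottom `kx`
#' rows of `A'` are zero: ancestral predictor signal never decays.
#'
#' @param A response drift (ky x ky).
#' @param Q regression of optima on predictors (ky x kx).
#' @param psi optimum intercepts (length ky, or ky x n_regimes).
#' @param Sigma_yy,Sigma_xx diffusion factors of responses/predictors.
#' @return a list with joint `A`, `theta` (k x n_regimes), `Sigma_factor`,
#'   and the partition sizes `ky`, `kx`.
#' @export
embed_oubm <- function(A, Q, psi, Sigma_yy, Sigma_xx) {
  A <- as.matrix(A); Q <- as.matrix(Q)
  Sigma_yy <- as.matrix(Sigma_yy); Sigma_xx <- as.matrix(Sigma_xx)
  ky <- nrow(A); kx <- ncol(Q)
  if (ncol(A) != ky) stop("'A' must be square")
  if (nrow(Q) != ky) stop("'Q' must be ky x kx")
  if (!all(dim(Sigma_yy) == ky)) stop("'Sigma_yy' must be ky x ky")
  if (!all(dim(Sigma_xx) == kx)) stop("'Sigma_xx' must be kx x kx")
  psi <- as.matrix(psi)
  if (nrow(psi) != ky) stop("'psi' must have ky rows")
  k <- ky + kx
  Aj <- rbind(cbind(A, -A %*% Q), matrix(0, kx, k))
  thetaj <- rbind(psi, matrix(0, kx, ncol(psi)))
  Sj <- rbind(cbind(Sigma_yy, matrix(0, ky, kx)),
              cbind(matrix(0, kx, ky), Sigma_xx))
  list(A = Aj, theta = thetaj, Sigma_factor = Sj, ky = ky, kx = kx)
}

## joint-state view of model_params: k x k A, k x R theta, k x k Sigma factor
joint_system <- function(params) {
  spec <- params$spec
  if (spec$family == "OUBM") {
    emb <- embed_oubm(params$A, params$Q, params$theta,
                      params$Sigma_yy, params$Sigma_xx)
    list(A = emb$A, theta = emb$theta, Sigma_factor = emb$Sigma_factor)
  } else {
    list(A = params$A, theta = params$theta, Sigma_factor = params$Sigma_yy)
  }
}

#' Model-implied trait regressions
#'
#' Regression slopes of a set of response traits on a set of covariate
#' traits under the model-implied joint distribution of the traits at time
#' `t` from the root: `slope = Cov(y, x) %*% solve(Var(x))`, the covariance
#' taken from the accumulated OU covariance `V(t)`.  With `t = "limit"` the
#' long-term value is returned: the stationary covariance for a stable OUOU
#' model, and for OUBM the optimal regression `Q` (which the evolutionary
#' regression approaches as ancestral signal decays).
#'
#' @param params a [model_params()].
#' @param t time from the root, or `"limit"`.
#' @param response,covariate integer indices of the two trait sets (for
#'   OUBM they default to the response/predictor partition).
#' @return the slope matrix (`length(response)` x `length(covariate)`).
#' @export
regressions <- function(params, t = "limit", response = NULL,
                        covariate = NULL) {
  spec <- params$spec
  js <- joint_system(params)
  k <- nrow(js$A)
  if (is.null(response)) {
    response <- if (spec$family == "OUBM") seq_len(spec$ky) else
      seq_len(max(1L, k - 1L))
  }
  if (is.null(covariate)) {
    covariate <- if (spec$family == "OUBM") spec$ky + seq_len(spec$kx) else k
  }
  if (identical(t, "limit")) {
    if (spec$family == "OUBM" &&
        identical(sort(response), seq_len(spec$ky)) &&
        identical(sort(covariate), spec$ky + seq_len(spec$kx))) {
      ## evolutionary regression -> optimal regression Q in the long run
      return(params$Q)
    }
    S <- stationary_covariance(js$A, js$Sigma_factor)
  } else {
    S <- branch_moments(js$A, js$Sigma_factor, rep(0, k), t)$V
  }
  Vx <- S[covariate, covariate, drop = FALSE]
  if (rcond(Vx) < 1e-12) stop("covariate covariance is singular")
  S[response, covariate, drop = FALSE] %*% solve(Vx)
}

#' Conditional correlation among traits given covariates
#'
#' Standard Gaussian conditioning of a covariance matrix: the correlation
#' of the response set after removing the linear effect of the covariate
#' set, `S_yy - S_yx S_xx^-1 S_xy` converted to a correlation matrix.
#'
#' @param S a covariance matrix (e.g. a stationary covariance).
#' @param response,covariate index vectors into `S`.
#' @return conditional correlation matrix of the responses.
#' @export
conditional_correlation <- function(S, response, covariate) {
  S <- as.matrix(S)
  Syy <- S[response, response, drop = FALSE]
  Sxx <- S[covariate, covariate, drop = FALSE]
  Syx <- S[response, covariate, drop = FALSE]
  if (rcond(Sxx) < 1e-12) stop("covariate covariance is singular")
  Sc <- Syy - Syx %*% solve(Sxx, t(Syx))
  stats::cov2cor((Sc + t(Sc)) / 2)
}
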