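#' Tip trait data
#'
#' Validates a tip-by-trait numeric matrix against a tree: every tip present
#' exactly once (rownames are tip labels), no missing values.
#'
#' @param x numeric matrix or data frame, rows named by tip labels.
#' @param tree the `phylo` object the data belong to.
#' @param trait_names optional column names to enforce.
#' @return a numeric matrix (rows ordered as `tree$tip.label`).
#' @export
trait_data <- function(x, tree, trait_names = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) stop("trait data must have tip labels as rownames")
  if (anyNA(x)) stop("trait data contain missing values")
  miss <- setdiff(tree$tip.label, rownames(x))
  if (length(miss)) stop("missing tips in trait data: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(rownames(x))) stop("duplicated tip rows in trait data")
  x <- x[tree$tip.label, , drop = FALSE]
  if (!is.null(trait_names)) colnames(x) <- trait_names
  if (is.null(colnames(x))) colnames(x) <- paste0("trait_", seq_len(ncol(x)))
  x
}

## ---------------------------------------------------------------------------
## layout of the stacked linear-parameter vector z:
##   OUOU: (vec(theta_1..R) [, x0 if free_root])
##   BM:   (x0)                     (theta does not enter the BM mean)
##   OUBM: (vec(psi_1..R), x0_x)    (root_equals_optimum ties the response
##                                   root to psi_root + Q x0_x)
##         (vec(psi_1..R), x0)      under free_root
z_layout <- function(spec) {
  ks <- if (spec$family == "OUBM") spec$ky else spec$k
  R <- length(spec$regimes)
  n_theta <- if (spec$family == "BM") 0L else ks * R
  nr <- root_pack_len(spec)
  list(p = n_theta + nr, n_theta = n_theta, ks = ks, R = R, n_root = nr)
}

## selector cubes: theta_r = Tsel[,,r] %*% z ; x0 = S0 %*% z
z_selectors <- function(spec, Q = NULL, root_regime = 1L) {
  lay <- z_layout(spec)
  k <- spec$k
  Tsel <- array(0, dim = c(k, lay$p, lay$R))
  if (spec$family != "BM") {
    for (r in seq_len(lay$R)) {
      for (j in seq_len(lay$ks)) {
        Tsel[j, (r - 1L) * lay$ks + j, r] <- 1
      }
    }
  }
  list(Tsel = Tsel, layout = lay)
}

## selector S0 with x0 = S0 %*% z under the root policy (needs Q for the
## OUBM root-equals-optimum tie x0_y = psi_root + Q x0_x)
root_selector <- function(spec, lay, root_regime, Q = NULL) {
  k <- spec$k
  S0 <- matrix(0, k, lay$p)
  if (spec$family == "BM") {
    S0[, seq_len(k)] <- diag(k)
  } else if (spec$root_policy == "free_root") {
    S0[, lay$n_theta + seq_len(k)] <- diag(k)
  } else if (spec$family == "OUBM") {
    off <- (root_regime - 1L) * lay$ks
    S0[seq_len(spec$ky), off + seq_len(spec$ky)] <- diag(spec$ky)
    S0[seq_len(spec$ky), lay$n_theta + seq_len(spec$kx)] <- Q
    S0[spec$ky + seq_len(spec$kx), lay$n_theta + seq_len(spec$kx)] <-
      diag(spec$kx)
  } else {
    off <- (root_regime - 1L) * k
    S0[, off + seq_len(k)] <- diag(k)
  }
  S0
}

## stack the linear parameters of a model_params into z
z_from_params <- function(params) {
  spec <- params$spec
  lay <- z_layout(spec)
  z <- numeric(0)
  if (spec$family != "BM") z <- as.vector(params$theta)
  if (lay$n_root > 0L) {
    x0 <- params$x0
    if (is.null(x0)) stop("'x0' is required for this root policy/family")
    if (spec$family == "OUBM" && spec$root_policy != "free_root") {
      z <- c(z, x0[spec$ky + seq_len(spec$kx)])
    } else {
      z <- c(z, x0)
    }
  }
  z
}

## root state implied by the root policy (shared by simulation, the dense
## oracle and the pruning engine so all routes use one convention):
## free_root/BM use the supplied x0; OUOU root_equals_optimum uses the
## root-regime optimum; OUBM root_equals_optimum ties the response block to
## psi_root + Q x0_x with the predictor root taken from the tail of x0
effective_root <- function(params, js, rootreg) {
  spec <- params$spec
  if (spec$family == "BM" || spec$root_policy == "free_root") {
    if (is.null(params$x0)) stop("'x0' is required for a free root")
    return(params$x0)
  }
  if (spec$family == "OUBM") {
    if (is.null(params$x0)) {
      stop("OUBM requires 'x0' (its last kx entries are the predictor root)")
    }
    x0x <- params$x0[spec$ky + seq_len(spec$kx)]
    return(c(params$theta[, rootreg] + as.vector(params$Q %*% x0x), x0x))
  }
  js$theta[, rootreg]
}

## regime label at the root: the regime of the first branch leaving the root
root_regime_index <- function(tree, regime_idx) {
  root <- ape::Ntip(tree) + 1L
  first <- which(tree$edge[, 1L] == root)[1L]
  regime_idx[first]
}

## normalize a measurement-error specification to a k x k x n_tip array
## aligned with tip ids (accepts NULL, scalar, k-vector, k x k matrix,
## an me_spec, or a full array)
as_me_array <- function(me, tree, k) {
  n_tip <- ape::Ntip(tree)
  out <- array(0, dim = c(k, k, n_tip))
  if (is.null(me)) return(out)
  if (inherits(me, "me_spec")) {
    for (i in seq_len(n_tip)) {
      lab <- tree$tip.label[i]
      Mi <- if (!is.null(me$per_tip) && lab %in% names(me$per_tip)) {
        me$per_tip[[lab]]
      } else {
        me$shared
      }
      if (is.null(Mi)) stop("measurement error missing for tip ", lab)
      out[, , i] <- as_me_matrix(Mi, k)
    }
    return(out)
  }
  if (is.array(me) && length(dim(me)) == 3L) {
    stopifnot(all(dim(me) == c(k, k, n_tip)))
    return(me)
  }
  M <- as_me_matrix(me, k)
  for (i in seq_len(n_tip)) out[, , i] <- M
  out
}

as_me_matrix <- function(m, k) {
  if (is.matrix(m)) {
    stopifnot(all(dim(m) == k))
    M <- (m + t(m)) / 2
  } else if (length(m) == 1L) {
    M <- diag(rep(as.numeric(m), k), k)
  } else if (length(m) == k) {
    M <- diag(as.numeric(m), k)
  } else {
    stop("cannot interpret measurement-error entry of length ", length(m))
  }
  if (any(eigen(M, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
    stop("measurement-error covariance is not positive semidefinite")
  }
  M
}

## static scaffolding shared by every likelihood evaluation on the same
## (tree, painting, spec, data, me): postorder edges, regime indices, data
## matrix, measurement-error array and z selectors
make_lik_context <- function(tree, painting, spec, data, me = NULL) {
  k <- spec$k
  regime_idx <- if (is.null(painting)) rep(1L, nrow(tree$edge)) else
    match(as.character(painting), spec$regimes)
  if (anyNA(regime_idx)) {
    stop("painting labels not declared in the spec: ",
         paste(setdiff(unique(as.character(painting)), spec$regimes),
               collapse = ", "))
  }
  if (length(regime_idx) != nrow(tree$edge)) {
    stop("painting length does not match the number of branches")
  }
  n_tip <- ape::Ntip(tree)
  rootreg <- root_regime_index(tree, regime_idx)
  sel <- z_selectors(spec, Q = NULL, root_regime = rootreg)
  Y <- t(trait_data(data, tree))          # k x n_tip, tip-id order
  if (nrow(Y) != k) {
    stop("trait dimension (", nrow(Y), ") does not match the model (", k, ")")
  }
  tr_post <- ape::reorder.phylo(tree, "postorder")
  perm <- match(tr_post$edge[, 2L], tree$edge[, 2L])
  list(spec = spec, k = k, p = sel$layout$p, layout = sel$layout,
       Tsel = sel$Tsel, rootreg = rootreg,
       n_tip = n_tip, n_node = n_tip + tree$Nnode, root = n_tip + 1L,
       edge = tr_post$edge, edge_len = tr_post$edge.length,
       edge_regime = regime_idx[perm],
       Y = Y, ME = as_me_array(me, tree, k))
}

## one pruning pass given concrete (joint) drift/diffusion; returns the
## (H, h, c) quadratic in z after applying the root policy
ctx_quadratic <- function(ctx, A, Sigma_factor, Q = NULL) {
  spec <- ctx$spec
  k <- ctx$k
  plan <- ou_eigen_plan(A, tcrossprod(Sigma_factor))
  if (plan$ok) {
    Farr <- array(0, dim = c(1, 1, 1)); Varr <- Farr
    res <- prune_tree_cpp(k, ctx$p, ctx$edge, ctx$edge_len, ctx$edge_regime,
                          ctx$n_tip, ctx$n_node, ctx$root, ctx$Y, ctx$ME,
                          ctx$Tsel, TRUE, plan$P, plan$Pinv, plan$lambda,
                          plan$Stilde, Farr, Varr)
  } else {
    E <- nrow(ctx$edge)
    Farr <- array(0, dim = c(k, k, E))
    Varr <- array(0, dim = c(k, k, E))
    for (e in seq_len(E)) {
      fm <- plan_moments(plan, ctx$edge_len[e])
      Farr[, , e] <- fm$F
      Varr[, , e] <- fm$V
    }
    cId <- matrix(complex(real = as.vector(diag(k))), k, k)
    res <- prune_tree_cpp(k, ctx$p, ctx$edge, ctx$edge_len, ctx$edge_regime,
                          ctx$n_tip, ctx$n_node, ctx$root, ctx$Y, ctx$ME,
                          ctx$Tsel, FALSE, cId, cId,
                          complex(real = rep(0, k)), cId, Farr, Varr)
  }
  if (spec$root_policy == "stationary_root") {
    S_stat <- stationary_covariance(A, Sigma_factor)
    W0 <- ctx$Tsel[, , ctx$rootreg]
    res <- integrate_root_state(res, W0, S_stat, k)
    H <- res$R; h <- res$r1; c0 <- res$r0
  } else {
    S0 <- root_selector(spec, ctx$layout, ctx$rootreg, Q)
    H <- res$R + t(S0) %*% res$L %*% S0 +
      (t(S0) %*% res$M + t(res$M) %*% S0) / 2
    h <- res$r1 + t(S0) %*% res$m0
    c0 <- res$r0
  }
  list(H = (H + t(H)) / 2, h = as.vector(h), c0 = c0,
       layout = ctx$layout, root_regime = ctx$rootreg, pieces = res)
}

## per-edge (F, w-selector, V) inputs + C++ pruning pass on a fresh context
tree_quadratic <- function(tree, painting, params, data, me = NULL) {
  spec <- params$spec
  ctx <- make_lik_context(tree, painting, spec, data, me)
  js <- joint_system(params)
  ctx_quadratic(ctx, js$A, js$Sigma_factor, Q = params$Q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## marginalize the root state x0 ~ N(W0 z, S_stat) out of the root quadratic
integrate_root_state <- function(res, W0, S_stat, k) {
  U <- chol((S_stat + t(S_stat)) / 2)
  Lam <- chol2inv(U)
  logdetV <- 2 * sum(log(diag(U)))
  C <- Lam / 2 - res$L
  Uc <- chol((C + t(C)) / 2)
  Cinv <- chol2inv(Uc)
  logdetC <- 2 * sum(log(diag(Uc)))
  G <- Lam %*% W0 + res$M
  R2 <- res$R + t(G) %*% Cinv %*% G / 4 - t(W0) %*% Lam %*% W0 / 2
  r12 <- res$r1 + t(G) %*% Cinv %*% res$m0 / 2
  r02 <- res$r0 + sum(res$m0 * (Cinv %*% res$m0)) / 4 -
    k * log(2) / 2 - logdetV / 2 - logdetC / 2
  list(L = matrix(0, k, k), M = matrix(0, k, ncol(res$M)),
       m0 = rep(0, k), R = (R2 + t(R2)) / 2, r1 = as.vector(r12), r0 = r02)
}

#' Exact log-likelihood of tip traits by post-order pruning
#'
#' Computes the exact multivariate-normal log-density of the tip data under
#' the model in one post-order pass over the tree (cost linear in the number
#' of tips), propagating the subtree density as a quadratic form in the node
#' state.  Equals the dense log-density implied by [full_joint_moments()] to
#' numerical precision.
#'
#' @param tree a `phylo` object.
#' @param painting a `regime_painting` (or `NULL` for one global regime).
#' @param params a [model_params()] with all linear parameters set
#'   (`theta`, and `x0` where the root policy needs it).
#' @param data tip trait matrix (rownames = tip labels).
#' @param me measurement error: `NULL`, a scalar/vector/matrix applied to
#'   all tips, an [me_spec()], or a `k x k x n_tip` array.
#' @return the log-likelihood (a single number).
#' @export
loglik_pruning <- function(tree, painting = NULL, params, data, me = NULL) {
  check_tree(tree)
  q <- tree_quadratic(tree, painting, params, data, me)
  z <- z_from_params(params)
  if (length(z) != q$layout$p) {
    stop("linear-parameter layout mismatch (z has ", length(z),
         ", expected ", q$layout$p, ")")
  }
  as.numeric(t(z) %*% q$H %*% z + sum(q$h * z) + q$c0)
}

#' Generalized least squares for the mean parameters
#'
#' Conditional on the drift and diffusion parameters, all parameters that
#' enter the mean linearly (optima `theta` per regime, OUBM intercepts
#' `psi`, the root state) have a closed-form GLS solution.  It is obtained
#' from the same pruning pass as the likelihood: the profiled quadratic in
#' the stacked linear parameter vector is maximized exactly.
#'
#' @inheritParams loglik_pruning
#' @param A,Sigma_yy drift matrix and diffusion factor to condition on.
#' @param spec the [model_spec()] defining regimes and root policy.
#' @param Q,Sigma_xx OUBM blocks (when `spec$family == "OUBM"`).
#' @return a list with `theta` (k(y) x n_regimes), `x0`, the stacked
#'   estimate `z`, its covariance matrix `cov` (inverse observed
#'   information), and the profiled log-likelihood `loglik`.
#' @export
gls_linear <- function(tree, painting = NULL, A, Sigma_yy, data, me = NULL,
                       spec, Q = NULL, Sigma_xx = NULL) {
  check_tree(tree)
  params <- model_params(spec, A = if (spec$family == "BM") NULL else A,
                         Sigma_yy = Sigma_yy, Q = Q, Sigma_xx = Sigma_xx)
  q <- tree_quadratic(tree, painting, params, data, me)
  I2 <- -2 * q$H                     # observed information of z
  ok <- tryCatch(rcond(I2) > 1e-14, error = function(e) FALSE)
  if (!ok || !all(is.finite(I2))) {
    stop("GLS design is rank deficient (a regime may paint no branch, or ",
         "the model is unidentifiable on this tree)")
  }
  zhat <- solve(I2, q$h)
  covz <- solve(I2)
  ll <- as.numeric(t(zhat) %*% q$H %*% zhat + sum(q$h * zhat) + q$c0)
  lay <- q$layout
  spec2 <- spec
  theta <- NULL
  if (spec$family != "BM") {
    theta <- matrix(zhat[seq_len(lay$n_theta)], lay$ks, lay$R)
    colnames(theta) <- spec$regimes
  }
  x0 <- recover_root(spec, params, zhat, lay, q$root_regime, theta)
  list(theta = theta, x0 = x0, z = zhat, cov = covz, loglik = ll,
       root_regime = spec$regimes[q$root_regime])
}

recover_root <- function(spec, params, z, lay, rootreg, theta) {
  if (spec$family == "BM") return(z[seq_len(spec$k)])
  if (lay$n_root == 0L) return(theta[, rootreg])
  xr <- z[lay$n_theta + seq_len(lay$n_root)]
  if (spec$family == "OUBM" && spec$root_policy != "free_root") {
    c(theta[, rootreg] + as.vector(params$Q %*% xr), xr)
  } else {
    xr
  }
}

## ---------------------------------------------------------------------------
## dense oracle: the joint tip distribution by explicit path composition

#' Joint tip mean and covariance by brute-force path composition
#'
#' Builds the exact stacked tip mean vector and `n k x n k` covariance of
#' the trait values (tip-major ordering: all traits of tip 1, then tip 2,
#' ...).  Intended as a transparent, quadratic-cost oracle for testing the
#' pruning engine and for small-tree GLS checks; refuses problems larger
#' than `cap` stacked dimensions.
#'
#' @inheritParams loglik_pruning
#' @param cap maximum allowed `n_tips * k`.
#' @return a list with `mean` (length nk), `cov` (nk x nk) and the tip
#'   ordering `tips`.
#' @export
full_joint_moments <- function(tree, painting = NULL, params, me = NULL,
                               cap = 4000) {
  check_tree(tree)
  spec <- params$spec
  js <- joint_system(params)
  k <- nrow(js$A)
  n_tip <- ape::Ntip(tree)
  if (n_tip * k > cap) {
    stop("full_joint_moments is an oracle: n_tips * k = ", n_tip * k,
         " exceeds the cap (", cap, ")")
  }
  regime_idx <- if (is.null(painting)) rep(1L, nrow(tree$edge)) else
    match(as.character(painting), spec$regimes)
  if (anyNA(regime_idx)) stop("painting labels not declared in the spec")
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  rootreg <- root_regime_index(tree, regime_idx)

  x0 <- if (spec$root_policy == "stationary_root") js$theta[, rootreg] else
    effective_root(params, js, rootreg)
  m <- matrix(0, k, n_node)       # marginal state means
  S <- array(0, dim = c(k, k, n_node))  # marginal state covariances
  Fl <- vector("list", n_node)    # F of the branch above each node
  parent <- integer(n_node)
  m[, root] <- x0
  if (spec$root_policy == "stationary_root") {
    S[, , root] <- stationary_covariance(js$A, js$Sigma_factor)
  }
  tr <- ape::reorder.phylo(tree, "cladewise")
  perm <- match(tr$edge[, 2L], tree$edge[, 2L])
  for (i in seq_len(nrow(tr$edge))) {
    par <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    bm <- branch_moments(js$A, js$Sigma_factor,
                         js$theta[, regime_idx[perm[i]]],
                         tr$edge.length[i])
    m[, ch] <- bm$F %*% m[, par] + bm$w
    S[, , ch] <- bm$F %*% S[, , par] %*% t(bm$F) + bm$V
    Fl[[ch]] <- bm$F
    parent[ch] <- par
  }

  ## per-tip products of F from each ancestor down to the tip
  anc_phi <- vector("list", n_tip)
  for (tip in seq_len(n_tip)) {
    phis <- list()
    Phi <- diag(k)
    v <- tip
    while (v != root) {
      Phi <- Phi %*% Fl[[v]]     # note: accumulates tip <- parent chain
      v <- parent[v]
      phis[[as.character(v)]] <- Phi
    }
    phis[[as.character(tip)]] <- diag(k)
    anc_phi[[tip]] <- phis
  }
  mrca_mat <- ape::mrca(tree)

  ME <- as_me_array(me, tree, k)
  mu <- as.vector(m[, seq_len(n_tip)])
  CC <- matrix(0, n_tip * k, n_tip * k)
  for (i in seq_len(n_tip)) {
    ri <- (i - 1L) * k + seq_len(k)
    for (j in i:n_tip) {
      rj <- (j - 1L) * k + seq_len(k)
      a <- if (i == j) i else mrca_mat[i, j]
      Phi_i <- anc_phi[[i]][[as.character(a)]]
      Phi_j <- anc_phi[[j]][[as.character(a)]]
      Cij <- Phi_i %*% S[, , a] %*% t(Phi_j)
      CC[ri, rj] <- Cij
      if (i != j) CC[rj, ri] <- t(Cij)
    }
    CC[ri, ri] <- CC[ri, ri] + ME[, , i]
  }
  list(mean = mu, cov = (CC + t(CC)) / 2, tips = tree$tip.label,
       trait_dim = k)
}

#' Dense-oracle log-likelihood
#'
#' Multivariate-normal log-density of the tip data using the explicit joint
#' covariance from [full_joint_moments()].  Quadratic cost; used to verify
#' [loglik_pruning()].
#'
#' @inheritParams full_joint_moments
#' @param data tip trait matrix.
#' @return the log-likelihood.
#' @export
dense_loglik <- function(tree, painting = NULL, params, data, me = NULL,
                         cap = 4000) {
  fj <- full_joint_moments(tree, painting, params, me = me, cap = cap)
  Y <- trait_data(data, tree)
  y <- as.vector(t(Y))              # tip-major stacking
  U <- chol(fj$cov)
  r <- backsolve(U, y - fj$mean, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi)) - sum(log(diag(U))) - 0.5 * sum(r^2)
}
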