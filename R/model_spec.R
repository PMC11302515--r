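## Model families and structural constraints on the drift matrix A and the
## diffusion factor Sigma.  A mask is a k x k character grid over
## {"0", "+", "?"}: the cell is fixed at zero, constrained positive, or free.
## Eigendecomposable classes ("DecomposablePositive"/"DecomposableReal")
## ignore the grid pattern (all cells vary) and are parameterized through
## eigenvalues and column-normalized eigenvectors.

A_CLASSES <- c("Diagonal", "UpperTriangular", "LowerTriangular",
               "SymmetricPositiveDefinite", "DecomposablePositive",
               "DecomposableReal", "Invertible", "CustomMask")
SIGMA_CLASSES <- c("Diagonal", "UpperTriangular")
ROOT_POLICIES <- c("root_equals_optimum", "free_root", "stationary_root")

#' Structural mask for the drift matrix A
#'
#' @param k trait dimension.
#' @param class one of `"Diagonal"`, `"UpperTriangular"`,
#'   `"LowerTriangular"`, `"SymmetricPositiveDefinite"`,
#'   `"DecomposablePositive"`, `"DecomposableReal"`, `"Invertible"`,
#'   `"CustomMask"`.
#' @param grid optional k x k character matrix over `"0"`, `"+"`, `"?"`;
#'   required for `"CustomMask"`, derived from the class otherwise.
#' @param positive_diagonal force the diagonal of A to be positive.  For the
#'   grid-based classes this turns diagonal cells into `"+"` cells; for the
#'   decomposable classes the diagonal is exponentiated after the matrix is
#'   reconstructed from its eigendecomposition parametrization.
#' @return an object of class `"a_mask"`.
#' @export
a_mask <- function(k, class = "CustomMask", grid = NULL,
                   positive_diagonal = TRUE) {
  class <- match.arg(class, A_CLASSES)
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  full <- matrix("?", k, k)
  base_grid <- switch(class,
    Diagonal = { g <- matrix("0", k, k); diag(g) <- "?"; g },
    UpperTriangular = { g <- matrix("0", k, k); g[upper.tri(g, diag = TRUE)] <- "?"; g },
    LowerTriangular = { g <- matrix("0", k, k); g[lower.tri(g, diag = TRUE)] <- "?"; g },
    SymmetricPositiveDefinite = full,
    DecomposablePositive = full,
    DecomposableReal = full,
    Invertible = full,
    CustomMask = {
      if (is.null(grid)) stop("'CustomMask' requires an explicit 'grid'")
      full
    })
  if (!is.null(grid)) {
    grid <- as.matrix(grid)
    if (!all(dim(grid) == c(k, k))) stop("'grid' must be ", k, " x ", k)
    if (!all(grid %in% c("0", "+", "?"))) {
      stop("'grid' entries must be \"0\", \"+\" or \"?\"")
    }
    if (class %in% c("Diagonal", "UpperTriangular", "LowerTriangular")) {
      if (any(grid != "0" & base_grid == "0")) {
        stop("'grid' is inconsistent with class ", class,
             ": structural zeros must stay \"0\"")
      }
    }
  } else {
    grid <- base_grid
  }
  if (positive_diagonal &&
      !(class %in% c("DecomposablePositive", "DecomposableReal",
                     "SymmetricPositiveDefinite"))) {
    d <- diag(grid)
    d[d == "?"] <- "+"
    diag(grid) <- d
  }
  structure(list(k = k, class = class, grid = grid,
                 positive_diagonal = positive_diagonal),
            class = "a_mask")
}

#' @export
print.a_mask <- function(x, ...) {
  cat("A mask (", x$class, ", k = ", x$k,
      if (x$positive_diagonal) ", positive diagonal" else "", ")\n", sep = "")
  print(x$grid, quote = FALSE)
  invisible(x)
}

## number of varying cells of a grid
n_grid_params <- function(grid) sum(grid != "0")

.diagonal_a_mask <- function(k) a_mask(k, "Diagonal")

#' Model specification: family, dimension, structural constraints
#'
#' A `model_spec` is a hypothesis: a model family (`"BM"`, `"OUOU"` or
#' `"OUBM"`) together with the structural mask on the drift matrix A, the
#' class of the diffusion factor(s), the regime label set switching the
#' optimum, and the root policy.  For OUBM the k traits are partitioned into
#' `ky` responses (OU pull toward an optimum tracking the predictors) and
#' `kx` predictors (Brownian motion); the first `ky` trait columns are the
#' responses.
#'
#' @param family `"BM"`, `"OUOU"` or `"OUBM"`.
#' @param k number of traits.
#' @param a_mask an [a_mask()]; ignored for BM.  Dimension `k` for OUOU,
#'   `ky` for OUBM.
#' @param sigma_class `"Diagonal"` or `"UpperTriangular"` class of the
#'   diffusion factor of the (response) traits.
#' @param sigma_x_class class of the predictor diffusion factor (OUBM only).
#' @param ky,kx response/predictor split (OUBM only; `ky + kx == k`).
#' @param regimes character vector of regime labels (default one global
#'   regime).  BM ignores regimes.
#' @param root_policy `"root_equals_optimum"` (default for OU families),
#'   `"free_root"`, or `"stationary_root"`.  BM always uses a free root.
#' @param name optional model name used in selection tables.
#' @param trait_names optional trait names.
#' @return an object of class `"model_spec"`.
#' @export
model_spec <- function(family = c("OUOU", "BM", "OUBM"), k,
                       a_mask = NULL,
                       sigma_class = "Diagonal",
                       sigma_x_class = "Diagonal",
                       ky = NULL, kx = NULL,
                       regimes = "global",
                       root_policy = "root_equals_optimum",
                       name = NULL, trait_names = NULL) {
  family <- match.arg(family)
  sigma_class <- match.arg(sigma_class, SIGMA_CLASSES)
  sigma_x_class <- match.arg(sigma_x_class, SIGMA_CLASSES)
  root_policy <- match.arg(root_policy, ROOT_POLICIES)
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  if (family == "OUBM") {
    if (is.null(ky) || is.null(kx)) stop("OUBM requires 'ky' and 'kx'")
    ky <- as.integer(ky); kx <- as.integer(kx)
    if (ky < 1L || kx < 1L) stop("OUBM requires ky >= 1 and kx >= 1")
    if (ky + kx != k) stop("ky + kx must equal k")
  } else {
    ky <- k; kx <- 0L
  }
  if (family == "BM") {
    a_mask <- NULL
    regimes <- "global"
    root_policy <- "free_root"
  } else {
    ka <- if (family == "OUBM") ky else k
    if (is.null(a_mask)) a_mask <- .diagonal_a_mask(ka)
    if (!inherits(a_mask, "a_mask")) stop("'a_mask' must be an a_mask object")
    if (a_mask$k != ka) {
      stop("a_mask dimension (", a_mask$k, ") does not match ", ka)
    }
  }
  regimes <- as.character(regimes)
  if (anyDuplicated(regimes)) stop("duplicate regime labels")
  if (is.null(trait_names)) trait_names <- paste0("trait_", seq_len(k))
  if (length(trait_names) != k) stop("'trait_names' must have length k")
  if (is.null(name)) {
    name <- paste0(family, "_", if (family == "BM") "" else a_mask$class,
                   "_S", substr(sigma_class, 1, 1))
  }
  structure(list(family = family, k = k, ky = ky, kx = kx,
                 a_mask = a_mask, sigma_class = sigma_class,
                 sigma_x_class = sigma_x_class,
                 regimes = regimes, root_policy = root_policy,
                 name = name, trait_names = trait_names),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec '", x$name, "': ", x$family, ", k = ", x$k, sep = "")
  if (x$family == "OUBM") cat(" (ky = ", x$ky, ", kx = ", x$kx, ")", sep = "")
  cat("\n  Sigma_yy: ", x$sigma_class, sep = "")
  if (x$family == "OUBM") cat("; Sigma_xx: ", x$sigma_x_class, sep = "")
  cat("\n  regimes: ", paste(x$regimes, collapse = ", "),
      "; root policy: ", x$root_policy, "\n", sep = "")
  if (!is.null(x$a_mask)) print(x$a_mask)
  cat("  dof:", count_dof(x), "\n")
  invisible(x)
}

## number of varying cells of a Sigma factor class
n_sigma_params <- function(class, k) {
  switch(class, Diagonal = k, UpperTriangular = k * (k + 1L) / 2L)
}

#' Count the free parameters (degrees of freedom) of a model specification
#'
#' The count is: varying cells of the A mask (all `k^2` for the
#' eigendecomposable classes, `k(k+1)/2` for symmetric positive definite),
#' plus varying cells of the diffusion factor(s), plus the mean-structure
#' parameters implied by the root policy: `k` per regime for OU families
#' with `root_equals_optimum` (or `stationary_root`), `k` more for a free
#' root; BM counts its diffusion cells plus `k` for the free root; OUBM
#' counts A (`ky x ky` mask), the regression block Q (`ky x kx`, always
#' free), both diffusion factors, `ky` per regime for the optimum intercepts
#' and `kx` for the predictor root state.
#'
#' @param spec a [model_spec()].
#' @return a nonnegative integer.
#' @export
count_dof <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  k <- spec$k
  if (spec$family == "BM") {
    return(n_sigma_params(spec$sigma_class, k) + k)
  }
  m <- spec$a_mask
  n_a <- switch(m$class,
    SymmetricPositiveDefinite = k * (k + 1L) / 2L,
    DecomposablePositive = m$k^2,
    DecomposableReal = m$k^2,
    Invertible = m$k^2,
    n_grid_params(m$grid))
  n_reg <- length(spec$regimes)
  if (spec$family == "OUOU") {
    n_lin <- k * n_reg + if (spec$root_policy == "free_root") k else 0L
    return(n_a + n_sigma_params(spec$sigma_class, k) + n_lin)
  }
  ## OUBM
  n_lin <- spec$ky * n_reg + spec$kx +
    if (spec$root_policy == "free_root") spec$ky else 0L
  n_a + spec$ky * spec$kx +
    n_sigma_params(spec$sigma_class, spec$ky) +
    n_sigma_params(spec$sigma_x_class, spec$kx) + n_lin
}

#' Concrete model parameters
#'
#' A point in parameter space for a given [model_spec()]: the drift matrix
#' `A`, the diffusion factor `Sigma_yy` (instantaneous covariance
#' `Sigma_yy %*% t(Sigma_yy)`), the optimum `theta` (one column per regime;
#' for OUBM these are the intercepts `psi`), the root state `x0`, and for
#' OUBM additionally the regression matrix `Q` (`ky x kx`) and the predictor
#' diffusion factor `Sigma_xx`.
#'
#' @param spec the governing [model_spec()].
#' @param A drift matrix (ignored for BM, stored as zero).
#' @param Sigma_yy diffusion factor of the (response) traits.
#' @param theta optimum matrix `k(y) x n_regimes` (or vector for one regime).
#' @param x0 root state (length `k`); when `NULL` and the policy ties the
#'   root to the optimum it is derived at use time.
#' @param Q,Sigma_xx OUBM blocks.
#' @return an object of class `"model_params"`.
#' @export
model_params <- function(spec, A = NULL, Sigma_yy, theta = NULL, x0 = NULL,
                         Q = NULL, Sigma_xx = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  k <- spec$k
  ka <- if (spec$family == "OUBM") spec$ky else k
  if (spec$family == "BM") {
    A <- matrix(0, k, k)
  } else {
    A <- as.matrix(A)
    if (!all(dim(A) == ka)) stop("'A' must be ", ka, " x ", ka)
    check_mask_conformance(A, spec$a_mask)
  }
  Sigma_yy <- as.matrix(Sigma_yy)
  ks <- if (spec$family == "OUBM") spec$ky else k
  if (!all(dim(Sigma_yy) == ks)) stop("'Sigma_yy' must be ", ks, " x ", ks)
  check_sigma_conformance(Sigma_yy, spec$sigma_class)
  n_reg <- length(spec$regimes)
  if (is.null(theta)) theta <- matrix(0, ks, n_reg)
  theta <- matrix(as.numeric(theta), ks, n_reg)
  colnames(theta) <- spec$regimes
  if (spec$family == "OUBM") {
    Q <- as.matrix(Q)
    if (!all(dim(Q) == c(spec$ky, spec$kx))) {
      stop("'Q' must be ", spec$ky, " x ", spec$kx)
    }
    Sigma_xx <- as.matrix(Sigma_xx)
    if (!all(dim(Sigma_xx) == spec$kx)) {
      stop("'Sigma_xx' must be ", spec$kx, " x ", spec$kx)
    }
    check_sigma_conformance(Sigma_xx, spec$sigma_x_class)
  }
  if (!is.null(x0)) {
    x0 <- as.numeric(x0)
    if (length(x0) != k) stop("'x0' must have length ", k)
  }
  structure(list(spec = spec, A = A, Sigma_yy = Sigma_yy, theta = theta,
                 x0 = x0, Q = Q, Sigma_xx = Sigma_xx),
            class = "model_params")
}

check_mask_conformance <- function(A, mask, tol = 1e-9) {
  if (mask$class %in% c("DecomposablePositive", "DecomposableReal")) {
    if (mask$positive_diagonal) {
      ## the positive diagonal is imposed by exponentiation AFTER the
      ## eigendecomposition reconstruction, so the realized matrix carries
      ## the diagonal constraint, not the eigenvalue one
      if (any(diag(A) <= 0)) {
        stop("A must have a positive diagonal under class ", mask$class,
             " with positive_diagonal")
      }
      return(invisible(TRUE))
    }
    ev <- eigen(A, only.values = TRUE)$values
    if (max(abs(Im(ev))) > 1e-8) {
      stop("A must have real eigenvalues under class ", mask$class)
    }
    if (mask$class == "DecomposablePositive" && any(Re(ev) <= 0)) {
      stop("A must have eigenvalues with positive real part under ",
           "class DecomposablePositive")
    }
    return(invisible(TRUE))
  }
  if (mask$class == "SymmetricPositiveDefinite") {
    if (max(abs(A - t(A))) > tol) stop("A must be symmetric")
    if (any(eigen(A, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
      stop("A must be positive definite")
    }
    return(invisible(TRUE))
  }
  bad0 <- which(mask$grid == "0" & abs(A) > tol, arr.ind = TRUE)
  badp <- which(mask$grid == "+" & A <= 0, arr.ind = TRUE)
  if (nrow(bad0) + nrow(badp)) {
    fmt <- function(ix) paste0("(", ix[, 1], ",", ix[, 2], ")", collapse = " ")
    msg <- c(if (nrow(bad0)) paste("nonzero in zero cells:", fmt(bad0)),
             if (nrow(badp)) paste("nonpositive in positive cells:", fmt(badp)))
    stop("A violates its mask: ", paste(msg, collapse = "; "))
  }
  invisible(TRUE)
}

check_sigma_conformance <- function(S, class, tol = 1e-9) {
  low <- S[lower.tri(S)]
  if (any(abs(low) > tol)) {
    stop("Sigma factor must be upper triangular (class ", class, ")")
  }
  if (class == "Diagonal" && any(abs(S[upper.tri(S)]) > tol)) {
    stop("Sigma factor must be diagonal")
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## pack / unpack: bijection-ish map between a constrained parameter point and
## an unconstrained real vector.  Any real vector unpacks to a
## mask-conforming point (positivity via exp; SPD via a triangular factor
## square; decomposable classes via eigenvalues [exp-mapped for the Positive
## variant] and column-normalized eigenvectors).

pack_grid <- function(A, grid) {
  idx <- which(grid != "0")
  v <- A[idx]
  pos <- grid[idx] == "+"
  v[pos] <- log(v[pos])
  v
}

unpack_grid <- function(v, grid) {
  k <- nrow(grid)
  A <- matrix(0, k, k)
  idx <- which(grid != "0")
  pos <- grid[idx] == "+"
  v[pos] <- exp(pmax(pmin(v[pos], 50), -50))
  A[idx] <- v
  A
}

## upper-triangular factor with exp-mapped diagonal
pack_ut <- function(S, diagonal_only) {
  if (diagonal_only) log(diag(as.matrix(S)))
  else {
    v <- S[upper.tri(S, diag = TRUE)]
    dpos <- which(upper.tri(S, diag = TRUE), arr.ind = TRUE)
    on_diag <- dpos[, 1] == dpos[, 2]
    v[on_diag] <- log(v[on_diag])
    v
  }
}

unpack_ut <- function(v, k, diagonal_only) {
  S <- matrix(0, k, k)
  if (diagonal_only) {
    diag(S) <- exp(pmax(pmin(v, 50), -50))
  } else {
    dpos <- which(upper.tri(S, diag = TRUE), arr.ind = TRUE)
    on_diag <- dpos[, 1] == dpos[, 2]
    v[on_diag] <- exp(pmax(pmin(v[on_diag], 50), -50))
    S[upper.tri(S, diag = TRUE)] <- v
  }
  S
}

## deterministic eigen parametrization for the decomposable classes:
## columns of P normalized to unit length with a positive largest-magnitude
## entry; eigenvalues sorted decreasing on pack.
pack_decomposable <- function(A, positive) {
  e <- eigen(A)
  if (max(abs(Im(e$values))) > 1e-8) {
    stop("A has complex eigenvalues; not representable in a Decomposable class")
  }
  lam <- Re(e$values)
  P <- Re(e$vectors)
  o <- order(lam, decreasing = TRUE)
  lam <- lam[o]; P <- P[, o, drop = FALSE]
  for (j in seq_len(ncol(P))) {
    cj <- P[, j]
    cj <- cj / sqrt(sum(cj^2))
    if (cj[which.max(abs(cj))] < 0) cj <- -cj
    P[, j] <- cj
  }
  if (positive) {
    if (any(lam <= 0)) stop("DecomposablePositive requires positive eigenvalues")
    lam <- log(lam)
  }
  c(lam, as.vector(P))
}

unpack_decomposable <- function(v, k, positive, force_positive_diagonal) {
  lam <- v[seq_len(k)]
  if (positive) lam <- exp(pmin(lam, 50))
  P <- matrix(v[k + seq_len(k * k)], k, k)
  nrm <- sqrt(colSums(P^2))
  nrm[nrm < 1e-12] <- 1
  P <- sweep(P, 2, nrm, "/")
  penalty <- 0
  rc <- tryCatch(rcond(P), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-8) {
    ## near-singular eigenvector matrix: regularize toward identity and
    ## report a penalty the optimizer can use to steer away
    penalty <- 1e6 * (1e-8 - min(rc, 1e-8)) / 1e-8 + 1e4
    P <- P + diag(1e-4, k)
  }
  A <- P %*% (lam * solve(P))
  if (force_positive_diagonal) {
    ## exp applied to the diagonal AFTER reconstruction from the
    ## eigendecomposition parametrization
    diag(A) <- exp(pmax(pmin(diag(A), 50), -50))
  }
  attr(A, "penalty") <- penalty
  A
}

pack_a <- function(A, mask) {
  switch(mask$class,
    SymmetricPositiveDefinite = {
      U <- chol(A)
      pack_ut(U, diagonal_only = FALSE)
    },
    DecomposablePositive = {
      if (mask$positive_diagonal) {
        A2 <- A; diag(A2) <- log(diag(A2))
        ## invert the post-hoc exp on the diagonal before eigen-packing
        pack_decomposable(A2, positive = TRUE)
      } else pack_decomposable(A, positive = TRUE)
    },
    DecomposableReal = {
      if (mask$positive_diagonal) {
        A2 <- A; diag(A2) <- log(diag(A2))
        pack_decomposable(A2, positive = FALSE)
      } else pack_decomposable(A, positive = FALSE)
    },
    Invertible = as.vector(A),
    pack_grid(A, mask$grid))
}

unpack_a <- function(v, mask) {
  k <- mask$k
  switch(mask$class,
    SymmetricPositiveDefinite = {
      U <- unpack_ut(v, k, diagonal_only = FALSE)
      A <- crossprod(U)
      attr(A, "penalty") <- 0
      A
    },
    DecomposablePositive = unpack_decomposable(
      v, k, positive = TRUE,
      force_positive_diagonal = mask$positive_diagonal),
    DecomposableReal = unpack_decomposable(
      v, k, positive = FALSE,
      force_positive_diagonal = mask$positive_diagonal),
    Invertible = {
      A <- matrix(v, k, k)
      attr(A, "penalty") <- 0
      A
    },
    {
      A <- unpack_grid(v, mask$grid)
      attr(A, "penalty") <- 0
      A
    })
}

n_pack_a <- function(mask) {
  k <- mask$k
  switch(mask$class,
    SymmetricPositiveDefinite = k * (k + 1L) / 2L,
    DecomposablePositive = k + k * k,
    DecomposableReal = k + k * k,
    Invertible = k * k,
    n_grid_params(mask$grid))
}

## Structural packing used by the optimizer: A cells (for OUBM, the compound
## B = -A Q occupies ky*kx free slots and Q is recovered as -solve(A) %*% B),
## then the Sigma factor(s).  Linear (GLS-profiled) parameters are appended
## only when include_linear = TRUE.
pack_structural <- function(params, spec) {
  out <- numeric(0)
  if (spec$family != "BM") out <- pack_a(params$A, spec$a_mask)
  if (spec$family == "OUBM") {
    B <- -params$A %*% params$Q
    out <- c(out, as.vector(B))
  }
  ks <- if (spec$family == "OUBM") spec$ky else spec$k
  out <- c(out, pack_ut(params$Sigma_yy, spec$sigma_class == "Diagonal"))
  if (spec$family == "OUBM") {
    out <- c(out, pack_ut(params$Sigma_xx, spec$sigma_x_class == "Diagonal"))
  }
  out
}

unpack_structural <- function(v, spec) {
  pos <- 0L
  take <- function(n) {
    out <- v[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  penalty <- 0
  A <- NULL; Q <- NULL; Sigma_xx <- NULL
  if (spec$family != "BM") {
    A <- unpack_a(take(n_pack_a(spec$a_mask)), spec$a_mask)
    penalty <- penalty + attr(A, "penalty")
    attr(A, "penalty") <- NULL
  } else {
    A <- matrix(0, spec$k, spec$k)
  }
  if (spec$family == "OUBM") {
    B <- matrix(take(spec$ky * spec$kx), spec$ky, spec$kx)
    Q <- tryCatch(-solve(A, B), error = function(e) NULL)
    if (is.null(Q)) {
      Q <- matrix(0, spec$ky, spec$kx)
      penalty <- penalty + 1e6
    }
  }
  ks <- if (spec$family == "OUBM") spec$ky else spec$k
  Sigma_yy <- unpack_ut(take(n_sigma_params(spec$sigma_class, ks)), ks,
                        spec$sigma_class == "Diagonal")
  if (spec$family == "OUBM") {
    Sigma_xx <- unpack_ut(take(n_sigma_params(spec$sigma_x_class, spec$kx)),
                          spec$kx, spec$sigma_x_class == "Diagonal")
  }
  if (pos != length(v)) stop("packed vector has wrong length (", length(v),
                             ", expected ", pos, ")")
  list(A = A, Sigma_yy = Sigma_yy, Q = Q, Sigma_xx = Sigma_xx,
       penalty = penalty)
}

n_pack_structural <- function(spec) {
  n <- 0L
  if (spec$family != "BM") n <- n + n_pack_a(spec$a_mask)
  ks <- if (spec$family == "OUBM") spec$ky else spec$k
  n <- n + n_sigma_params(spec$sigma_class, ks)
  if (spec$family == "OUBM") {
    n <- n + spec$ky * spec$kx +
      n_sigma_params(spec$sigma_x_class, spec$kx)
  }
  n
}

#' Map model parameters to an unconstrained real vector and back
#'
#' `pack` serializes a mask-conforming [model_params()] into a real vector;
#' `unpack` reconstructs parameters from any real vector such that every
#' mask constraint holds by construction (positive cells via the exponential
#' map, symmetric positive definite matrices via a triangular-factor square,
#' the eigendecomposable classes via an eigenvalue/eigenvector
#' parametrization with eigenvalues exp-mapped for the `Positive` variant).
#' For OUBM the packed slots hold the compound `B = -A %*% Q`, which is what
#' the numerical optimization estimates directly; `Q` is recovered as
#' `-solve(A) %*% B`.
#'
#' The layout is: structural block (A cells, OUBM `B`, diffusion factors)
#' followed, when `include_linear = TRUE`, by the linear mean parameters
#' (`theta` per regime and, for a free root or OUBM, the root state).
#'
#' @param params a [model_params()].
#' @param spec its [model_spec()].
#' @param v a real vector of the correct length.
#' @param include_linear append/recover `theta` and the root state.
#' @return `pack`: a numeric vector; `unpack`: a [model_params()] (with
#'   attribute `"penalty"` used internally to steer the optimizer away from
#'   near-singular eigenvector matrices).
#' @export
pack <- function(params, spec = params$spec, include_linear = TRUE) {
  stopifnot(inherits(params, "model_params"))
  out <- pack_structural(params, spec)
  if (include_linear) {
    out <- c(out, as.vector(params$theta))
    if (needs_packed_root(spec)) {
      x0 <- params$x0
      if (is.null(x0)) x0 <- rep(0, root_pack_len(spec))
      out <- c(out, x0[seq_len(root_pack_len(spec))])
    }
  }
  out
}

needs_packed_root <- function(spec) {
  spec$family == "BM" || spec$root_policy == "free_root" ||
    spec$family == "OUBM"
}

root_pack_len <- function(spec) {
  if (spec$family == "BM") return(spec$k)
  if (spec$family == "OUBM") {
    ## predictor root always free; response root free only under free_root
    if (spec$root_policy == "free_root") return(spec$k)
    return(spec$kx)
  }
  if (spec$root_policy == "free_root") spec$k else 0L
}

#' @rdname pack
#' @export
unpack <- function(v, spec, include_linear = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  ns <- n_pack_structural(spec)
  st <- unpack_structural(v[seq_len(ns)], spec)
  pos <- ns
  ks <- if (spec$family == "OUBM") spec$ky else spec$k
  n_reg <- length(spec$regimes)
  theta <- matrix(0, ks, n_reg)
  x0 <- NULL
  if (include_linear) {
    theta <- matrix(v[pos + seq_len(ks * n_reg)], ks, n_reg)
    pos <- pos + ks * n_reg
    nr <- root_pack_len(spec)
    if (nr > 0L) {
      xr <- v[pos + seq_len(nr)]
      pos <- pos + nr
      x0 <- assemble_root(spec, st, theta, xr)
    } else {
      x0 <- assemble_root(spec, st, theta, numeric(0))
    }
    if (pos != length(v)) {
      stop("packed vector has wrong length (", length(v), ", expected ",
           pos, ")")
    }
  }
  p <- model_params(spec, A = if (spec$family == "BM") NULL else st$A,
                    Sigma_yy = st$Sigma_yy, theta = theta, x0 = x0,
                    Q = st$Q, Sigma_xx = st$Sigma_xx)
  attr(p, "penalty") <- st$penalty
  p
}

## Full root state implied by policy + packed root block.
## OUOU root_equals_optimum: x0 = theta of the first (root) regime.
## OUBM root_equals_optimum: x0 = (psi_root + Q x0x, x0x).
assemble_root <- function(spec, st, theta, xr) {
  if (spec$family == "BM") return(as.numeric(xr))
  if (spec$root_policy == "free_root") {
    if (spec$family == "OUBM") return(as.numeric(xr))
    return(as.numeric(xr))
  }
  if (spec$family == "OUBM") {
    x0x <- as.numeric(xr)
    c(theta[, 1L] + as.vector(st$Q %*% x0x), x0x)
  } else {
    theta[, 1L]
  }
}
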