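## Exact simulation of trait values at the tips of a tree under any model
## parameters, plus Gaussian measurement-error corruption and packaged
## study-dataset generation.  Simulation is exact (no Euler stepping): each
## branch draws child = F parent + w + eps with eps ~ N(0, V) from the
## closed-form OU transition.

## matrix square root tolerant of PSD rank deficiency
psd_sqrt <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Simulate tip trait values on a tree
#'
#' Pre-order recursion over the tree: the root state is set by the root
#' policy (`x0`, the root-regime optimum, or a draw from the stationary
#' distribution), and each branch adds the exact OU transition
#' `child = F parent + w + eps`, `eps ~ N(0, V)`, with `(F, w, V)` from
#' [branch_moments()] using the branch's regime optimum.  A fixed seed gives
#' bit-identical output.
#'
#' @inheritParams loglik_pruning
#' @param seed optional integer seed (RNG state restored on exit).
#' @return tip trait matrix (rows `tree$tip.label`, columns trait names).
#' @export
simulate_traits <- function(tree, painting = NULL, params, seed = NULL) {
  check_tree(tree)
  spec <- params$spec
  js <- joint_system(params)
  k <- nrow(js$A)
  regime_idx <- if (is.null(painting)) rep(1L, nrow(tree$edge)) else
    match(as.character(painting), spec$regimes)
  if (anyNA(regime_idx)) stop("painting labels not declared in the spec")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  rootreg <- root_regime_index(tree, regime_idx)
  if (spec$root_policy == "stationary_root") {
    ev <- eigen(js$A, only.values = TRUE)$values
    if (any(Re(ev) <= 0)) {
      stop("stationary_root requires a stable drift matrix ",
           "(all eigenvalues with positive real part)")
    }
    S0 <- stationary_covariance(js$A, js$Sigma_factor)
    x0 <- js$theta[, rootreg] + as.vector(psd_sqrt(S0) %*% stats::rnorm(k))
  } else {
    x0 <- effective_root(params, js, rootreg)
  }

  n_node <- n_tip + tree$Nnode
  state <- matrix(0, k, n_node)
  state[, root] <- x0
  tr <- ape::reorder.phylo(tree, "cladewise")
  perm <- match(tr$edge[, 2L], tree$edge[, 2L])
  plan <- ou_eigen_plan(js$A, tcrossprod(js$Sigma_factor))
  Ik <- diag(k)
  for (i in seq_len(nrow(tr$edge))) {
    par <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    t_b <- tr$edge.length[i]
    if (t_b == 0) {
      state[, ch] <- state[, par]
      next
    }
    fm <- plan_moments(plan, t_b)
    w <- (Ik - fm$F) %*% js$theta[, regime_idx[perm[i]]]
    state[, ch] <- fm$F %*% state[, par] + w +
      psd_sqrt(fm$V) %*% stats::rnorm(k)
  }
  out <- t(state[, seq_len(n_tip), drop = FALSE])
  rownames(out) <- tree$tip.label
  colnames(out) <- if (!is.null(spec$trait_names) &&
                       length(spec$trait_names) == k) spec$trait_names
                   else paste0("trait_", seq_len(k))
  out
}

#' Corrupt tip traits with Gaussian measurement error
#'
#' Adds an independent `N(0, ME_tip)` draw to every tip row; the per-tip
#' covariance comes from the same specification accepted by
#' [loglik_pruning()] (scalar, vector, matrix, [me_spec()], or array).
#'
#' @param data tip trait matrix (rownames = tip labels).
#' @param tree the tree the tips belong to.
#' @param me measurement-error specification; each per-tip covariance must
#'   be positive semidefinite.
#' @param seed optional integer seed.
#' @return the corrupted trait matrix.
#' @export
add_measurement_error <- function(data, tree, me, seed = NULL) {
  data <- trait_data(data, tree)
  k <- ncol(data)
  ME <- as_me_array(me, tree, k)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  for (i in seq_len(nrow(data))) {
    M <- ME[, , i]
    if (any(M != 0)) {
      data[i, ] <- data[i, ] + as.vector(psd_sqrt(M) %*% stats::rnorm(k))
    }
  }
  data
}

#' Generate a complete synthetic study dataset
#'
#' Bundles the two halves of the synthetic-data generator: a pure-birth
#' tree rescaled to unit height (or a user-supplied fixed tree), exact
#' trait simulation under the configured model, and optional
#' measurement-error corruption.  All ingredients (tree, painting, true
#' parameters, seeds) are returned so parameter recovery can be scored.
#'
#' @param config a list with elements
#'   \describe{
#'     \item{spec}{a [model_spec()] (required).}
#'     \item{params}{a [model_params()] (required; the generator never
#'       invents effect sizes silently).}
#'     \item{n_tips}{tip count for the pure-birth tree (ignored when
#'       `tree` is supplied).}
#'     \item{tree, painting}{optional fixed tree/painting.}
#'     \item{birth_rate}{pure-birth rate (default 1).}
#'     \item{me}{optional measurement-error specification.}
#'   }
#' @param seed integer master seed; tree, traits and measurement error use
#'   derived substreams so each ingredient is independently reproducible.
#' @return a list with `tree`, `painting`, `data` (corrupted when `me` is
#'   set), `data_clean`, `params`, `me` and `seed`.
#' @export
generate_study_dataset <- function(config, seed) {
  stopifnot(is.list(config), inherits(config$spec, "model_spec"),
            inherits(config$params, "model_params"))
  if (missing(seed)) stop("a seed is required for a study dataset")
  tree <- config$tree
  if (is.null(tree)) {
    if (is.null(config$n_tips)) stop("config needs 'n_tips' or a 'tree'")
    tree <- simulate_pure_birth(config$n_tips,
                                birth_rate = config$birth_rate %||% 1,
                                seed = derive_seed(seed, 1L))
    tree <- rescale_to_unit_height(tree)
  }
  painting <- config$painting
  if (is.null(painting)) {
    painting <- uniform_painting(tree, label = config$spec$regimes[1L])
  }
  data_clean <- simulate_traits(tree, painting, config$params,
                                seed = derive_seed(seed, 2L))
  data <- data_clean
  if (!is.null(config$me)) {
    data <- add_measurement_error(data_clean, tree, config$me,
                                  seed = derive_seed(seed, 3L))
  }
  list(tree = tree, painting = painting, data = data,
       data_clean = data_clean, params = config$params, me = config$me,
       seed = seed)
}

## deterministic substream seeds below 2^31 derived from a master seed
derive_seed <- function(master, index) {
  (as.numeric(master) * 48271 + as.numeric(index) * 104729) %% 2147483647
}
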