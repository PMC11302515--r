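#' Small-sample Akaike information criterion (AICc)
#'
#' `AICc = -2 loglik + 2 dof + 2 dof (dof + 1) / (n_obs - dof - 1)`.
#' The observation count convention throughout the package is
#' `n_obs = n_tips * n_traits` (every trait value at every tip counts as an
#' observation).  The correction is undefined when `n_obs <= dof + 1`.
#'
#' @param loglik maximized log-likelihood.
#' @param dof number of free parameters.
#' @param n_obs number of observations.
#' @return the AICc value.
#' @export
aicc <- function(loglik, dof, n_obs) {
  if (dof < 1 || dof != round(dof)) stop("'dof' must be a positive integer")
  if (n_obs <= dof + 1) {
    stop("AICc undefined: n_obs (", n_obs, ") must exceed dof + 1 (",
         dof + 1, ")")
  }
  -2 * loglik + 2 * dof + 2 * dof * (dof + 1) / (n_obs - dof - 1)
}

new_fit_result <- function(spec, params, loglik, n_obs, starts = NULL,
                           convergence = 0L, seed = NA_integer_,
                           tree_height = 1, note = NULL) {
  dof <- count_dof(spec)
  aic <- if (is.finite(loglik)) {
    tryCatch(aicc(loglik, dof, n_obs), error = function(e) Inf)
  } else Inf
  derived <- NULL
  if (!is.null(params) && spec$family != "BM" && is.finite(loglik)) {
    derived <- tryCatch(derived_quantities(params, tree_height),
                        error = function(e) NULL)
  }
  structure(list(spec = spec, params = params, loglik = loglik, dof = dof,
                 n_obs = n_obs, aicc = aic, derived = derived,
                 starts = starts, convergence = convergence, seed = seed,
                 note = note),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Model fit '", x$spec$name, "' (", x$spec$family, ")\n", sep = "")
  cat(sprintf("  loglik %.4f, dof %d, n_obs %d, AICc %.4f\n",
              x$loglik, x$dof, x$n_obs, x$aicc))
  if (!is.null(x$starts)) {
    cat("  starts:", length(x$starts$loglik), "; loglik spread",
        sprintf("%.4f", x$starts$spread), "\n")
    if (isTRUE(x$starts$spread > 2)) {
      cat("  WARN: log-likelihood spread across starts exceeds 2 units;\n",
          "  consider more starting points\n")
    }
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

## derived block reported with OU fits
derived_quantities <- function(params, tree_height = 1) {
  spec <- params$spec
  hl <- half_lives(params$A, tree_height)
  out <- list(half_lives = hl)
  js <- joint_system(params)
  ev <- eigen(params$A, only.values = TRUE)$values
  if (all(Re(ev) > 0) && spec$family == "OUOU") {
    S <- stationary_covariance(params$A, params$Sigma_yy)
    out$stationary_covariance <- S
    out$stationary_correlation <- stats::cov2cor(S)
  }
  if (spec$family == "OUBM") {
    out$optimal_regression <- params$Q
    out$evolutionary_regression <- tryCatch(
      regressions(params, t = tree_height), error = function(e) NULL)
  }
  out
}

#' Closed-form maximum likelihood for the Brownian-motion model
#'
#' Without measurement error the BM likelihood has an analytic optimum:
#' the GLS root estimate and the (profiled) maximum-likelihood diffusion
#' `Sigma Sigma' = R' T^-1 R / n` with `T` the shared-path-length tree
#' covariance and `R` the root-centered data (per-trait scalar analogue
#' under a diagonal diffusion class).  With measurement error the closed
#' form no longer applies and the generic numerical fit is used.  A
#' singular tree covariance is reported as an infinite-AICc failure flag
#' rather than an error.
#'
#' @inheritParams loglik_pruning
#' @param sigma_class `"Diagonal"` or `"UpperTriangular"`.
#' @param n_starts,seed forwarded to [fit()] when measurement error forces
#'   the numerical path.
#' @return a `fit_result`.
#' @export
fit_bm <- function(tree, data, me = NULL, sigma_class = "UpperTriangular",
                   n_starts = 3L, seed = 1L) {
  check_tree(tree)
  spec <- model_spec("BM", k = ncol(as.matrix(data)),
                     sigma_class = sigma_class,
                     trait_names = colnames(as.matrix(data)))
  Y <- trait_data(data, tree)
  n <- nrow(Y); k <- ncol(Y)
  if (!is.null(me)) {
    return(fit(tree, NULL, Y, spec, me = me, n_starts = n_starts,
               seed = seed))
  }
  Tm <- ape::vcv(tree)
  Tm <- Tm[tree$tip.label, tree$tip.label]
  ch <- tryCatch(chol(Tm), error = function(e) NULL)
  if (is.null(ch)) {
    return(new_fit_result(spec, NULL, -Inf, n * k,
                          note = "singular phylogenetic covariance"))
  }
  logdetT <- 2 * sum(log(diag(ch)))
  Tinv1 <- backsolve(ch, backsolve(ch, rep(1, n), transpose = TRUE))
  x0 <- as.vector(crossprod(Y, Tinv1) / sum(Tinv1))
  Rm <- sweep(Y, 2L, x0)
  TinvR <- backsolve(ch, backsolve(ch, Rm, transpose = TRUE))
  S_full <- crossprod(Rm, TinvR) / n
  if (sigma_class == "Diagonal") {
    S_hat <- diag(diag(S_full), k)
  } else {
    S_hat <- S_full
  }
  chS <- tryCatch(chol((S_hat + t(S_hat)) / 2), error = function(e) NULL)
  if (is.null(chS)) {
    return(new_fit_result(spec, NULL, -Inf, n * k,
                          note = "degenerate diffusion estimate"))
  }
  ## matrix-normal log-likelihood at the profiled optimum
  quad <- sum(TinvR * (Rm %*% chol2inv(chS)))
  ll <- -0.5 * (n * k * log(2 * pi) + k * logdetT +
                  n * 2 * sum(log(diag(chS))) + quad)
  Sigma_factor <- chS                      # upper-triangular factor
  if (sigma_class == "Diagonal") Sigma_factor <- diag(sqrt(diag(S_hat)), k)
  params <- model_params(spec, Sigma_yy = Sigma_factor, x0 = x0)
  new_fit_result(spec, params, ll, n * k)
}

## random spec-conforming start in packed structural space
random_start <- function(spec, seed_offset = 0L) {
  n <- n_pack_structural(spec)
  v <- stats::rnorm(n, 0, 0.7)
  if (spec$family != "BM" &&
      spec$a_mask$class %in% c("Diagonal", "UpperTriangular",
                               "LowerTriangular", "CustomMask")) {
    ## bias "+" diagonal cells toward rates of order 1-10 on unit-height trees
    idx <- which(spec$a_mask$grid != "0")
    pos <- spec$a_mask$grid[idx] == "+"
    v[seq_along(idx)][pos] <- stats::rnorm(sum(pos), log(2), 1)
  }
  v
}

#' Maximum-likelihood fit of a model specification
#'
#' Numerical optimization over the packed structural parameters (drift
#' matrix cells under their mask, diffusion factors, and for OUBM the
#' compound `B = -A Q` estimated directly), with every optimum/intercept
#' and the root state profiled out exactly by GLS at each likelihood
#' evaluation.  Multiple starting points are tried (spec-conforming random
#' draws in packed space; optionally one start from a preliminary
#' `DecomposablePositive` fit, and/or user-supplied parameter values); the
#' best is returned and the per-start log-likelihoods are retained, with a
#' warning flag when their spread exceeds 2 units.
#'
#' @inheritParams loglik_pruning
#' @param spec the [model_spec()] to fit.
#' @param n_starts number of random starting points (>= 1).
#' @param seed integer seed controlling the starts (fit is deterministic
#'   given data and seed).
#' @param start optional [model_params()] (or packed numeric vector) used
#'   as an additional starting point.
#' @param preliminary_decomposable seed one start from a preliminary fit
#'   with A in the `DecomposablePositive` class.
#' @param control list: `reltol` (default 1e-8), `maxit` Nelder-Mead
#'   iteration cap (default 2000).
#' @return a `fit_result`; if every start fails, a failure result with
#'   `loglik = -Inf`, infinite AICc and diagnostics in `note`.
#' @export
fit <- function(tree, painting = NULL, data, spec, me = NULL,
                n_starts = 3L, seed = 1L, start = NULL,
                preliminary_decomposable = FALSE, control = list()) {
  check_tree(tree)
  if (spec$family == "BM" && is.null(me)) {
    res <- fit_bm(tree, data, me = NULL, sigma_class = spec$sigma_class)
    res$spec$name <- spec$name
    return(res)
  }
  Y <- trait_data(data, tree)
  n_obs <- nrow(Y) * ncol(Y)
  reltol <- control$reltol %||% 1e-8
  maxit <- control$maxit %||% 500L
  ## coarse simplex stage, then quasi-Newton polish at full tolerance
  nm_reltol <- max(reltol * 100, 1e-6)
  ctx <- make_lik_context(tree, painting, spec, Y, me)

  joint_of <- function(st) {
    if (spec$family == "OUBM") {
      emb <- embed_oubm(st$A, st$Q, matrix(0, spec$ky, length(spec$regimes)),
                        st$Sigma_yy, st$Sigma_xx)
      list(A = emb$A, S = emb$Sigma_factor)
    } else {
      list(A = st$A, S = st$Sigma_yy)
    }
  }
  profiled <- function(st) {
    js <- joint_of(st)
    q <- tryCatch(ctx_quadratic(ctx, js$A, js$S, Q = st$Q),
                  error = function(e) NULL)
    if (is.null(q)) return(NULL)
    I2 <- -2 * q$H
    ok <- tryCatch(all(is.finite(I2)) && rcond(I2) > 1e-14,
                   error = function(e) FALSE)
    if (!ok) return(NULL)
    zhat <- solve(I2, q$h)
    ll <- as.numeric(t(zhat) %*% q$H %*% zhat + sum(q$h * zhat) + q$c0)
    list(loglik = ll, z = zhat, q = q)
  }
  objective <- function(v) {
    st <- tryCatch(unpack_structural(v, spec), error = function(e) NULL)
    if (is.null(st)) return(1e10)
    pr <- profiled(st)
    if (is.null(pr) || !is.finite(pr$loglik)) return(1e10)
    -pr$loglik + st$penalty
  }

  starts <- list()
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(derive_seed(seed, 17L)))
  for (i in seq_len(max(1L, n_starts))) starts[[i]] <- random_start(spec)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  if (!is.null(start)) {
    sv <- if (inherits(start, "model_params")) {
      tryCatch(pack_structural(start, spec), error = function(e) NULL)
    } else as.numeric(start)
    if (!is.null(sv)) starts <- c(list(sv), starts)
  }
  if (preliminary_decomposable && spec$family == "OUOU" &&
      !(spec$a_mask$class %in% c("DecomposablePositive", "DecomposableReal"))) {
    pre_spec <- model_spec("OUOU", k = spec$k,
                           a_mask = a_mask(spec$k, "DecomposablePositive"),
                           sigma_class = spec$sigma_class,
                           regimes = spec$regimes,
                           root_policy = spec$root_policy,
                           name = "preliminary")
    pre <- fit(tree, painting, Y, pre_spec, me = me, n_starts = 2L,
               seed = derive_seed(seed, 23L))
    if (is.finite(pre$loglik)) {
      A0 <- pre$params$A
      A0[spec$a_mask$grid == "0"] <- 0
      d0 <- diag(A0); d0[d0 <= 0] <- 0.5; diag(A0) <- d0
      sv <- tryCatch({
        p0 <- model_params(spec, A = A0, Sigma_yy = pre$params$Sigma_yy)
        pack_structural(p0, spec)
      }, error = function(e) NULL)
      if (!is.null(sv)) starts <- c(starts, list(sv))
    }
  }

  per_start <- lapply(starts, function(v0) {
    f0 <- objective(v0)
    if (f0 >= 1e10) {
      ## nudge a failing start rather than giving up on it
      v0 <- v0 * 0.3
      f0 <- objective(v0)
      if (f0 >= 1e10) return(list(value = Inf, par = v0, conv = 1L))
    }
    o1 <- stats::optim(v0, objective, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = nm_reltol))
    o2 <- tryCatch(
      stats::optim(o1$par, objective, method = "BFGS",
                   control = list(maxit = 200L, reltol = reltol)),
      error = function(e) o1)
    best <- if (o2$value <= o1$value) o2 else o1
    list(value = best$value, par = best$par, conv = best$convergence)
  })
  vals <- vapply(per_start, `[[`, numeric(1), "value")
  if (!any(is.finite(vals))) {
    return(new_fit_result(spec, NULL, -Inf, n_obs,
                          starts = list(loglik = -vals, spread = NA_real_),
                          convergence = 1L, seed = seed,
                          note = "all starts failed"))
  }
  ibest <- which.min(vals)
  vbest <- per_start[[ibest]]$par
  st <- unpack_structural(vbest, spec)
  g <- gls_linear(tree, painting, A = st$A, Sigma_yy = st$Sigma_yy,
                  data = Y, me = me, spec = spec, Q = st$Q,
                  Sigma_xx = st$Sigma_xx)
  params <- model_params(spec, A = if (spec$family == "BM") NULL else st$A,
                         Sigma_yy = st$Sigma_yy, theta = g$theta,
                         x0 = g$x0, Q = st$Q, Sigma_xx = st$Sigma_xx)
  ll_starts <- -vals
  spread <- diff(range(ll_starts[is.finite(ll_starts)]))
  if (is.finite(spread) && spread > 2) {
    warning("log-likelihood spread across starts is ",
            sprintf("%.2f", spread),
            " units; run more starting points/seeds", call. = FALSE)
  }
  res <- new_fit_result(spec, params, g$loglik, n_obs,
                        starts = list(loglik = ll_starts, spread = spread,
                                      packed = vbest),
                        convergence = per_start[[ibest]]$conv, seed = seed,
                        tree_height = tree_height(tree))
  res$gls <- g[c("z", "cov", "root_regime")]
  res
}

## scalar summary vector of a fit used by the bootstrap
fit_scalar_summary <- function(fitres) {
  p <- fitres$params
  out <- c()
  if (!is.null(p$theta)) {
    th <- as.vector(p$theta)
    names(th) <- paste0("theta_", seq_along(th))
    out <- c(out, th)
  }
  if (!is.null(p$x0)) {
    x0 <- p$x0
    names(x0) <- paste0("x0_", seq_along(x0))
    out <- c(out, x0)
  }
  if (fitres$spec$family != "BM") {
    hl <- fitres$derived$half_lives$percent_tree_height
    names(hl) <- paste0("half_life_pct_", seq_along(hl))
    out <- c(out, hl)
    a <- as.vector(p$A)
    names(a) <- paste0("A_", rep(seq_len(nrow(p$A)), ncol(p$A)), "_",
                       rep(seq_len(ncol(p$A)), each = nrow(p$A)))
    out <- c(out, a)
  }
  if (!is.null(p$Q)) {
    q <- as.vector(p$Q)
    names(q) <- paste0("Q_", seq_along(q))
    out <- c(out, q)
  }
  s <- as.vector(tcrossprod(p$Sigma_yy))
  names(s) <- paste0("SigSig_", seq_along(s))
  c(out, s)
}

#' Parametric bootstrap confidence intervals
#'
#' Simulates `reps` datasets from the fitted parameters on the same tree
#' (and painting, and measurement error), refits the same specification to
#' each, and returns marginal 2.5% and 97.5% quantiles of every reported
#' scalar (optima, root state, half-lives, drift cells, OUBM regression,
#' diffusion covariance cells).  Replicates whose refit fails numerically
#' are excluded and counted.
#'
#' @param fitres a converged `fit_result` from [fit()].
#' @inheritParams fit
#' @param reps number of bootstrap replicates.
#' @param n_starts starts per refit (refits also start from the fitted
#'   parameters themselves).
#' @return a list with `intervals` (matrix: rows = scalars, columns
#'   `lower`/`upper`), `estimates` (point values), `n_failed`, `reps`.
#' @export
parametric_bootstrap <- function(fitres, tree, painting = NULL, me = NULL,
                                 reps = 200L, seed = 1L, n_starts = 1L) {
  if (!is.finite(fitres$loglik)) stop("cannot bootstrap a failed fit")
  spec <- fitres$spec
  est <- fit_scalar_summary(fitres)
  sims <- matrix(NA_real_, reps, length(est),
                 dimnames = list(NULL, names(est)))
  n_failed <- 0L
  start_par <- fitres$starts$packed
  for (b in seq_len(reps)) {
    dat_b <- simulate_traits(tree, painting, fitres$params,
                             seed = derive_seed(seed, b))
    if (!is.null(me)) {
      dat_b <- add_measurement_error(dat_b, tree, me,
                                     seed = derive_seed(seed, reps + b))
    }
    fit_b <- tryCatch(
      suppressWarnings(
        fit(tree, painting, dat_b, spec, me = me, n_starts = n_starts,
            seed = derive_seed(seed, 2L * reps + b), start = start_par)),
      error = function(e) NULL)
    if (is.null(fit_b) || !is.finite(fit_b$loglik)) {
      n_failed <- n_failed + 1L
      next
    }
    sims[b, ] <- fit_scalar_summary(fit_b)
  }
  ok <- stats::complete.cases(sims)
  qs <- apply(sims[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  intervals <- t(qs)
  colnames(intervals) <- c("lower", "upper")
  list(intervals = intervals, estimates = est, n_failed = n_failed,
       reps = reps)
}
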