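#' AICc model selection over a set of candidate specifications
#'
#' Fits every candidate to the same data, ranks by AICc and attaches
#' plausibility bands relative to the best model: `Delta <= 7` plausible,
#' `7 < Delta <= 14` equivocal, `Delta > 14` implausible.  A candidate
#' whose fit fails contributes an infinite-AICc row flagged `failed`;
#' remaining candidates are unaffected.  Exact AICc ties are broken by
#' smaller dof, then lexicographic model name.
#'
#' @inheritParams fit
#' @param specs named list of at least two [model_spec()] objects.
#' @return a `selection_table` data frame (one row per candidate, sorted
#'   ascending by AICc) with columns `model`, `family`, `loglik`, `dof`,
#'   `aicc`, `delta_aicc`, `band`, `failed`; fitted objects in
#'   `attr(, "fits")`.
#' @export
model_select <- function(tree, painting = NULL, data, specs, me = NULL,
                         n_starts = 3L, seed = 1L) {
  if (length(specs) < 2L) stop("model selection needs at least two candidates")
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s) s$name, character(1))
  }
  fits <- lapply(seq_along(specs), function(i) {
    tryCatch(
      suppressWarnings(
        fit(tree, painting, data, specs[[i]], me = me, n_starts = n_starts,
            seed = derive_seed(seed, 1000L + i))),
      error = function(e) {
        new_fit_result(specs[[i]], NULL, -Inf,
                       nrow(as.matrix(data)) * ncol(as.matrix(data)),
                       note = conditionMessage(e))
      })
  })
  names(fits) <- names(specs)
  selection_table(fits)
}

#' Build a selection table from fitted models
#'
#' @param fits named list of `fit_result` objects on the same data.
#' @return a `selection_table` data frame (see [model_select()]).
#' @export
selection_table <- function(fits) {
  df <- data.frame(
    model = names(fits),
    family = vapply(fits, function(f) f$spec$family, character(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    dof = vapply(fits, function(f) f$dof, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    failed = vapply(fits, function(f) !is.finite(f$loglik), logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  o <- order(df$aicc, df$dof, df$model)
  df <- df[o, , drop = FALSE]
  df$delta_aicc <- df$aicc - df$aicc[1L]
  df$band <- aicc_band(df$delta_aicc)
  rownames(df) <- NULL
  df <- df[, c("model", "family", "loglik", "dof", "aicc", "delta_aicc",
               "band", "failed")]
  attr(df, "fits") <- fits[o]
  class(df) <- c("selection_table", "data.frame")
  df
}

#' AICc plausibility band for a difference from the best model
#'
#' @param delta nonnegative AICc difference(s).
#' @return `"plausible"` (`delta <= 7`), `"equivocal"`
#'   (`7 < delta <= 14`) or `"implausible"` (`delta > 14`).
#' @export
aicc_band <- function(delta) {
  out <- ifelse(delta <= 7, "plausible",
                ifelse(delta <= 14, "equivocal", "implausible"))
  out[!is.finite(delta)] <- "implausible"
  out
}

#' Estimation-error metrics for parameter recovery
#'
#' Joint (not entry-by-entry) comparison of a vectorized parameter with its
#' estimate: the squared Euclidean error `(x - xhat)' (x - xhat)`,
#' optionally divided by `x' x` (the relative error).  The relative form is
#' undefined for a zero true parameter (use the Euclidean form for
#' ancestral states and optima at the origin).
#'
#' @param x_true,x_est numeric vectors/matrices of equal length (matrices
#'   are vectorized).
#' @param relative divide by the squared norm of the truth.
#' @return a nonnegative scalar.
#' @export
estimation_error <- function(x_true, x_est, relative = FALSE) {
  x <- as.numeric(x_true); xh <- as.numeric(x_est)
  if (length(x) != length(xh)) stop("lengths differ")
  err <- sum((x - xh)^2)
  if (!relative) return(err)
  nrm <- sum(x^2)
  if (nrm == 0) {
    stop("relative error undefined for a zero true parameter; ",
         "use the Euclidean form")
  }
  err / nrm
}

## Eq.-style error summary of a fit of the true spec against the truth
recovery_errors <- function(true_params, fitres) {
  if (!is.finite(fitres$loglik)) return(NULL)
  p <- fitres$params
  out <- list()
  safe_rel <- function(a, b) {
    if (sum(as.numeric(a)^2) == 0) estimation_error(a, b)
    else estimation_error(a, b, relative = TRUE)
  }
  if (true_params$spec$family != "BM") {
    out$A_rel <- safe_rel(true_params$A, p$A)
    out$theta_euc <- estimation_error(true_params$theta, p$theta)
  }
  out$SigSig_rel <- safe_rel(tcrossprod(true_params$Sigma_yy),
                             tcrossprod(p$Sigma_yy))
  if (!is.null(true_params$Q)) {
    out$Q_rel <- safe_rel(true_params$Q, p$Q)
    out$SigSigxx_rel <- safe_rel(tcrossprod(true_params$Sigma_xx),
                                 tcrossprod(p$Sigma_xx))
  }
  x0t <- true_params$x0
  if (!is.null(x0t) && !is.null(p$x0)) {
    out$x0_euc <- estimation_error(x0t, p$x0)
  }
  out
}

#' Simulation-reestimation identifiability study
#'
#' For each tip count in the grid and each replicate: simulate a unit-height
#' pure-birth tree (or reuse a fixed tree), simulate traits under the true
#' model, optionally corrupt with measurement error, fit every candidate,
#' record which candidate attains the strictly smallest AICc, and score
#' parameter recovery of the true specification with the squared
#' Euclidean/relative error metrics.  Replicates in which any required fit
#' fails numerically are discarded, logged and re-drawn until the target
#' count of successes is reached (up to `attempt_cap` draws; the attempt
#' count is reported).
#'
#' @param config a list with elements
#'   \describe{
#'     \item{true_spec, true_params}{the generating model (required).}
#'     \item{candidates}{named list of [model_spec()] to fit (must include
#'       the true model under its own name).}
#'     \item{true_name}{name of the true model among the candidates.}
#'     \item{n_grid}{vector of tip counts.}
#'     \item{reps}{successful replicates per tip count.}
#'     \item{me}{optional measurement-error specification (also used when
#'       simulating).}
#'     \item{tree, painting}{optional fixed tree (used for every n).}
#'     \item{n_starts}{starts per fit (default 2).}
#'     \item{attempt_cap}{maximum draws per tip count (default
#'       `10 * reps`).}
#'     \item{score_recovery}{record recovery errors (default TRUE).}
#'   }
#' @param seed master seed; replicate r at tip count n uses a derived
#'   substream, so failures and redraws are reproducible.
#' @return a `study_result` list: `replicates` (data frame: one row per
#'   replicate x candidate), `errors` (per-replicate recovery errors under
#'   the true spec), `aggregate` (per tip count: `fraction_true_selected`,
#'   tie/failure counts, attempts), and the `config` echo.
#' @export
run_identifiability_study <- function(config, seed) {
  stopifnot(inherits(config$true_spec, "model_spec"),
            inherits(config$true_params, "model_params"),
            is.list(config$candidates), length(config$candidates) >= 1L)
  if (missing(seed)) stop("a seed is required in study mode")
  true_name <- config$true_name %||% config$true_spec$name
  if (!(true_name %in% names(config$candidates))) {
    stop("'candidates' must include the true model under name '",
         true_name, "'")
  }
  n_grid <- config$n_grid %||% ape::Ntip(config$tree)
  reps <- config$reps %||% 20L
  n_starts <- config$n_starts %||% 2L
  attempt_cap <- config$attempt_cap %||% (10L * reps)
  score_recovery <- config$score_recovery %||% TRUE

  rep_rows <- list()
  err_rows <- list()
  agg_rows <- list()
  for (n in n_grid) {
    successes <- 0L
    attempts <- 0L
    ties <- 0L
    while (successes < reps && attempts < attempt_cap) {
      attempts <- attempts + 1L
      rep_seed <- derive_seed(seed, n * 131071 + attempts)
      ds <- generate_study_dataset(
        list(spec = config$true_spec, params = config$true_params,
             n_tips = if (is.null(config$tree)) n else NULL,
             tree = config$tree, painting = config$painting,
             me = config$me),
        seed = rep_seed)
      fits <- lapply(seq_along(config$candidates), function(i) {
        tryCatch(
          suppressWarnings(
            fit(ds$tree, ds$painting, ds$data, config$candidates[[i]],
                me = config$me, n_starts = n_starts,
                seed = derive_seed(rep_seed, i))),
          error = function(e) NULL)
      })
      names(fits) <- names(config$candidates)
      bad <- vapply(fits, function(f) is.null(f) || !is.finite(f$loglik),
                    logical(1))
      if (any(bad)) next                       # discard, log, re-draw
      successes <- successes + 1L
      aic <- vapply(fits, `[[`, numeric(1), "aicc")
      winner <- names(aic)[aic == min(aic)]
      tie <- length(winner) > 1L
      if (tie) ties <- ties + 1L
      sel <- if (tie) NA_character_ else winner
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        n_tips = n, replicate = successes, candidate = names(aic),
        loglik = vapply(fits, `[[`, numeric(1), "loglik"),
        dof = vapply(fits, `[[`, numeric(1), "dof"),
        aicc = aic,
        selected = !tie & names(aic) == (sel %||% ""),
        stringsAsFactors = FALSE, row.names = NULL)
      if (score_recovery) {
        errs <- recovery_errors(config$true_params, fits[[true_name]])
        if (!is.null(errs)) {
          err_rows[[length(err_rows) + 1L]] <- data.frame(
            n_tips = n, replicate = successes,
            parameter = names(errs),
            error = as.numeric(unlist(errs)),
            stringsAsFactors = FALSE, row.names = NULL)
        }
      }
    }
    sel_count <- sum(vapply(rep_rows, function(df) {
      any(df$n_tips == n & df$candidate == true_name & df$selected)
    }, logical(1)))
    agg_rows[[length(agg_rows) + 1L]] <- data.frame(
      n_tips = n, true_model = true_name, reps_target = reps,
      reps_done = successes, attempts = attempts,
      failures = attempts - successes, ties = ties,
      fraction_true_selected = if (successes > 0) sel_count / successes
                               else NA_real_,
      shortfall = successes < reps,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(replicates = do.call(rbind, rep_rows),
                 errors = if (length(err_rows)) do.call(rbind, err_rows)
                          else NULL,
                 aggregate = do.call(rbind, agg_rows),
                 config = config, seed = seed),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Simulation-reestimation study (true model: ",
      x$aggregate$true_model[1L], ")\n", sep = "")
  print(x$aggregate[, c("n_tips", "reps_done", "attempts",
                        "fraction_true_selected")], row.names = FALSE)
  invisible(x)
}
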