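#' Measurement-error specification
#'
#' Per-tip observation-noise covariance added to the tip's phylogenetic
#' covariance in the likelihood, and used to corrupt simulated data.  A
#' single `shared` entry (scalar variance, per-trait variance vector, or
#' full covariance matrix) applies to every tip; `per_tip` overrides it for
#' named tips.
#'
#' @param shared scalar, length-k vector, or k x k PSD matrix.
#' @param per_tip optional named list of per-tip entries (same forms).
#' @return an object of class `"me_spec"`.
#' @export
me_spec <- function(shared = NULL, per_tip = NULL) {
  if (is.null(shared) && is.null(per_tip)) {
    stop("an me_spec needs 'shared' and/or 'per_tip' entries")
  }
  if (!is.null(per_tip) && is.null(names(per_tip))) {
    stop("'per_tip' must be a named list (tip label -> covariance)")
  }
  structure(list(shared = shared, per_tip = per_tip), class = "me_spec")
}

#' Pooled within-species variance from replicate measurements
#'
#' When replicate counts per species are too small to estimate a
#' species-specific measurement variance, the within-species variance of
#' each trait is assumed identical across species and estimated as a
#' weighted average of the per-species sample variances.  Species with
#' fewer than two replicates contribute nothing to the average (their
#' sample variance is undefined) but still receive the pooled value when a
#' measurement-error specification is built from it.
#'
#' Weighting conventions: `"sample_size"` weights species `i` by its
#' replicate count `n_i` (the convention used with mericarp-type replicate
#' data); `"df"` weights by `n_i - 1`, the classical pooled-variance
#' estimator.
#'
#' @param reps a named list: species -> numeric matrix of replicates (rows
#'   = replicates, columns = traits), or a data frame with a `species`
#'   column followed by trait columns.
#' @param weighting `"sample_size"` (default) or `"df"`.
#' @return named numeric vector of pooled per-trait variances.
#' @export
pooled_within_species_variance <- function(reps,
                                           weighting = c("sample_size", "df")) {
  weighting <- match.arg(weighting)
  if (is.data.frame(reps)) {
    if (!"species" %in% names(reps)) {
      stop("data-frame input needs a 'species' column")
    }
    sp <- reps$species
    mat <- as.matrix(reps[setdiff(names(reps), "species")])
    reps <- lapply(split(seq_len(nrow(mat)), sp),
                   function(ix) mat[ix, , drop = FALSE])
  }
  if (!length(reps)) stop("no species supplied")
  k <- ncol(as.matrix(reps[[1L]]))
  num <- den <- rep(0, k)
  for (m in reps) {
    m <- as.matrix(m)
    if (ncol(m) != k) stop("inconsistent trait dimension across species")
    n_i <- nrow(m)
    if (n_i < 2L) next
    v_i <- apply(m, 2L, stats::var)
    w_i <- if (weighting == "sample_size") n_i else n_i - 1L
    num <- num + w_i * v_i
    den <- den + w_i
  }
  if (any(den == 0)) {
    stop("no species with >= 2 replicates; cannot pool trait(s): ",
         paste(colnames(as.matrix(reps[[1L]])) %||%
                 seq_len(k), collapse = ", "))
  }
  out <- num / den
  names(out) <- colnames(as.matrix(reps[[1L]])) %||% paste0("trait_", seq_len(k))
  out
}

#' Build a measurement-error specification from pooled variances
#'
#' Assigns the same diagonal measurement-error covariance (the pooled
#' within-species variances) to every tip.  With `divide_by_n`, each tip's
#' variance is divided by its replicate count, i.e. the variance of the
#' species mean rather than of a single measurement.
#'
#' @param pooled nonnegative per-trait variance vector.
#' @param tips tip labels.
#' @param n_replicates optional named vector of per-tip replicate counts
#'   (required when `divide_by_n = TRUE`).
#' @param divide_by_n divide each tip's variances by its replicate count.
#' @return an [me_spec()].
#' @export
me_spec_from_pooled <- function(pooled, tips, n_replicates = NULL,
                                divide_by_n = FALSE) {
  pooled <- as.numeric(pooled)
  if (any(pooled < 0)) stop("pooled variances must be nonnegative")
  if (!divide_by_n) {
    return(me_spec(shared = pooled))
  }
  if (is.null(n_replicates)) {
    stop("'divide_by_n' requires per-tip replicate counts")
  }
  per_tip <- lapply(tips, function(lab) {
    n_i <- n_replicates[[lab]]
    if (is.null(n_i) || is.na(n_i) || n_i < 1) {
      stop("missing replicate count for tip ", lab)
    }
    pooled / n_i
  })
  names(per_tip) <- tips
  me_spec(per_tip = per_tip)
}

#' Sample per-trait measurement-error variances for simulation studies
#'
#' When an identifiability study needs measurement-error variance on
#' simulated trees larger than the empirical study, the per-trait variances
#' are drawn i.i.d.: by default resampled with replacement from a supplied
#' empirical vector (e.g. pooled within-species variances), otherwise from
#' a log-normal distribution with the given log-scale parameters.
#'
#' @param k number of traits.
#' @param empirical optional vector of nonnegative empirical variances to
#'   resample from.
#' @param meanlog,sdlog log-normal parameters used when `empirical` is
#'   `NULL` (defaults: `meanlog = log(0.1)`, `sdlog = 0.5`).
#' @param seed optional integer seed (RNG state restored on exit).
#' @return numeric vector of `k` nonnegative variances.
#' @export
sample_me_variances <- function(k, empirical = NULL, meanlog = log(0.1),
                                sdlog = 0.5, seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  if (!is.null(empirical)) {
    empirical <- as.numeric(empirical)
    if (any(empirical < 0)) stop("empirical variances must be nonnegative")
    return(sample(empirical, k, replace = TRUE))
  }
  stats::rlnorm(k, meanlog = meanlog, sdlog = sdlog)
}

#' Read replicate measurements from CSV
#'
#' Expected layout: a `species` column, an optional `replicate` column
#' (ignored), then numeric trait columns.
#'
#' @param file path to the CSV file.
#' @return named list species -> replicate matrix, as consumed by
#'   [pooled_within_species_variance()].
#' @export
read_replicates_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (!"species" %in% names(df)) stop("replicates CSV needs a 'species' column")
  trait_cols <- setdiff(names(df), c("species", "replicate"))
  mat <- as.matrix(df[trait_cols])
  storage.mode(mat) <- "double"
  lapply(split(seq_len(nrow(mat)), df$species),
         function(ix) mat[ix, , drop = FALSE])
}
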