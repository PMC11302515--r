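#' Read and write tip trait matrices as CSV
#'
#' Layout: header row; first column `tip` holds tip labels, remaining
#' columns are named numeric traits.
#'
#' @param file path of the CSV file.
#' @param data tip trait matrix (rownames = tip labels).
#' @param tree optional tree to validate against on read.
#' @return `read_traits_csv`: a numeric matrix with tip-label rownames.
#' @export
read_traits_csv <- function(file, tree = NULL) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (names(df)[1L] != "tip") stop("traits CSV must start with a 'tip' column")
  mat <- as.matrix(df[-1L])
  storage.mode(mat) <- "double"
  rownames(mat) <- df$tip
  if (!is.null(tree)) mat <- trait_data(mat, tree)
  mat
}

#' @rdname read_traits_csv
#' @export
write_traits_csv <- function(data, file) {
  df <- data.frame(tip = rownames(data), as.data.frame(data),
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Serialize a model specification to JSON and back
#'
#' The JSON object holds: `family`, `traits` (names), `mask` (k x k grid of
#' `"0"`/`"+"`/`"?"` with its `class` and `positive_diagonal` flag),
#' `sigma_class` (and `sigma_x_class`, `ky`, `kx` for OUBM), `regimes`,
#' `root_policy`, `name`.
#'
#' @param spec a [model_spec()].
#' @param file path; `model_spec_to_json` returns the JSON string when
#'   `file` is `NULL`.
#' @return `model_spec_from_json`: a [model_spec()].
#' @export
model_spec_to_json <- function(spec, file = NULL) {
  obj <- list(name = spec$name, family = spec$family,
              traits = spec$trait_names,
              sigma_class = spec$sigma_class,
              regimes = spec$regimes, root_policy = spec$root_policy)
  if (spec$family == "OUBM") {
    obj$ky <- spec$ky; obj$kx <- spec$kx
    obj$sigma_x_class <- spec$sigma_x_class
  }
  if (!is.null(spec$a_mask)) {
    obj$mask <- list(class = spec$a_mask$class,
                     grid = apply(spec$a_mask$grid, 1L, paste, collapse = ""),
                     positive_diagonal = spec$a_mask$positive_diagonal)
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(file)) return(as.character(js))
  writeLines(js, file)
  invisible(file)
}

#' @rdname model_spec_to_json
#' @param json a JSON string (or path to a JSON file).
#' @export
model_spec_from_json <- function(json) {
  if (length(json) == 1L && !grepl("{", json, fixed = TRUE) &&
      file.exists(json)) {
    obj <- jsonlite::fromJSON(json)
  } else {
    obj <- jsonlite::fromJSON(paste(json, collapse = "\n"))
  }
  k <- length(obj$traits)
  mask <- NULL
  if (!is.null(obj$mask)) {
    rows <- strsplit(obj$mask$grid, "")
    grid <- do.call(rbind, rows)
    mask <- a_mask(nrow(grid), obj$mask$class, grid = grid,
                   positive_diagonal = isTRUE(obj$mask$positive_diagonal))
  }
  model_spec(obj$family, k = k, a_mask = mask,
             sigma_class = obj$sigma_class,
             sigma_x_class = obj$sigma_x_class %||% "Diagonal",
             ky = obj$ky, kx = obj$kx,
             regimes = obj$regimes, root_policy = obj$root_policy,
             name = obj$name, trait_names = obj$traits)
}

#' Serialize a fit result to JSON
#'
#' Writes the fitted parameters, log-likelihood, dof, AICc, derived
#' quantities (half-lives, stationary covariance, regressions), the
#' per-start log-likelihood table and the seed, so a fit is fully
#' re-inspectable from disk.
#'
#' @param fitres a `fit_result`.
#' @param file path; returns the JSON string when `NULL`.
#' @export
fit_result_to_json <- function(fitres, file = NULL) {
  p <- fitres$params
  obj <- list(
    model = fitres$spec$name, family = fitres$spec$family,
    loglik = fitres$loglik, dof = fitres$dof, n_obs = fitres$n_obs,
    aicc = fitres$aicc, seed = fitres$seed,
    params = if (is.null(p)) NULL else list(
      A = p$A, Sigma_yy = p$Sigma_yy, theta = p$theta, x0 = p$x0,
      Q = p$Q, Sigma_xx = p$Sigma_xx),
    derived = if (is.null(fitres$derived)) NULL else list(
      half_life = fitres$derived$half_lives$half_life,
      half_life_percent = fitres$derived$half_lives$percent_tree_height,
      stationary_covariance = fitres$derived$stationary_covariance,
      optimal_regression = fitres$derived$optimal_regression),
    starts_loglik = fitres$starts$loglik,
    note = fitres$note)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
  if (is.null(file)) return(as.character(js))
  writeLines(js, file)
  invisible(file)
}

#' Write study results as tidy TSV plus an aggregate JSON
#'
#' The replicate table (one row per replicate x candidate) goes to
#' `<stem>_replicates.tsv`, recovery errors (when scored) to
#' `<stem>_errors.tsv`, and the aggregate selection fractions to
#' `<stem>_aggregate.json`.
#'
#' @param study a `study_result` from [run_identifiability_study()].
#' @param stem output path stem (directories created as needed).
#' @return the paths written, invisibly.
#' @export
write_study_tsv <- function(study, stem) {
  stopifnot(inherits(study, "study_result"))
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  paths <- c(replicates = paste0(stem, "_replicates.tsv"),
             aggregate = paste0(stem, "_aggregate.json"))
  utils::write.table(study$replicates, paths[["replicates"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(study$errors)) {
    paths[["errors"]] <- paste0(stem, "_errors.tsv")
    utils::write.table(study$errors, paths[["errors"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  agg <- c(as.list(study$aggregate), list(seed = study$seed))
  writeLines(jsonlite::toJSON(agg, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             paths[["aggregate"]])
  invisible(paths)
}

#' Read a declarative study configuration from YAML
#'
#' Maps a YAML document onto the configuration list consumed by
#' [run_identifiability_study()]: model specs are given inline using the
#' same fields as the JSON serialization, true parameters as numeric
#' matrices/vectors.
#'
#' @param file path to the YAML file.
#' @return a config list (specs instantiated, params built).
#' @export
read_study_config <- function(file) {
  y <- yaml::read_yaml(file)
  build_spec <- function(s) {
    mask <- NULL
    if (!is.null(s$mask)) {
      grid <- do.call(rbind, strsplit(unlist(s$mask$grid), ""))
      mask <- a_mask(nrow(grid), s$mask$class %||% "CustomMask", grid = grid,
                     positive_diagonal = isTRUE(s$mask$positive_diagonal))
    }
    model_spec(s$family, k = s$k, a_mask = mask,
               sigma_class = s$sigma_class %||% "Diagonal",
               sigma_x_class = s$sigma_x_class %||% "Diagonal",
               ky = s$ky, kx = s$kx, regimes = s$regimes %||% "global",
               root_policy = s$root_policy %||% "root_equals_optimum",
               name = s$name)
  }
  true_spec <- build_spec(y$true_model)
  tp <- y$true_model$params
  as_mat <- function(x) if (is.null(x)) NULL else
    do.call(rbind, lapply(x, as.numeric))
  true_params <- model_params(
    true_spec,
    A = as_mat(tp$A),
    Sigma_yy = as_mat(tp$Sigma_yy),
    theta = if (is.null(tp$theta)) NULL else as.numeric(unlist(tp$theta)),
    x0 = if (is.null(tp$x0)) NULL else as.numeric(tp$x0),
    Q = as_mat(tp$Q), Sigma_xx = as_mat(tp$Sigma_xx))
  candidates <- lapply(y$candidates, build_spec)
  names(candidates) <- vapply(candidates, function(s) s$name, character(1))
  list(true_spec = true_spec, true_params = true_params,
       true_name = true_spec$name, candidates = candidates,
       n_grid = as.integer(unlist(y$n_grid)), reps = y$reps %||% 20L,
       n_starts = y$n_starts %||% 2L,
       me = if (is.null(y$me_variance)) NULL else as.numeric(y$me_variance),
       attempt_cap = y$attempt_cap)
}
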