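#' Registry of the eight fruit-trait adaptive hypotheses
#'
#' Eight OUOU model specifications for five fruit traits of the umbellifer
#' genus *Ferula* -- ratio of oil ducts (ROD), mean periderm thickness
#' (MPT), wing area (WA), wing thickness (WTH) and fruit mass (FM) -- each
#' encoding a hypothesis about how the three primary fruit functions
#' (protection: ROD+MPT, dispersal: WA+WTH, provision: FM) influence one
#' another's optima through the structure of the drift matrix A.  Rows and
#' columns of A follow `trait_order`; cell `(i, j) != 0` means trait `j`
#' enters the adaptive pull on trait `i`.
#'
#' \describe{
#'   \item{model 1}{functional allometry: full blocks \{ROD,MPT\} and
#'     \{WA,WTH\}, FM diagonal, FM column affecting all four other traits
#'     (13 varying cells).}
#'   \item{model 2}{parcellation, FM affects dispersal only (11).}
#'   \item{model 3}{parcellation, FM affects protection only (11).}
#'   \item{model 4}{parcellation, modules fully independent (9).}
#'   \item{model 5}{developmental allometry: full block \{ROD,MPT,WTH\},
#'     WA and FM diagonal, FM affects WA (12).}
#'   \item{model 6}{developmental allometry, FM affects \{ROD,MPT,WTH\}
#'     (14).}
#'   \item{model 7}{all traits independent: diagonal A (5).}
#'   \item{model 8}{all traits interacting: full 5x5 A constrained to the
#'     `DecomposablePositive` class (25).}
#' }
#'
#' Diagonal cells are constrained positive throughout.  With a diagonal
#' diffusion factor and one global regime the degrees of freedom are
#' 23, 21, 21, 19, 22, 24, 15 and 35 for models 1-8.
#'
#' @param trait_order trait names in row/column order.
#' @param sigma_class `"Diagonal"` or `"UpperTriangular"` diffusion factor
#'   applied to every model.
#' @param regimes regime label set (default one global regime).
#' @return a named list of 8 [model_spec()] objects (`"model_1"` ...).
#' @export
ferula_model_registry <- function(trait_order = c("ROD", "MPT", "WA", "WTH", "FM"),
                                  sigma_class = "Diagonal",
                                  regimes = "global") {
  stopifnot(length(trait_order) == 5L)
  k <- 5L
  blocks2 <- function() {
    g <- matrix("0", k, k)
    g[1:2, 1:2] <- "?"
    g[3:4, 3:4] <- "?"
    g
  }
  blocks3 <- function() {
    g <- matrix("0", k, k)
    idx <- c(1L, 2L, 4L)          # ROD, MPT, WTH fruit-wall module
    g[idx, idx] <- "?"
    g
  }
  finish <- function(g) {
    diag(g) <- "+"
    g
  }
  grids <- list(
    model_1 = { g <- blocks2(); g[1:4, 5] <- "?"; finish(g) },
    model_2 = { g <- blocks2(); g[3:4, 5] <- "?"; finish(g) },
    model_3 = { g <- blocks2(); g[1:2, 5] <- "?"; finish(g) },
    model_4 = finish(blocks2()),
    model_5 = { g <- blocks3(); g[3L, 5L] <- "?"; finish(g) },
    model_6 = { g <- blocks3(); g[c(1L, 2L, 4L), 5L] <- "?"; finish(g) },
    model_7 = finish(matrix("0", k, k))
  )
  specs <- lapply(names(grids), function(nm) {
    model_spec("OUOU", k = k,
               a_mask = a_mask(k, "CustomMask", grid = grids[[nm]],
                               positive_diagonal = TRUE),
               sigma_class = sigma_class, regimes = regimes,
               root_policy = "root_equals_optimum",
               name = nm, trait_names = trait_order)
  })
  names(specs) <- names(grids)
  specs$model_8 <- model_spec(
    "OUOU", k = k,
    a_mask = a_mask(k, "DecomposablePositive", positive_diagonal = TRUE),
    sigma_class = sigma_class, regimes = regimes,
    root_policy = "root_equals_optimum",
    name = "model_8", trait_names = trait_order)
  specs[paste0("model_", 1:8)]
}
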