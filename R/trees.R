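#' Simulate a pure-birth (Yule) tree conditioned on the number of tips
#'
#' Grows a Yule process forward in time with a constant per-lineage
#' speciation rate: waiting times between speciations are exponential with
#' rate `m * birth_rate` when `m` lineages are extant, and the lineage that
#' splits is chosen uniformly.  Growth stops at the `n_tips`-th speciation
#' (i.e. the tree is cut at the moment the tip count is reached), so the
#' returned tree is ultrametric and binary with exactly `n_tips` tips.
#'
#' The height of the returned tree is random; analyses in this package
#' conventionally rescale it to height 1 with [rescale_to_unit_height()] so
#' that rates and half-lives are comparable across tree sizes.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate per-lineage speciation rate (> 0).
#' @param seed optional integer seed; when supplied the simulation is
#'   reproducible (the seed is set locally, the caller's RNG state is
#'   restored on exit).
#' @return an object of class `"phylo"` (see \pkg{ape}).
#' @seealso [rescale_to_unit_height()]
#' @export
simulate_pure_birth <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (!is.numeric(n_tips) || length(n_tips) != 1L || n_tips < 2 ||
      n_tips != round(n_tips)) {
    stop("'n_tips' must be a single integer >= 2")
  }
  if (!is.numeric(birth_rate) || length(birth_rate) != 1L || birth_rate <= 0) {
    stop("'birth_rate' must be a single positive number")
  }
  n_tips <- as.integer(n_tips)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }

  ## Forward simulation on pendant "open" lineages; each open lineage keeps
  ## the time at which it was born.  At n_tips lineages we stop: open
  ## lineages become tips sharing the final time point (ultrametric cut).
  n_nodes <- 2L * n_tips - 1L
  parent <- integer(n_nodes)         # 0 = root
  birth_time <- numeric(n_nodes)     # time the node (lineage) starts
  root <- 1L
  birth_time[root] <- 0
  open <- root                       # currently extant lineage ids
  next_id <- 2L
  t_now <- 0
  m <- 1L
  while (m < n_tips) {
    t_now <- t_now + stats::rexp(1L, rate = m * birth_rate)
    split <- open[sample.int(m, 1L)]
    c1 <- next_id; c2 <- next_id + 1L; next_id <- next_id + 2L
    parent[c1] <- split; parent[c2] <- split
    birth_time[c1] <- t_now; birth_time[c2] <- t_now
    open <- c(open[open != split], c1, c2)
    m <- m + 1L
  }
  t_end <- t_now + stats::rexp(1L, rate = m * birth_rate)

  ## Convert to ape numbering: tips 1..n, internals n+1..2n-1 (root first).
  is_tip <- rep(TRUE, n_nodes)
  is_tip[parent[parent > 0L]] <- FALSE
  tip_ids <- which(is_tip)
  int_ids <- c(root, setdiff(which(!is_tip), root))
  new_id <- integer(n_nodes)
  new_id[tip_ids] <- seq_len(n_tips)
  new_id[int_ids] <- n_tips + seq_along(int_ids)

  end_time <- numeric(n_nodes)
  end_time[is_tip] <- t_end
  has_child <- which(parent > 0L)
  end_time[parent[has_child]] <- birth_time[has_child]

  child <- which(parent > 0L)
  edge <- cbind(new_id[parent[child]], new_id[child])
  edge_len <- end_time[child] - birth_time[child]

  tr <- list(
    edge = edge,
    edge.length = edge_len,
    Nnode = n_tips - 1L,
    tip.label = paste0("t", seq_len(n_tips))
  )
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Node depths (time from the root) for every node of a tree
#'
#' @param tree a `phylo` object with branch lengths.
#' @return numeric vector indexed by ape node id (tips first).
#' @keywords internal
node_depths <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_node <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_node)
  root <- ape::Ntip(tree) + 1L
  depth[root] <- 0
  for (i in seq_len(nrow(tree$edge))) {
    depth[tree$edge[i, 2L]] <- depth[tree$edge[i, 1L]] + tree$edge.length[i]
  }
  depth
}

#' Tree height (maximum root-to-tip path length)
#'
#' @param tree a `phylo` object with branch lengths.
#' @return a single nonnegative number.
#' @export
tree_height <- function(tree) {
  check_tree(tree)
  max(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

#' Rescale a tree to unit height
#'
#' Divides every branch length by the current height so that the longest
#' root-to-tip path equals 1.  Idempotent; errors on a zero-height tree.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return the rescaled `phylo` object.
#' @export
rescale_to_unit_height <- function(tree) {
  check_tree(tree)
  h <- tree_height(tree)
  if (h <= 0) stop("cannot rescale a tree of height 0")
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks: class `phylo`, branch lengths present and nonnegative, unique tip
#' labels, a single root, positive height.  Zero-length terminal branches are
#' allowed but flagged with a warning because they make the tip-level
#' covariance of an OU increment singular unless measurement error is added.
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly.
#' @export
check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a \"phylo\" object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  n_tip <- ape::Ntip(tree)
  kids <- tree$edge[, 2L]
  if (anyDuplicated(kids)) stop("a node has more than one parent")
  roots <- setdiff(unique(tree$edge[, 1L]), kids)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  term_zero <- tree$edge.length == 0 & kids <= n_tip
  if (any(term_zero)) {
    warning("zero-length terminal branch(es) at tip(s): ",
            paste(tree$tip.label[kids[term_zero]], collapse = ", "),
            " (tip covariance will be singular without measurement error)")
  }
  invisible(tree)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that enforce
#' the package's invariants: branch lengths mandatory, tip labels unique.
#' `read_newick` accepts either a file path or a literal Newick string.
#'
#' @param text a Newick string, or a path to a file containing one.
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL`, `write_newick` returns the string.
#' @return `read_newick`: a `phylo`; `write_newick`: the Newick string
#'   (invisibly when written to a file).
#' @export
read_newick <- function(text) {
  if (length(text) == 1L && !grepl("(", text, fixed = TRUE) &&
      file.exists(text)) {
    tr <- ape::read.tree(file = text)
  } else {
    tr <- ape::read.tree(text = paste(text, collapse = ""))
  }
  if (is.null(tr)) stop("could not parse Newick input")
  if (is.null(tr$edge.length)) {
    stop("Newick input lacks branch lengths (required)")
  }
  if (anyNA(tr$edge.length)) {
    miss <- tr$edge[is.na(tr$edge.length), 2L]
    lab <- ifelse(miss <= ape::Ntip(tr), tr$tip.label[miss],
                  paste0("node_", miss))
    stop("missing branch length above: ", paste(lab, collapse = ", "))
  }
  check_tree(tr)
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, file = NULL) {
  check_tree(tree)
  s <- ape::write.tree(tree, digits = 15)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Paint selective regimes onto the branches of a tree
#'
#' A regime painting assigns one label from a declared label set to every
#' branch; the optimum vector of the OU pull switches with the label.
#' Regimes are constant along a branch and change only at nodes.  Branches
#' are addressed by their child node: a tip label for terminal branches or
#' an integer ape node id for internal ones.
#'
#' @param tree a `phylo` object.
#' @param assignment named character vector, `child (tip label or node id) ->
#'   regime label`; may be `NULL` when a `default` covers the whole tree.
#' @param labels character vector of declared regime labels.
#' @param default optional label applied to branches absent from
#'   `assignment`; when `NULL` every branch must be assigned explicitly.
#' @return an object of class `"regime_painting"`: a character vector with
#'   one label per row of `tree$edge`, with attribute `labels`.
#' @export
paint_regimes <- function(tree, assignment = NULL, labels, default = NULL) {
  check_tree(tree)
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("'labels' must declare at least one regime")
  if (!is.null(default) && !(default %in% labels)) {
    stop("default label '", default, "' is not in the declared label set")
  }
  n_tip <- ape::Ntip(tree)
  kids <- tree$edge[, 2L]
  key <- ifelse(kids <= n_tip, tree$tip.label[kids], as.character(kids))
  out <- rep(NA_character_, length(kids))
  if (!is.null(assignment)) {
    if (is.null(names(assignment))) {
      stop("'assignment' must be a named vector (child -> regime)")
    }
    bad_lab <- setdiff(unname(assignment), labels)
    if (length(bad_lab)) {
      stop("regime label(s) outside the declared set: ",
           paste(bad_lab, collapse = ", "))
    }
    unknown <- setdiff(names(assignment), key)
    if (length(unknown)) {
      stop("assignment refers to unknown branch(es): ",
           paste(unknown, collapse = ", "))
    }
    idx <- match(names(assignment), key)
    out[idx] <- unname(assignment)
  }
  if (anyNA(out)) {
    if (is.null(default)) {
      stop("branch(es) without a regime and no default given: ",
           paste(key[is.na(out)], collapse = ", "))
    }
    out[is.na(out)] <- default
  }
  structure(out, labels = labels, class = "regime_painting")
}

#' One-regime painting covering the whole tree
#'
#' @param tree a `phylo` object.
#' @param label the single regime label (default `"global"`).
#' @return a `regime_painting`.
#' @export
uniform_painting <- function(tree, label = "global") {
  paint_regimes(tree, assignment = NULL, labels = label, default = label)
}

#' Read / write a regime painting as two-column TSV
#'
#' Column 1: child node (tip label or internal node id); column 2: regime
#' label.  Rows may omit branches only when a `default` is supplied.
#'
#' @param tree the tree the painting refers to.
#' @param file path of the TSV file.
#' @param labels declared label set; defaults to the labels present.
#' @param default optional default label for unlisted branches.
#' @param painting a `regime_painting` to write.
#' @return `read_regimes_tsv`: a `regime_painting`.
#' @export
read_regimes_tsv <- function(tree, file, labels = NULL, default = NULL) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          colClasses = "character", col.names = c("child", "regime"))
  assignment <- stats::setNames(df$regime, df$child)
  if (is.null(labels)) labels <- unique(c(df$regime, default))
  paint_regimes(tree, assignment, labels = labels, default = default)
}

#' @rdname read_regimes_tsv
#' @export
write_regimes_tsv <- function(tree, painting, file) {
  n_tip <- ape::Ntip(tree)
  kids <- tree$edge[, 2L]
  key <- ifelse(kids <= n_tip, tree$tip.label[kids], as.character(kids))
  utils::write.table(data.frame(child = key, regime = as.character(painting)),
                     file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

## internal: painting as integer regime index per edge + label set
painting_index <- function(tree, painting) {
  if (is.null(painting)) painting <- uniform_painting(tree)
  labels <- attr(painting, "labels")
  if (is.null(labels)) labels <- unique(as.character(painting))
  if (length(painting) != nrow(tree$edge)) {
    stop("painting length does not match the number of branches")
  }
  list(index = match(as.character(painting), labels), labels = labels)
}
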