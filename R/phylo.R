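#' Parse a Newick string into a phylogenetic tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' `ape` `"phylo"` object, the container used throughout the package. Trees
#' must be rooted for covariance construction, carry branch lengths on every
#' edge, and have unique tip labels.
#'
#' @param text A Newick string (single tree, terminated by `;`).
#' @return An object of class `"phylo"`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick string: ", substr(text, 1L, 60L), call. = FALSE)
  }
  validate_tree(tree)
  tree
}

#' Read trees from a Newick file
#'
#' Reads either a single tree or a multi-tree file (one tree per line, e.g. a
#' posterior sample). Multi-tree files are returned as a `"multiPhylo"` list;
#' all member trees must share an identical tip set.
#'
#' @param path Path to a Newick file.
#' @return A `"phylo"` object, or `"multiPhylo"` if the file holds several
#'   trees.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("no trees could be parsed from ", path, call. = FALSE)
  if (inherits(trees, "multiPhylo")) {
    purrr::walk(trees, validate_tree)
    tips <- lapply(trees, function(t) sort(t$tip.label))
    if (!all(vapply(tips, identical, logical(1), y = tips[[1]]))) {
      stop("trees in ", path, " do not share an identical tip set", call. = FALSE)
    }
  } else {
    validate_tree(trees)
  }
  trees
}

#' Write trees to a Newick file
#'
#' @param tree A `"phylo"` or `"multiPhylo"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    stop("missing branch length on ", sum(is.na(tree$edge.length)), " edge(s)",
         call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  invisible(tree)
}

#' Root-to-tip depths of a tree
#'
#' @param tree A `"phylo"` object.
#' @return Named numeric vector of root-to-tip path lengths, one per tip.
#' @export
tip_depths <- function(tree) {
  nd <- ape::node.depth.edgelength(tree)
  stats::setNames(nd[seq_along(tree$tip.label)], tree$tip.label)
}

#' Is a tree ultrametric?
#'
#' All root-to-tip path sums equal within a relative tolerance.
#'
#' @param tree A `"phylo"` object.
#' @param tol Relative tolerance on the depth spread.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  d <- tip_depths(tree)
  diff(range(d)) <= tol * max(d)
}

# ---- covariance models -------------------------------------------------------

new_covariance_model <- function(family, parameter, matrix) {
  structure(
    list(family = family, parameter = parameter, matrix = matrix),
    class = "covariance_model"
  )
}

#' @export
print.covariance_model <- function(x, ...) {
  par <- if (is.null(x$parameter)) "" else sprintf(" (parameter = %.6g)", x$parameter)
  cat(sprintf("<covariance_model> family = %s%s, %d species\n",
              x$family, par, nrow(x$matrix)))
  invisible(x)
}

transform_families <- c("BM", "lambda", "kappa", "delta", "OU")

#' Default bounds for a branch-length transform parameter
#'
#' Lambda is a signal multiplier in `[0, 1]`; kappa and delta are exponents in
#' `[0, 3]`; the Ornstein-Uhlenbeck rate alpha is positive with an upper bound
#' scaled to tree height so that `alpha * height <= 50` (beyond which the
#' correlation matrix is numerically diagonal).
#'
#' @param family One of `"lambda"`, `"kappa"`, `"delta"`, `"OU"`.
#' @param tree_height Root-to-tip height, used only for the OU upper bound.
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @export
transform_bounds <- function(family, tree_height = 1) {
  switch(family,
    lambda = c(0, 1),
    kappa  = c(0, 3),
    delta  = c(0, 3),
    OU     = c(1e-8, 50 / tree_height),
    stop("family ", family, " has no transform parameter", call. = FALSE)
  )
}

bm_vcv <- function(tree) {
  V <- ape::vcv.phylo(tree)
  ord <- order(rownames(V))
  V[ord, ord, drop = FALSE]
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Builds the species-by-species covariance implied by Brownian evolution on a
#' rooted tree: `V[i, j]` is the root-to-MRCA shared path length of tips `i`
#' and `j`, and `V[i, i]` the root-to-tip depth. Rows and columns are ordered
#' alphabetically by tip label; all downstream joins are by label.
#'
#' @param tree A rooted `"phylo"` object with branch lengths.
#' @return A `"covariance_model"` with `family = "BM"`.
#' @examples
#' phylo_covariance(parse_newick("((A:1,B:1):1,C:2);"))$matrix
#' @export
phylo_covariance <- function(tree) {
  validate_tree(tree)
  new_covariance_model("BM", NULL, bm_vcv(tree))
}

#' Apply a branch-length transformation and build its covariance matrix
#'
#' The four transform families modify the Brownian covariance `V` of the tree:
#' \describe{
#'   \item{lambda}{off-diagonal entries multiplied by `lambda` (phylogenetic
#'     signal; 0 = star phylogeny, 1 = Brownian motion).}
#'   \item{kappa}{every branch length raised to the power `kappa` before `V`
#'     is built; `kappa = 0` makes all branches unit length (speciational
#'     change).}
#'   \item{delta}{every entry of `V` (an MRCA depth) raised elementwise to the
#'     power `delta`, modelling accelerating (`delta > 1`) or decelerating
#'     (`delta < 1`) evolution through time.}
#'   \item{OU}{single-optimum Ornstein-Uhlenbeck covariance,
#'     `V[i, j] = exp(-alpha * d[i, j]) * (1 - exp(-2 * alpha * t[i, j])) /
#'     (2 * alpha)`, with `d` the patristic (tip-to-tip) distance and `t` the
#'     root-to-MRCA depth; as `alpha -> 0` this approaches the Brownian
#'     matrix, and for large `alpha` the correlation decays as
#'     `exp(-alpha * d)` (the Martins-Hansen structure). The variance scale
#'     is absorbed into the residual variance of any model using it.}
#' }
#' `family = "BM"` returns the untransformed covariance and ignores
#' `parameter`.
#'
#' @param tree A rooted `"phylo"` object with branch lengths.
#' @param family One of `"BM"`, `"lambda"`, `"kappa"`, `"delta"`, `"OU"`.
#' @param parameter Transform parameter, within [transform_bounds()] for the
#'   family; ignored for `"BM"`.
#' @return A `"covariance_model"`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' apply_transform(tr, "lambda", 0.5)$matrix
#' @export
apply_transform <- function(tree, family, parameter = NULL) {
  family <- match.arg(family, transform_families)
  validate_tree(tree)
  if (family == "BM") return(new_covariance_model("BM", NULL, bm_vcv(tree)))

  height <- max(tip_depths(tree))
  b <- transform_bounds(family, tree_height = height)
  if (is.null(parameter) || !is.finite(parameter) ||
      parameter < b[1] || parameter > b[2]) {
    stop(sprintf("parameter %s out of bounds [%g, %g] for family %s",
                 format(parameter), b[1], b[2], family), call. = FALSE)
  }

  V <- switch(family,
    lambda = {
      V0 <- bm_vcv(tree)
      d <- diag(V0)
      V0 <- V0 * parameter
      diag(V0) <- d
      V0
    },
    kappa = {
      tk <- tree
      tk$edge.length <- tree$edge.length^parameter
      bm_vcv(tk)
    },
    delta = bm_vcv(tree)^parameter,
    OU = {
      D <- ape::cophenetic.phylo(tree)
      ord <- order(rownames(D))
      D <- D[ord, ord, drop = FALSE]
      ou_cov(bm_vcv(tree), D, parameter)
    }
  )
  new_covariance_model(family, parameter, V)
}

# Single-optimum OU covariance from the BM matrix (MRCA depths) and the
# patristic distance matrix; -expm1 keeps the alpha -> 0 limit stable.
ou_cov <- function(V_bm, D, alpha) {
  exp(-alpha * D) * (-expm1(-2 * alpha * V_bm)) / (2 * alpha)
}

# Cholesky with a small logged ridge fallback for numerically singular cases
# (e.g. zero-length terminal branches). Returns the upper-triangular factor.
chol_with_ridge <- function(V, label = "covariance matrix") {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    ridge <- 1e-10 * mean(diag(V))
    message(sprintf("Cholesky of %s failed; adding ridge %.3g to the diagonal",
                    label, ridge))
    R <- chol(V + diag(ridge, nrow(V)))
  }
  R
}
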