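#' Phylogenetic principal component analysis
#'
#' PCA of a species-level trait table that accounts for phylogenetic
#' nonindependence. With Brownian covariance `V` from the tree, the
#' phylogenetic (GLS) mean is `a = (1' V^-1 1)^-1 1' V^-1 X`, the evolutionary
#' covariance `R = (X - 1a)' V^-1 (X - 1a) / (n - 1)`, and components are the
#' eigenvectors of `R` (covariance mode) or of its correlation rescaling
#' (correlation mode, the default). Scores are the centred (and, in
#' correlation mode, standardised) trait values projected on the
#' eigenvectors. Eigenvectors are sign-oriented so each component's
#' largest-|loading| variable loads positively.
#'
#' @param traits A data frame with a `species` column and numeric trait
#'   columns. Rows with missing values are dropped (listwise) with a message.
#' @param tree A rooted `"phylo"` object whose tips match `traits$species`.
#' @param mode `"correlation"` (default) or `"covariance"`.
#' @param vars Trait columns to analyse; defaults to all numeric columns.
#' @param lambda Optional Pagel's lambda in `[0, 1]` applied to `V` before
#'   the analysis (off-diagonal multiplier); `NULL` (default) uses the plain
#'   Brownian covariance — no transform parameter is estimated within the
#'   PPCA.
#' @return An object of class `"ppca"`: `loadings` (variable x component),
#'   `eigenvalues`, `scores` (tibble with `species` and `PC*` columns),
#'   `retained` (component indices with eigenvalue > 1, the Kaiser
#'   criterion), `mode`, `evolutionary_cov`, `phylo_mean`.
#' @export
phylogenetic_pca <- function(traits, tree,
                             mode = c("correlation", "covariance"),
                             vars = NULL, lambda = NULL) {
  mode <- match.arg(mode)
  traits <- tibble::as_tibble(traits)
  if (!"species" %in% names(traits)) stop("traits needs a `species` column",
                                          call. = FALSE)
  if (is.null(vars)) {
    vars <- names(traits)[vapply(traits, is.numeric, logical(1))]
    vars <- setdiff(vars, "species")
  }
  complete <- stats::complete.cases(traits[vars])
  if (!all(complete)) {
    message(sum(!complete), " species dropped from PPCA (missing trait values)")
    traits <- traits[complete, , drop = FALSE]
  }
  check_species_match(traits$species, tree$tip.label)

  traits <- dplyr::arrange(traits, .data$species)
  V <- if (is.null(lambda)) {
    phylo_covariance(tree)$matrix
  } else {
    apply_transform(tree, "lambda", lambda)$matrix
  }
  V <- V[traits$species, traits$species]
  X <- as.matrix(traits[vars])
  rownames(X) <- traits$species
  n <- nrow(X)

  L <- chol_with_ridge(V, "phylogenetic covariance")
  Vi_X <- backsolve(L, forwardsolve(t(L), X))
  Vi_1 <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  a <- drop(crossprod(Vi_X, rep(1, n))) / sum(Vi_1)
  Xc <- sweep(X, 2, a)
  Vi_Xc <- backsolve(L, forwardsolve(t(L), Xc))
  R <- crossprod(Xc, Vi_Xc) / (n - 1)

  if (mode == "correlation") {
    target <- stats::cov2cor(R)
    Xproj <- sweep(Xc, 2, sqrt(diag(R)), "/")
  } else {
    target <- R
    Xproj <- Xc
  }
  eig <- eigen(target, symmetric = TRUE)
  vectors <- orient_signs(eig$vectors)
  dimnames(vectors) <- list(vars, paste0("PC", seq_along(eig$values)))
  scores <- Xproj %*% vectors

  structure(
    list(
      loadings = vectors,
      eigenvalues = eig$values,
      scores = dplyr::bind_cols(tibble::tibble(species = traits$species),
                                tibble::as_tibble(scores)),
      retained = which(eig$values > 1),
      mode = mode,
      evolutionary_cov = R,
      phylo_mean = a
    ),
    class = "ppca"
  )
}

check_species_match <- function(data_species, tip_labels) {
  only_data <- setdiff(data_species, tip_labels)
  only_tree <- setdiff(tip_labels, data_species)
  if (length(only_data) || length(only_tree)) {
    stop("species mismatch between data and tree.\n",
         "  in data only: ", paste(utils::head(only_data, 10), collapse = ", "),
         if (length(only_data) > 10) " ..." else "", "\n",
         "  in tree only: ", paste(utils::head(only_tree, 10), collapse = ", "),
         if (length(only_tree) > 10) " ..." else "",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' How many components does the Kaiser criterion retain?
#'
#' @param eigenvalues Numeric vector of eigenvalues.
#' @return Integer count of eigenvalues strictly greater than 1.
#' @examples
#' kaiser_retained(c(2.98, 1.82, 1.23, 0.40))
#' @export
kaiser_retained <- function(eigenvalues) {
  sum(eigenvalues > 1)
}

#' @export
print.ppca <- function(x, ...) {
  cat(sprintf("<ppca> mode = %s, %d traits, %d species\n", x$mode,
              nrow(x$loadings), nrow(x$scores)))
  cat("eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = " "),
      "\n")
  cat(length(x$retained), "component(s) retained by the Kaiser criterion\n")
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.ppca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "trait") |>
    tidyr::pivot_longer(-"trait", names_to = "component",
                        values_to = "loading")
}

#' @rdname tidiers
#' @export
glance.ppca <- function(x, ...) {
  tibble::tibble(
    component = colnames(x$loadings),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$eigenvalues / sum(x$eigenvalues),
    retained = seq_along(x$eigenvalues) %in% x$retained
  )
}

#' @export
autoplot.ppca <- function(object, components = c(1, 2), ...) {
  sc <- object$scores
  xs <- paste0("PC", components[1])
  ys <- paste0("PC", components[2])
  ggplot2::ggplot(sc, ggplot2::aes(x = .data[[xs]], y = .data[[ys]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = sprintf("%s (eigenvalue %.2f)", xs, object$eigenvalues[components[1]]),
      y = sprintf("%s (eigenvalue %.2f)", ys, object$eigenvalues[components[2]])
    )
}
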