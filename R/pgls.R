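#' Maximum-likelihood generalized least squares
#'
#' Fits `y = X b + e`, `e ~ N(0, sigma2 * V)`, by maximum likelihood via
#' Cholesky whitening (no explicit matrix inversion):
#' `b = (X' V^-1 X)^-1 X' V^-1 y`, `sigma2 = e' V^-1 e / n`, and
#' `logLik = -1/2 [n log(2 pi) + n log(sigma2) + log|V| + n]`.
#'
#' @param y Numeric response vector.
#' @param X Design matrix (including any intercept column), full column rank.
#' @param V Positive-definite error covariance (up to the scale `sigma2`).
#' @return A list: `coefficients` (named by `colnames(X)`), `sigma2` (ML),
#'   `loglik`, `residuals`, `degenerate` (`TRUE` when the residual variance
#'   underflows, i.e. `y` lies in the column span of `X`).
#' @export
gls_fit <- function(y, X, V) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  U <- tryCatch(chol(V), error = function(e) {
    stop("V is not positive definite", call. = FALSE)
  })
  yw <- forwardsolve(t(U), y)
  Xw <- forwardsolve(t(U), X)
  qr_x <- qr(Xw)
  if (qr_x$rank < ncol(Xw)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(Xw)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_x, yw)
  resid_w <- yw - Xw %*% beta
  rss <- sum(resid_w^2)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(U)))
  degenerate <- sigma2 < 1e-12 * max(1, mean(y^2))
  loglik <- if (degenerate) {
    Inf
  } else {
    -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetV + n)
  }
  list(
    coefficients = stats::setNames(drop(beta), colnames(X)),
    sigma2 = sigma2,
    loglik = loglik,
    residuals = drop(y - X %*% beta),
    degenerate = degenerate
  )
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters (design columns + residual
#'   variance + any estimated transform parameter).
#' @param n Sample size (species).
#' @return Numeric AICc value.
#' @examples
#' aicc(0, 2, 10)  # 4 + 12/7
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) {
    stop("AICc undefined: need n - k - 1 > 0 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Build the design matrix for a character vector of terms. Each term is a
# numeric column of `data` or a product `a:b`; the intercept is always first.
model_matrix_terms <- function(data, terms) {
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n))
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    for (p in parts) {
      if (!p %in% names(data)) {
        stop("term component not found in data: ", p, call. = FALSE)
      }
    }
    cols[[tm]] <- Reduce(`*`, lapply(parts, function(p) as.numeric(data[[p]])))
  }
  do.call(cbind, cols)
}

term_vars <- function(terms) {
  unique(unlist(strsplit(terms, ":", fixed = TRUE)))
}

# precompute the pieces each transform family reuses across profile steps
transform_precompute <- function(tree) {
  V <- bm_vcv(tree)
  list(
    tree = tree,
    V = V,
    D = {
      D <- ape::cophenetic.phylo(tree)
      ord <- order(rownames(D))
      D[ord, ord, drop = FALSE]
    },
    height = max(tip_depths(tree))
  )
}

transform_matrix <- function(pre, family, parameter) {
  switch(family,
    BM = pre$V,
    lambda = {
      V <- pre$V * parameter
      diag(V) <- diag(pre$V)
      V
    },
    kappa = {
      tk <- pre$tree
      tk$edge.length <- pre$tree$edge.length^parameter
      bm_vcv(tk)
    },
    delta = pre$V^parameter,
    OU = ou_cov(pre$V, pre$D, parameter)
  )
}

#' Fit a phylogenetic regression with profile-ML transform estimation
#'
#' Fits the mean structure given by `terms` under one branch-length
#' transformation family, simultaneously estimating the transform parameter
#' by profile maximum likelihood: for each candidate parameter the exact GLS
#' solution ([gls_fit()]) is computed, and the parameter is optimised by a
#' 5-point grid initialisation followed by bounded scalar search (tolerance
#' `1e-6`). `family = "BM"` fits the untransformed Brownian covariance and
#' estimates no transform parameter.
#'
#' The parameter count `k` is the number of design columns (intercept
#' included) plus one for the residual variance plus one if a transform
#' parameter is estimated.
#'
#' @param data A data frame with a `species` column, the response and all
#'   term variables. Rows with missing values in the used columns are dropped
#'   (listwise) and `n` reflects the fit actually performed.
#' @param response Name of the response column.
#' @param terms Character vector of predictor terms (column names; interaction
#'   products written `"a:b"`). `character(0)` fits the constant
#'   (intercept-only) model.
#' @param tree A rooted `"phylo"` object; pruned to the species present in
#'   `data`.
#' @param family Covariance family: `"BM"`, `"lambda"`, `"kappa"`, `"delta"`,
#'   `"OU"`.
#' @param bounds Optional length-2 override of the transform-parameter bounds.
#' @param grid_points Number of profile initialisation points (default 5).
#' @param standardize If `TRUE`, non-intercept design columns are scaled to
#'   unit standard deviation so coefficients are comparable across terms;
#'   off by default, leaving coefficients on the log/measurement scales.
#' @return An object of class `"pgls_fit"`: coefficients, `sigma2`,
#'   `transform_estimate` (`NA` for BM), `loglik`, `k`, `n`, `aicc`,
#'   `boundary` flag, plus the response/terms/family labels.
#' @export
fit_pgls <- function(data, response, terms = character(0), tree,
                     family = c("BM", "lambda", "kappa", "delta", "OU"),
                     bounds = NULL, grid_points = 5, standardize = FALSE) {
  family <- match.arg(family)
  data <- tibble::as_tibble(data)
  used <- c(response, term_vars(terms))
  keep <- stats::complete.cases(data[used])
  data <- data[keep, , drop = FALSE]
  data <- dplyr::arrange(data, .data$species)
  extra <- setdiff(data$species, tree$tip.label)
  if (length(extra)) {
    stop("species in data but not in tree: ",
         paste(utils::head(extra, 10), collapse = ", "), call. = FALSE)
  }
  if (length(setdiff(tree$tip.label, data$species))) {
    tree <- ape::keep.tip(tree, data$species)
  }
  X <- model_matrix_terms(data, terms)
  if (standardize && ncol(X) > 1L) {
    sds <- apply(X[, -1L, drop = FALSE], 2, stats::sd)
    sds[sds == 0] <- 1
    X[, -1L] <- sweep(X[, -1L, drop = FALSE], 2, sds, "/")
  }
  y <- as.numeric(data[[response]])
  n <- length(y)
  k <- ncol(X) + 1L + as.integer(family != "BM")
  if (n < k + 2L) stop("too few species (n = ", n, ") for k = ", k,
                       " parameters", call. = FALSE)

  pre <- transform_precompute(tree)
  profile <- function(par) gls_fit(y, X, transform_matrix(pre, family, par))

  if (family == "BM") {
    fit <- profile(NA)
    estimate <- NA_real_
    boundary <- FALSE
  } else {
    b <- if (is.null(bounds)) transform_bounds(family, pre$height) else bounds
    # keep delta/kappa strictly positive so the matrix stays nondegenerate
    lo <- if (family %in% c("kappa", "delta")) max(b[1], 1e-6) else b[1]
    grid <- seq(lo, b[2], length.out = grid_points)
    ll <- vapply(grid, function(p) profile(p)$loglik, numeric(1))
    i <- which.max(ll)
    lower <- grid[max(1L, i - 1L)]
    upper <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(function(p) profile(p)$loglik,
                           lower = lower, upper = upper,
                           maximum = TRUE, tol = 1e-6)
    estimate <- opt$maximum
    # grid endpoints can beat the local search when the optimum sits there
    if (ll[i] > opt$objective) estimate <- grid[i]
    fit <- profile(estimate)
    boundary <- (estimate - b[1]) < 1e-4 * (b[2] - b[1]) ||
      (b[2] - estimate) < 1e-4 * (b[2] - b[1])
  }

  structure(
    list(
      coefficients = fit$coefficients,
      sigma2 = fit$sigma2,
      transform_estimate = estimate,
      loglik = fit$loglik,
      k = k,
      n = n,
      aicc = if (is.finite(fit$loglik)) aicc(fit$loglik, k, n) else -Inf,
      boundary = boundary,
      degenerate = fit$degenerate,
      response = response,
      terms = terms,
      family = family
    ),
    class = "pgls_fit"
  )
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("<pgls_fit> %s ~ %s [%s]\n", x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
              x$family))
  cat(sprintf("  n = %d, k = %d, logLik = %.3f, AICc = %.3f\n",
              x$n, x$k, x$loglik, x$aicc))
  if (!is.na(x$transform_estimate)) {
    cat(sprintf("  transform estimate = %.6f%s\n", x$transform_estimate,
                if (x$boundary) " (boundary)" else ""))
  }
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.pgls_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidiers
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    model = if (length(x$terms)) paste(x$terms, collapse = " + ") else "constant",
    family = x$family,
    transform_estimate = x$transform_estimate,
    sigma2 = x$sigma2,
    loglik = x$loglik,
    k = x$k,
    n = x$n,
    aicc = x$aicc,
    boundary = x$boundary
  )
}

#' Broom-style tidiers and plots
#'
#' `tidy()` returns per-term estimates, `glance()` one-row model summaries,
#' for the package's fitted-object classes (`upper_bound`, `ppca`,
#' `pgls_fit`, `model_set`, `averaged_model`).
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name tidiers
NULL
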