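# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force Brownian covariance: V[i, j] = sum of branch lengths shared by
# the root-to-tip paths of i and j, computed edge by edge from the raw edge
# table.
bf_phylo_cov <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  V <- matrix(0, n, n, dimnames = list(tips, tips))
  n_tip <- length(tree$tip.label)
  # descendant tip set of each edge, by walking down from the edge's child
  desc_tips <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  for (e in seq_len(nrow(tree$edge))) {
    d <- desc_tips(tree$edge[e, 2])
    V[d, d] <- V[d, d] + tree$edge.length[e]
  }
  V
}

# Closed-form OLS
bf_ols <- function(y, X) {
  unname(drop(solve(t(X) %*% X, t(X) %*% y)))
}

# Numeric nearest-point search: minimum Euclidean distance from (x0, y0) to
# the line y = m x + b, signed positive below the line.
bf_line_distance <- function(x0, y0, m, b) {
  obj <- function(x) sqrt((x - x0)^2 + (m * x + b - y0)^2)
  opt <- stats::optimize(obj, interval = c(x0 - 1e5, x0 + 1e5), tol = 1e-10)
  sign(m * x0 + b - y0) * opt$objective
}

# Random tree with uniform branch lengths
random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(n)
  tree$edge.length <- runif(length(tree$edge.length), 0.1, 2)
  tree
}

# fabricate a ranked fits tibble for the multimodel bookkeeping tests
fake_fits <- function(models, terms, aicc, coefs = NULL) {
  w <- exp(-(aicc - min(aicc)) / 2)
  w <- w / sum(w)
  if (is.null(coefs)) {
    coefs <- lapply(terms, function(t) {
      stats::setNames(rep(1, length(t) + 1), c("(Intercept)", t))
    })
  }
  tb <- tibble::tibble(
    model = models, family = "BM", terms = terms,
    fit = lapply(coefs, function(cf) list(coefficients = cf)),
    aicc = aicc, weight = w
  )
  tb <- dplyr::arrange(tb, aicc)
  tb$delta_aicc <- tb$aicc - tb$aicc[1]
  tb
}
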