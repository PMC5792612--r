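#' Morphology composites: body size, beak size and the beak-moment term pair
#'
#' Body size is the mean of the two natural-log body measures (mass, tarsus);
#' beak size the mean of the three natural-log beak measures (length, width,
#' depth). The beak's moment of inertia scales as width x depth x length to an
#' unknown power, so "beak moment" is represented not as a single composite
#' but as the term pair (beak size, log beak length), letting a regression
#' estimate the extra weight of length. Species with a nonpositive measurement
#' are dropped with a message.
#'
#' @param morph A data frame with columns `species`, `mass_g`, `tarsus_mm`,
#'   `beak_length_mm`, `beak_width_mm`, `beak_depth_mm`.
#' @return A tibble with one row per species: `body_size`, `beak_size`,
#'   `log_beak_length` (all on the natural-log scale).
#' @examples
#' morphology_composites(data.frame(
#'   species = "sp1", mass_g = exp(2), tarsus_mm = exp(2),
#'   beak_length_mm = exp(1), beak_width_mm = exp(1), beak_depth_mm = exp(1)
#' ))
#' @export
morphology_composites <- function(morph) {
  required <- c("species", "mass_g", "tarsus_mm", "beak_length_mm",
                "beak_width_mm", "beak_depth_mm")
  missing <- setdiff(required, names(morph))
  if (length(missing)) {
    stop("missing morphology columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  morph <- tibble::as_tibble(morph)
  meas <- as.matrix(morph[required[-1]])
  bad <- apply(!is.finite(meas) | meas <= 0, 1, any)
  if (any(bad)) {
    message(sum(bad), " species dropped (nonpositive morphology measure): ",
            paste(morph$species[bad], collapse = ", "))
    morph <- morph[!bad, , drop = FALSE]
  }
  morph |>
    dplyr::transmute(
      species = .data$species,
      body_size = (log(.data$mass_g) + log(.data$tarsus_mm)) / 2,
      beak_size = (log(.data$beak_length_mm) + log(.data$beak_width_mm) +
                     log(.data$beak_depth_mm)) / 3,
      log_beak_length = log(.data$beak_length_mm)
    ) |>
    dplyr::arrange(.data$species)
}

climate_temperature_vars <- paste0("bio", 1:11)
climate_precipitation_vars <- paste0("bio", 12:19)

#' Redundancy filter for bioclimatic variables
#'
#' Temperature variables (`bio1`-`bio11`) are retained iff their absolute
#' Pearson correlation with annual mean temperature (`bio1`) is below the
#' threshold; precipitation variables (`bio12`-`bio19`) likewise with respect
#' to annual precipitation (`bio12`). `bio1` and `bio12` themselves are always
#' retained for interpretability. Zero-variance variables are excluded with a
#' warning. Elevation, if present, is never retained (it is carried in climate
#' tables but excluded from the climate PCA).
#'
#' @param climate A data frame with a `species` column and per-species means
#'   of `bio1`...`bio19` (any subset), optionally `elevation_m`.
#' @param threshold Absolute-correlation cutoff (default 0.90).
#' @return Character vector of retained variable names.
#' @export
climate_filter <- function(climate, threshold = 0.90) {
  if (nrow(climate) < 2L) stop("need >= 2 species rows", call. = FALSE)
  vars <- intersect(c(climate_temperature_vars, climate_precipitation_vars),
                    names(climate))
  for (anchor in c("bio1", "bio12")) {
    if (!anchor %in% vars) stop("column ", anchor, " is required", call. = FALSE)
  }
  sds <- vapply(climate[vars], stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("zero-variance climate variable(s) excluded: ",
            paste(vars[sds == 0], collapse = ", "), call. = FALSE)
    vars <- vars[sds > 0]
  }
  keep_one <- function(v, anchor) {
    v == anchor || abs(stats::cor(climate[[v]], climate[[anchor]])) < threshold
  }
  temp <- intersect(vars, climate_temperature_vars)
  prec <- intersect(vars, climate_precipitation_vars)
  c(temp[vapply(temp, keep_one, logical(1), anchor = "bio1")],
    prec[vapply(prec, keep_one, logical(1), anchor = "bio12")])
}

#' Principal component analysis of retained climate variables
#'
#' Correlation-matrix PCA (variables standardised to unit variance, as the
#' temperature and precipitation variables are in incommensurate units).
#' Components with eigenvalue > 1 are flagged as retained (Kaiser criterion).
#' Each eigenvector is sign-oriented so that its largest-|loading| variable
#' loads positively. `env_pc1`, the species score on the first component, is
#' the continuous habitat measure used downstream.
#'
#' @param climate A data frame with `species` and the climate columns.
#' @param vars Variables to analyse; defaults to [climate_filter()] output.
#' @return A list of class `"env_pca"`: `scores` (tibble, species by
#'   component, including `env_pc1`), `loadings` (matrix), `eigenvalues`,
#'   `variance_fraction`, `retained` (indices with eigenvalue > 1), `vars`.
#' @export
env_pca <- function(climate, vars = climate_filter(climate)) {
  if (length(vars) < 2L) stop("need >= 2 variables for PCA", call. = FALSE)
  if (nrow(climate) < 3L) stop("need >= 3 species for PCA", call. = FALSE)
  X <- as.matrix(climate[vars])
  Z <- scale(X, center = TRUE, scale = TRUE)
  C <- stats::cor(X)
  eig <- eigen(C, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  if (any(eig$values < -1e-8)) {
    warning("correlation matrix numerically indefinite", call. = FALSE)
  }
  if (any(values < 1e-12)) {
    message(sum(values < 1e-12), " zero eigenvalue(s): rank-deficient ",
            "correlation matrix")
  }
  vectors <- orient_signs(eig$vectors)
  dimnames(vectors) <- list(vars, paste0("PC", seq_along(values)))
  scores <- Z %*% vectors
  out <- tibble::tibble(species = climate$species)
  out$env_pc1 <- scores[, 1]
  out <- dplyr::bind_cols(out, tibble::as_tibble(scores))
  structure(
    list(scores = out, loadings = vectors, eigenvalues = values,
         variance_fraction = values / sum(values),
         retained = which(values > 1), vars = vars),
    class = "env_pca"
  )
}

# flip eigenvector columns so the largest-|loading| row is positive
orient_signs <- function(vectors) {
  for (j in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  vectors
}

#' @export
print.env_pca <- function(x, ...) {
  cat(sprintf("<env_pca> %d variables, %d components with eigenvalue > 1\n",
              length(x$vars), length(x$retained)))
  cat("variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}

habitat_levels <- c("closed", "semi_open", "open")

#' Dummy-encode the three-level habitat category
#'
#' Closed-canopy forest is the reference level; the two dummies mark
#' open-canopy woodland/shrubland (`semi_open`) and grassland/desert (`open`).
#'
#' @param category Character vector of habitat labels
#'   (`"closed"`, `"semi_open"`, `"open"`).
#' @return A tibble with columns `habitat_semi_open` and `habitat_open`
#'   (0/1 integers).
#' @examples
#' encode_habitat(c("closed", "semi_open", "open"))
#' @export
encode_habitat <- function(category) {
  bad <- setdiff(unique(category), habitat_levels)
  if (length(bad)) {
    stop("unknown habitat label(s): ", paste(bad, collapse = ", "),
         "; expected one of: ", paste(habitat_levels, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    habitat_semi_open = as.integer(category == "semi_open"),
    habitat_open = as.integer(category == "open")
  )
}
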