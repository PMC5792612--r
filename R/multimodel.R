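# predictor term groups used by the candidate set
morphology_groups <- function() {
  list(
    BodySize = "body_size",
    BeakSize = "beak_size",
    BeakMoment = c("beak_size", "log_beak_length")
  )
}
habitat_groups <- function() {
  list(
    Habitat = c("habitat_semi_open", "habitat_open"),
    EnvPC1 = "env_pc1"
  )
}

#' Enumerate the candidate mean structures and covariance families
#'
#' The candidate set crosses a constrained family of mean structures with the
#' five covariance families. To limit collinearity each model contains at most
#' one morphology group (BodySize; BeakSize; BeakMoment = BeakSize + log beak
#' length) and at most one habitat measure (the categorical Habitat dummies or
#' the continuous EnvPC1): the constant model, each morphology group alone,
#' each habitat measure alone, every morphology + habitat pair, and every
#' morphology x Habitat interaction. Interactions are allowed with the
#' categorical habitat only; the BeakMoment interaction expands to both
#' BeakSize x Habitat and BeakLength x Habitat product terms. With defaults
#' this yields 15 mean structures x 5 families = 75 model specifications.
#'
#' @param families Covariance families to cross with (default all five).
#' @param interaction_with Habitat measures allowed in interactions; must be
#'   `"Habitat"` (requesting `"EnvPC1"` errors, as there is no a-priori
#'   prediction for particular climate-axis values).
#' @return A tibble with columns `model` (label), `terms` (list column of
#'   character term vectors) and `family`.
#' @export
build_model_set <- function(families = transform_families,
                            interaction_with = "Habitat") {
  bad <- setdiff(interaction_with, "Habitat")
  if (length(bad)) {
    stop("interactions are allowed with the categorical habitat measure ",
         "only; requested: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  families <- match.arg(families, transform_families, several.ok = TRUE)
  morph <- morphology_groups()
  habit <- habitat_groups()

  structures <- list(Constant = character(0))
  for (m in names(morph)) structures[[m]] <- morph[[m]]
  for (h in names(habit)) structures[[h]] <- habit[[h]]
  for (m in names(morph)) {
    for (h in names(habit)) {
      structures[[paste(m, "+", h)]] <- c(morph[[m]], habit[[h]])
    }
  }
  if ("Habitat" %in% interaction_with) {
    hd <- habit$Habitat
    for (m in names(morph)) {
      inter <- as.vector(outer(morph[[m]], hd, paste, sep = ":"))
      structures[[paste(m, "x Habitat")]] <- c(morph[[m]], hd, inter)
    }
  }

  tidyr::crossing(
    tibble::tibble(model = names(structures),
                   terms = unname(structures)),
    family = families
  ) |>
    dplyr::arrange(match(.data$model, names(structures)),
                   match(.data$family, transform_families))
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-dAICc_i / 2) / sum_j exp(-dAICc_j / 2)`; invariant to adding a
#' constant to every AICc.
#'
#' @param aicc_values Numeric vector of AICc values (non-finite entries get
#'   weight 0).
#' @return Numeric weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  finite <- is.finite(aicc_values)
  if (!any(finite)) stop("no finite AICc values", call. = FALSE)
  delta <- aicc_values - min(aicc_values[finite])
  w <- ifelse(finite, exp(-delta / 2), 0)
  w / sum(w)
}

#' Fit every candidate model for one response
#'
#' Runs [fit_pgls()] for each row of a [build_model_set()] table, then ranks
#' by AICc and attaches Akaike weights (computed jointly over the full
#' candidate set, pooling mean structures and covariance families) and
#' evidence ratios relative to the constant model. The constant model's
#' weight is the total weight of the intercept-only structure summed over
#' families; when it underflows to zero the evidence ratio is `Inf`
#' (reported downstream as "> 1e6").
#'
#' @param data Merged species-level data frame (a `species` column, the
#'   response and all predictor columns).
#' @param response Response column name.
#' @param tree A rooted `"phylo"` object.
#' @param model_set Tibble from [build_model_set()].
#' @param weight_basis `"joint"` (default) normalises Akaike weights over
#'   the full candidate set; `"per_family"` normalises within each
#'   covariance family separately (weights then sum to 1 per family, and
#'   downstream subsetting/averaging should be applied per family block).
#' @return An object of class `"model_set"`: `fits` (ranked tibble with
#'   `model`, `family`, `terms`, `fit` list column, `aicc`, `delta_aicc`,
#'   `weight`, `evidence_ratio`), `response`, `w_constant`.
#' @export
fit_model_set <- function(data, response, tree,
                          model_set = build_model_set(),
                          weight_basis = c("joint", "per_family")) {
  weight_basis <- match.arg(weight_basis)
  fits <- model_set
  fits$fit <- purrr::pmap(
    list(fits$terms, fits$family),
    function(terms, family) fit_pgls(data, response, terms, tree, family)
  )
  fits$loglik <- vapply(fits$fit, `[[`, numeric(1), "loglik")
  fits$k <- vapply(fits$fit, `[[`, numeric(1), "k")
  fits$n <- vapply(fits$fit, `[[`, numeric(1), "n")
  fits$aicc <- vapply(fits$fit, `[[`, numeric(1), "aicc")
  fits$weight <- if (weight_basis == "joint") {
    akaike_weights(fits$aicc)
  } else {
    stats::ave(fits$aicc, fits$family,
               FUN = function(a) akaike_weights(a))
  }
  fits <- dplyr::arrange(fits, .data$aicc)
  fits$delta_aicc <- fits$aicc - fits$aicc[1]
  w_constant <- sum(fits$weight[lengths(fits$terms) == 0])
  fits$evidence_ratio <- if (w_constant > 0) fits$weight / w_constant else Inf
  structure(
    list(fits = fits, response = response, w_constant = w_constant),
    class = "model_set"
  )
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set> response = %s, %d fits\n", x$response,
              nrow(x$fits)))
  top <- utils::head(x$fits, 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-28s %-7s dAICc = %6.2f  w = %.3f\n", top$model[i],
                top$family[i], top$delta_aicc[i], top$weight[i]))
  }
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.model_set <- function(x, ...) {
  dplyr::select(x$fits, "model", "family", "delta_aicc", "weight",
                "evidence_ratio", "aicc", "loglik", "k", "n")
}

#' @rdname tidiers
#' @export
glance.model_set <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    n_fits = nrow(x$fits),
    top_model = x$fits$model[1],
    top_family = x$fits$family[1],
    top_weight = x$fits$weight[1],
    w_constant = x$w_constant
  )
}

#' Prune models rendered uninformative by a simpler, better-ranked model
#'
#' A model is rejected as uninformative when it sits within `delta` AICc units
#' of a higher-ranked (lower-AICc) model whose term set its own terms strictly
#' contain: the extra parameters bought no meaningful improvement. The
#' top-ranked model is never pruned.
#'
#' @param fits A ranked fits tibble (from `fit_model_set()$fits`) or a
#'   `"model_set"`.
#' @param delta AICc window (default 2).
#' @return The retained fits tibble, rank order preserved, with a
#'   `pruned_by` attribute naming each removed model and its dominating model.
#' @export
prune_uninformative <- function(fits, delta = 2) {
  if (inherits(fits, "model_set")) fits <- fits$fits
  fits <- dplyr::arrange(fits, .data$aicc)
  n <- nrow(fits)
  drop <- logical(n)
  log <- list()
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(i - 1L)) {
      if (drop[j]) next
      nested <- all(fits$terms[[j]] %in% fits$terms[[i]]) &&
        length(fits$terms[[i]]) > length(fits$terms[[j]])
      if (nested && (fits$aicc[i] - fits$aicc[j]) <= delta) {
        drop[i] <- TRUE
        log[[length(log) + 1L]] <- tibble::tibble(
          pruned = paste(fits$model[i], fits$family[i]),
          dominated_by = paste(fits$model[j], fits$family[j])
        )
        break
      }
    }
  }
  out <- fits[!drop, , drop = FALSE]
  attr(out, "pruned_by") <- dplyr::bind_rows(log)
  out
}

#' The 95% cumulative-weight model subset
#'
#' Sorts models by Akaike weight (descending; ties broken by AICc, then by
#' stable input order) and returns the smallest prefix whose cumulative
#' weight reaches the threshold.
#'
#' @param fits A fits tibble with `weight` and `aicc` columns, or a
#'   `"model_set"`.
#' @param threshold Cumulative-weight target (default 0.95).
#' @return The retained fits tibble, weight-sorted.
#' @export
cumulative_weight_set <- function(fits, threshold = 0.95) {
  if (inherits(fits, "model_set")) fits <- fits$fits
  ord <- order(-fits$weight, fits$aicc, seq_len(nrow(fits)))
  fits <- fits[ord, , drop = FALSE]
  cum <- cumsum(fits$weight)
  m <- which(cum >= threshold - 1e-12)[1]
  if (is.na(m)) m <- nrow(fits)
  fits[seq_len(m), , drop = FALSE]
}

#' Total Akaike weight carried by one parameter
#'
#' The sum of the weights of every model whose term set includes the
#' parameter — the probability-of-inclusion analogue used to compare
#' predictors across the candidate set.
#'
#' @param fits A fits tibble with `terms` and `weight`, or a `"model_set"`.
#' @param parameter Term name (e.g. `"body_size"` or
#'   `"beak_size:habitat_open"`).
#' @return Numeric scalar in `[0, 1]`.
#' @export
parameter_total_weight <- function(fits, parameter) {
  if (inherits(fits, "model_set")) fits <- fits$fits
  present <- vapply(fits$terms, function(t) parameter %in% t, logical(1))
  if (!any(present) &&
      !parameter %in% unique(unlist(fits$terms))) {
    warning("parameter not present in any model: ", parameter, call. = FALSE)
  }
  sum(fits$weight[present])
}

#' Zero-substitution model-averaged coefficients
#'
#' Weighted average of every parameter (including the intercept) over a model
#' subset, treating a parameter as 0 in models that do not contain it.
#' Weights are renormalised over the subset before averaging.
#'
#' @param fits A fits tibble (typically a [cumulative_weight_set()] result)
#'   with `fit` and `weight` columns, or a `"model_set"`.
#' @param parameters Parameters to report; defaults to the union over the
#'   subset (intercept first).
#' @return An object of class `"averaged_model"`: a tibble `estimates` with
#'   `parameter`, `total_weight` (within the averaged subset) and
#'   `averaged_beta`, plus `n_models`, `tree_count`.
#' @export
model_average <- function(fits, parameters = NULL) {
  if (inherits(fits, "model_set")) fits <- fits$fits
  if (nrow(fits) == 0L) stop("empty model subset", call. = FALSE)
  w <- fits$weight / sum(fits$weight)
  coefs <- lapply(fits$fit, `[[`, "coefficients")
  if (is.null(parameters)) {
    parameters <- unique(c("(Intercept)", unlist(lapply(coefs, names))))
  }
  beta <- vapply(parameters, function(p) {
    sum(w * vapply(coefs, function(cf) if (p %in% names(cf)) cf[[p]] else 0,
                   numeric(1)))
  }, numeric(1))
  tw <- vapply(parameters, function(p) {
    sum(w[vapply(coefs, function(cf) p %in% names(cf), logical(1))])
  }, numeric(1))
  structure(
    list(
      estimates = tibble::tibble(parameter = parameters,
                                 total_weight = unname(tw),
                                 averaged_beta = unname(beta)),
      n_models = nrow(fits),
      tree_count = 1L
    ),
    class = "averaged_model"
  )
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(sprintf("<averaged_model> %d model(s), %d tree(s)\n", x$n_models,
              x$tree_count))
  print(x$estimates, n = Inf)
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.averaged_model <- function(x, ...) x$estimates

#' @rdname tidiers
#' @export
glance.averaged_model <- function(x, ...) {
  tibble::tibble(n_models = x$n_models, tree_count = x$tree_count)
}

#' Model-average a response across a posterior sample of trees
#'
#' For each tree in the sample: fit the full candidate set, take its 95%
#' cumulative-weight subset, and model-average with zero substitution. The
#' final coefficients are the unweighted mean of the per-tree averaged
#' coefficients (and the parameter total weights the mean of the per-tree
#' subset weights); the modal top family across trees is reported.
#'
#' @param trees A `"multiPhylo"` collection sharing the data's species.
#' @param data Merged species-level data frame.
#' @param response Response column name.
#' @param model_set Tibble from [build_model_set()].
#' @param threshold Cumulative-weight threshold (default 0.95).
#' @return An `"averaged_model"` with `tree_count` set, `modal_family`, and
#'   per-tree averaged estimates in `per_tree`.
#' @export
average_across_trees <- function(trees, data, response,
                                 model_set = build_model_set(),
                                 threshold = 0.95) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  per_tree <- purrr::imap(trees, function(tree, i) {
    ms <- fit_model_set(data, response, tree, model_set)
    sub <- cumulative_weight_set(ms, threshold)
    avg <- model_average(sub)
    avg$estimates$tree <- i
    avg$estimates$top_family <- sub$family[1]
    avg$estimates
  })
  all_est <- dplyr::bind_rows(per_tree)
  pooled <- all_est |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(total_weight = mean(.data$total_weight),
                     averaged_beta = mean(.data$averaged_beta),
                     .groups = "drop")
  # keep intercept-first parameter ordering from the first tree
  pooled <- pooled[order(match(pooled$parameter,
                               unique(all_est$parameter))), ]
  top_fams <- vapply(per_tree, function(d) d$top_family[1], character(1))
  structure(
    list(
      estimates = pooled,
      n_models = NA_integer_,
      tree_count = length(trees),
      modal_family = names(sort(table(top_fams), decreasing = TRUE))[1],
      per_tree = all_est
    ),
    class = "averaged_model"
  )
}

#' Dot-and-bar plot of model-averaged coefficients
#'
#' @param object An `"averaged_model"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.averaged_model <- function(object, ...) {
  est <- object$estimates
  est$parameter <- factor(est$parameter, levels = rev(est$parameter))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$averaged_beta,
                                    y = .data$parameter)) +
    ggplot2::geom_col(ggplot2::aes(alpha = .data$total_weight),
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Model-averaged coefficient", y = NULL,
                  alpha = "Total weight")
}
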