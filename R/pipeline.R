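#' Analysis configuration from input files
#'
#' Bundles the file paths and method options of a full run. Either a
#' ready-made predictor table (`predictors_file`, with the composite and
#' dummy columns) or the raw per-species tables (`morphology_file`,
#' `habitat_file`, optionally `climate_file`) must be supplied; raw tables
#' are passed through [morphology_composites()], [encode_habitat()] and
#' [env_pca()] during loading. All tables are tab- or comma-delimited text
#' with a header and a `species` column.
#'
#' @param tree_file Newick file with the consensus tree.
#' @param songs_file Delimited per-recording song table (`species`,
#'   `n_notes`, `duration_s`, `max_freq_hz`, `min_freq_hz`, `peak_freq_hz`).
#' @param predictors_file Optional delimited species predictor table.
#' @param morphology_file,habitat_file,climate_file Optional raw tables.
#' @param posterior_trees_file Optional multi-tree Newick file.
#' @param ... Method options forwarded to [run_pipeline()].
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(tree_file, songs_file, predictors_file = NULL,
                            morphology_file = NULL, habitat_file = NULL,
                            climate_file = NULL, posterior_trees_file = NULL,
                            ...) {
  paths <- c(tree_file = tree_file, songs_file = songs_file,
             predictors_file = predictors_file,
             morphology_file = morphology_file,
             habitat_file = habitat_file, climate_file = climate_file,
             posterior_trees_file = posterior_trees_file)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(predictors_file) &&
      (is.null(morphology_file) || is.null(habitat_file))) {
    stop("supply either predictors_file or morphology_file + habitat_file",
         call. = FALSE)
  }
  structure(list(paths = as.list(paths), options = list(...)),
            class = "analysis_config")
}

read_delim_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "",
                                      stringsAsFactors = FALSE))
}

load_analysis_inputs <- function(config) {
  p <- config$paths
  tree <- read_newick(p$tree_file)
  songs <- read_delim_table(p$songs_file)
  tree_set <- if (!is.null(p$posterior_trees_file)) {
    read_newick(p$posterior_trees_file)
  }
  predictors <- if (!is.null(p$predictors_file)) {
    read_delim_table(p$predictors_file)
  } else {
    morph <- morphology_composites(read_delim_table(p$morphology_file))
    hab <- read_delim_table(p$habitat_file)
    hab <- dplyr::bind_cols(hab, encode_habitat(hab$habitat))
    pred <- dplyr::inner_join(morph, hab, by = "species")
    if (!is.null(p$climate_file)) {
      clim <- read_delim_table(p$climate_file)
      scores <- env_pca(clim)$scores
      pred <- dplyr::inner_join(pred,
                                dplyr::select(scores, "species", "env_pc1"),
                                by = "species")
    }
    pred
  }
  list(tree = tree, tree_set = tree_set, predictors = predictors,
       songs = songs)
}

# Table 3 / Table 4 parameter column order
report_parameters <- function() {
  c("(Intercept)", "beak_size", "habitat_semi_open", "habitat_open",
    "log_beak_length",
    "beak_size:habitat_semi_open", "beak_size:habitat_open",
    "log_beak_length:habitat_semi_open", "log_beak_length:habitat_open",
    "body_size",
    "body_size:habitat_semi_open", "body_size:habitat_open",
    "env_pc1")
}

#' Run the full comparative song-evolution analysis
#'
#' Orchestrates every stage: song feature derivation, species aggregation,
#' both performance-frontier fits, vocal deviation, phylogenetic PCA of the
#' species song table, assembly of the predictor table, candidate-set PGLS
#' fitting per response, AICc ranking with Arnold pruning, parameter total
#' weights, zero-substitution model averaging of the 95% cumulative-weight
#' set on the consensus tree, and (optionally) averaging across a posterior
#' tree sample. Responses analysed are the retained song principal
#' components, the seven individual log song traits, and vocal deviation.
#'
#' @param x A `"song_bundle"` (from [simulate_bundle()] or assembled by
#'   hand) or an [analysis_config()].
#' @param responses Response columns to analyse; `NULL` (default) uses the
#'   retained Song PCs, the seven log traits and `vocal_deviation`.
#' @param ppca_mode `"correlation"` or `"covariance"` for the song PPCA.
#' @param bin_width,x_value Options of [upper_bound_regression()].
#' @param window_width,step,percentile_q,min_count Options of
#'   [percentile_bound()].
#' @param families Covariance families for the candidate set.
#' @param threshold Cumulative-weight threshold for averaging (default
#'   0.95).
#' @param n_posterior_trees How many trees of the sample to average across
#'   (0 skips tree averaging; default 25).
#' @param exclude_species Explicit species ids to drop before analysis
#'   (e.g. a known outlier); never auto-detected.
#' @param min_overlap Minimum species shared by songs, predictors and tree
#'   (default 10); below it the run aborts with the intersection report.
#' @return A list of class `"report_bundle"`: `frontier` (both fits,
#'   glanced), `ppca`, `ppca_table`, `species_data`, `rankings` (per
#'   response, pruned top models), `full_rankings`, `parameter_weights`
#'   (Table-3-shaped), `averaged_consensus` and `averaged_trees`
#'   (Table-4-shaped), `log` (every option and decision actually used).
#' @export
run_pipeline <- function(x, responses = NULL,
                         ppca_mode = c("correlation", "covariance"),
                         bin_width = 2, x_value = "actual",
                         window_width = 2, step = 1, percentile_q = 90,
                         min_count = 32,
                         families = transform_families,
                         threshold = 0.95,
                         n_posterior_trees = 25,
                         exclude_species = character(0),
                         min_overlap = 10) {
  ppca_mode <- match.arg(ppca_mode)
  if (inherits(x, "analysis_config")) {
    opts <- x$options
    x <- load_analysis_inputs(x)
    if (length(opts)) {
      call_args <- c(list(x = x), opts)
      return(do.call(run_pipeline, call_args))
    }
  }
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  songs <- derive_song_features(x$songs)
  predictors <- tibble::as_tibble(x$predictors)
  tree <- x$tree
  if (length(exclude_species)) {
    songs <- songs[!songs$species %in% exclude_species, ]
    predictors <- predictors[!predictors$species %in% exclude_species, ]
    note("excluded %d species by explicit config: %s",
         length(exclude_species), paste(exclude_species, collapse = ", "))
  }

  shared <- Reduce(intersect, list(unique(songs$species),
                                   predictors$species, tree$tip.label))
  if (length(shared) < min_overlap) {
    stop("species overlap across songs, predictors and tree is ",
         length(shared), " (< ", min_overlap, "): ",
         paste(shared, collapse = ", "), call. = FALSE)
  }
  dropped <- setdiff(unique(c(songs$species, predictors$species,
                              tree$tip.label)), shared)
  if (length(dropped)) {
    note("%d species dropped for incomplete coverage: %s", length(dropped),
         paste(utils::head(dropped, 20), collapse = ", "))
  }
  songs <- songs[songs$species %in% shared, ]
  predictors <- predictors[predictors$species %in% shared, ]
  tree <- ape::keep.tip(tree, shared)

  note("frontier options: bin_width = %g, x_value = %s; window_width = %g, step = %g, q = %g, min_count = %d",
       bin_width, x_value, window_width, step, percentile_q, min_count)
  bound <- upper_bound_regression(songs, bin_width = bin_width,
                                  x_value = x_value)
  pct <- tryCatch(
    percentile_bound(songs, window_width = window_width, step = step,
                     q = percentile_q, min_count = min_count),
    error = function(e) {
      note("percentile bound skipped: %s", conditionMessage(e))
      NULL
    }
  )
  vp <- species_vocal_performance(songs, bound)

  sp_table <- species_song_table(songs)
  log_traits <- paste0("log_", song_trait_vars)
  ppca <- phylogenetic_pca(sp_table, tree, mode = ppca_mode,
                           vars = log_traits)
  note("PPCA mode = %s; %d component(s) retained by the Kaiser criterion",
       ppca_mode, length(ppca$retained))

  n_pc <- max(length(ppca$retained), 1L)
  pc_scores <- ppca$scores[, c("species", paste0("PC", seq_len(n_pc)))]
  names(pc_scores) <- c("species", paste0("song_pc", seq_len(n_pc)))

  data <- sp_table |>
    dplyr::inner_join(pc_scores, by = "species") |>
    dplyr::inner_join(dplyr::select(vp, "species", "vocal_deviation"),
                      by = "species") |>
    dplyr::inner_join(predictors, by = "species")

  if (is.null(responses)) {
    responses <- c(paste0("song_pc", seq_len(n_pc)), log_traits,
                   "vocal_deviation")
  }
  note("responses: %s", paste(responses, collapse = ", "))
  note("model set: %d mean structures x %d families; k counts design columns + sigma2 + transform",
       nrow(build_model_set(families)) / length(families), length(families))

  model_set <- build_model_set(families)
  params <- setdiff(report_parameters(), "(Intercept)")

  rankings <- list()
  full_rankings <- list()
  weights_rows <- list()
  avg_rows <- list()
  tree_avg_rows <- list()
  for (resp in responses) {
    ms <- fit_model_set(data, resp, tree, model_set)
    full_rankings[[resp]] <- dplyr::mutate(tidy(ms), response = resp,
                                           .before = 1)
    pruned <- prune_uninformative(ms)
    top <- pruned[pruned$delta_aicc <= 2, , drop = FALSE]
    rankings[[resp]] <- tibble::tibble(
      response = resp, model = top$model, family = top$family,
      delta_aicc = top$delta_aicc, weight = top$weight,
      evidence_ratio = pmin(top$evidence_ratio, 1e6),
      er_censored = top$evidence_ratio > 1e6
    )
    weights_rows[[resp]] <- tibble::tibble(
      response = resp,
      parameter = params,
      total_weight = vapply(params, function(p)
        parameter_total_weight(ms, p), numeric(1))
    )
    avg <- model_average(cumulative_weight_set(ms, threshold),
                         parameters = report_parameters())
    avg_rows[[resp]] <- dplyr::mutate(avg$estimates, response = resp,
                                      .before = 1)
    if (n_posterior_trees > 0 && !is.null(x$tree_set)) {
      sub <- x$tree_set[seq_len(min(n_posterior_trees,
                                    length(x$tree_set)))]
      sub <- lapply(sub, ape::keep.tip, tip = shared)
      class(sub) <- "multiPhylo"
      tavg <- average_across_trees(sub, data, resp, model_set, threshold)
      est <- tavg$estimates
      est <- est[match(report_parameters(), est$parameter), , drop = FALSE]
      est$parameter <- report_parameters()
      est$averaged_beta[is.na(est$averaged_beta)] <- 0
      est$total_weight[is.na(est$total_weight)] <- 0
      tree_avg_rows[[resp]] <- dplyr::mutate(
        est, response = resp, tree_count = tavg$tree_count,
        modal_family = tavg$modal_family, .before = 1)
    }
  }
  if (n_posterior_trees > 0 && !is.null(x$tree_set)) {
    note("averaged across %d posterior trees", min(n_posterior_trees,
                                                   length(x$tree_set)))
  }

  structure(
    list(
      frontier = dplyr::bind_rows(glance(bound),
                                  if (!is.null(pct)) glance(pct)),
      upper_bound = bound,
      percentile = pct,
      ppca = ppca,
      ppca_table = glance(ppca),
      species_data = data,
      rankings = dplyr::bind_rows(rankings),
      full_rankings = dplyr::bind_rows(full_rankings),
      parameter_weights = dplyr::bind_rows(weights_rows) |>
        tidyr::pivot_wider(names_from = "parameter",
                           values_from = "total_weight"),
      averaged_consensus = dplyr::bind_rows(avg_rows),
      averaged_trees = dplyr::bind_rows(tree_avg_rows),
      log = log
    ),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat("  frontier fits:\n")
  print(x$frontier)
  cat("  PPCA eigenvalues:",
      paste(sprintf("%.3f", x$ppca$eigenvalues), collapse = " "), "\n")
  cat("  responses analysed:", length(unique(x$rankings$response)), "\n")
  invisible(x)
}

#' Write a report bundle to delimited text and JSON
#'
#' Emits each table of the report as a TSV file plus a JSON twin, and the
#' run log as plain text. Rerunning with an identical configuration
#' reproduces the files byte for byte.
#'
#' @param report A `"report_bundle"`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(
    frontier = report$frontier,
    ppca = report$ppca_table,
    ppca_loadings = tidy(report$ppca),
    rankings = report$rankings,
    full_rankings = report$full_rankings,
    parameter_weights = report$parameter_weights,
    averaged_consensus = report$averaged_consensus,
    averaged_trees = report$averaged_trees
  )
  for (nm in names(tables)) {
    if (is.null(tables[[nm]]) || nrow(tables[[nm]]) == 0) next
    utils::write.table(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(tables[[nm]], file.path(dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
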