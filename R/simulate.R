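#' Configuration for the synthetic-data generator
#'
#' Collects every generative parameter of the simulated study: tree size,
#' sampling effort per species, the pace-bandwidth performance frontier, the
#' predictor-to-song effect map, phylogenetic residual scales, habitat
#' prevalences and the correlation targets among predictors. Defaults emulate
#' the structure of a 276-species radiation sampled at 6.6 +/- 5.4 recordings
#' per species with a triangular pace-by-bandwidth cloud bounded by the
#' frontier `bw = -79.374 * pace + 5066.2`, morphology composites correlated
#' at 0.8 and a continuous climate axis correlated at 0.7 with the latent
#' habitat gradient.
#'
#' @param n_species Number of tips (default 276).
#' @param songs_per_species_mean,songs_per_species_sd Mean and SD of the
#'   per-species recording count (lognormal truncated at 1; defaults 6.6,
#'   5.4).
#' @param frontier_slope,frontier_intercept Generative performance frontier
#'   (Hz bandwidth per Hz pace; Hz).
#' @param beta Named list of generative effects: `pace` (effects of
#'   `beak_size`, `log_beak_length`, `habitat_semi_open`, `habitat_open` on
#'   log pace) and `min_freq` (effect of `body_size` on log minimum
#'   frequency).
#' @param mu_log_pace,mu_log_min_freq Grand means of log pace (log Hz) and
#'   log minimum frequency (log Hz).
#' @param sigma_pace,sigma_freq Phylogenetic (Brownian) residual SDs of the
#'   species-mean log pace and log minimum frequency.
#' @param song_sd_pace,song_sd_freq Within-species (per-recording) SDs on the
#'   log scale.
#' @param trait_sd Brownian SD of the morphology composites.
#' @param beak_body_cor Target correlation of beak size and body size
#'   (default 0.8).
#' @param beak_length_cor Target correlation of log beak length with beak
#'   size (default 0.85).
#' @param habitat_env_cor Target correlation of `env_pc1` with the latent
#'   habitat gradient (default 0.7).
#' @param habitat_prevalence Length-3 proportions of closed / semi-open /
#'   open species (sums to 1).
#' @param performance_range Range of the per-species performance factor
#'   (fraction of the frontier a species can reach), drawn uniformly.
#' @param performance_beak_beta Optional effect of beak size on the logit of
#'   the performance factor (0 disables the link).
#' @param mu_log_duration,song_sd_duration Lognormal song-duration parameters
#'   (log seconds).
#' @param jitter_sd Lognormal SD of branch-length perturbation for the
#'   emulated posterior tree sample.
#' @param n_posterior_trees Size of the perturbed tree sample (default 500).
#' @param seed Integer seed; mandatory for a reproducible bundle.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_species = 276,
                              songs_per_species_mean = 6.6,
                              songs_per_species_sd = 5.4,
                              frontier_slope = -79.374,
                              frontier_intercept = 5066.2,
                              beta = list(
                                pace = c(beak_size = -0.6,
                                         log_beak_length = 0,
                                         habitat_semi_open = 0.25,
                                         habitat_open = 0.5),
                                min_freq = c(body_size = -0.8)
                              ),
                              mu_log_pace = 2.0,
                              mu_log_min_freq = log(1500),
                              sigma_pace = 0.8,
                              sigma_freq = 0.25,
                              song_sd_pace = 0.25,
                              song_sd_freq = 0.08,
                              trait_sd = 0.3,
                              beak_body_cor = 0.8,
                              beak_length_cor = 0.85,
                              habitat_env_cor = 0.7,
                              habitat_prevalence = c(closed = 0.45,
                                                     semi_open = 0.30,
                                                     open = 0.25),
                              performance_range = c(0.6, 1),
                              performance_beak_beta = 0,
                              mu_log_duration = log(3),
                              song_sd_duration = 0.3,
                              jitter_sd = 0.1,
                              n_posterior_trees = 500,
                              seed = 1L) {
  config <- as.list(environment())
  for (r in c(beak_body_cor, beak_length_cor, habitat_env_cor)) {
    if (abs(r) > 0.999) stop("unattainable correlation target: ", r,
                             call. = FALSE)
  }
  stopifnot(n_species >= 2, songs_per_species_mean >= 1,
            abs(sum(habitat_prevalence) - 1) < 1e-8,
            length(performance_range) == 2,
            performance_range[1] > 0, performance_range[2] <= 1)
  structure(config, class = "simulation_config")
}

#' Simulate an ultrametric pure-birth tree
#'
#' A Yule (pure-birth) tree rescaled to unit root-to-tip height, with tips
#' labelled `sp001 ... spNNN` so that alphabetical and numeric orders agree.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A `"phylo"` object, ultrametric with height 1.
#' @export
simulate_tree <- function(n_tips, seed) {
  stopifnot(n_tips >= 2)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  h <- max(tip_depths(tree))
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- sprintf("sp%0*d", nchar(as.character(n_tips)),
                            seq_len(n_tips))
  tree
}

#' Emulate a posterior sample by jittering branch lengths
#'
#' Each branch length of the source tree is multiplied by an independent
#' lognormal factor with mean 1 (meanlog `-jitter_sd^2 / 2`); topology is
#' preserved, so the sample mimics posterior uncertainty in divergence times
#' only.
#'
#' @param tree Source `"phylo"` object.
#' @param m Number of trees to generate.
#' @param jitter_sd Lognormal SD of the multipliers (0 gives identical
#'   copies).
#' @param seed Integer seed.
#' @return A `"multiPhylo"` collection of `m` trees.
#' @export
perturb_trees <- function(tree, m, jitter_sd, seed) {
  stopifnot(jitter_sd >= 0, m >= 1)
  set.seed(seed)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    t2 <- tree
    t2$edge.length <- tree$edge.length *
      stats::rlnorm(length(tree$edge.length),
                    meanlog = -jitter_sd^2 / 2, sdlog = jitter_sd)
    out[[i]] <- t2
  }
  class(out) <- "multiPhylo"
  out
}

# matrix-normal Brownian draws: rows follow the tree covariance, columns the
# trait correlation R
sim_bm_traits <- function(tree, sd, R, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  V <- bm_vcv(tree)
  n <- nrow(V)
  p <- nrow(R)
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- t(chol(V)) %*% Z %*% chol(R) * sd
  rownames(X) <- rownames(V)
  X
}

#' Simulate species-level predictors on a tree
#'
#' Morphology composites (`body_size`, `beak_size`) are drawn from correlated
#' Brownian motion on the tree at the configured correlation target;
#' `log_beak_length` tracks beak size with added Brownian noise scaled to its
#' correlation target. Habitat is generated by thresholding a latent Brownian
#' "openness" gradient at the configured prevalences (a threshold model, so
#' the category inherits phylogenetic signal), and `env_pc1` is the
#' standardised latent gradient plus Gaussian noise tuned to the
#' habitat-climate correlation target.
#'
#' @param tree A `"phylo"` object.
#' @param config A [simulation_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A tibble with one row per species: `body_size`, `beak_size`,
#'   `log_beak_length`, `habitat`, `habitat_semi_open`, `habitat_open`,
#'   `env_pc1`, `latent_habitat`.
#' @export
simulate_predictors <- function(tree, config, seed = config$seed) {
  set.seed(seed)
  n <- length(tree$tip.label)
  sp <- sort(tree$tip.label)
  R <- matrix(c(1, config$beak_body_cor, config$beak_body_cor, 1), 2, 2)
  M <- sim_bm_traits(tree, config$trait_sd, R)  # rows in alphabetical order
  body <- 3.45 + M[, 1]
  beak <- 1.95 + M[, 2]
  # extra Brownian noise dilutes the beak-size signal to the length target
  noise_sd <- config$trait_sd * sqrt(1 / config$beak_length_cor^2 - 1)
  lbl <- 2.5 + (beak - 1.95) +
    drop(sim_bm_traits(tree, noise_sd, matrix(1, 1, 1)))

  latent <- drop(sim_bm_traits(tree, 1, matrix(1, 1, 1)))
  cuts <- stats::quantile(latent,
                          probs = cumsum(config$habitat_prevalence)[1:2],
                          type = 7)
  habitat <- as.character(cut(latent, breaks = c(-Inf, cuts, Inf),
                              labels = habitat_levels))
  if (length(unique(habitat)) < 3L) {
    warning("not all habitat categories are occupied", call. = FALSE)
  }
  r <- config$habitat_env_cor
  z <- as.numeric(scale(latent))
  env <- r * z + stats::rnorm(n, sd = sqrt(1 - r^2))

  dplyr::bind_cols(
    tibble::tibble(
      species = sp,
      body_size = unname(body[sp]),
      beak_size = unname(beak[sp]),
      log_beak_length = unname(lbl[sp]),
      habitat = habitat,
      env_pc1 = env,
      latent_habitat = unname(latent[sp])
    ),
    encode_habitat(habitat)
  )
}

#' Simulate per-recording songs under a known frontier
#'
#' Species-mean log pace is the configured linear predictor (beak terms and
#' habitat dummies) plus a Brownian phylogenetic residual; species-mean log
#' minimum frequency likewise (body-size effect, negative by default).
#' Per-recording values scatter lognormally around the species means. Each
#' species carries a performance factor `f` in `(0, 1]`, and every song's
#' bandwidth is drawn uniformly on `(0, frontier(pace) * f]`, so no song can
#' exceed the generative frontier at its (realised) pace; paces at which the
#' frontier is nonpositive are redrawn and counted. Note counts and durations
#' are back-solved from pace (`n_notes = round(pace * duration)`, at least
#' 1), so the recorded pace is exactly `n_notes / duration_s`.
#'
#' @param predictors Species table from [simulate_predictors()].
#' @param tree The `"phylo"` object the predictors were simulated on.
#' @param config A [simulation_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A tibble with one row per recording: `species`, `n_notes`,
#'   `duration_s`, `max_freq_hz`, `min_freq_hz`, `peak_freq_hz`, plus the
#'   realised `pace_hz` and `bandwidth_hz`. The per-species truth (mean log
#'   pace/frequency, performance factor) is attached as attribute
#'   `"species_truth"`; the redraw count as `"n_redrawn"`.
#' @export
simulate_songs <- function(predictors, tree, config, seed = config$seed) {
  set.seed(seed)
  pr <- dplyr::arrange(tibble::as_tibble(predictors), .data$species)
  n <- nrow(pr)
  bp <- config$beta$pace
  bf <- config$beta$min_freq
  Xp <- cbind(beak_size = pr$beak_size - mean(pr$beak_size),
              log_beak_length = pr$log_beak_length - mean(pr$log_beak_length),
              habitat_semi_open = pr$habitat_semi_open,
              habitat_open = pr$habitat_open)
  lp_pace <- config$mu_log_pace + drop(Xp[, names(bp), drop = FALSE] %*% bp)
  lp_freq <- config$mu_log_min_freq +
    (pr$body_size - mean(pr$body_size)) * bf[["body_size"]]
  eps_pace <- drop(sim_bm_traits(tree, config$sigma_pace, matrix(1, 1, 1)))
  eps_freq <- drop(sim_bm_traits(tree, config$sigma_freq, matrix(1, 1, 1)))
  mean_log_pace <- lp_pace + eps_pace[pr$species]
  mean_log_freq <- lp_freq + eps_freq[pr$species]

  perf <- stats::runif(n, config$performance_range[1],
                       config$performance_range[2])
  if (config$performance_beak_beta != 0) {
    lin <- stats::qlogis(pmin(perf, 0.999)) +
      config$performance_beak_beta * (pr$beak_size - mean(pr$beak_size))
    perf <- stats::plogis(lin)
  }

  n_songs <- pmax(1L, round(stats::rlnorm(
    n,
    meanlog = log(config$songs_per_species_mean) -
      0.5 * log(1 + (config$songs_per_species_sd /
                       config$songs_per_species_mean)^2),
    sdlog = sqrt(log(1 + (config$songs_per_species_sd /
                            config$songs_per_species_mean)^2))
  )))

  frontier <- function(p) config$frontier_intercept + config$frontier_slope * p
  n_redrawn <- 0L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- n_songs[i]
    dur <- stats::rlnorm(m, config$mu_log_duration, config$song_sd_duration)
    pace <- numeric(m)
    notes <- integer(m)
    for (j in seq_len(m)) {
      tries <- 0L
      repeat {
        target <- exp(mean_log_pace[i] +
                        stats::rnorm(1, sd = config$song_sd_pace))
        tries <- tries + 1L
        if (tries > 200L) {
          # species mean beyond the frontier's zero crossing: truncate the
          # draw into the admissible pace range instead of looping forever
          zero <- -config$frontier_intercept / config$frontier_slope
          target <- stats::runif(1, 0.5, 0.9) * zero
        }
        nn <- max(1L, as.integer(round(target * dur[j])))
        realised <- nn / dur[j]
        if (frontier(realised) > 0) {
          pace[j] <- realised
          notes[j] <- nn
          break
        }
        n_redrawn <- n_redrawn + 1L
      }
    }
    bw <- stats::runif(m, 0, frontier(pace) * perf[i])
    minf <- exp(mean_log_freq[i] + stats::rnorm(m, sd = config$song_sd_freq))
    maxf <- minf + bw
    peak <- minf + stats::runif(m, 0.2, 0.8) * bw
    rows[[i]] <- tibble::tibble(
      species = pr$species[i], n_notes = notes, duration_s = dur,
      max_freq_hz = maxf, min_freq_hz = minf, peak_freq_hz = peak,
      pace_hz = pace, bandwidth_hz = bw
    )
  }
  if (n_redrawn > 0) {
    message(n_redrawn, " pace draw(s) redrawn (frontier nonpositive)")
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "species_truth") <- tibble::tibble(
    species = pr$species, mean_log_pace = mean_log_pace,
    mean_log_min_freq = mean_log_freq, performance_factor = perf,
    n_songs = n_songs
  )
  attr(out, "n_redrawn") <- n_redrawn
  out
}

#' Generate a complete synthetic study bundle
#'
#' Runs the full generator: a unit-height pure-birth tree, a perturbed
#' posterior tree sample, species-level predictors, and a per-recording song
#' table, together with the truth record (the config itself plus realised
#' species-level parameters). Stage-specific seeds are derived
#' deterministically from `config$seed`, so an identical config yields a
#' byte-identical bundle.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"song_bundle"`: `tree`, `tree_set`,
#'   `predictors`, `songs`, `truth`.
#' @export
simulate_bundle <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  base <- as.integer(config$seed) %% 2000000000L
  tree <- simulate_tree(config$n_species, seed = base)
  tree_set <- perturb_trees(tree, config$n_posterior_trees,
                            config$jitter_sd, seed = base + 1L)
  predictors <- simulate_predictors(tree, config, seed = base + 2L)
  songs <- simulate_songs(predictors, tree, config, seed = base + 3L)
  structure(
    list(
      tree = tree,
      tree_set = tree_set,
      predictors = predictors,
      songs = songs,
      truth = list(config = config,
                   species_truth = attr(songs, "species_truth"),
                   n_redrawn = attr(songs, "n_redrawn"))
    ),
    class = "song_bundle"
  )
}

#' @export
print.song_bundle <- function(x, ...) {
  cat(sprintf("<song_bundle> %d species, %d recordings, %d posterior trees\n",
              length(x$tree$tip.label), nrow(x$songs),
              length(x$tree_set)))
  invisible(x)
}

#' Write a synthetic bundle to plain-text files
#'
#' Writes the consensus tree and tree sample as Newick, the predictor and
#' song tables as tab-separated text, and the truth record as JSON.
#'
#' @param bundle A `"song_bundle"`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(bundle$tree, file.path(dir, "tree.nwk"))
  write_newick(bundle$tree_set, file.path(dir, "posterior_trees.nwk"))
  utils::write.table(bundle$predictors, file.path(dir, "predictors.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$songs, file.path(dir, "songs.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- bundle$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
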