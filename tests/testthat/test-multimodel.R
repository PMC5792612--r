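test_that("the candidate set enumerates 15 mean structures x 5 families", {
  ms <- build_model_set()
  expect_equal(nrow(ms), 75)
  expect_equal(length(unique(ms$model)), 15)
  # constant model appears exactly once per family
  expect_equal(sum(lengths(ms$terms) == 0), 5)
  # every interaction structure expands morphology term x both habitat dummies
  bm_int <- ms$terms[ms$model == "BeakMoment x Habitat"][[1]]
  expect_setequal(bm_int, c(
    "beak_size", "log_beak_length", "habitat_semi_open", "habitat_open",
    "beak_size:habitat_semi_open", "beak_size:habitat_open",
    "log_beak_length:habitat_semi_open", "log_beak_length:habitat_open"
  ))
  expect_error(build_model_set(interaction_with = c("Habitat", "EnvPC1")),
               "categorical habitat")
})

test_that("Akaike weights are normalized, symmetric and shift-invariant", {
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  set.seed(4)
  a <- runif(20, 100, 150)
  expect_equal(akaike_weights(a), akaike_weights(a + 57.3), tolerance = 1e-12)
  expect_equal(sum(akaike_weights(a)), 1, tolerance = 1e-12)
  expect_error(akaike_weights(c(Inf, Inf)), "finite")
})

test_that("Arnold pruning removes only dominated supersets", {
  f1 <- fake_fits(c("A", "AB"), list("a", c("a", "b")), c(100, 101.5))
  kept <- prune_uninformative(f1)
  expect_equal(kept$model, "A")
  expect_equal(attr(kept, "pruned_by")$pruned, "AB BM")

  f2 <- fake_fits(c("A", "B"), list("a", "b"), c(100, 101))
  expect_equal(prune_uninformative(f2)$model, c("A", "B"))

  f3 <- fake_fits(c("A", "AB", "ABC"),
                  list("a", c("a", "b"), c("a", "b", "c")),
                  c(100, 101, 101.9))
  expect_equal(prune_uninformative(f3)$model, "A")

  # a superset more than 2 units away survives
  f4 <- fake_fits(c("A", "AB"), list("a", c("a", "b")), c(100, 103))
  expect_equal(prune_uninformative(f4)$model, c("A", "AB"))
  # the top-ranked model is never pruned
  f5 <- fake_fits(c("AB", "A"), list(c("a", "b"), "a"), c(99, 100))
  expect_true("AB" %in% prune_uninformative(f5)$model)
})

test_that("the 95% cumulative-weight set is the smallest covering prefix", {
  f <- fake_fits(paste0("m", 1:4), as.list(paste0("t", 1:4)),
                 aicc = c(0, 0, 0, 0))
  f$weight <- c(0.6, 0.3, 0.06, 0.04)
  expect_equal(cumulative_weight_set(f)$model, c("m1", "m2", "m3"))
  f1 <- f[1, ]
  f1$weight <- 1
  expect_equal(nrow(cumulative_weight_set(f1)), 1)
  fu <- fake_fits(paste0("m", 1:20), as.list(paste0("t", 1:20)),
                  aicc = rep(0, 20))
  fu$weight <- rep(1 / 20, 20)
  expect_equal(nrow(cumulative_weight_set(fu)), 19)
})

test_that("parameter total weights sum the weights of containing models", {
  f <- fake_fits(c("m1", "m2", "m3"),
                 list("body_size", c("body_size", "habitat_semi_open"),
                      character(0)),
                 aicc = c(0, 0, 0))
  f$weight <- c(0.6, 0.2, 0.2)
  expect_equal(parameter_total_weight(f, "body_size"), 0.8)
  expect_equal(parameter_total_weight(f, "habitat_semi_open"), 0.2)
  expect_warning(w0 <- parameter_total_weight(f, "beak_size"), "not present")
  expect_equal(w0, 0)
})

test_that("zero-substitution averaging matches hand-computed cases", {
  f <- fake_fits(c("m1", "m2"), list("x", character(0)), aicc = c(0, 0),
                 coefs = list(c("(Intercept)" = 0, x = 1),
                              c("(Intercept)" = 0)))
  f$weight <- c(0.5, 0.5)
  avg <- model_average(f)
  expect_equal(avg$estimates$averaged_beta[avg$estimates$parameter == "x"],
               0.5)
  expect_equal(avg$estimates$total_weight[avg$estimates$parameter == "x"],
               0.5)
  # shared coefficient value is preserved by convexity
  f2 <- fake_fits(c("m1", "m2"), list("x", c("x", "z")), aicc = c(0, 1),
                  coefs = list(c("(Intercept)" = 1, x = 3),
                               c("(Intercept)" = 1, x = 3, z = 2)))
  avg2 <- model_average(f2)
  expect_equal(avg2$estimates$averaged_beta[avg2$estimates$parameter == "x"],
               3)
  # weights renormalise after subsetting
  sub <- cumulative_weight_set(f2, threshold = 0.5)
  avg3 <- model_average(sub)
  expect_equal(sum(avg3$estimates$total_weight[
    avg3$estimates$parameter == "(Intercept)"]), 1)
  expect_error(model_average(f2[0, ]), "empty")
})

test_that("identical trees reduce tree-averaging to the single-tree result", {
  cfg <- simulation_config(n_species = 40, n_posterior_trees = 3,
                           jitter_sd = 0, seed = 5)
  b <- simulate_bundle(cfg)
  st <- species_song_table(derive_song_features(b$songs))
  data <- dplyr::inner_join(st, b$predictors, by = "species")
  small_set <- build_model_set(families = c("BM", "lambda"))
  single <- model_average(
    cumulative_weight_set(fit_model_set(data, "log_pace_hz", b$tree,
                                        small_set)))
  multi <- average_across_trees(b$tree_set, data, "log_pace_hz", small_set)
  joined <- dplyr::inner_join(single$estimates, multi$estimates,
                              by = "parameter")
  expect_equal(joined$averaged_beta.x, joined$averaged_beta.y,
               tolerance = 1e-10)
  expect_equal(multi$tree_count, 3)
  # two trees with per-tree averages 0.4 and 0.6 pool to 0.5
  fake <- tibble::tibble(parameter = c("x", "x"), total_weight = c(1, 1),
                         averaged_beta = c(0.4, 0.6), tree = 1:2,
                         top_family = "BM")
  pooled <- fake |>
    dplyr::group_by(parameter) |>
    dplyr::summarise(averaged_beta = mean(averaged_beta))
  expect_equal(pooled$averaged_beta, 0.5)
})

test_that("a strong generative predictor wins the model competition", {
  # single strong body-size -> frequency effect; reduced problem size
  wins <- logical(6)
  dominant <- logical(6)
  for (i in 1:6) {
    cfg <- simulation_config(
      n_species = 80, n_posterior_trees = 2, seed = 4000 + i,
      beta = list(pace = c(beak_size = 0, log_beak_length = 0,
                           habitat_semi_open = 0, habitat_open = 0),
                  min_freq = c(body_size = -1.5)),
      sigma_freq = 0.15
    )
    b <- simulate_bundle(cfg)
    st <- species_song_table(derive_song_features(b$songs))
    data <- dplyr::inner_join(st, b$predictors, by = "species")
    ms <- fit_model_set(data, "log_min_freq_hz", b$tree)
    wins[i] <- "body_size" %in% ms$fits$terms[[1]]
    w_body <- parameter_total_weight(ms, "body_size")
    others <- c("beak_size", "env_pc1", "habitat_semi_open")
    dominant[i] <- all(w_body > vapply(others, function(p)
      parameter_total_weight(ms, p), numeric(1)))
  }
  expect_gte(mean(wins), 0.8)
  expect_gte(mean(dominant), 0.8)
})

test_that("per-family weighting normalises within each family block", {
  cfg <- simulation_config(n_species = 30, n_posterior_trees = 2, seed = 55)
  b <- simulate_bundle(cfg)
  st <- species_song_table(derive_song_features(b$songs))
  data <- dplyr::inner_join(st, b$predictors, by = "species")
  small <- build_model_set(families = c("BM", "lambda"))
  ms <- fit_model_set(data, "log_pace_hz", b$tree, small,
                      weight_basis = "per_family")
  sums <- tapply(ms$fits$weight, ms$fits$family, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-12)
})
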