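make_songs <- function(species, pace, bw, min_freq = 2000) {
  # back-solve note counts and durations so pace = n_notes / duration_s
  dur <- rep(2, length(pace))
  tibble::tibble(
    species = species,
    n_notes = pace * dur,
    duration_s = dur,
    min_freq_hz = min_freq,
    max_freq_hz = min_freq + bw,
    peak_freq_hz = min_freq + bw / 2
  )
}

test_that("pace and bandwidth are derived and bad recordings rejected", {
  raw <- tibble::tibble(
    species = c("a", "a", "b"),
    n_notes = c(10, 5, 8),
    duration_s = c(2, 0, 4),
    max_freq_hz = c(5000, 4000, 1000),
    min_freq_hz = c(2000, 1000, 3000),
    peak_freq_hz = c(3000, 2000, 3500)
  )
  out <- suppressMessages(derive_song_features(raw))
  expect_equal(out$pace_hz, 5)
  expect_equal(out$bandwidth_hz, 3000)
  rej <- attr(out, "rejected")
  expect_equal(nrow(rej), 2)
  expect_setequal(rej$reason, c("nonpositive duration",
                                "inverted frequency range"))
})

test_that("species aggregation is mean-then-log and drops empty species", {
  songs <- derive_song_features(make_songs(c("a", "a", "b"),
                                           pace = c(4, 6, 3),
                                           bw = c(1000, 2000, 1500)))
  tab <- species_song_table(songs)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$mean_pace_hz[tab$species == "a"], 5)
  expect_equal(tab$log_pace_hz[tab$species == "a"], log(5))
  expect_equal(tab$n_recordings, c(2, 1))
  # a single-record species keeps that record's values
  expect_equal(tab$mean_bandwidth_hz[tab$species == "b"], 1500)
})

test_that("upper-bound regression recovers an exact collinear frontier", {
  pace <- seq(1, 39, by = 2)
  bw <- -79.374 * pace + 5066.2
  songs <- make_songs(paste0("s", seq_along(pace)), pace, bw)
  ub <- upper_bound_regression(derive_song_features(songs))
  expect_equal(ub$slope, -79.374, tolerance = 1e-6)
  expect_equal(ub$intercept, 5066.2, tolerance = 1e-6)
  expect_equal(ub$diagnostics$n_points, 20)
  expect_equal(ub$diagnostics$r_squared, 1, tolerance = 1e-9)
})

test_that("binned maxima honour the bin geometry and tie rule", {
  # data only in bins [0,2) and [4,6): regression through exactly 2 points
  songs <- derive_song_features(
    make_songs(c("a", "b", "c"), pace = c(1, 1.5, 5), bw = c(900, 800, 500)))
  ub <- upper_bound_regression(songs)
  expect_equal(ub$diagnostics$n_points, 2)
  expect_equal(ub$diagnostics$r_squared, 1)
  # within-bin tie on bandwidth resolves to the smaller pace
  tie <- derive_song_features(
    make_songs(c("a", "b", "c"), pace = c(1.8, 1.2, 5), bw = c(700, 700, 500)))
  ub2 <- upper_bound_regression(tie)
  expect_equal(ub2$points$pace_hz[ub2$points$bin_lo == 0], 1.2)
  # input order does not change the fit (except through the tie rule)
  set.seed(1)
  shuffled <- songs[sample(nrow(songs)), ]
  ub3 <- upper_bound_regression(shuffled)
  expect_equal(ub3$slope, ub$slope)
  expect_equal(ub3$intercept, ub$intercept)
  expect_error(upper_bound_regression(songs[3, ]), "insufficient bins")
})

test_that("percentile bound drops thin windows and handles constant data", {
  set.seed(42)
  pace <- runif(500, 0, 6)
  songs <- derive_song_features(make_songs(paste0("s", 1:500), pace,
                                           bw = rep(1234, 500)))
  pb <- percentile_bound(songs, min_count = 32)
  expect_equal(pb$slope, 0, tolerance = 1e-9)
  expect_equal(pb$intercept, 1234, tolerance = 1e-6)
  expect_equal(pb$diagnostics$df_den, pb$diagnostics$n_points - 2)

  # a window holding 31 songs is excluded from the fit
  pace31 <- c(runif(31, 10, 11.99), runif(100, 0, 2), runif(100, 2, 4))
  s31 <- derive_song_features(make_songs(paste0("t", seq_along(pace31)),
                                         pace31, bw = rep(100, 231)))
  pb31 <- percentile_bound(s31, window_width = 2, step = 2, min_count = 32)
  expect_false(any(pb31$points$center > 10))
})

test_that("vocal deviation matches the orthogonal-distance oracle", {
  m <- -79.374
  b <- 5066.2
  bound <- list(slope = m, intercept = b)
  # points on the frontier deviate by zero
  x <- c(2, 10, 30)
  expect_equal(vocal_deviation(x, m * x + b, bound), rep(0, 3))
  # worked constant: pace 10, bandwidth 3000
  expect_equal(vocal_deviation(10, 3000, bound), 16.03, tolerance = 1e-3)
  expect_equal(vocal_deviation(10, 3000, bound),
               bf_line_distance(10, 3000, m, b), tolerance = 1e-6)
  # above the frontier the sign flips negative
  expect_lt(vocal_deviation(10, m * 10 + b + 500, bound), 0)
  # random points agree with the brute-force nearest-point search
  set.seed(8)
  px <- runif(200, 0, 40)
  py <- runif(200, 0, 6000)
  d_pkg <- vocal_deviation(px, py, bound)
  d_bf <- mapply(bf_line_distance, px, py, MoreArgs = list(m = m, b = b))
  expect_lt(max(abs(d_pkg - d_bf)), 1e-6)
})

test_that("species vocal performance is the mean of per-song deviations", {
  bound <- list(slope = -10, intercept = 1000)
  songs <- derive_song_features(
    make_songs(c("a", "a"), pace = c(10, 20), bw = c(800, 500)))
  vp <- species_vocal_performance(songs, bound)
  expect_equal(vp$vocal_deviation,
               mean(vocal_deviation(c(10, 20), c(800, 500), bound)))
})

test_that("binned-max intercept sits at or above the percentile intercept", {
  # frontier-bounded triangular clouds: the frontier estimate should exceed
  # the 90th-percentile line, here compared as a median over replicates
  reps <- 20
  diffs <- vapply(seq_len(reps), function(i) {
    set.seed(100 + i)
    pace <- runif(3000, 0, 20)
    bw <- runif(3000, 0, -100 * pace + 4000)
    songs <- derive_song_features(make_songs(paste0("r", 1:3000), pace, bw))
    ub <- upper_bound_regression(songs)
    pb <- percentile_bound(songs)
    ub$intercept - pb$intercept
  }, numeric(1))
  expect_gt(median(diffs), 0)
})

test_that("configurable variants change only what they claim", {
  songs <- derive_song_features(
    make_songs(c("a", "a", "b"), pace = c(4, 6, 3), bw = c(1000, 2000, 1500)))
  # log-then-mean aggregates per-recording logs
  alt <- species_song_table(songs, order = "log_then_mean")
  expect_equal(alt$log_pace_hz[alt$species == "a"], mean(log(c(4, 6))))
  expect_lt(alt$log_pace_hz[alt$species == "a"], log(5))  # Jensen
  # standardized deviation preserves the on-frontier zero
  bound <- list(slope = -10, intercept = 1000)
  pace <- c(10, 20, 30)
  on_line <- bound$slope * pace + bound$intercept
  expect_equal(vocal_deviation(pace, on_line, bound, standardize = TRUE),
               rep(0, 3))
  # deviation-of-means variant evaluates at the species centroid
  vp2 <- species_vocal_performance(songs, bound,
                                   method = "deviation_of_means")
  expect_equal(vp2$vocal_deviation[vp2$species == "a"],
               vocal_deviation(5, 1500, bound))
  # midpoint x-values shift the regression but keep the bin maxima
  ub_a <- upper_bound_regression(songs)
  ub_m <- upper_bound_regression(songs, x_value = "midpoint")
  expect_equal(ub_a$points$bandwidth_hz, ub_m$points$bandwidth_hz)
})
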