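#' Derive pace and bandwidth from raw song measurements
#'
#' Takes one row per recording with the five core acoustic measurements and
#' appends the two derived variables: pace (note production rate,
#' `n_notes / duration_s`, in Hz) and frequency bandwidth
#' (`max_freq_hz - min_freq_hz`, in Hz). Rows with nonpositive duration or an
#' inverted frequency range are dropped and reported; a peak frequency outside
#' `[min_freq_hz, max_freq_hz]` raises a warning but keeps the row.
#'
#' @param songs A data frame with columns `species`, `n_notes`, `duration_s`,
#'   `max_freq_hz`, `min_freq_hz`, `peak_freq_hz`.
#' @return A tibble with the input columns plus `pace_hz` and `bandwidth_hz`.
#'   Rejected rows (with a `reason` column) are attached as attribute
#'   `"rejected"`.
#' @export
derive_song_features <- function(songs) {
  required <- c("species", "n_notes", "duration_s", "max_freq_hz",
                "min_freq_hz", "peak_freq_hz")
  missing <- setdiff(required, names(songs))
  if (length(missing)) {
    stop("missing song columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  songs <- tibble::as_tibble(songs)
  reason <- dplyr::case_when(
    !is.finite(songs$duration_s) | songs$duration_s <= 0 ~ "nonpositive duration",
    !is.finite(songs$max_freq_hz) | !is.finite(songs$min_freq_hz) |
      songs$max_freq_hz < songs$min_freq_hz ~ "inverted frequency range",
    !is.finite(songs$n_notes) | songs$n_notes <= 0 ~ "nonpositive note count",
    TRUE ~ NA_character_
  )
  rejected <- dplyr::mutate(songs[!is.na(reason), , drop = FALSE],
                            reason = reason[!is.na(reason)])
  if (nrow(rejected)) {
    message(nrow(rejected), " recording(s) rejected: ",
            paste(unique(rejected$reason), collapse = "; "))
  }
  kept <- songs[is.na(reason), , drop = FALSE]
  n_peak_out <- sum(kept$peak_freq_hz < kept$min_freq_hz |
                      kept$peak_freq_hz > kept$max_freq_hz, na.rm = TRUE)
  if (n_peak_out > 0) {
    warning(n_peak_out, " recording(s) have peak frequency outside [min, max]",
            call. = FALSE)
  }
  out <- dplyr::mutate(kept,
    pace_hz = .data$n_notes / .data$duration_s,
    bandwidth_hz = .data$max_freq_hz - .data$min_freq_hz
  )
  attr(out, "rejected") <- rejected
  out
}

# the seven species-level song traits carried through the analysis
song_trait_vars <- c("peak_freq_hz", "bandwidth_hz", "max_freq_hz",
                     "min_freq_hz", "duration_s", "n_notes", "pace_hz")

#' Aggregate per-recording songs to a species-level table
#'
#' Computes the arithmetic mean of each song variable per species on the raw
#' scale, then natural-log-transforms the means (mean-then-log, the default).
#' The alternative order (`"log_then_mean"`: per-recording logs averaged per
#' species) is available for sensitivity analyses. Species whose mean is
#' nonpositive for any logged variable are dropped with a message, as are
#' species with zero recordings.
#'
#' @param songs A tibble from [derive_song_features()].
#' @param order `"mean_then_log"` (default) or `"log_then_mean"`.
#' @return A tibble with one row per species: `n_recordings`, the raw means
#'   (`mean_<var>`), and the logged traits (`log_<var>`).
#' @export
species_song_table <- function(songs,
                               order = c("mean_then_log", "log_then_mean")) {
  order <- match.arg(order)
  out <- songs |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_recordings = dplyr::n(),
      dplyr::across(dplyr::all_of(song_trait_vars), mean, .names = "mean_{.col}"),
      .groups = "drop"
    )
  mean_cols <- paste0("mean_", song_trait_vars)
  bad <- apply(out[mean_cols] <= 0 | !is.finite(as.matrix(out[mean_cols])), 1, any)
  if (any(bad)) {
    message(sum(bad), " species dropped (nonpositive mean song variable): ",
            paste(out$species[bad], collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  if (order == "mean_then_log") {
    for (v in song_trait_vars) {
      out[[paste0("log_", v)]] <- log(out[[paste0("mean_", v)]])
    }
  } else {
    logs <- songs |>
      dplyr::filter(.data$species %in% out$species) |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(
        dplyr::across(dplyr::all_of(song_trait_vars),
                      function(x) mean(log(x)), .names = "log_{.col}"),
        .groups = "drop"
      )
    out <- dplyr::left_join(out, logs, by = "species")
  }
  dplyr::arrange(out, .data$species)
}

new_upper_bound <- function(slope, intercept, method, diagnostics, points) {
  structure(
    list(slope = slope, intercept = intercept, method = method,
         diagnostics = diagnostics, points = points),
    class = "upper_bound"
  )
}

#' @export
print.upper_bound <- function(x, ...) {
  cat(sprintf("<upper_bound> %s: bandwidth = %.4f * pace + %.4f (R^2 = %.3f, n = %d)\n",
              x$method, x$slope, x$intercept, x$diagnostics$r_squared,
              x$diagnostics$n_points))
  invisible(x)
}

bound_diagnostics <- function(fit, n_points) {
  # collinear frontiers fit exactly; the perfect-fit warning is expected there
  s <- suppressWarnings(summary(fit))
  fstat <- s$fstatistic
  list(
    r_squared = unname(s$r.squared),
    f_statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    df_num = if (is.null(fstat)) NA_real_ else unname(fstat[2]),
    df_den = if (is.null(fstat)) NA_real_ else unname(fstat[3]),
    p_value = if (is.null(fstat)) {
      NA_real_
    } else {
      unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
    },
    n_points = n_points
  )
}

#' Upper-bound regression through binned bandwidth maxima
#'
#' The traditional frontier estimator for a triangular bivariate distribution:
#' pace is cut into half-open bins `[lo, lo + bin_width)` (the last bin
#' closed), the song with the maximum bandwidth is selected within each
#' nonempty bin (ties broken by smaller pace, then input order), and an
#' ordinary least-squares line is fitted through the selected songs'
#' (pace, bandwidth) pairs.
#'
#' @param songs A tibble with `pace_hz` and `bandwidth_hz` columns.
#' @param bin_width Pace bin width in Hz (default 2).
#' @param bin_range Numeric length-2 range of the bin grid; defaults to
#'   `c(0, ceiling(max(pace)))`, extended upward so the grid covers the data.
#' @param x_value `"actual"` regresses on each selected song's own pace;
#'   `"midpoint"` uses the bin midpoint instead.
#' @return An `"upper_bound"` object (`method = "binned_max"`); its `points`
#'   element holds the selected per-bin maxima.
#' @export
upper_bound_regression <- function(songs, bin_width = 2, bin_range = NULL,
                                   x_value = c("actual", "midpoint")) {
  x_value <- match.arg(x_value)
  stopifnot(bin_width > 0)
  pace <- songs$pace_hz
  bw <- songs$bandwidth_hz
  if (is.null(bin_range)) bin_range <- c(0, ceiling(max(pace)))
  breaks <- seq(bin_range[1], by = bin_width,
                length.out = ceiling((bin_range[2] - bin_range[1]) / bin_width) + 1L)
  if (max(breaks) < max(pace)) breaks <- c(breaks, max(breaks) + bin_width)

  # half-open [lo, lo+width), last bin closed on the right
  bin <- findInterval(pace, breaks, rightmost.closed = TRUE)
  keep <- bin >= 1L & bin <= length(breaks) - 1L
  df <- tibble::tibble(pace_hz = pace[keep], bandwidth_hz = bw[keep],
                       bin = bin[keep], .row = seq_along(pace)[keep])
  sel <- df |>
    dplyr::group_by(.data$bin) |>
    dplyr::arrange(dplyr::desc(.data$bandwidth_hz), .data$pace_hz, .data$.row,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::mutate(bin_lo = breaks[.data$bin],
                  bin_mid = breaks[.data$bin] + bin_width / 2)
  if (nrow(sel) < 2L) stop("insufficient bins: need >= 2 nonempty pace bins",
                           call. = FALSE)
  sel$x <- if (x_value == "actual") sel$pace_hz else sel$bin_mid
  fit <- stats::lm(bandwidth_hz ~ x, data = sel)
  co <- stats::coef(fit)
  new_upper_bound(unname(co[2]), unname(co[1]), "binned_max",
                  bound_diagnostics(fit, nrow(sel)),
                  dplyr::select(sel, -".row"))
}

#' Sliding-window 90th-percentile bound
#'
#' A robust alternative to the binned-maximum frontier: a window of width
#' `window_width` Hz slides along the pace axis in steps of `step` Hz; within
#' each window holding at least `min_count` songs, the `q`-th percentile of
#' bandwidth is computed (linear interpolation), and an OLS line is fitted
#' through the (window centre, percentile) pairs. Windows with fewer than
#' `min_count` songs are dropped to avoid outlier-driven sampling error.
#'
#' @param songs A tibble with `pace_hz` and `bandwidth_hz` columns.
#' @param window_width Window width in Hz (default 2).
#' @param step Step between successive window starts in Hz (default 1).
#' @param q Percentile of bandwidth to track (default 90).
#' @param min_count Minimum songs per retained window (default 32).
#' @return An `"upper_bound"` object (`method = "percentile"`); `points` holds
#'   the retained window centres, counts and percentiles. Regression degrees
#'   of freedom are `(1, n_windows - 2)`.
#' @export
percentile_bound <- function(songs, window_width = 2, step = 1, q = 90,
                             min_count = 32) {
  stopifnot(window_width > 0, step > 0, q > 0, q < 100)
  pace <- songs$pace_hz
  bw <- songs$bandwidth_hz
  starts <- seq(0, max(pace), by = step)
  wins <- purrr::map_dfr(starts, function(lo) {
    hi <- lo + window_width
    inside <- pace >= lo & pace < hi
    tibble::tibble(center = lo + window_width / 2, count = sum(inside),
                   percentile = if (sum(inside) > 0) {
                     unname(stats::quantile(bw[inside], q / 100, type = 7))
                   } else NA_real_)
  })
  kept <- wins[wins$count >= min_count, , drop = FALSE]
  if (nrow(kept) < 2L) {
    stop("insufficient windows: fewer than 2 windows hold >= ", min_count,
         " songs", call. = FALSE)
  }
  fit <- stats::lm(percentile ~ center, data = kept)
  co <- stats::coef(fit)
  diag <- bound_diagnostics(fit, nrow(kept))
  diag$df_num <- 1
  diag$df_den <- nrow(kept) - 2
  new_upper_bound(unname(co[2]), unname(co[1]), "percentile", diag, kept)
}

#' Signed orthogonal distance from the performance frontier
#'
#' Vocal deviation is the minimum (orthogonal) Euclidean distance of a song
#' from the upper-bound line in the pace-bandwidth plane, in the line's mixed
#' units (pace in Hz of notes, bandwidth in Hz of frequency). With frontier
#' slope `m` and intercept `b`, `d = (m * pace - bw + b) / sqrt(m^2 + 1)`:
#' positive below the frontier (low vocal performance), negative above, zero
#' exactly on it.
#'
#' @param pace,bw Numeric vectors of pace (Hz) and bandwidth (Hz).
#' @param bound An `"upper_bound"` object (or a list with `slope` and
#'   `intercept`).
#' @param standardize If `TRUE`, both axes are divided by their standard
#'   deviations (computed from `pace` and `bw`) before the distance is
#'   measured, removing the dominance of the bandwidth axis; off by default
#'   to match the frontier's raw mixed units.
#' @return Numeric vector of signed deviations.
#' @examples
#' b <- list(slope = -79.374, intercept = 5066.2)
#' vocal_deviation(10, 3000, b)
#' @export
vocal_deviation <- function(pace, bw, bound, standardize = FALSE) {
  m <- bound$slope
  b <- bound$intercept
  if (standardize) {
    sx <- stats::sd(pace)
    sy <- stats::sd(bw)
    if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
      stop("standardized deviation needs > 1 distinct value on each axis",
           call. = FALSE)
    }
    m <- m * sx / sy
    b <- b / sy
    pace <- pace / sx
    bw <- bw / sy
  }
  (m * pace - bw + b) / sqrt(m^2 + 1)
}

#' Species-level vocal performance scores
#'
#' Appends per-song vocal deviation and summarises it per species as the mean
#' of per-song deviations (higher deviation = lower vocal performance). The
#' alternative (`"deviation_of_means"`: deviation evaluated at the species
#' mean pace and bandwidth) is available for sensitivity analyses.
#'
#' @param songs A tibble from [derive_song_features()].
#' @param bound An `"upper_bound"` object.
#' @param method `"mean_deviation"` (default) or `"deviation_of_means"`.
#' @return A tibble with one row per species: `vocal_deviation` and
#'   `n_recordings`.
#' @export
species_vocal_performance <- function(songs, bound,
                                      method = c("mean_deviation",
                                                 "deviation_of_means")) {
  method <- match.arg(method)
  if (method == "mean_deviation") {
    songs |>
      dplyr::mutate(deviation = vocal_deviation(.data$pace_hz,
                                                .data$bandwidth_hz, bound)) |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(vocal_deviation = mean(.data$deviation),
                       n_recordings = dplyr::n(), .groups = "drop") |>
      dplyr::arrange(.data$species)
  } else {
    songs |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(
        vocal_deviation = vocal_deviation(mean(.data$pace_hz),
                                          mean(.data$bandwidth_hz), bound),
        n_recordings = dplyr::n(), .groups = "drop") |>
      dplyr::arrange(.data$species)
  }
}

#' @rdname tidiers
#' @export
tidy.upper_bound <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname tidiers
#' @export
glance.upper_bound <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    method = x$method, slope = x$slope, intercept = x$intercept,
    r_squared = d$r_squared, f_statistic = d$f_statistic,
    df_num = d$df_num, df_den = d$df_den, p_value = d$p_value,
    n_points = d$n_points
  )
}

#' Plot a song cloud with its fitted frontier
#'
#' @param songs A tibble with `pace_hz` and `bandwidth_hz`.
#' @param bound An `"upper_bound"` object (optional; drawn as a line).
#' @return A ggplot object.
#' @export
plot_frontier <- function(songs, bound = NULL) {
  p <- ggplot2::ggplot(songs, ggplot2::aes(x = .data$pace_hz,
                                           y = .data$bandwidth_hz)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::labs(x = "Pace (Hz)", y = "Frequency bandwidth (Hz)")
  if (!is.null(bound)) {
    p <- p + ggplot2::geom_abline(slope = bound$slope,
                                  intercept = bound$intercept,
                                  colour = "firebrick")
  }
  p
}
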