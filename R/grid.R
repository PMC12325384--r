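#' Construct a multielectrode site grid
#'
#' Builds the geometry of a rectangular microelectrode array spanning a fixed
#' cortical extent (default 4 x 4 mm, matching a 10 x 10 Utah-style array).
#' Corner sites can be flagged offline, which reproduces the common situation
#' where the four corner pads of a 10 x 10 array are not wired, leaving 96
#' active recording sites.
#'
#' Active sites are ordered row-major (row 1 left-to-right, then row 2, ...),
#' skipping offline sites; this ordering is fixed so that feature indices are
#' comparable across sessions and animals.
#'
#' @param rows,cols Grid dimensions (each >= 2).
#' @param offline_corners If `TRUE` (default) the four corner sites are marked
#'   offline and excluded from all downstream feature vectors.
#' @param extent_mm Physical extent of the grid, `c(width, height)` in mm.
#'   Sites are placed at the centers of an even subdivision.
#' @return An object of class `site_grid`: a list with `rows`, `cols`,
#'   `extent_mm`, and `sites`, a data frame with one row per grid position
#'   (`row`, `col`, `x`, `y` in mm, logical `active`, and `site` = index among
#'   active sites or `NA`).
#' @examples
#' g <- make_grid(10, 10)
#' sum(g$sites$active)  # 96
#' @export
make_grid <- function(rows = 10, cols = 10, offline_corners = TRUE,
                      extent_mm = c(4, 4)) {
  if (length(rows) != 1 || length(cols) != 1 || rows < 2 || cols < 2 ||
      rows != round(rows) || cols != round(cols)) {
    stop("`rows` and `cols` must be integers >= 2")
  }
  xs <- (seq_len(cols) - 0.5) / cols * extent_mm[1]
  ys <- (seq_len(rows) - 0.5) / rows * extent_mm[2]
  sites <- expand.grid(col = seq_len(cols), row = seq_len(rows))[, c("row", "col")]
  sites$x <- xs[sites$col]
  sites$y <- ys[sites$row]
  sites$active <- TRUE
  if (offline_corners) {
    corner <- (sites$row %in% c(1, rows)) & (sites$col %in% c(1, cols))
    sites$active[corner] <- FALSE
  }
  sites$site <- NA_integer_
  sites$site[sites$active] <- seq_len(sum(sites$active))
  structure(
    list(rows = rows, cols = cols, extent_mm = extent_mm, sites = sites),
    class = "site_grid"
  )
}

#' Number of active sites in a grid
#' @param grid A `site_grid`.
#' @return Integer count of active sites.
#' @export
n_active_sites <- function(grid) {
  stopifnot(inherits(grid, "site_grid"))
  sum(grid$sites$active)
}

#' Positions of active sites
#' @param grid A `site_grid`.
#' @return Data frame of active sites in the fixed row-major ordering, with
#'   columns `site`, `row`, `col`, `x`, `y`.
#' @export
active_sites <- function(grid) {
  stopifnot(inherits(grid, "site_grid"))
  s <- grid$sites[grid$sites$active, c("site", "row", "col", "x", "y")]
  s[order(s$site), , drop = FALSE]
}

#' @export
print.site_grid <- function(x, ...) {
  cat(sprintf("<site_grid> %d x %d over %.1f x %.1f mm, %d active sites\n",
              x$rows, x$cols, x$extent_mm[1], x$extent_mm[2], n_active_sites(x)))
  invisible(x)
}

#' Construct a pure-tone trial schedule
#'
#' Lays out a session of long pure tones interleaved with silent gaps. The
#' default reproduces the study design this package targets: five test
#' frequencies (8, 10, 13, 16, 32 kHz), each presented seven times as a 29-s
#' tone interleaved with 29-s silence, with frequency order pseudorandomized
#' within each repetition block ("sequence"). The session starts with one
#' leading silent gap.
#'
#' @param frequencies Tone frequencies in Hz.
#' @param repetitions Number of presentations per frequency.
#' @param tone_s Tone duration in seconds.
#' @param gap_s Silent gap duration in seconds.
#' @param seed Integer seed for the pseudorandom ordering.
#' @return An object of class `trial_schedule`: a list with the parameters and
#'   `trials`, a data frame (`trial`, `freq_hz`, `onset_ms`, `dur_ms`) ordered
#'   by onset. `total_ms` gives the session length.
#' @examples
#' sch <- make_schedule(tone_s = 4, gap_s = 1, seed = 1)
#' table(sch$trials$freq_hz)
#' @export
make_schedule <- function(frequencies = c(8000, 10000, 13000, 16000, 32000),
                          repetitions = 7, tone_s = 29, gap_s = 29, seed = 1) {
  if (anyDuplicated(frequencies)) stop("`frequencies` must be distinct")
  if (tone_s <= 0 || gap_s < 0) stop("durations must be positive")
  if (repetitions < 1) stop("`repetitions` must be >= 1")
  local_rng(seed)
  order_all <- unlist(lapply(seq_len(repetitions), function(b) sample(frequencies)))
  n <- length(order_all)
  tone_ms <- round(tone_s * 1000)
  gap_ms <- round(gap_s * 1000)
  onsets <- gap_ms + (seq_len(n) - 1) * (tone_ms + gap_ms)
  trials <- data.frame(
    trial = seq_len(n),
    freq_hz = order_all,
    onset_ms = onsets,
    dur_ms = tone_ms
  )
  structure(
    list(frequencies = sort(frequencies), repetitions = repetitions,
         tone_ms = tone_ms, gap_ms = gap_ms, trials = trials,
         total_ms = gap_ms + n * (tone_ms + gap_ms), seed = seed),
    class = "trial_schedule"
  )
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %d tones (%d freqs x %d reps), %d ms tone / %d ms gap, total %.1f min\n",
              nrow(x$trials), length(x$frequencies), x$repetitions,
              x$tone_ms, x$gap_ms, x$total_ms / 60000))
  invisible(x)
}

# Seed the RNG for the duration of the calling function, restoring the
# caller's random stream afterwards.
local_rng <- function(seed, env = parent.frame()) {
  withr::local_seed(seed, .local_envir = env)
  invisible(NULL)
}
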