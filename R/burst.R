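#' Per-site standard deviation over consecutive windows
#'
#' Slices the recording into consecutive non-overlapping windows (default
#' 100 ms) and computes the population standard deviation of each site's
#' samples in each window. A partial trailing window is discarded.
#'
#' @param lfp Sites-by-samples matrix (uV).
#' @param win_ms Window length in ms (default 100).
#' @param fs Sampling rate in Hz (default 1000).
#' @return Sites-by-windows matrix of SD values, with attribute `win_ms`.
#' @export
window_sd <- function(lfp, win_ms = 100, fs = 1000) {
  if (!is.matrix(lfp) || ncol(lfp) == 0) stop("`lfp` must be a non-empty matrix")
  w <- round(win_ms * fs / 1000)
  n_win <- ncol(lfp) %/% w
  if (n_win < 1) stop("signal shorter than one window")
  use <- lfp[, seq_len(n_win * w), drop = FALSE]
  # population SD per (site, window): sqrt(E[x^2] - E[x]^2) on each slice
  sds <- vapply(seq_len(n_win), function(j) {
    seg <- use[, ((j - 1) * w + 1):(j * w), drop = FALSE]
    sqrt(rowMeans(seg^2) - rowMeans(seg)^2)
  }, numeric(nrow(lfp)))
  sds <- matrix(sds, nrow = nrow(lfp))
  attr(sds, "win_ms") <- win_ms
  sds
}

#' Classify bursting epochs from windowed SD
#'
#' A 100-ms window is supra-threshold when its SD exceeds the per-site
#' threshold at more than `site_count_threshold` sites; runs of consecutive
#' supra-threshold windows spanning at least `min_duration_ms` are classified
#' as bursting. Since the SD is computed on a 100-ms grid, intervals snap to
#' window boundaries, and a 150-ms minimum requires two consecutive
#' supra-threshold windows.
#'
#' The threshold is per site: `sd_multiplier` times the median of that site's
#' windowed SDs over the whole recording (robust against the bursts themselves
#' inflating the scale). An explicit `thresholds` vector overrides the rule.
#'
#' @param sd_series Sites-by-windows SD matrix from [window_sd()].
#' @param site_count_threshold Burst requires strictly more than this many
#'   supra-threshold sites (default 24, i.e. >= 25 sites trigger).
#' @param min_duration_ms Minimum burst span in ms (default 150).
#' @param sd_multiplier Threshold = multiplier x per-site median SD (default 3).
#' @param thresholds Optional explicit per-site thresholds (uV).
#' @param win_ms Window length matching `sd_series` (taken from its attribute
#'   when present).
#' @return A `burst_mask`: list with `intervals` (data frame `start_ms`,
#'   `end_ms`, sorted, non-overlapping), `exceed_counts` (per window),
#'   `thresholds`, `win_ms`, `sd_series` and the rule parameters.
#' @export
classify_bursts <- function(sd_series, site_count_threshold = 24,
                            min_duration_ms = 150, sd_multiplier = 3,
                            thresholds = NULL, win_ms = NULL) {
  if (!is.matrix(sd_series) || nrow(sd_series) == 0) {
    stop("`sd_series` must have at least one site")
  }
  if (is.null(win_ms)) win_ms <- attr(sd_series, "win_ms")
  if (is.null(win_ms)) win_ms <- 100
  if (site_count_threshold < 0 || min_duration_ms <= 0 || sd_multiplier <= 0) {
    stop("thresholds must be positive")
  }
  if (is.null(thresholds)) {
    thresholds <- sd_multiplier * apply(sd_series, 1, stats::median)
  }
  if (length(thresholds) != nrow(sd_series)) {
    stop("`thresholds` must have one value per site")
  }
  exceed <- colSums(sd_series > thresholds)
  supra <- exceed > site_count_threshold
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths * win_ms >= min_duration_ms)
  intervals <- data.frame(
    start_ms = (starts[keep] - 1) * win_ms,
    end_ms = ends[keep] * win_ms
  )
  structure(list(
    intervals = intervals, exceed_counts = exceed, thresholds = thresholds,
    sd_series = sd_series, win_ms = win_ms,
    site_count_threshold = site_count_threshold,
    min_duration_ms = min_duration_ms, sd_multiplier = sd_multiplier
  ), class = "burst_mask")
}

#' @export
print.burst_mask <- function(x, ...) {
  cat(sprintf("<burst_mask> %d interval(s), %.1f s bursting of %.1f s (>%d sites, >=%d ms)\n",
              nrow(x$intervals), sum(x$intervals$end_ms - x$intervals$start_ms) / 1000,
              length(x$exceed_counts) * x$win_ms / 1000,
              x$site_count_threshold, x$min_duration_ms))
  invisible(x)
}

#' Total bursting duration of a mask
#' @param mask A `burst_mask`.
#' @return Total bursting time in ms.
#' @export
burst_duration_ms <- function(mask) {
  sum(mask$intervals$end_ms - mask$intervals$start_ms)
}

#' Jaccard overlap between two interval sets
#'
#' Intersection-over-union of total time covered by two sets of
#' `[start_ms, end_ms)` intervals; used to score detected bursts against the
#' generator's ground truth.
#'
#' @param a,b Data frames with `start_ms`, `end_ms`.
#' @return Jaccard index in \[0, 1\] (1 when both sets are empty).
#' @export
interval_jaccard <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(1)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  a <- merge_intervals(a); b <- merge_intervals(b)
  hi <- max(a$end_ms, b$end_ms)
  cover <- function(iv) {
    v <- logical(hi)
    for (i in seq_len(nrow(iv))) {
      if (iv$end_ms[i] > iv$start_ms[i]) v[(iv$start_ms[i] + 1):iv$end_ms[i]] <- TRUE
    }
    v
  }
  ca <- cover(a); cb <- cover(b)
  sum(ca & cb) / sum(ca | cb)
}

#' Extract non-burst one-second analysis windows
#'
#' Candidate windows tile each tone presentation in consecutive
#' non-overlapping steps of `window_ms`, starting `onset_exclusion_s` after
#' tone onset (the initial transient onset response is excluded). Candidates
#' overlapping any burst interval are dropped. Exactly `n_per_label` windows
#' per tone frequency are then retained by deterministic uniform subsampling
#' across the surviving candidates in acquisition order (evenly spaced
#' positions; `seed` is unused unless needed to break remainder ties, and the
#' selection is reproducible either way). If fewer than `n_per_label`
#' candidates survive for some frequency, an explicit shortfall error names
#' the frequency and counts -- there is never silent padding.
#'
#' @param session A `recording_session`.
#' @param mask A `burst_mask` for the same session.
#' @param onset_exclusion_s Seconds excluded after each tone onset (default 1).
#' @param window_ms Analysis window length (default 1000).
#' @param n_per_label Retained windows per frequency (default 70); `NULL`
#'   keeps all candidates.
#' @param seed Integer seed (tie-breaking only).
#' @return Data frame of class `analysis_windows`: `window`, `trial`,
#'   `freq_hz`, `start_ms` (window is `[start_ms, start_ms + window_ms)`),
#'   ordered by acquisition time.
#' @export
extract_analysis_windows <- function(session, mask, onset_exclusion_s = 1,
                                     window_ms = 1000, n_per_label = 70,
                                     seed = 1) {
  stopifnot(inherits(session, "recording_session"))
  if (window_ms %% (1000 / session$fs) != 0) {
    stop("`window_ms` must be a multiple of the sample period")
  }
  tr <- session$schedule$trials
  excl_ms <- round(onset_exclusion_s * 1000)
  cand <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    first <- tr$onset_ms[i] + excl_ms
    last <- tr$onset_ms[i] + tr$dur_ms[i] - window_ms
    if (last < first) return(NULL)
    starts <- seq(first, last, by = window_ms)
    data.frame(trial = tr$trial[i], freq_hz = tr$freq_hz[i], start_ms = starts)
  }))
  if (is.null(cand)) stop("tone presentations too short for any analysis window")
  # drop candidates overlapping any burst interval
  iv <- mask$intervals
  if (nrow(iv) > 0) {
    ok <- !vapply(cand$start_ms, function(s) {
      any(iv$start_ms < s + window_ms & iv$end_ms > s)
    }, logical(1))
    cand <- cand[ok, , drop = FALSE]
  }
  cand <- cand[order(cand$start_ms), , drop = FALSE]
  if (!is.null(n_per_label)) {
    kept <- lapply(split(cand, cand$freq_hz), function(d) {
      m <- nrow(d)
      if (m < n_per_label) {
        stop(sprintf(
          "shortfall for %g Hz: %d non-burst candidate window(s), %d required",
          d$freq_hz[1], m, n_per_label))
      }
      pick <- floor((seq_len(n_per_label) - 1) * m / n_per_label) + 1
      d[pick, , drop = FALSE]
    })
    cand <- do.call(rbind, kept)
    cand <- cand[order(cand$start_ms), , drop = FALSE]
  }
  cand$window <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  out <- cand[, c("window", "trial", "freq_hz", "start_ms")]
  class(out) <- c("analysis_windows", "data.frame")
  attr(out, "window_ms") <- window_ms
  attr(out, "session_id") <- session$session_id
  out
}
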