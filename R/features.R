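#' Build a band-specific feature table from analysis windows
#'
#' For each retained one-second window, computes either per-site band power
#' (RMS of the band-pass-filtered LFP, one column per active site) or the
#' phase-locking values between all site pairs (one column per unordered pair
#' in fixed lexicographic order; `choose(96, 2) = 4560` for a full array).
#'
#' Filtering and the analytic signal are computed on the full contiguous
#' recording and the one-second windows cropped out afterwards, so both
#' operators see maximal context and their edge distortion never reaches a
#' window interior. Windows closer than `pad_ms` to a recording edge, or
#' containing an all-zero (phase-undefined) site, are flagged and excluded
#' from the table rather than given arbitrary values.
#'
#' @param session A `recording_session`.
#' @param windows An `analysis_windows` data frame from
#'   [extract_analysis_windows()] for the *same* session.
#' @param band A `band_definition` or canonical band name.
#' @param kind `"power"` or `"plv"`.
#' @param pad_ms Minimum distance (ms) from a window to a recording edge
#'   before the window is flagged as edge-distorted (default 500).
#' @return A `feature_table`: list with `x` (windows x features matrix; power
#'   in uV, PLV in \[0, 1\]), `label` (tone frequency in Hz per row, rows in
#'   acquisition order), `band`, `kind`, `session_id`, `windows` (the
#'   retained window metadata) and `dropped` (flagged windows, if any).
#' @export
build_feature_table <- function(session, windows, band, kind = c("power", "plv"),
                                pad_ms = 500) {
  kind <- match.arg(kind)
  stopifnot(inherits(session, "recording_session"))
  sid <- attr(windows, "session_id")
  if (!is.null(sid) && !identical(sid, session$session_id)) {
    stop("`windows` were extracted from session '", sid,
         "', not '", session$session_id, "'")
  }
  band <- as_band(band, session$fs)
  window_ms <- attr(windows, "window_ms")
  if (is.null(window_ms)) window_ms <- 1000
  S <- nrow(session$lfp)
  n <- ncol(session$lfp)
  p <- if (kind == "power") S else choose(S, 2)
  feat_names <- if (kind == "power") paste0("site", seq_len(S)) else plv_pair_names(S)

  if (nrow(windows) == 0) {
    return(empty_feature_table(p, feat_names, band, kind, session$session_id))
  }

  filt <- bandpass(session$lfp, band, session$fs)
  ph <- if (kind == "plv") analytic_phase(filt) else NULL
  rows <- vector("list", nrow(windows))
  flagged <- logical(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    a <- windows$start_ms[i] + 1           # first sample of the window
    b <- a + window_ms - 1
    edge_short <- (a - pad_ms < 1) || (b + pad_ms > n)
    win_raw <- session$lfp[, a:b, drop = FALSE]
    degenerate <- any(rowSums(win_raw != 0) == 0)
    if (edge_short || degenerate) {
      flagged[i] <- TRUE
      next
    }
    rows[[i]] <- if (kind == "power") {
      band_power(filt[, a:b, drop = FALSE])
    } else {
      plv_matrix(ph[, a:b, drop = FALSE])
    }
  }
  keep <- !flagged
  x <- do.call(rbind, rows[keep])
  if (is.null(x)) x <- matrix(numeric(0), 0, p)
  colnames(x) <- feat_names
  structure(list(
    x = x, label = windows$freq_hz[keep], band = band$band, kind = kind,
    session_id = session$session_id,
    windows = windows[keep, , drop = FALSE],
    dropped = windows[flagged, , drop = FALSE]
  ), class = "feature_table")
}

empty_feature_table <- function(p, feat_names, band, kind, session_id) {
  x <- matrix(numeric(0), 0, p)
  colnames(x) <- feat_names
  structure(list(x = x, label = numeric(0), band = band$band, kind = kind,
                 session_id = session_id,
                 windows = data.frame(window = integer(0), trial = integer(0),
                                      freq_hz = numeric(0), start_ms = numeric(0)),
                 dropped = NULL),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s %s: %d windows x %d features, labels {%s} Hz\n",
              x$band, x$kind, nrow(x$x), ncol(x$x),
              paste(sort(unique(x$label)), collapse = ", ")))
  invisible(x)
}

#' Subset a feature table to a label set
#' @param table A `feature_table`.
#' @param labels Frequencies (Hz) to keep.
#' @return A `feature_table` restricted to rows with those labels.
#' @export
subset_labels <- function(table, labels) {
  stopifnot(inherits(table, "feature_table"))
  keep <- table$label %in% labels
  table$x <- table$x[keep, , drop = FALSE]
  table$windows <- table$windows[keep, , drop = FALSE]
  table$label <- table$label[keep]
  table
}

# --- shared-spectrum fast path -----------------------------------------------
# decode_session extracts several band/kind feature tables from one session;
# computing each site's padded FFT once and deriving every band (and, for PLV,
# the analytic signal in the same inverse transform) halves the transform work
# relative to repeated build_feature_table calls.

session_spectra <- function(session) {
  n <- ncol(session$lfp)
  np <- stats::nextn(n, c(2, 3, 5))
  list(
    np = np, n = n,
    X = lapply(seq_len(nrow(session$lfp)), function(s) {
      stats::fft(c(session$lfp[s, ], numeric(np - n)))
    })
  )
}

features_from_spectra <- function(session, windows, band, kind, spectra,
                                  pad_ms = 500, order = 4) {
  stopifnot(inherits(session, "recording_session"))
  band <- as_band(band, session$fs)
  window_ms <- attr(windows, "window_ms")
  if (is.null(window_ms)) window_ms <- 1000
  S <- nrow(session$lfp)
  n <- spectra$n
  np <- spectra$np
  p <- if (kind == "power") S else choose(S, 2)
  feat_names <- if (kind == "power") paste0("site", seq_len(S)) else plv_pair_names(S)
  if (nrow(windows) == 0) {
    return(empty_feature_table(p, feat_names, band, kind, session$session_id))
  }
  flt <- signal::butter(order, c(band$low_hz, band$high_hz) / (session$fs / 2),
                        type = "pass")
  mag2 <- butter_mag2(flt, np)
  if (kind == "plv") {
    h <- numeric(np)
    if (np %% 2 == 0) {
      h[c(1, np / 2 + 1)] <- 1
      h[2:(np / 2)] <- 2
    } else {
      h[1] <- 1
      h[2:((np + 1) / 2)] <- 2
    }
    sig <- t(vapply(spectra$X, function(X) {
      Arg(stats::fft(X * mag2 * h, inverse = TRUE)[seq_len(n)])
    }, numeric(n)))
  } else {
    sig <- t(vapply(spectra$X, function(X) {
      Re(stats::fft(X * mag2, inverse = TRUE) / np)[seq_len(n)]
    }, numeric(n)))
  }
  rows <- vector("list", nrow(windows))
  flagged <- logical(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    a <- windows$start_ms[i] + 1
    b <- a + window_ms - 1
    edge_short <- (a - pad_ms < 1) || (b + pad_ms > n)
    win_raw <- session$lfp[, a:b, drop = FALSE]
    degenerate <- any(rowSums(win_raw != 0) == 0)
    if (edge_short || degenerate) {
      flagged[i] <- TRUE
      next
    }
    rows[[i]] <- if (kind == "power") {
      band_power(sig[, a:b, drop = FALSE])
    } else {
      plv_matrix(sig[, a:b, drop = FALSE])
    }
  }
  keep <- !flagged
  x <- do.call(rbind, rows[keep])
  if (is.null(x)) x <- matrix(numeric(0), 0, p)
  colnames(x) <- feat_names
  structure(list(
    x = x, label = windows$freq_hz[keep], band = band$band, kind = kind,
    session_id = session$session_id,
    windows = windows[keep, , drop = FALSE],
    dropped = windows[flagged, , drop = FALSE]
  ), class = "feature_table")
}
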