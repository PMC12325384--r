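#' Canonical frequency bands
#'
#' The five analysis bands used throughout the package: theta (4-8 Hz),
#' alpha (8-14 Hz), beta (14-30 Hz), low-gamma (30-40 Hz) and high-gamma
#' (60-80 Hz). Bands are deliberately narrow so that the instantaneous angle
#' obtained from the analytic signal is well defined.
#'
#' @return Data frame with columns `band`, `low_hz`, `high_hz`.
#' @export
canonical_bands <- function() {
  data.frame(
    band = c("theta", "alpha", "beta", "low_gamma", "high_gamma"),
    low_hz = c(4, 8, 14, 30, 60),
    high_hz = c(8, 14, 30, 40, 80),
    stringsAsFactors = FALSE
  )
}

#' Define a frequency band
#'
#' @param band Either the name of a canonical band (see [canonical_bands()])
#'   or a custom name when `low_hz`/`high_hz` are given.
#' @param low_hz,high_hz Band edges in Hz (needed only for custom bands).
#' @param fs Sampling rate in Hz; edges must lie below Nyquist.
#' @param allow_wide Above 30 Hz, bands wider than one octave distort
#'   instantaneous-phase estimates; such bands are rejected unless
#'   `allow_wide = TRUE`.
#' @return A `band_definition` list with `band`, `low_hz`, `high_hz`.
#' @export
band_definition <- function(band, low_hz = NULL, high_hz = NULL, fs = 1000,
                            allow_wide = FALSE) {
  if (is.null(low_hz) || is.null(high_hz)) {
    cb <- canonical_bands()
    i <- match(band, cb$band)
    if (is.na(i)) {
      stop("unknown band '", band, "'; give `low_hz` and `high_hz` or one of: ",
           paste(cb$band, collapse = ", "))
    }
    low_hz <- cb$low_hz[i]
    high_hz <- cb$high_hz[i]
  }
  if (!(low_hz > 0 && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
  if (high_hz >= fs / 2) {
    stop(sprintf("band edge %g Hz at/above Nyquist (%g Hz)", high_hz, fs / 2))
  }
  if (!allow_wide && low_hz >= 30 && log2(high_hz / low_hz) > 1) {
    stop("bands above 30 Hz wider than one octave blur instantaneous phase; ",
         "set allow_wide = TRUE to override")
  }
  structure(list(band = band, low_hz = low_hz, high_hz = high_hz),
            class = "band_definition")
}

as_band <- function(band, fs = 1000) {
  if (inherits(band, "band_definition")) band else band_definition(band, fs = fs)
}

#' Zero-phase bandpass filter
#'
#' 4th-order Butterworth applied with zero phase distortion and an effective
#' 8th-order magnitude response, the standard choice when the filtered signal
#' feeds phase estimation. Two equivalent realizations are provided: `"fft"`
#' (default) applies the squared Butterworth magnitude response in the
#' frequency domain in a single FFT round trip, `"filtfilt"` runs the filter
#' forward-backward in the time domain (`signal::filtfilt`). Away from the
#' recording edges the two agree; the FFT realization is several-fold faster
#' on long multichannel recordings and its circular boundary only affects the
#' first/last fraction of a second, which window extraction already flags.
#'
#' @param x Numeric vector, or matrix with one row per site (samples in
#'   columns).
#' @param band A `band_definition` or canonical band name.
#' @param fs Sampling rate in Hz (default 1000).
#' @param order Filter order before the magnitude squaring.
#' @param method `"fft"` or `"filtfilt"`.
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, band, fs = 1000, order = 4,
                     method = c("fft", "filtfilt")) {
  method <- match.arg(method)
  band <- as_band(band, fs)
  flt <- signal::butter(order, c(band$low_hz, band$high_hz) / (fs / 2),
                        type = "pass")
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (n < 2) stop("signal too short to filter")
  if (method == "fft") {
    # pad to a highly composite length: R's mixed-radix FFT degrades badly
    # when the signal length has large prime factors
    np <- stats::nextn(n, c(2, 3, 5))
    mag2 <- butter_mag2(flt, np)
    one <- function(v) {
      Re(stats::fft(stats::fft(c(v, numeric(np - n))) * mag2,
                    inverse = TRUE) / np)[seq_len(n)]
    }
  } else {
    one <- function(v) as.numeric(signal::filtfilt(flt, v))
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1, one))
    dimnames(out) <- dimnames(x)
    out
  } else {
    one(x)
  }
}

# Squared magnitude response |H|^2 of an Arma filter at the n FFT bin
# frequencies (the amplitude response of a forward-backward pass).
butter_mag2 <- function(flt, n) {
  z <- exp(-2i * pi * (seq_len(n) - 1) / n)
  num <- as.vector(outer(z, seq_along(flt$b) - 1, `^`) %*% flt$b)
  den <- as.vector(outer(z, seq_along(flt$a) - 1, `^`) %*% flt$a)
  Mod(num / den)^2
}

#' Band-specific power (RMS amplitude)
#'
#' Root mean square of a band-pass-filtered window, per site. For a sinusoid
#' of amplitude A spanning an integer number of cycles this equals A/sqrt(2).
#'
#' @param x Numeric vector, or sites-by-samples matrix of filtered samples.
#' @return RMS per site (microvolts if the input is in microvolts).
#' @export
band_power <- function(x) {
  if (is.matrix(x)) sqrt(rowMeans(x^2)) else sqrt(mean(x^2))
}

# Analytic signal via the FFT method (Marple 1999): double positive
# frequencies, zero negative ones, keep DC and Nyquist. Long signals are
# zero-padded to a highly composite FFT length and truncated back.
analytic_signal <- function(v) {
  n <- length(v)
  np <- if (n > 4096) stats::nextn(n, c(2, 3, 5)) else n
  V <- stats::fft(c(v, numeric(np - n)))
  h <- numeric(np)
  if (np %% 2 == 0) {
    h[c(1, np / 2 + 1)] <- 1
    h[2:(np / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((np + 1) / 2)] <- 2
  }
  (stats::fft(V * h, inverse = TRUE) / np)[seq_len(n)]
}

#' Instantaneous phase of band-limited signals
#'
#' Computes the angle of the analytic signal (FFT method) per sample and per
#' site. All-zero signals have no defined phase: their rows are returned as
#' `NaN` and flagged in the `"degenerate"` attribute so that callers can
#' exclude those windows rather than propagate arbitrary angles.
#'
#' @param x Numeric vector or sites-by-samples matrix of *filtered* samples.
#' @return Object of the same shape containing phases in (-pi, pi], with
#'   attribute `degenerate`: logical per site.
#' @export
analytic_phase <- function(x) {
  one <- function(v) {
    if (all(v == 0)) return(rep(NaN, length(v)))
    Arg(analytic_signal(v))
  }
  if (is.matrix(x)) {
    if (ncol(x) < 2) stop("window must have length >= 2")
    out <- t(apply(x, 1, one))
    attr(out, "degenerate") <- apply(x, 1, function(v) all(v == 0))
    out
  } else {
    if (length(x) < 2) stop("window must have length >= 2")
    out <- one(x)
    attr(out, "degenerate") <- all(x == 0)
    out
  }
}

#' Pairwise phase-locking values
#'
#' For every unordered pair of sites (m, n), m < n, computes
#' \deqn{PLV(m,n) = \frac{1}{T}\left|\sum_{t=1}^{T} e^{i(\theta_m(t) - \theta_n(t))}\right|}
#' the modulus of the time-averaged unit phasor of the instantaneous phase
#' difference. PLV is 1 for perfectly synchronized sites (including a constant
#' phase offset) and near 0 for independent phases.
#'
#' Pairs are ordered lexicographically over site indices ((1,2), (1,3), ...,
#' (S-1,S)) so that feature indices are comparable across sessions.
#'
#' @param phases Sites-by-samples matrix of instantaneous phases (radians),
#'   e.g. from [analytic_phase()]. Must contain no NaN (degenerate windows are
#'   excluded upstream).
#' @return Named numeric vector of length `choose(S, 2)` with values in
#'   \[0, 1\]; names are `"m_n"`.
#' @export
plv_matrix <- function(phases) {
  if (!is.matrix(phases)) stop("`phases` must be a sites-by-samples matrix")
  T_len <- ncol(phases)
  if (T_len == 0) stop("window length T must be positive")
  if (anyNA(phases)) stop("phases contain NaN (degenerate window); exclude upstream")
  S <- nrow(phases)
  z <- exp(1i * phases)                  # S x T unit phasors
  M <- (z %*% Conj(t(z))) / T_len        # M[m, n] = mean e^{i(theta_m - theta_n)}
  iu <- which(upper.tri(M), arr.ind = TRUE)
  iu <- iu[order(iu[, 1], iu[, 2]), , drop = FALSE]
  out <- Mod(M[iu])
  names(out) <- paste0(iu[, 1], "_", iu[, 2])
  # numerical guard: modulus of a mean of unit phasors cannot exceed 1
  pmin(out, 1)
}

#' Names of PLV pair features for S sites
#' @param S Number of sites.
#' @return Character vector `"m_n"` in lexicographic order, length choose(S,2).
#' @export
plv_pair_names <- function(S) {
  iu <- which(upper.tri(diag(S)), arr.ind = TRUE)
  iu <- iu[order(iu[, 1], iu[, 2]), , drop = FALSE]
  paste0(iu[, 1], "_", iu[, 2])
}
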