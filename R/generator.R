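#' Default tonotopic focus layout
#'
#' Spatial gain foci per test frequency over the array extent. For the
#' canonical five-frequency set, the two lowest frequencies (8, 10 kHz) get two
#' Gaussian foci (posterior-dorsal and anterior-ventral), 13 kHz an
#' intermediate single focus, and the high frequencies (16, 32 kHz) a single
#' anterior-medial focus -- a stylized tonotopic map in which the activation
#' focus shifts with frequency. For other frequency sets a single focus slides
#' along the array diagonal with frequency rank.
#'
#' @param frequencies Tone frequencies in Hz.
#' @param extent_mm Array extent `c(width, height)` in mm.
#' @param width_mm Gaussian focus SD in mm.
#' @return Named list (one element per frequency, names = Hz) of lists with
#'   `centers` (k x 2 matrix, mm) and `width_mm`.
#' @export
default_foci <- function(frequencies = c(8000, 10000, 13000, 16000, 32000),
                         extent_mm = c(4, 4), width_mm = 0.8) {
  sx <- extent_mm[1] / 4
  sy <- extent_mm[2] / 4
  canon <- c(8000, 10000, 13000, 16000, 32000)
  mk <- function(...) list(centers = rbind(...), width_mm = width_mm)
  if (setequal(frequencies, canon)) {
    out <- list(
      `8000`  = mk(c(0.8 * sx, 3.2 * sy), c(3.2 * sx, 0.8 * sy)),
      `10000` = mk(c(1.2 * sx, 2.8 * sy), c(2.8 * sx, 1.2 * sy)),
      `13000` = mk(c(2.0 * sx, 2.0 * sy)),
      `16000` = mk(c(2.8 * sx, 2.4 * sy)),
      `32000` = mk(c(3.4 * sx, 2.8 * sy))
    )
    return(out[as.character(sort(frequencies))])
  }
  fr <- sort(frequencies)
  rk <- (seq_along(fr) - 1) / max(1, length(fr) - 1)
  out <- lapply(rk, function(r) {
    mk(c((0.8 + 2.6 * r) * sx, (1.2 + 1.6 * r) * sy))
  })
  names(out) <- as.character(fr)
  out
}

#' Generator parameters for synthetic LFP sessions
#'
#' Ground-truth parameters of the synthetic tonotopic LFP model. Per band b,
#' each active site records
#' \deqn{x(t) = \sum_b a_b \, g_b(site, tone) \cos(\phi_b(t) + \eta_{site,b}(t)) + noise(t) + bursts(t)}
#' where `phi_b` is a latent band phase (integrated random-walk frequency
#' centered mid-band), `eta` is smooth per-site phase wander whose wrapped-normal
#' resultant equals the coupling `kappa` (so the noise-free PLV between two
#' sites is close to `kappa^2`), and the gain
#' `g_b(site, tone) = 1 + contrast_b * bump(site, tone)` carries the tonotopic
#' information through Gaussian spatial foci. The pink-noise floor is per-site
#' independent; burst events are global high-amplitude low-frequency transients
#' shared by all sites.
#'
#' Default amplitudes grade downward with frequency (theta largest), putting
#' per-band RMS at roughly 8-18 uV against a 60 uV broadband 1/f floor --
#' a realistic amplitude regime for anesthetized cortical LFP. The floor's
#' in-band share is then comparable to the oscillation amplitude, so
#' phase-estimation fidelity (hence PLV) genuinely depends on the tone-driven
#' gain: tone identity is decodable from both power and PLV, but not
#' trivially so.
#'
#' @param amp_uv Per-band oscillation amplitude in uV (scalar or named per
#'   band).
#' @param contrast Per-band tonotopic contrast c_b >= 0: how strongly site gain
#'   depends on the tone (0 removes all tone information from that band).
#' @param kappa Per-band phase coupling in \[0, 1\] between each site and the
#'   latent band phase (1 = perfectly locked).
#' @param foci Focus layout as from [default_foci()], or `NULL` to build the
#'   default for the schedule's frequencies at simulation time.
#' @param noise_uv RMS of the per-site pink-noise floor (uV).
#' @param burst_rate_per_min Rate of global burst events (events/min).
#' @param burst_dur_ms Range `c(min, max)` of burst durations (ms).
#' @param burst_amp_mult Burst amplitude as a multiple of the background RMS.
#' @param layer Cortical layer label ("L2/3", "L4" or "L5/6").
#' @param jitter_tau_ms Correlation time of the phase wander (ms).
#' @param bands Band table (default [canonical_bands()]).
#' @return A `generator_params` list.
#' @export
generator_params <- function(amp_uv = c(theta = 25, alpha = 18, beta = 14,
                                        low_gamma = 12, high_gamma = 12),
                             contrast = 1, kappa = 0.8,
                             foci = NULL, noise_uv = 60,
                             burst_rate_per_min = 6,
                             burst_dur_ms = c(150, 500),
                             burst_amp_mult = 10,
                             layer = "L5/6", jitter_tau_ms = 200,
                             bands = canonical_bands()) {
  bn <- bands$band
  expand <- function(v, what, lo = 0, hi = Inf) {
    if (length(v) == 1 && is.null(names(v))) v <- stats::setNames(rep(v, length(bn)), bn)
    if (!all(bn %in% names(v))) stop("`", what, "` must name every band")
    v <- v[bn]
    if (any(v < lo) || any(v > hi)) {
      stop(sprintf("`%s` must lie in [%g, %g]", what, lo, hi))
    }
    v
  }
  if (length(burst_dur_ms) != 2 || burst_dur_ms[1] <= 0 ||
      burst_dur_ms[1] > burst_dur_ms[2]) {
    stop("`burst_dur_ms` must be c(min, max) with 0 < min <= max")
  }
  if (noise_uv < 0 || burst_rate_per_min < 0 || burst_amp_mult < 0) {
    stop("noise, burst rate and burst amplitude must be >= 0")
  }
  structure(list(
    bands = bands,
    amp_uv = expand(amp_uv, "amp_uv"),
    contrast = expand(contrast, "contrast"),
    kappa = expand(kappa, "kappa", 0, 1),
    foci = foci,
    noise_uv = noise_uv,
    burst_rate_per_min = burst_rate_per_min,
    burst_dur_ms = burst_dur_ms,
    burst_amp_mult = burst_amp_mult,
    layer = layer,
    jitter_tau_ms = jitter_tau_ms
  ), class = "generator_params")
}

#' Intervention effect on generator parameters
#'
#' Multiplicative ground-truth changes applied to a session's generator
#' parameters, the synthetic analogue of a neuromodulatory intervention: e.g.
#' halving high-gamma tonotopic contrast degrades high-gamma frequency
#' information, raising theta contrast enhances it.
#'
#' @param contrast_mult Named per-band multipliers on tonotopic contrast
#'   (bands not named are unchanged); all multipliers must be >= 0.
#' @param kappa_mult Named per-band multipliers on phase coupling; results are
#'   clipped to \[0, 1\] with a warning.
#' @param amp_mult Named per-band multipliers on oscillation amplitude.
#' @return A `vns_effect` list.
#' @export
vns_effect <- function(contrast_mult = NULL, kappa_mult = NULL, amp_mult = NULL) {
  chk <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (is.null(names(v)) || any(names(v) == "")) {
      stop("`", what, "` must be a named vector of band multipliers")
    }
    if (any(v < 0)) stop("`", what, "` multipliers must be >= 0")
    v
  }
  structure(list(contrast_mult = chk(contrast_mult, "contrast_mult"),
                 kappa_mult = chk(kappa_mult, "kappa_mult"),
                 amp_mult = chk(amp_mult, "amp_mult")),
            class = "vns_effect")
}

#' Apply an intervention effect to generator parameters
#'
#' @param params A `generator_params`.
#' @param effect A `vns_effect`. An empty effect returns `params` unchanged.
#' @return Modified copy of `params`. Coupling values pushed outside \[0, 1\]
#'   are clipped with a warning.
#' @export
apply_vns_effect <- function(params, effect) {
  stopifnot(inherits(params, "generator_params"), inherits(effect, "vns_effect"))
  mul <- function(x, m) {
    if (is.null(m)) return(x)
    bad <- setdiff(names(m), names(x))
    if (length(bad)) stop("unknown band(s) in effect: ", paste(bad, collapse = ", "))
    x[names(m)] <- x[names(m)] * m
    x
  }
  params$contrast <- mul(params$contrast, effect$contrast_mult)
  params$amp_uv <- mul(params$amp_uv, effect$amp_mult)
  k <- mul(params$kappa, effect$kappa_mult)
  if (any(k > 1)) {
    warning("kappa clipped to 1 for band(s): ",
            paste(names(k)[k > 1], collapse = ", "))
    k <- pmin(k, 1)
  }
  params$kappa <- k
  params
}

# Tonotopic gain bump per active site for one frequency: max over Gaussian
# foci, in [0, 1].
site_bump <- function(grid, focus) {
  s <- active_sites(grid)
  w2 <- 2 * focus$width_mm^2
  vals <- sapply(seq_len(nrow(focus$centers)), function(k) {
    d2 <- (s$x - focus$centers[k, 1])^2 + (s$y - focus$centers[k, 2])^2
    exp(-d2 / w2)
  })
  apply(as.matrix(vals), 1, max)
}

# 1/f-shaped noise, unit RMS, length n; generated at a highly composite FFT
# length and truncated (R's FFT is slow for lengths with large prime factors).
pink_noise <- function(n) {
  np <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(np)
  W <- stats::fft(w)
  f <- c(1, seq_len(np - 1))                # avoid DC blow-up
  f <- pmin(f, np - f + 1)                  # mirror for negative freqs
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE) / np)[seq_len(n)]
  x / sqrt(mean(x^2))
}

# AR(1) series at knot spacing, stationary sd `sd`, correlation time tau_ms.
ar1_knots <- function(n_knots, sd, tau_ms, knot_ms, n_series = 1) {
  rho <- exp(-knot_ms / tau_ms)
  innov_sd <- sd * sqrt(1 - rho^2)
  out <- matrix(0, n_series, n_knots)
  out[, 1] <- stats::rnorm(n_series, 0, sd)
  for (k in seq_len(n_knots - 1)) {
    out[, k + 1] <- rho * out[, k] + stats::rnorm(n_series, 0, innov_sd)
  }
  out
}

# Linear interpolation of knot series (rows) onto the sample grid; knots are
# uniformly spaced, so interpolation is a weighted blend of adjacent columns.
interp_knots <- function(knots, knot_ms, n_samples, fs) {
  t_out <- (seq_len(n_samples) - 1) * (1000 / fs) / knot_ms   # in knot units
  i0 <- pmin(floor(t_out) + 1, ncol(knots) - 1)
  frac <- t_out - (i0 - 1)
  lo <- knots[, i0, drop = FALSE]
  hi <- knots[, i0 + 1, drop = FALSE]
  sweep(lo, 2, 1 - frac, "*") + sweep(hi, 2, frac, "*")
}

#' Simulate a multichannel LFP session
#'
#' Generates a full session of synthetic LFP (1 kHz sampling, microvolts) for
#' every active site of `grid`, following `schedule` and the ground-truth
#' model of [generator_params()]. Identical arguments and seed give bitwise
#' identical sessions.
#'
#' @param grid A `site_grid`.
#' @param schedule A `trial_schedule`.
#' @param params A `generator_params`. Burst durations must fit within a tone
#'   presentation; focus centers must lie inside the grid extent.
#' @param seed Integer seed.
#' @param session_id Identifier stored with the session.
#' @return A `recording_session`: list with `lfp` (active sites x samples
#'   matrix, uV), `fs` (1000), `grid`, `schedule`, `params`, `seed`,
#'   `session_id`, and `ground_truth` (`bursts`: data frame of exact planted
#'   event intervals in ms; `site_bumps`: per-frequency tonotopic gain bumps).
#' @export
simulate_session <- function(grid, schedule, params, seed,
                             session_id = "session") {
  stopifnot(inherits(grid, "site_grid"), inherits(schedule, "trial_schedule"),
            inherits(params, "generator_params"))
  fs <- 1000
  if (params$burst_dur_ms[2] >= schedule$tone_ms) {
    stop("burst durations must be shorter than the tone duration")
  }
  foci <- params$foci
  if (is.null(foci)) foci <- default_foci(schedule$frequencies, grid$extent_mm)
  need <- as.character(schedule$frequencies)
  if (!all(need %in% names(foci))) {
    stop("focus layout missing frequencies: ",
         paste(setdiff(need, names(foci)), collapse = ", "))
  }
  for (f in need) {
    ctr <- foci[[f]]$centers
    if (any(ctr[, 1] < 0 | ctr[, 1] > grid$extent_mm[1] |
            ctr[, 2] < 0 | ctr[, 2] > grid$extent_mm[2])) {
      stop("focus center outside grid extent for frequency ", f)
    }
  }

  local_rng(seed)
  S <- n_active_sites(grid)
  n <- schedule$total_ms                      # 1 sample per ms at 1 kHz
  knot_ms <- 100
  n_knots <- ceiling(n / (fs * knot_ms / 1000)) + 1
  x <- matrix(0, S, n)

  # per-sample tonotopic bump weight: which trial (if any) covers each sample
  bumps <- lapply(need, function(f) site_bump(grid, foci[[f]]))
  names(bumps) <- need
  trial_of_sample <- rep(0L, n)
  tr <- schedule$trials
  for (i in seq_len(nrow(tr))) {
    a <- tr$onset_ms[i] + 1L
    b <- min(n, tr$onset_ms[i] + tr$dur_ms[i])
    trial_of_sample[a:b] <- i
  }

  # per-sample tone column into the bump matrix (0 during silence)
  bump_mat <- do.call(cbind, bumps)
  freq_col <- match(as.character(tr$freq_hz), need)
  bump_col <- integer(n)
  on_tone <- trial_of_sample > 0L
  bump_col[on_tone] <- freq_col[trial_of_sample[on_tone]]

  bands <- params$bands
  for (bi in seq_len(nrow(bands))) {
    b <- bands$band[bi]
    a_b <- params$amp_uv[[b]]
    c_b <- params$contrast[[b]]
    k_b <- params$kappa[[b]]
    f0 <- (bands$low_hz[bi] + bands$high_hz[bi]) / 2
    bw <- bands$high_hz[bi] - bands$low_hz[bi]
    # latent instantaneous frequency: slow AR(1) wander within the band
    f_knots <- f0 + ar1_knots(n_knots, sd = bw / 8, tau_ms = 500, knot_ms = knot_ms)
    # per-site phase wander; wrapped-normal sd chosen so resultant = kappa
    sigma <- if (k_b >= 1) 0 else if (k_b <= 1e-6) sqrt(-2 * log(1e-6)) else
      sqrt(-2 * log(k_b))
    eta_knots <- ar1_knots(n_knots, sd = sigma, tau_ms = params$jitter_tau_ms,
                           knot_ms = knot_ms, n_series = S)
    if (a_b == 0) next                        # draws above keep RNG stream aligned
    f_inst <- interp_knots(f_knots, knot_ms, n, fs)[1, ]
    phi <- 2 * pi * cumsum(f_inst) / fs
    lfp_add_band(x, phi, eta_knots, knot_ms, bump_col, bump_mat, a_b, c_b)
  }

  # pink-noise floor, per-site independent
  if (params$noise_uv > 0) {
    for (s in seq_len(S)) x[s, ] <- x[s, ] + params$noise_uv * pink_noise(n)
  } else {
    for (s in seq_len(S)) pink_noise(2)       # keep RNG stream aligned
  }

  # global burst events: Poisson onsets, uniform durations, low-freq transient
  background_rms <- sqrt(params$noise_uv^2 + sum(params$amp_uv^2) / 2)
  bursts <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
  if (params$burst_rate_per_min > 0) {
    n_ev <- stats::rpois(1, params$burst_rate_per_min * n / 1000 / 60)
    if (n_ev > 0) {
      onset <- sort(stats::runif(n_ev, 0, n - params$burst_dur_ms[2] - 1))
      dur <- stats::runif(n_ev, params$burst_dur_ms[1], params$burst_dur_ms[2])
      carrier <- stats::runif(n_ev, 3, 8)
      phase0 <- stats::runif(n_ev, 0, 2 * pi)
      for (e in seq_len(n_ev)) {
        a <- floor(onset[e]) + 1L
        b <- min(n, floor(onset[e] + dur[e]))
        if (b <= a) next
        tt <- seq(a, b)
        # Tukey envelope: sustained amplitude with short cosine ramps, the
        # abrupt-onset profile of burst-suppression bursts
        L <- length(tt)
        ramp <- max(2L, min(25L, L %/% 4))
        env <- rep(1, L)
        up <- seq_len(ramp)
        env[up] <- 0.5 * (1 - cos(pi * (up - 1) / ramp))
        env[L + 1 - up] <- env[up]
        wave <- env * cos(2 * pi * carrier[e] * (tt - a) / fs + phase0[e])
        # scale so the event's RMS is burst_amp_mult x the background RMS
        wave <- wave * params$burst_amp_mult * background_rms /
          sqrt(mean(wave^2))
        x[, tt] <- sweep(x[, tt, drop = FALSE], 2, wave, "+")
      }
      bursts <- data.frame(start_ms = floor(onset),
                           end_ms = floor(onset + dur))
    }
  }

  structure(list(
    lfp = x, fs = fs, grid = grid, schedule = schedule, params = params,
    seed = seed, session_id = session_id,
    ground_truth = list(bursts = bursts, site_bumps = bumps,
                        background_rms = background_rms)
  ), class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> '%s': %d sites x %d samples (%.1f min), %d planted bursts\n",
              x$session_id, nrow(x$lfp), ncol(x$lfp), ncol(x$lfp) / 60000,
              nrow(x$ground_truth$bursts)))
  invisible(x)
}

#' Ground-truth burst intervals on the analysis grid
#'
#' Burst detection operates on consecutive 100-ms standard-deviation windows,
#' so planted events are reported snapped to that grid for comparison: every
#' analysis window overlapped by a planted event is part of the truth mask,
#' and abutting windows are merged.
#'
#' @param session A `recording_session`.
#' @param win_ms Analysis window (default 100 ms).
#' @return Data frame `start_ms`, `end_ms` of merged grid-aligned intervals.
#' @export
true_burst_intervals <- function(session, win_ms = 100) {
  ev <- session$ground_truth$bursts
  if (nrow(ev) == 0) return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
  start <- floor(ev$start_ms / win_ms) * win_ms
  end <- ceiling(ev$end_ms / win_ms) * win_ms
  merge_intervals(data.frame(start_ms = start, end_ms = end))
}

# Merge sorted, possibly overlapping [start, end) intervals.
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$start_ms), , drop = FALSE]
  out_s <- iv$start_ms[1]; out_e <- iv$end_ms[1]
  ss <- c(); ee <- c()
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start_ms[i] <= out_e) {
      out_e <- max(out_e, iv$end_ms[i])
    } else {
      ss <- c(ss, out_s); ee <- c(ee, out_e)
      out_s <- iv$start_ms[i]; out_e <- iv$end_ms[i]
    }
  }
  data.frame(start_ms = c(ss, out_s), end_ms = c(ee, out_e))
}

#' Simulate a cohort of pre/post session pairs
#'
#' Draws per-animal generator parameters with small between-animal variation
#' (lognormal, ~10 percent) around `base`, then simulates a pre session with
#' those parameters and a post session with `effect` applied. Per-animal seeds
#' are derived from the master seed by sequential iid draws, so extending the
#' cohort does not change earlier animals.
#'
#' @param n_animals Number of animals (>= 1).
#' @param layer Layer label stored in each animal's parameters.
#' @param base Baseline `generator_params`.
#' @param effect `vns_effect` applied to the post session.
#' @param seed Master integer seed.
#' @param grid,schedule Shared recording geometry and trial schedule.
#' @param animal_jitter_sdlog Lognormal sdlog of between-animal variation in
#'   amplitudes, contrasts and noise floor (default 0.1, i.e. ~10 percent).
#' @return List of length `n_animals`; each element has `pre`, `post`
#'   (`recording_session`), `params` (that animal's baseline) and `animal`.
#' @export
simulate_cohort <- function(n_animals, layer, base, effect, seed,
                            grid = make_grid(), schedule = make_schedule(),
                            animal_jitter_sdlog = 0.1) {
  stopifnot(n_animals >= 1)
  specs <- cohort_specs(n_animals, layer, base, effect, seed,
                        animal_jitter_sdlog)
  lapply(specs, function(sp) {
    list(
      pre = simulate_session(grid, schedule, sp$params, sp$seed_pre,
                             session_id = sprintf("%s_a%02d_pre", layer, sp$animal)),
      post = simulate_session(grid, schedule, sp$params_post, sp$seed_post,
                              session_id = sprintf("%s_a%02d_post", layer, sp$animal)),
      params = sp$params, animal = sp$animal
    )
  })
}

# Per-animal parameter draws and seeds, without materializing sessions.
cohort_specs <- function(n_animals, layer, base, effect, seed,
                         animal_jitter_sdlog = 0.1) {
  local_rng(seed)
  animal_seeds <- sample.int(.Machine$integer.max, n_animals, replace = TRUE)
  lapply(seq_len(n_animals), function(i) {
    local_rng(animal_seeds[i])
    p <- base
    p$layer <- layer
    nb <- nrow(p$bands)
    p$amp_uv <- p$amp_uv * stats::rlnorm(nb, 0, animal_jitter_sdlog)
    p$contrast <- p$contrast * stats::rlnorm(nb, 0, animal_jitter_sdlog)
    p$noise_uv <- p$noise_uv * stats::rlnorm(1, 0, animal_jitter_sdlog)
    seed_pre <- sample.int(.Machine$integer.max, 1)
    seed_post <- sample.int(.Machine$integer.max, 1)
    list(animal = i, params = p, params_post = apply_vns_effect(p, effect),
         seed_pre = seed_pre, seed_post = seed_post)
  })
}
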