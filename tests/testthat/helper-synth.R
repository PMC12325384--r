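# Shared fixtures, built in code at test time.

# Small, fast recording setup: 5x5 grid (21 active sites), short tones,
# 7 repetitions of the five canonical frequencies.
scaled_grid <- function() make_grid(5, 5)

scaled_schedule <- function(seed = 99, tone_s = 4, gap_s = 1) {
  make_schedule(tone_s = tone_s, gap_s = gap_s, seed = seed)
}

scaled_params <- function(...) {
  generator_params(burst_dur_ms = c(150, 400), ...)
}

scaled_session <- function(seed = 1, params = scaled_params(), grid = scaled_grid(),
                           schedule = scaled_schedule()) {
  simulate_session(grid, schedule, params, seed = seed)
}

# Reduced-scale cohort configuration used by the parameter-recovery checks:
# the site-count burst threshold keeps the full design's 1/4-of-sites fraction
# (5 of 21 sites ~ 24 of 96); 6-s tones leave 35 window candidates per label
# (21 retained, 105 test decisions per session) so burst losses never starve
# a label, and the 3/min burst rate reflects the lighter anesthesia plane
# assumed for these short tones.
scaled_cohort_config <- function(seed, effect = vns_effect(
                                   contrast_mult = c(theta = 1.5, high_gamma = 0.5)),
                                 analyses = data.frame(
                                   band = c("theta", "high_gamma"),
                                   kind = c("power", "plv")), ...) {
  pipeline_config(
    grid = scaled_grid(),
    schedule = scaled_schedule(tone_s = 6, gap_s = 0.6),
    params = scaled_params(burst_rate_per_min = 3),
    effect = effect,
    n_animals = 8, layer = "L5/6",
    analyses = analyses,
    decoder = list(max_outer = 30),
    n_per_label = 21, site_count_threshold = 5, seed = seed, ...)
}

# A schedule-only session stub for window-extraction geometry tests (no LFP
# needed to enumerate candidate windows).
geometry_session <- function(schedule) {
  structure(list(fs = 1000, schedule = schedule, session_id = "geom",
                 lfp = matrix(0, 1, 1)),
            class = "recording_session")
}

empty_mask <- function() {
  classify_bursts(matrix(0, 2, 10), site_count_threshold = 1,
                  thresholds = c(1, 1))
}

# Independent oracle: PLV by explicit double loop over pairs and time.
plv_naive <- function(phases) {
  S <- nrow(phases); T_len <- ncol(phases)
  out <- c()
  nm <- c()
  for (m in seq_len(S - 1)) {
    for (n2 in (m + 1):S) {
      acc <- 0 + 0i
      for (t in seq_len(T_len)) {
        acc <- acc + exp(1i * (phases[m, t] - phases[n2, t]))
      }
      out <- c(out, Mod(acc) / T_len)
      nm <- c(nm, paste0(m, "_", n2))
    }
  }
  stats::setNames(out, nm)
}

# Independent oracle: exact signed-rank p by enumerating all 2^n sign
# assignments of the observed absolute-rank multiset.
wilcoxon_enum <- function(deltas) {
  nz <- deltas[deltas != 0]
  n <- length(nz)
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Two-class toy with a few informative features among Gaussian noise.
separable_toy <- function(n = 120, p = 100, seed = 1, shift = 1.5) {
  set.seed(seed)
  y <- rep(c(1000, 2000), each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- x[, 1] + ifelse(y == 1000, shift, -shift)
  x[, 2] <- x[, 2] + ifelse(y == 1000, -shift / 1.5, shift / 1.5)
  list(x = x, y = y)
}

# Feature table wrapper around a plain matrix (for decoder-level tests).
as_feature_table <- function(x, label, band = "theta", kind = "power",
                             session_id = "toy") {
  structure(list(x = x, label = label, band = band, kind = kind,
                 session_id = session_id,
                 windows = data.frame(window = seq_len(nrow(x)))),
            class = "feature_table")
}

unwrap_phase <- function(p) signal::unwrap(p)
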