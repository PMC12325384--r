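test_that("canonical band table and band validation are enforced", {
  cb <- canonical_bands()
  expect_equal(cb$band, c("theta", "alpha", "beta", "low_gamma", "high_gamma"))
  expect_equal(cb$low_hz, c(4, 8, 14, 30, 60))
  expect_equal(cb$high_hz, c(8, 14, 30, 40, 80))
  expect_error(band_definition("delta"), "unknown band")
  expect_error(band_definition("custom", 100, 600), "Nyquist")
  expect_error(band_definition("wide", 40, 120), "octave")
  expect_s3_class(band_definition("wide", 40, 120, allow_wide = TRUE),
                  "band_definition")
  expect_error(band_definition("bad", 10, 5), "low_hz < high_hz")
})

test_that("bandpass passes in-band tones and rejects out-of-band ones", {
  t <- seq(1 / 1000, 20, by = 1 / 1000)
  mid <- 5000:15000
  y6 <- bandpass(sin(2 * pi * 6 * t), "theta")
  expect_lt(abs(max(abs(y6[mid])) - 1), 0.01)
  y50 <- bandpass(sin(2 * pi * 50 * t), "theta")
  expect_lt(sqrt(mean(y50[mid]^2)) / sqrt(0.5), 0.01)

  # white noise through high-gamma: >= 95% of output variance inside 55-85 Hz
  set.seed(2)
  w <- rnorm(60000)
  yf <- bandpass(w, "high_gamma")
  sp <- Mod(fft(yf))^2
  freqs <- (seq_along(sp) - 1) * 1000 / length(sp)
  half <- freqs <= 500
  inband <- half & freqs >= 55 & freqs <= 85
  expect_gte(sum(sp[inband]) / sum(sp[half]), 0.95)
})

test_that("FFT and forward-backward realizations agree away from edges", {
  set.seed(3)
  x <- rnorm(30000)
  mid <- 5000:25000
  a <- bandpass(x, "high_gamma", method = "fft")
  b <- bandpass(x, "high_gamma", method = "filtfilt")
  expect_lt(max(abs(a[mid] - b[mid])) / stats::sd(b[mid]), 1e-6)
})

test_that("band power is the RMS with its closed-form and symmetry properties", {
  expect_equal(band_power(rep(0, 1000)), 0)
  # amplitude-A sinusoid over integer cycles: closed form A/sqrt(2),
  # cross-checked against direct summation
  t <- (0:999) / 1000
  A <- 3.7
  x <- A * sin(2 * pi * 20 * t)
  expect_equal(band_power(x), sqrt(sum(x^2) / length(x)), tolerance = 1e-12)
  expect_equal(band_power(x), A / sqrt(2), tolerance = 1e-9)
  # the RMS operator itself: constant offset c gives |c|
  expect_equal(band_power(rep(-2.5, 100)), 2.5)
  # sign-flip invariance and linear amplitude scaling
  set.seed(4)
  r <- rnorm(1000)
  expect_equal(band_power(-r), band_power(r))
  expect_equal(band_power(3 * r), 3 * band_power(r), tolerance = 1e-12)
  # matrix input: one value per site
  m <- rbind(x, -x)
  expect_equal(unname(band_power(m)), rep(A / sqrt(2), 2), tolerance = 1e-9)
})

test_that("analytic phase advances at the oscillation frequency", {
  t <- (1:4000) / 1000
  f <- 23
  ph <- analytic_phase(cos(2 * pi * f * t))
  mid <- 1000:3000
  slope <- mean(diff(unwrap_phase(ph[mid]))) * 1000 / (2 * pi)
  expect_lt(abs(slope - f) / f, 0.01)

  # quadrature: sin lags cos by pi/2
  ph_s <- analytic_phase(sin(2 * pi * f * t))
  d <- Arg(exp(1i * (ph_s[mid] - ph[mid])))
  expect_equal(mean(d), -pi / 2, tolerance = 0.01)

  # identical signals on two sites: pointwise zero difference
  x <- cos(2 * pi * 7 * t)
  m <- analytic_phase(rbind(x, x))
  expect_equal(m[1, ], m[2, ], tolerance = 1e-12)

  # degenerate all-zero input is NaN and flagged
  z <- analytic_phase(rbind(x, rep(0, length(t))))
  expect_true(all(is.nan(z[2, ])))
  expect_equal(unname(attr(z, "degenerate")), c(FALSE, TRUE))
  expect_error(analytic_phase(1), "length >= 2")
})

test_that("vectorized PLV equals the naive double-loop oracle", {
  set.seed(5)
  ph <- matrix(runif(8 * 200, -pi, pi), 8, 200)
  v <- plv_matrix(ph)
  o <- plv_naive(ph)
  expect_equal(v, o, tolerance = 1e-12)
  expect_equal(length(v), choose(8, 2))
  expect_identical(names(v), plv_pair_names(8))
})

test_that("PLV satisfies its bounds, symmetry and invariances", {
  set.seed(6)
  for (rep in 1:5) {
    ph <- matrix(runif(6 * 150, -pi, pi), 6, 150)
    v <- plv_matrix(ph)
    expect_true(all(v >= 0 & v <= 1))
    # symmetry: reversing site order permutes but preserves pair values
    vr <- plv_matrix(ph[6:1, ])
    expect_equal(unname(sort(round(v, 12))), unname(sort(round(vr, 12))))
    # invariance under a common phase shift across all sites
    shift <- Arg(exp(1i * (ph + runif(1, -pi, pi))))
    expect_equal(plv_matrix(shift), v, tolerance = 1e-9)
  }
  # perfectly synchronized sites: PLV exactly 1; constant offset too
  base <- matrix(rep(runif(300, -pi, pi), each = 2), 2, byrow = FALSE)
  ph2 <- rbind(base[1, ], base[1, ])
  expect_equal(unname(plv_matrix(ph2)), 1, tolerance = 1e-12)
  ph3 <- rbind(base[1, ], Arg(exp(1i * (base[1, ] + 1.1))))
  expect_equal(unname(plv_matrix(ph3)), 1, tolerance = 1e-9)
  expect_error(plv_matrix(ph2[, 0, drop = FALSE]), "positive")
  expect_error(plv_matrix(matrix(NaN, 2, 5)), "NaN")
})

test_that("PLV declines monotonically with phase-wander dispersion", {
  # wrapped-normal jitter with increasing sd; mean over 100 replicates
  set.seed(7)
  sds <- c(0.2, 0.5, 0.9, 1.4, 2.0)
  means <- sapply(sds, function(s) {
    mean(replicate(100, {
      t <- 300
      ph <- rbind(rnorm(t, 0, s), rnorm(t, 0, s))
      unname(plv_matrix(Arg(exp(1i * ph))))
    }))
  })
  expect_equal(cor(means, sds, method = "spearman"), -1)
})

test_that("feature tables carry the documented shapes and labels", {
  ses <- scaled_session(seed = 8)
  mask <- classify_bursts(window_sd(ses$lfp), site_count_threshold = 4)
  w <- extract_analysis_windows(ses, mask, n_per_label = 7)
  S <- n_active_sites(ses$grid)

  tp <- build_feature_table(ses, w, "theta", "power")
  expect_equal(dim(tp$x), c(35, S))
  expect_true(all(tp$x >= 0))
  expect_equal(as.integer(table(tp$label)), rep(7L, 5))
  # rows in acquisition order
  expect_true(all(diff(tp$windows$start_ms) > 0))

  tv <- build_feature_table(ses, w, "high_gamma", "plv")
  expect_equal(dim(tv$x), c(35, choose(S, 2)))
  expect_true(all(tv$x >= 0 & tv$x <= 1))
  expect_identical(colnames(tv$x), plv_pair_names(S))

  # empty window set: schema intact
  w0 <- w[0, , drop = FALSE]
  attr(w0, "session_id") <- ses$session_id
  t0 <- build_feature_table(ses, w0, "theta", "power")
  expect_equal(dim(t0$x), c(0, S))

  # windows from another session are refused
  ses2 <- scaled_session(seed = 9)
  ses2$session_id <- "other"
  expect_error(build_feature_table(ses2, w, "theta", "power"), "extracted from")
})
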