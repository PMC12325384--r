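quiet_params <- function(...) {
  generator_params(amp_uv = 0, noise_uv = 0, burst_rate_per_min = 0,
                   burst_dur_ms = c(100, 200), ...)
}

small_sched <- function(seed = 2) make_schedule(tone_s = 2, gap_s = 0.5, seed = seed)

test_that("silent parameters generate an all-zero session", {
  ses <- simulate_session(make_grid(3, 3), small_sched(), quiet_params(), seed = 1)
  expect_true(all(ses$lfp == 0))
  expect_equal(nrow(ses$ground_truth$bursts), 0)
})

test_that("simulation is deterministic in the seed", {
  g <- make_grid(3, 3)
  p <- scaled_params()
  a <- simulate_session(g, small_sched(), p, seed = 5)
  b <- simulate_session(g, small_sched(), p, seed = 5)
  d <- simulate_session(g, small_sched(), p, seed = 6)
  expect_identical(a$lfp, b$lfp)
  expect_identical(a$ground_truth$bursts, b$ground_truth$bursts)
  expect_false(identical(a$lfp, d$lfp))
})

test_that("perfect coupling with no noise yields identical narrowband phases", {
  p <- generator_params(amp_uv = c(theta = 0, alpha = 0, beta = 0,
                                   low_gamma = 0, high_gamma = 12),
                        kappa = 1, contrast = 0, noise_uv = 0,
                        burst_rate_per_min = 0, burst_dur_ms = c(100, 200))
  ses <- simulate_session(make_grid(3, 3, offline_corners = FALSE),
                          small_sched(), p, seed = 3)
  filt <- bandpass(ses$lfp, "high_gamma")
  ph <- analytic_phase(filt)
  mid <- 2000:4000
  plv <- plv_matrix(ph[, mid])
  expect_true(all(plv > 1 - 1e-6))
})

test_that("planted burst count is a plausible draw of the configured rate", {
  # ~10-minute quiet session at 2 events/min
  sch <- make_schedule(tone_s = 40, gap_s = 20, repetitions = 2, seed = 1)
  p <- generator_params(burst_rate_per_min = 2, burst_dur_ms = c(200, 400))
  ses <- simulate_session(make_grid(2, 2, offline_corners = FALSE), sch, p, seed = 8)
  lambda <- 2 * sch$total_ms / 60000
  n_ev <- nrow(ses$ground_truth$bursts)
  expect_gte(n_ev, qpois(0.001, lambda))
  expect_lte(n_ev, qpois(0.999, lambda))
  # events fit inside the session and respect the configured durations
  d <- ses$ground_truth$bursts$end_ms - ses$ground_truth$bursts$start_ms
  expect_true(all(d >= 199 & d <= 401))
})

test_that("intervention effects transform parameters arithmetically", {
  p <- generator_params(contrast = 0.5)
  expect_equal(apply_vns_effect(p, vns_effect()), p)
  p2 <- apply_vns_effect(p, vns_effect(contrast_mult = c(theta = 2)))
  expect_equal(unname(p2$contrast[["theta"]]), 1.0)
  expect_equal(p2$contrast[["high_gamma"]], p$contrast[["high_gamma"]])
  expect_warning(
    apply_vns_effect(p, vns_effect(kappa_mult = c(theta = 2))),
    "clipped")
  p3 <- suppressWarnings(apply_vns_effect(p, vns_effect(kappa_mult = c(theta = 2))))
  expect_equal(unname(p3$kappa[["theta"]]), 1)
  expect_error(apply_vns_effect(p, vns_effect(contrast_mult = c(delta = 2))),
               "unknown band")
  expect_error(vns_effect(contrast_mult = c(theta = -1)), ">= 0")
})

test_that("parameter validation rejects illegal values", {
  expect_error(generator_params(kappa = 1.5), "\\[0, 1\\]")
  expect_error(generator_params(amp_uv = -1), "amp_uv")
  expect_error(generator_params(burst_dur_ms = c(300, 200)), "burst_dur_ms")
  # burst duration must fit inside a tone; focus centers inside the extent
  expect_error(
    simulate_session(make_grid(3, 3), small_sched(),
                     generator_params(burst_dur_ms = c(150, 3000)), seed = 1),
    "shorter than the tone")
  bad_foci <- default_foci()
  bad_foci[["8000"]]$centers[1, ] <- c(9, 9)
  expect_error(
    simulate_session(make_grid(3, 3), small_sched(),
                     generator_params(foci = bad_foci), seed = 1),
    "outside grid extent")
})

test_that("cohorts are reproducible, pairwise distinct, and jittered", {
  base <- quiet_params()
  eff <- vns_effect(contrast_mult = c(high_gamma = 0.5))
  co <- simulate_cohort(3, "L5/6", base, eff, seed = 11,
                        grid = make_grid(2, 3, offline_corners = FALSE),
                        schedule = small_sched())
  expect_length(co, 3)
  seeds_pre <- vapply(co, function(a) a$pre$seed, numeric(1))
  expect_false(any(duplicated(seeds_pre)))
  co2 <- simulate_cohort(3, "L5/6", base, eff, seed = 11,
                         grid = make_grid(2, 3, offline_corners = FALSE),
                         schedule = small_sched())
  expect_identical(co[[1]]$pre$lfp, co2[[1]]$pre$lfp)
  expect_identical(co[[3]]$post$lfp, co2[[3]]$post$lfp)
  # between-animal jitter: animals differ in their drawn parameters
  expect_false(identical(co[[1]]$params$contrast, co[[2]]$params$contrast))
  # post params carry the effect relative to that animal's own baseline
  expect_equal(co[[1]]$post$params$contrast[["high_gamma"]],
               co[[1]]$params$contrast[["high_gamma"]] * 0.5)
})

test_that("extending a cohort does not change earlier animals", {
  base <- quiet_params()
  s3 <- lfpdecode:::cohort_specs(3, "L4", base, vns_effect(), seed = 7)
  s5 <- lfpdecode:::cohort_specs(5, "L4", base, vns_effect(), seed = 7)
  expect_identical(s3[[1]]$seed_pre, s5[[1]]$seed_pre)
  expect_identical(s3[[3]]$params$amp_uv, s5[[3]]$params$amp_uv)
})
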