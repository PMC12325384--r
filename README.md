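# lfpdecode

Layer- and band-specific decoding of tone frequency from multielectrode
local field potentials (LFP) of the auditory cortex under burst-suppression
anesthesia — and paired pre/post comparison of decoding accuracy across an
intervention such as vagus nerve stimulation (VNS).

## Who this is for

Electrophysiologists and computational neuroscientists who record sustained
cortical activity with microelectrode arrays (e.g. a 10 × 10 grid with 96
active sites at 1 kHz) during long pure-tone presentation, and who want a
tested, reproducible implementation of the full analysis chain:

1. **Burst screening** — bursting epochs are detected where the 100-ms
   standard deviation exceeds a per-site threshold at more than 24 recording
   sites for at least 150 ms, and excluded.
2. **Analysis windows** — 1,000-ms non-burst windows taken from sustained
   activity (the first second after tone onset is excluded as onset
   transient), 70 windows per test frequency.
3. **Band features** — per-site band power (RMS of the band-pass-filtered
   LFP) and the phase-locking value between all 4,560 site pairs,

   PLV(m,n) = (1/T) · | Σ_t exp(i(θ_m(t) − θ_n(t))) |,

   in five narrow bands: theta 4–8, alpha 8–14, beta 14–30, low-gamma
   30–40, high-gamma 60–80 Hz.
4. **Sparse decoding** — multinomial logistic regression with automatic
   relevance determination decodes the tone frequency (five-choice, or
   two-choice stratified into six frequency-ratio difficulty classes) under
   seven-fold periodic cross-validation or a rolling-window scheme.
5. **Cohort comparison** — per-animal accuracy change (post − pre) tested
   against zero with an exact two-sided Wilcoxon signed-rank test.

Because such recordings are rarely public, the package includes a synthetic
tonotopic LFP generator with full ground truth (spatial gain foci per
frequency, controllable inter-site phase coupling, 1/f noise floor, global
burst events), so every stage is testable without any download. See the
vignette `vignettes/decoding-methods.Rmd` for the model and all numerical
choices.

## Worked example

Simulate a small pre/post cohort in which the intervention halves the
high-gamma tonotopic contrast and raises theta contrast 1.5×, then run the
whole pipeline:

```r
library(lfpdecode)

cfg <- pipeline_config(
  grid     = make_grid(5, 5),                      # 21 active sites
  schedule = make_schedule(tone_s = 6, gap_s = 0.6, seed = 99),
  params   = generator_params(burst_rate_per_min = 3,
                              burst_dur_ms = c(150, 400)),
  effect   = vns_effect(contrast_mult = c(theta = 1.5, high_gamma = 0.5)),
  n_animals = 8, layer = "L5/6",
  analyses = data.frame(band = c("theta", "high_gamma"),
                        kind = c("power", "plv")),
  decoder  = list(max_outer = 30),
  n_per_label = 21, site_count_threshold = 5, seed = 3)

out <- run_pipeline(cfg)
out$grid[, c("band", "kind", "task", "n", "median_delta", "p_value", "stars")]
```

```
        band  kind        task n median_delta   p_value stars
1 high_gamma   plv five_choice 8     -14.7619 0.0078125    **
2      theta power five_choice 8      15.2381 0.0078125    **
```

Read: across 8 simulated animals, five-choice decoding from high-gamma PLV
lost a median 14.8 percentage points after the intervention (exact
signed-rank p = 0.0078), while decoding from theta power gained a median
15.2 points (p = 0.0078) — the pipeline recovers both planted effect
directions. (At this reduced scale each accuracy is estimated from 105 test
decisions per session; the full design uses 96 sites and 350.)

Individual stages are exposed directly:

```r
ses  <- simulate_session(make_grid(10, 10), make_schedule(), 
                         generator_params(), seed = 1)
mask <- classify_bursts(window_sd(ses$lfp))          # burst intervals
w    <- extract_analysis_windows(ses, mask)          # 70 windows / frequency
tab  <- build_feature_table(ses, w, "high_gamma", "plv")   # 350 x 4560
res  <- run_task(tab, decoding_task(ses$schedule$frequencies))
res$mean_acc                                         # % correct, 7-fold CV
```

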