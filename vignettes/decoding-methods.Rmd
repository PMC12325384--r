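---
title: "Decoding tone frequency from sustained auditory-cortex LFP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding tone frequency from sustained auditory-cortex LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpdecode)
```

## The analysis problem

Under isoflurane anesthesia, the auditory cortex responds to a long pure tone
with *sustained* oscillatory activity whose spatial pattern depends on the
tone's frequency (tonotopy). This package implements a complete pipeline that
quantifies that sustained activity on a multielectrode array and asks how much
tone-frequency information it carries, and how that information changes
between two recording sessions (for example before and after a
neuromodulatory intervention such as vagus nerve stimulation):

1. **Burst screening.** Anesthesia produces burst suppression: intermittent
   high-amplitude bursts synchronized across the array. Bursts swamp the
   tone-related signal and are excluded. A 100-ms window is classified as
   bursting when its per-site standard deviation exceeds a threshold at more
   than 24 of 96 sites, and runs of such windows lasting at least 150 ms form
   burst intervals.
2. **Analysis windows.** The first second after tone onset (the transient
   onset response) is excluded; the remaining tone time is tiled into
   consecutive non-overlapping 1,000-ms windows, and windows overlapping any
   burst are dropped. Exactly 70 windows per test frequency are retained per
   session.
3. **Band features.** In each window and each of five narrow bands (theta
   4–8, alpha 8–14, beta 14–30, low-gamma 30–40, high-gamma 60–80 Hz), two
   feature sets are computed: the per-site RMS of the band-pass-filtered LFP
   (96 *power* features) and the phase-locking value between all
   `choose(96, 2) = 4560` site pairs (*PLV* features),
   \deqn{PLV(m,n) = \frac{1}{T}\Bigl|\sum_{t=1}^{T} e^{i(\theta_m(t)-\theta_n(t))}\Bigr|,}
   with instantaneous angles \eqn{\theta} from the analytic signal of the
   filtered LFP.
4. **Decoding.** Sparse multinomial logistic regression decodes the tone
   frequency from the feature table, under seven-fold periodic
   cross-validation (the j-th window of each label goes to group j mod 7) or
   a rolling-window scheme for time-series-safe validation. Tasks are
   five-choice (all frequencies) or two-choice, the latter stratified into
   six frequency-ratio difficulty classes.
5. **Comparison.** Per animal, the post-session mean accuracy minus the
   pre-session accuracy is tested against zero across the cohort with an
   exact two-sided Wilcoxon signed-rank test.

Because the recordings the design describes are not publicly released, the
package ships a synthetic LFP generator with known ground truth; every stage
of the pipeline is validated against planted structure.

## The synthetic LFP model

Each active site of a rectangular array (default 10 × 10 over 4 × 4 mm with
the four corners offline, i.e. 96 active sites) records, at 1 kHz,

\deqn{x_s(t) = \sum_b a_b\, g_b(s, \mathrm{tone}(t))\, \cos(\phi_b(t) + \eta_{s,b}(t)) + n_s(t) + \mathrm{bursts}(t)}

* **Latent band phase** \eqn{\phi_b}: integrated instantaneous frequency that
  wanders (AR(1), correlation time 500 ms, SD = bandwidth/8) around the band
  center — a narrowband but non-sinusoidal rhythm.
* **Phase coupling** \eqn{\eta_{s,b}}: per-site wrapped-normal AR(1) phase
  wander (correlation time 200 ms) whose stationary SD is
  \eqn{\sigma = \sqrt{-2\log\kappa}}, so the per-site resultant equals the
  coupling parameter \eqn{\kappa \in [0,1]} exactly and the noise-free PLV
  between two sites is \eqn{\kappa^2}. The wrapped-normal construction was
  chosen over a von Mises draw-and-interpolate scheme because the
  resultant–parameter mapping is closed-form and the AR(1) structure gives
  temporal smoothness directly.
* **Tonotopic gain** \eqn{g_b(s, f) = 1 + c_b\,\mathrm{bump}_f(s)}: Gaussian
  spatial foci per test frequency (default layout: two foci for 8 and
  10 kHz — posterior-dorsal and anterior-ventral — one intermediate focus for
  13 kHz, one anterior-medial focus for 16 and 32 kHz; width 0.8 mm). The
  contrast \eqn{c_b \ge 0} is the information dial: at \eqn{c_b = 0} the tone
  leaves no trace in band *b*.
* **Pink noise** \eqn{n_s}: per-site independent 1/f-shaped noise, default
  60 µV RMS.
* **Bursts**: global Poisson events (default 6/min), identical on all sites,
  3–8 Hz carrier under a Tukey envelope with the event RMS scaled to 10× the
  background RMS, durations uniform in a configurable range (default
  150–500 ms, within the detectability regime of the 150-ms screening rule).

**Why these amplitudes.** The band amplitudes grade downward with frequency
(theta 25 µV down to 12 µV for the gamma bands) against the 60 µV floor.
Since the recording-band share of 1/f noise falling inside a narrow band is
comparable to these oscillation amplitudes, the fidelity of single-site phase
estimates — and therefore the measured PLV — depends on the tone-driven gain.
This is the mechanism by which tone identity reaches the PLV features at all:
the model deliberately modulates *only* the gain with the tone, and PLV
information emerges through in-band signal-to-noise ratio. The defaults were
fixed once so that, at scaled problem sizes, five-choice decoding from both
power and PLV sits in the 40–75 % range (well above the 20 % chance level,
well below ceiling), the regime in which accuracy *changes* are
interpretable. They are parameters of the model, not claims about any
particular dataset: absolute LFP scales vary widely with electrode and
anesthesia depth.

**What the generator does not emulate.** No spiking, no biophysics, no
cross-frequency coupling, no shared reference artifacts, no electrode drift,
and tone information enters only through smooth spatial gain fields. Passing
parameter-recovery tests on this generator therefore shows the *pipeline* is
correct and sensitive, not that real recordings would yield the same
accuracies.

## Intervention effects and cohorts

An intervention is modeled as multiplicative ground-truth changes to
band-specific contrast, amplitude, or coupling (`vns_effect()`), applied to
the post session of each animal. Cohorts draw per-animal parameters with
~10 % lognormal jitter around the base (so paired deltas have genuine
between-animal variance), and per-animal seeds derive from the master seed by
sequential draws, so extending a cohort never changes earlier animals. Pre
and post sessions use independent realizations: an identity effect produces
sessions that differ only by realization noise, which is exactly the null the
signed-rank comparison should not reject.

## Numerical choices

* **Filtering**: 4th-order Butterworth, applied with zero phase. The default
  realization multiplies the spectrum by the squared magnitude response in
  one FFT round trip — identical to forward–backward (`filtfilt`) filtering
  away from the recording edges (agreement to 1e-9 in mid-signal high-gamma)
  and several-fold faster on long multichannel recordings; `filtfilt` remains
  available. Bands above 30 Hz wider than one octave are refused without an
  explicit override, since wide bands blur the instantaneous angle.
* **Analytic signal**: FFT method on the full contiguous recording; windows
  are cropped afterwards, so filter and Hilbert edge distortion never reaches
  a window interior. Windows within 500 ms of a recording edge, or containing
  an all-zero site (undefined phase), are flagged and excluded — never given
  arbitrary values.
* **Windowed SD**: population SD per consecutive 100-ms window; burst
  intervals snap to this grid, so the 150-ms persistence rule means two or
  more consecutive supra-threshold windows. The SD threshold itself is per
  site, 3× that site's median windowed SD — the design quantity the screening
  rule leaves open; the median is robust to the bursts themselves.
* **Window subselection**: from the surviving candidates of each label,
  `n_per_label` windows are retained by deterministic evenly-spaced
  subsampling in acquisition order. If a label cannot supply the requested
  count, the extraction fails with an explicit shortfall error naming the
  label — never silent padding.
* **Sparse decoder**: multinomial logistic regression with automatic
  relevance determination. Each feature carries a precision acting as an
  adaptive ridge penalty shared across classes; the fit alternates L-BFGS
  weight updates (Rcpp objective/gradient) with the MacKay evidence update
  \eqn{\alpha_f \leftarrow \gamma_f / \sum_k w_{fk}^2}, where
  \eqn{\gamma_{fk} = h_{fk}/(h_{fk}+\alpha_f)} uses the diagonal likelihood
  Hessian. The textbook naive update \eqn{\alpha \leftarrow 1/w^2} was
  implemented first and rejected: on separable data its fixed point is
  degenerate (every weight shrinks geometrically until the model collapses to
  the bias). Features are pruned when their relevance precision
  \eqn{1/(\mathrm{mean}_k\, w_{fk}^2 + \varepsilon)} exceeds 1e8, i.e. when
  their standardized weights are numerically zero; pruned features have
  exactly zero weight and the active set never grows. Standardization is
  computed on each training fold only and applied to its test fold — no
  leakage. Convergence: largest weight change below 1e-3 (on standardized
  features; beyond this no prediction changes — the hyperparameter
  quasi-equilibrium drifts at ~1e-4/iteration essentially forever, which is
  why a much smaller tolerance is not meaningful), at most 200 outer
  iterations; non-convergence is flagged on the model and logged, never
  silently accepted.
* **Prediction ties**: argmax over class probabilities with ties (within
  1e-9) resolved toward the lowest frequency — deterministic by construction.
* **Rolling scheme geometry**: expanding-window with block size
  `floor(n_per_label / (n_folds + 1))`; every test block strictly follows all
  its training data. With 70 windows per label and 3 splits this trains on
  17/34/51 and tests on the next 17 per label. This is one reasonable
  reading of a "three-run rolling window" design; the package documents it as
  its own convention.
* **Ratio classes**: two-choice pairs are binned by flooring
  \eqn{\log_2(f_2/f_1)} into quarter-octave bins. On the canonical
  frequencies this produces exactly six classes
  ({8–10, 10–13, 13–16}, {8–13, 10–16}, {8–16, 16–32}, {13–32}, {10–32},
  {8–32}); rounding instead of flooring would split the first class and is
  not used.
* **Signed-rank test**: exact two-sided p from the permutation distribution
  of the positive-rank sum over all \eqn{2^n} sign assignments, computed by
  convolution on a doubled-rank grid so midranks (ties) are handled exactly;
  zeros are dropped before ranking (Wilcoxon's original treatment). No
  multiple-comparison correction is applied by default — each cell of the
  comparison grid reports its own p — with a Benjamini–Hochberg option
  available.

## Reduced problem sizes

The full design (96 sites, 29-s tones, 70 windows per label) is what the
defaults describe, and the pipeline runs it unchanged. The package's own test
suite and recovery studies run a reduced geometry chosen once: a 5 × 5 grid
with offline corners (21 active sites, 210 PLV pairs), 6-s tones with 0.6-s
gaps, 21 windows per label with the same seven-fold periodic scheme
(18 training / 3 test windows per label per fold, 105 test decisions per
session), a site-count threshold of 5 (the same quarter-of-sites fraction as
24/96), a 3/min burst rate, and an ARD iteration cap of 30 (accuracy at
these sizes is unchanged from the 200-iteration default; the extra
iterations only polish weights below the decision level). The 6-s tones
leave 35 candidate windows per label for the 21 retained, so burst losses
never starve a label and window extraction cannot shortfall. The window
count was set as high as a desk-scale run affords because the accuracy
estimator's sampling noise — not the planted effect — is what limits the
paired comparison at n = 8. Parameter recovery uses cohorts of n = 8 with
post-session high-gamma contrast ×0.5 and theta contrast ×1.5, ten replicate
cohorts — the directionality analogue of a deep-layer intervention that
degrades high-gamma synchrony information while enhancing theta power
information. Inside `decode_session()` the per-site spectrum is computed
once and every band's filtered signal (and, for PLV, analytic signal) is
derived from it; this fast path is tested against the reference
`build_feature_table()` route.

## Known limitations

* PLV information in the generator is an SNR phenomenon; mechanisms that
  change inter-site coupling without changing SNR are expressible (via
  \eqn{\kappa}) but not part of the default recovery scenario.
* The exact signed-rank enumeration is exact for any tie pattern but the
  test is only meaningful for n ≥ 5 non-zero deltas (smallest attainable
  two-sided p at n = 4 is 0.125); cohorts below that report deltas without p.
* The text-based session container stores full double precision but is
  bulky; it targets reproducibility and interoperability, not archival
  storage of full-scale sessions.
* Decoding accuracy differences between CV schemes (periodic vs rolling) are
  expected on autocorrelated data and are part of what the package lets you
  study; the package takes no position on which is "correct".
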