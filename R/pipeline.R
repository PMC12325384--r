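#' Pipeline configuration
#'
#' Validated configuration for the end-to-end analysis: synthetic cohort
#' design, burst-screening thresholds, window parameters, feature bands and
#' kinds, decoding tasks and cross-validation scheme. Every field is checked
#' against the preconditions of the stage that consumes it, so invalid
#' configurations fail at load time rather than mid-run.
#'
#' @param grid A `site_grid` (default: 10 x 10, corners offline).
#' @param schedule A `trial_schedule` (default: the canonical five-frequency,
#'   seven-repetition design).
#' @param params Baseline `generator_params`.
#' @param effect `vns_effect` applied to post sessions.
#' @param n_animals Animals in the cohort.
#' @param layer Layer label.
#' @param bands Character vector of canonical band names to analyse.
#' @param kinds Feature kinds, subset of `c("power", "plv")`.
#' @param analyses Optional data frame with columns `band`, `kind` naming the
#'   exact band/kind combinations to run (default: all of `bands` x `kinds`).
#' @param decoder Named list of extra arguments passed to [fit_slr()] via
#'   [run_task()] (e.g. `list(max_outer = 40)` for reduced-scale runs).
#' @param tasks `"five_choice"`, `"two_choice"`, or both.
#' @param scheme CV scheme, `"periodic"` or `"rolling"`.
#' @param k Periodic CV groups.
#' @param n_folds Rolling CV splits.
#' @param n_per_label Retained windows per frequency per session.
#' @param sd_multiplier,site_count_threshold,min_duration_ms Burst rule.
#' @param onset_exclusion_s,window_ms Analysis-window parameters.
#' @param seed Master seed; all per-animal and per-session seeds derive from
#'   it deterministically.
#' @param out_dir Optional directory for artifacts (session containers, burst
#'   BED files, feature TSVs, result JSON).
#' @return A `pipeline_config` list with a content hash in `$hash`.
#' @export
pipeline_config <- function(grid = make_grid(),
                            schedule = make_schedule(),
                            params = generator_params(),
                            effect = vns_effect(),
                            n_animals = 8, layer = "L5/6",
                            bands = canonical_bands()$band,
                            kinds = c("power", "plv"),
                            analyses = NULL,
                            decoder = list(),
                            tasks = "five_choice",
                            scheme = c("periodic", "rolling"),
                            k = 7, n_folds = 3, n_per_label = 70,
                            sd_multiplier = 3, site_count_threshold = 24,
                            min_duration_ms = 150,
                            onset_exclusion_s = 1, window_ms = 1000,
                            seed = 1, out_dir = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(grid, "site_grid"), inherits(schedule, "trial_schedule"),
            inherits(params, "generator_params"), inherits(effect, "vns_effect"))
  for (b in bands) band_definition(b)     # validates names and Nyquist bounds
  kinds <- match.arg(kinds, c("power", "plv"), several.ok = TRUE)
  if (is.null(analyses)) {
    analyses <- expand.grid(band = bands, kind = kinds,
                            stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(analyses), all(c("band", "kind") %in% names(analyses)))
    for (b in analyses$band) band_definition(b)
    if (!all(analyses$kind %in% c("power", "plv"))) stop("unknown feature kind")
  }
  tasks <- match.arg(tasks, c("five_choice", "two_choice"), several.ok = TRUE)
  if (n_animals < 1) stop("`n_animals` must be >= 1")
  if (n_per_label < k) stop("`n_per_label` must be >= k")
  if (sd_multiplier <= 0 || min_duration_ms <= 0) stop("burst thresholds must be positive")
  if (site_count_threshold >= n_active_sites(grid)) {
    stop("`site_count_threshold` must be below the active site count")
  }
  # every tone must accommodate at least one analysis window
  if (schedule$tone_ms < onset_exclusion_s * 1000 + window_ms) {
    stop("tones too short for the onset exclusion plus one analysis window")
  }
  cfg <- list(grid = grid, schedule = schedule, params = params,
              effect = effect, n_animals = n_animals, layer = layer,
              bands = bands, kinds = kinds, analyses = analyses,
              decoder = decoder, tasks = tasks, scheme = scheme,
              k = k, n_folds = n_folds, n_per_label = n_per_label,
              sd_multiplier = sd_multiplier,
              site_count_threshold = site_count_threshold,
              min_duration_ms = min_duration_ms,
              onset_exclusion_s = onset_exclusion_s, window_ms = window_ms,
              seed = seed, out_dir = out_dir)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> %s n=%d, %d band(s) x {%s}, %s CV, seed %d, hash %s\n",
              x$layer, x$n_animals, length(x$bands),
              paste(x$kinds, collapse = ","), x$scheme, x$seed, x$hash))
  invisible(x)
}

#' Screen one session and decode all configured analyses
#'
#' Runs burst screening, analysis-window extraction, feature extraction for
#' every configured band and kind, and cross-validated decoding for every
#' configured task on one session.
#'
#' @param session A `recording_session`.
#' @param config A `pipeline_config`.
#' @return List with `mask`, `windows`, and `results`: a data frame with one
#'   row per (band, kind, task) holding the mean accuracy (%), plus the
#'   underlying `decoding_result` objects in the list-column `result`.
#' @export
decode_session <- function(session, config) {
  stopifnot(inherits(session, "recording_session"),
            inherits(config, "pipeline_config"))
  sds <- window_sd(session$lfp, fs = session$fs)
  mask <- classify_bursts(sds, config$site_count_threshold,
                          config$min_duration_ms, config$sd_multiplier)
  windows <- extract_analysis_windows(session, mask,
                                      config$onset_exclusion_s,
                                      config$window_ms, config$n_per_label)
  rows <- list()
  spectra <- session_spectra(session)
  for (ai in seq_len(nrow(config$analyses))) {
    b <- config$analyses$band[ai]
    kd <- config$analyses$kind[ai]
    tab <- features_from_spectra(session, windows, b, kd, spectra)
    if ("five_choice" %in% config$tasks) {
      res <- do.call(run_task, c(
        list(tab, decoding_task(session$schedule$frequencies),
             scheme = config$scheme, k = config$k, n_folds = config$n_folds),
        config$decoder))
      rows[[length(rows) + 1]] <- data.frame(
        band = b, kind = kd, task = "five_choice", acc = res$mean_acc)
      attr(rows[[length(rows)]], "result") <- res
    }
    if ("two_choice" %in% config$tasks) {
      tcs <- two_choice_tasks(session$schedule$frequencies)
      accs <- vapply(tcs, function(tk) {
        do.call(run_task, c(
          list(tab, tk, scheme = config$scheme, k = config$k,
               n_folds = config$n_folds),
          config$decoder))$mean_acc
      }, numeric(1))
      rc <- vapply(tcs, function(tk) tk$ratio_class, numeric(1))
      for (cl in sort(unique(rc))) {
        rows[[length(rows) + 1]] <- data.frame(
          band = b, kind = kd, task = sprintf("two_choice_r%d", cl),
          acc = mean(accs[rc == cl]))
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(mask = mask, windows = windows, results = results)
}

#' Run the full pre/post cohort pipeline
#'
#' Simulates (or processes) a cohort of pre/post session pairs and carries
#' each session through burst screening, feature extraction, decoding and the
#' paired comparison: the complete analysis chain, end to end, deterministic
#' under the master seed. Sessions are simulated and processed one at a time
#' to bound memory.
#'
#' @param config A `pipeline_config`.
#' @param progress Print per-animal progress lines (default FALSE).
#' @return List with `accs` (per animal x cell accuracies), `grid` (the
#'   `comparison_grid` from [summarize_comparison()]), `config`, and `hash`.
#'   If `config$out_dir` is set, artifacts are written beneath it.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  specs <- cohort_specs(config$n_animals, config$layer, config$params,
                        config$effect, config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  acc_rows <- list()
  for (sp in specs) {
    t0 <- proc.time()[["elapsed"]]
    for (phase in c("pre", "post")) {
      pars <- if (phase == "pre") sp$params else sp$params_post
      sd_seed <- if (phase == "pre") sp$seed_pre else sp$seed_post
      ses <- simulate_session(config$grid, config$schedule, pars, sd_seed,
                              session_id = sprintf("%s_a%02d_%s", config$layer,
                                                   sp$animal, phase))
      dec <- decode_session(ses, config)
      if (!is.null(out_dir)) {
        write_burst_intervals(dec$mask,
                              file.path(out_dir, paste0(ses$session_id, "_bursts.bed")),
                              ses$session_id)
      }
      r <- dec$results
      r$animal <- sp$animal
      r$phase <- phase
      acc_rows[[length(acc_rows) + 1]] <- r
      rm(ses)
    }
    if (progress) {
      message(sprintf("animal %d/%d done in %.1f s", sp$animal,
                      config$n_animals, proc.time()[["elapsed"]] - t0))
    }
  }
  long <- do.call(rbind, acc_rows)
  wide <- stats::reshape(long, direction = "wide",
                         idvar = c("band", "kind", "task", "animal"),
                         timevar = "phase")
  accs <- data.frame(layer = config$layer, band = wide$band, kind = wide$kind,
                     task = wide$task, animal = wide$animal,
                     pre_acc = wide$acc.pre, post_acc = wide$acc.post)
  grid <- summarize_comparison(accs)
  if (!is.null(out_dir)) {
    utils::write.table(accs, file.path(out_dir, "accuracies.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(config_hash = config$hash, seed = config$seed,
           grid = grid[setdiff(names(grid), "deltas")]),
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  list(accs = accs, grid = grid, config = config, hash = config$hash)
}
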