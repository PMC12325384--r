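#' Write a recording session to a plain-text container
#'
#' Persists a session as a directory: `lfp.tsv` (sites x samples, full
#' double precision, uV), `schedule.tsv`, `grid.tsv`, `bursts.tsv` (planted
#' ground-truth events) and `meta.json` (sampling rate, seed, generator
#' parameters, container schema version). The container round-trips losslessly
#' through [read_session()].
#'
#' @param session A `recording_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lfp_lines <- apply(session$lfp, 1, function(r) paste(sprintf("%.17g", r),
                                                       collapse = "\t"))
  writeLines(lfp_lines, file.path(dir, "lfp.tsv"))
  utils::write.table(session$schedule$trials, file.path(dir, "schedule.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(session$grid$sites, file.path(dir, "grid.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(session$ground_truth$bursts, file.path(dir, "bursts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(
    schema = "lfpdecode-session-v1",
    session_id = session$session_id,
    fs = session$fs,
    seed = session$seed,
    n_sites = nrow(session$lfp),
    n_samples = ncol(session$lfp),
    grid = list(rows = session$grid$rows, cols = session$grid$cols,
                extent_mm = session$grid$extent_mm),
    schedule = list(frequencies = session$schedule$frequencies,
                    repetitions = session$schedule$repetitions,
                    tone_ms = session$schedule$tone_ms,
                    gap_ms = session$schedule$gap_ms,
                    total_ms = session$schedule$total_ms,
                    seed = session$schedule$seed),
    params = unclass_params(session$params),
    background_rms = session$ground_truth$background_rms
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

unclass_params <- function(p) {
  u <- unclass(p)
  u$bands <- NULL
  u$foci <- NULL       # rebuilt from the schedule frequencies on read
  # named vectors must become JSON objects, not bare arrays
  for (f in c("amp_uv", "contrast", "kappa")) u[[f]] <- as.list(u[[f]])
  u
}

#' Read a recording session from a plain-text container
#'
#' @param dir Directory written by [write_session()].
#' @return A `recording_session`. Schema violations (missing files, truncated
#'   matrices, field mismatches) raise a descriptive error naming the field;
#'   no partial session is returned.
#' @export
read_session <- function(dir) {
  need <- c("lfp.tsv", "schedule.tsv", "grid.tsv", "bursts.tsv", "meta.json")
  have <- file.exists(file.path(dir, need))
  if (!all(have)) {
    stop("session container incomplete; missing: ",
         paste(need[!have], collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$schema, "lfpdecode-session-v1")) {
    stop("field `schema`: unsupported value '", meta$schema, "'")
  }
  lines <- readLines(file.path(dir, "lfp.tsv"))
  if (length(lines) != meta$n_sites) {
    stop("field `n_sites`: meta declares ", meta$n_sites, " sites but lfp.tsv has ",
         length(lines), " rows")
  }
  lfp <- do.call(rbind, lapply(lines, function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  if (ncol(lfp) != meta$n_samples) {
    stop("field `n_samples`: meta declares ", meta$n_samples,
         " samples but lfp.tsv has ", ncol(lfp))
  }
  if (anyNA(lfp)) stop("field `lfp`: non-numeric or truncated values")
  grid_sites <- utils::read.table(file.path(dir, "grid.tsv"), header = TRUE,
                                  sep = "\t")
  grid <- make_grid(meta$grid$rows, meta$grid$cols,
                    offline_corners = !all(grid_sites$active),
                    extent_mm = meta$grid$extent_mm)
  if (!identical(grid$sites$active, grid_sites$active)) {
    stop("field `grid`: stored active-site pattern is not a corner-offline grid")
  }
  schedule <- make_schedule(meta$schedule$frequencies, meta$schedule$repetitions,
                            tone_s = meta$schedule$tone_ms / 1000,
                            gap_s = meta$schedule$gap_ms / 1000,
                            seed = meta$schedule$seed)
  if (!identical(schedule$total_ms, as.integer(meta$schedule$total_ms)) &&
      schedule$total_ms != meta$schedule$total_ms) {
    stop("field `schedule`: stored schedule does not reproduce total_ms")
  }
  pm <- meta$params
  params <- generator_params(
    amp_uv = unlist(pm$amp_uv), contrast = unlist(pm$contrast),
    kappa = unlist(pm$kappa), noise_uv = pm$noise_uv,
    burst_rate_per_min = pm$burst_rate_per_min,
    burst_dur_ms = unlist(pm$burst_dur_ms),
    burst_amp_mult = pm$burst_amp_mult, layer = pm$layer,
    jitter_tau_ms = pm$jitter_tau_ms
  )
  bursts <- utils::read.table(file.path(dir, "bursts.tsv"), header = TRUE,
                              sep = "\t")
  structure(list(
    lfp = lfp, fs = meta$fs, grid = grid, schedule = schedule, params = params,
    seed = meta$seed, session_id = meta$session_id,
    ground_truth = list(bursts = bursts,
                        site_bumps = NULL,
                        background_rms = meta$background_rms)
  ), class = "recording_session")
}

#' Export burst intervals as BED-like text
#'
#' Three tab-separated columns: session id, interval start (ms), interval end
#' (ms), one row per burst interval.
#'
#' @param mask A `burst_mask`.
#' @param path Output file.
#' @param session_id Identifier written in column 1.
#' @return `path`, invisibly.
#' @export
write_burst_intervals <- function(mask, path, session_id = "session") {
  stopifnot(inherits(mask, "burst_mask"))
  df <- data.frame(session = session_id,
                   start_ms = mask$intervals$start_ms,
                   end_ms = mask$intervals$end_ms)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature table as wide TSV
#'
#' First columns: `window`, `trial`, `freq_hz`, `start_ms`; then one column
#' per feature. Band, kind and session id go into a `# key: value` header.
#'
#' @param table A `feature_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# band: %s\n# kind: %s\n# session: %s",
                     table$band, table$kind, table$session_id), con)
  df <- cbind(table$windows, as.data.frame(table$x))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
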