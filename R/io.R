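# File dialects: growth curves as CSV with column 1 `time_h` and one column
# per well; rate designs as CSV with `concentration` and `rate_per_h` (or
# `doubling_min`) plus optional `replicate`; traces as TSV with `position`,
# one column per unit spectrum, and a final `mixed` column. Readers reject
# malformed input rather than coercing silently; writers round-trip.

#' Read growth curves from CSV
#'
#' @param path CSV file: header row, column 1 `time_h` (strictly
#'   increasing), remaining columns one well each.
#' @param condition Optional condition label applied to all curves.
#' @return List of [growth_curve()] objects, one per well column.
#' @export
read_growth_csv <- function(path, condition = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "time_h")
    stop(sprintf("'%s': first column must be 'time_h', found '%s'",
                 path, names(df)[1L]))
  if (ncol(df) < 2L) stop("no well columns found")
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad))
    stop(sprintf("non-numeric cells in column(s): %s",
                 paste(bad, collapse = ", ")))
  if (any(diff(df$time_h) <= 0))
    stop("'time_h' must be strictly increasing")
  wells <- names(df)[-1L]
  stats::setNames(lapply(wells, function(w)
    growth_curve(df$time_h, df[[w]], replicate_id = w,
                 condition = condition)), wells)
}

#' Write growth curves to CSV
#'
#' @param curves List of [growth_curve()] objects sharing the same times.
#' @param path Output path.
#' @export
write_growth_csv <- function(curves, path) {
  times <- curves[[1L]]$times
  for (cv in curves) if (!isTRUE(all.equal(cv$times, times)))
    stop("all curves must share the same time grid")
  df <- data.frame(time_h = times)
  for (cv in curves) df[[cv$replicate_id]] <- cv$od
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rate-vs-concentration design from CSV
#'
#' @param path CSV with columns `concentration` and either `rate_per_h` or
#'   `doubling_min`, optionally `replicate`.
#' @return A [rate_design()].
#' @export
read_rate_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"concentration" %in% names(df))
    stop("missing 'concentration' column")
  if (!is.numeric(df$concentration)) stop("non-numeric 'concentration'")
  has_rate <- "rate_per_h" %in% names(df)
  has_dt <- "doubling_min" %in% names(df)
  if (has_rate == has_dt)
    stop("need exactly one of 'rate_per_h' or 'doubling_min'")
  rate_design(df$concentration,
              rate_per_h = if (has_rate) df$rate_per_h,
              doubling_min = if (has_dt) df$doubling_min,
              replicate = df$replicate)
}

#' Write a rate design to CSV
#' @param design A [rate_design()].
#' @param path Output path.
#' @export
write_rate_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an aligned trace matrix from TSV
#'
#' @param path TSV: first column `position`, one column per unit spectrum,
#'   final column `mixed`.
#' @return A [trace_matrix()].
#' @export
read_trace_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1L] != "position" || names(df)[ncol(df)] != "mixed")
    stop("trace TSV must start with 'position' and end with 'mixed'")
  if (ncol(df) < 3L) stop("no unit-spectrum columns found")
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("non-numeric cells in trace TSV")
  k <- ncol(df) - 2L
  trace_matrix(df$position,
               as.matrix(df[, seq(2L, 1L + k), drop = FALSE]),
               df$mixed, labels = names(df)[seq(2L, 1L + k)])
}

#' Write a trace matrix to TSV
#' @param tm A [trace_matrix()].
#' @param path Output path.
#' @export
write_trace_tsv <- function(tm, path) {
  df <- data.frame(position = tm$positions, check.names = FALSE)
  for (j in seq_along(tm$labels)) df[[tm$labels[j]]] <- tm$unit_spectra[, j]
  df$mixed <- tm$mixed
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a competition series as tidy CSV
#' @param series A `"competition_series"`.
#' @param path Output path.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("index", "day", "population",
                                             "level", "fraction",
                                             "below_detection")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a scenario and write its outputs with a manifest
#'
#' Executes [run_scenario()], writes the tidy series CSV and a JSON summary,
#' and emits a run manifest (command, configuration hash, seed, package and
#' R versions, output paths, timestamp). Re-running with the same inputs
#' reproduces the outputs deterministically (the simulator itself is
#' deterministic; `seed` is recorded for observation layers).
#'
#' @param sc A [scenario()] or builtin scenario name.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer recorded in the manifest and used for any
#'   observation noise.
#' @param observation_depth If non-`NULL`, apply
#'   [gen_competition_observations()] at this depth before writing.
#' @return The manifest (list), invisibly; files are written to `out_dir`.
#' @export
run_pipeline <- function(sc, out_dir, seed = NULL, observation_depth = NULL) {
  if (is.character(sc)) sc <- builtin_scenario(sc)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_scenario(sc)
  series <- res$series
  if (!is.null(observation_depth))
    series <- gen_competition_observations(series, depth = observation_depth,
                                           seed = seed)
  series_path <- file.path(out_dir, paste0(sc$name, "_series.csv"))
  write_series_csv(series, series_path)
  summary_path <- file.path(out_dir, paste0(sc$name, "_summary.json"))
  jsonlite::write_json(list(scenario = sc$name,
                            winner = res$winner,
                            n_transfers = sc$regime$n_transfers,
                            period_h = sc$regime$period_h,
                            detection_limit = sc$detection_limit),
                       summary_path, auto_unbox = TRUE, digits = NA)
  cfg <- utils::capture.output(utils::str(sc, give.attr = FALSE))
  tf <- tempfile(); writeLines(cfg, tf)
  manifest <- list(command = "run_pipeline",
                   scenario = sc$name,
                   config_hash = unname(tools::md5sum(tf)),
                   seed = seed,
                   package_version = as.character(utils::packageVersion("shulk")),
                   r_version = as.character(getRversion()),
                   outputs = c(series_path, summary_path),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, paste0(sc$name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Human-readable summary of scenario results
#'
#' @param results A `"scenario_result"` or list of them.
#' @param threshold Exclusion threshold for transfer counts.
#' @return Character vector of summary lines (also printed).
#' @export
report <- function(results, threshold = 0.05) {
  if (inherits(results, "scenario_result")) results <- list(results)
  lines <- character(0)
  for (res in results) {
    sc <- res$scenario
    lines <- c(lines, sprintf("Scenario %-20s winner: %-12s (%d transfers of %g h)",
                              sc$name, res$winner, sc$regime$n_transfers,
                              sc$regime$period_h))
    strains <- unique(res$strain_series$population)
    for (st in strains) {
      ex <- transfers_to_exclusion(res$series, st, threshold)
      if (!is.null(ex))
        lines <- c(lines, sprintf("  %s excluded (< %.0f%%) at transfer %d",
                                  st, 100 * threshold, ex))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
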