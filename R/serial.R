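# Relative-abundance bookkeeping shared by the serial, stationary and
# scenario drivers. Strain fractions are computed within each species'
# strains; species fractions (strains aggregated by species, plus
# species-level populations) are fractions of the whole community.
.abundance_rows <- function(index, day, densities, levels, species,
                            detection_limit) {
  ids <- names(densities)
  rows <- list()
  is_strain <- levels == "strain"
  for (sp in unique(species[is_strain])) {
    sel <- is_strain & species == sp
    tot <- sum(densities[sel])
    fr <- if (tot > 0) densities[sel] / tot else rep(NA_real_, sum(sel))
    rows[[length(rows) + 1L]] <- data.frame(
      index = index, day = day, population = ids[sel], level = "strain",
      fraction = as.numeric(fr), stringsAsFactors = FALSE)
  }
  sp_tot <- tapply(densities, species, sum)
  comm <- sum(sp_tot)
  fr <- if (comm > 0) as.numeric(sp_tot) / comm else rep(NA_real_, length(sp_tot))
  rows[[length(rows) + 1L]] <- data.frame(
    index = index, day = day, population = names(sp_tot), level = "species",
    fraction = fr, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$below_detection <- !is.na(out$fraction) & out$fraction < detection_limit
  out
}

.as_competition_series <- function(df, detection_limit) {
  rownames(df) <- NULL
  structure(df, class = c("competition_series", "data.frame"),
            detection_limit = detection_limit)
}

#' @export
print.competition_series <- function(x, ...) {
  cat(sprintf("Competition series: %d sampling points, %d populations (detection limit %.0f%%)\n",
              length(unique(x$index)),
              length(unique(x$population)),
              100 * attr(x, "detection_limit")))
  print.data.frame(utils::head(as.data.frame(x), 12L))
  if (nrow(x) > 12L) cat(sprintf("... %d more rows\n", nrow(x) - 12L))
  invisible(x)
}

#' @export
plot.competition_series <- function(x, level = "strain", ...) {
  d <- x[x$level == level, ]
  pops <- unique(d$population)
  graphics::plot(range(d$index), c(0, 1), type = "n",
                 xlab = "transfer / day", ylab = "relative abundance", ...)
  for (i in seq_along(pops)) {
    di <- d[d$population == pops[i], ]
    graphics::lines(di$index, di$fraction, col = i)
    graphics::points(di$index, di$fraction, col = i, pch = 16)
  }
  graphics::abline(h = attr(x, "detection_limit"), lty = 3)
  graphics::legend("right", legend = pops, col = seq_along(pops),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Simulate serial batch-culture competition
#'
#' Runs repeated batch cycles: each cycle integrates [simulate_batch()] for
#' `period_h` hours, records relative abundances at the cycle end, then
#' multiplies densities by the dilution factor and resets resources to the
#' fresh medium. Transfers are handled by stopping and restarting the
#' integrator, never by interpolating across the discontinuity.
#'
#' True fractions are never censored; the detection limit only sets the
#' `below_detection` flags in the reported series.
#'
#' @inheritParams simulate_batch
#' @param regime A [transfer_regime()].
#' @param events Optional list of spike events, each
#'   `list(day =, population =, dose_ratio =)`: at the start of the first
#'   cycle beginning at or after `day`, `population` is added at
#'   `dose_ratio` times the current total focal-species density.
#' @param detection_limit Reporting detection limit (fraction, default 0.05).
#' @param keep_trajectories Keep each cycle's [simulate_batch()] trajectory
#'   (attribute `"trajectories"`).
#' @param start_index,start_day Index/day offsets used when continuing a run
#'   (see [spike_species()]).
#' @return A `"competition_series"` data frame (`index`, `day`, `population`,
#'   `level`, `fraction`, `below_detection`) with attributes `state` (a
#'   snapshot for continuation) and, optionally, `trajectories`.
#' @export
simulate_serial <- function(populations, medium, regime,
                            recycling_fraction = 0, events = NULL,
                            detection_limit = 0.05,
                            keep_trajectories = FALSE,
                            init_densities = NULL,
                            start_index = 0L, start_day = 0) {
  stopifnot(inherits(regime, "transfer_regime"))
  if (inherits(populations, "population")) populations <- list(populations)
  if (length(populations) == 0L) stop("at least one population is required")
  ids <- vapply(populations, `[[`, character(1), "id")
  dens <- stats::setNames(vapply(populations, `[[`, numeric(1), "init_density"), ids)
  if (!is.null(init_densities)) dens[names(init_densities)] <- init_densities
  period_d <- regime$period_h / 24
  rows <- list(); trajs <- list()
  pending <- events
  for (k in seq_len(regime$n_transfers)) {
    day0 <- start_day + (k - 1L) * period_d
    # apply spike events scheduled before this cycle starts growing
    if (length(pending)) {
      due <- vapply(pending, function(e) e$day <= day0 + 1e-9, logical(1))
      for (e in pending[due]) {
        focal <- sum(dens[vapply(populations, function(p) p$level == "strain", logical(1))])
        if (e$dose_ratio < 0) stop("spike dose_ratio must be >= 0")
        populations <- c(populations, list(e$population))
        dens <- c(dens, stats::setNames(e$dose_ratio * focal, e$population$id))
        ids <- names(dens)
      }
      pending <- pending[!due]
    }
    traj <- simulate_batch(populations, medium, regime$period_h,
                           recycling_fraction = recycling_fraction,
                           init_densities = dens)
    if (keep_trajectories) trajs[[k]] <- traj
    dens <- stats::setNames(as.numeric(traj[nrow(traj), ids]), ids)
    rows[[k]] <- .abundance_rows(start_index + k, day0 + period_d, dens,
                                 vapply(populations, `[[`, character(1), "level"),
                                 vapply(populations, `[[`, character(1), "species"),
                                 detection_limit)
    state <- list(populations = populations, densities = dens,
                  medium = medium, regime = regime,
                  recycling_fraction = recycling_fraction,
                  detection_limit = detection_limit,
                  transfers_done = start_index + k, day = day0 + period_d)
    dens <- dens * regime$dilution_factor
  }
  out <- .as_competition_series(do.call(rbind, rows), detection_limit)
  attr(out, "state") <- structure(state, class = "serial_state")
  if (keep_trajectories) attr(out, "trajectories") <- trajs
  out
}

#' Continue a serial run after spiking in a species
#'
#' Takes the end-of-cycle snapshot from a [simulate_serial()] run (attribute
#' `"state"`), adds `species` at `dose_ratio` times the current total
#' focal-species (strain-level) density, and continues the transfer regime.
#' A dose of zero reproduces the unspiked continuation exactly.
#'
#' @param state A `"serial_state"` (attribute of a [simulate_serial()] result).
#' @param species A [population()] to add.
#' @param dose_ratio Spike density as a multiple of the current total
#'   strain-level density, >= 0. Default 10 (a 10:1 spike).
#' @param n_transfers Number of further transfers (default: as in the
#'   original regime).
#' @return A `"competition_series"` whose indices continue the original run.
#' @export
spike_species <- function(state, species, dose_ratio = 10, n_transfers = NULL) {
  stopifnot(inherits(state, "serial_state"))
  if (!is.finite(dose_ratio) || dose_ratio < 0)
    stop("'dose_ratio' must be >= 0")
  if (is.null(n_transfers)) n_transfers <- state$regime$n_transfers
  pops <- state$populations
  dens <- state$densities
  if (dose_ratio > 0 || !species$id %in% names(dens)) {
    focal <- sum(dens[vapply(pops, function(p) p$level == "strain", logical(1))])
    pops <- c(pops, list(species))
    dens <- c(dens, stats::setNames(dose_ratio * focal, species$id))
  }
  regime2 <- transfer_regime(state$regime$period_h, state$regime$dilution_factor,
                             n_transfers)
  simulate_serial(pops, state$medium, regime2,
                  recycling_fraction = state$recycling_fraction,
                  detection_limit = state$detection_limit,
                  init_densities = dens * state$regime$dilution_factor,
                  start_index = state$transfers_done, start_day = state$day)
}

#' Transfers until a population is excluded
#'
#' First transfer index at which the focal population's (strain-level)
#' fraction falls below the detection threshold and never returns to it.
#'
#' @param series A `"competition_series"`.
#' @param focal Population id.
#' @param threshold Exclusion threshold (default 0.05, the detection limit).
#' @return Integer transfer index, or `NULL` if the population is never
#'   excluded.
#' @export
transfers_to_exclusion <- function(series, focal, threshold = 0.05) {
  stopifnot(inherits(series, "competition_series"))
  d <- series[series$population == focal & series$level == "strain", ]
  if (nrow(d) == 0L) stop(sprintf("unknown focal population '%s'", focal))
  d <- d[order(d$index), ]
  below <- d$fraction < threshold
  if (!any(below)) return(NULL)
  last_above <- if (any(!below)) max(which(!below)) else 0L
  if (last_above == nrow(d)) return(NULL)
  d$index[last_above + 1L]
}

#' Long-term stationary-phase culture
#'
#' A single un-renewed batch (no fresh medium) run for `duration_days`,
#' sampled every `sample_every_days`. With biomass turnover (`death_rate` >
#' 0) and partial nutrient recycling, the resource settles at low
#' quasi-steady concentrations, which favours the low-\eqn{K_s} (gleaner)
#' strain over time.
#'
#' @inheritParams simulate_serial
#' @param duration_days Total duration in days.
#' @param sample_every_days Sampling interval (default 2 days).
#' @return A `"competition_series"` indexed by day, with the full
#'   trajectory as attribute `"trajectory"`.
#' @export
simulate_stationary <- function(populations, medium, duration_days,
                                recycling_fraction = 0,
                                sample_every_days = 2,
                                detection_limit = 0.05) {
  if (inherits(populations, "population")) populations <- list(populations)
  sample_h <- seq(0, duration_days * 24, by = sample_every_days * 24)
  times <- sort(unique(c(sample_h, seq(0, duration_days * 24, length.out = 401L))))
  traj <- simulate_batch(populations, medium, duration_days * 24,
                         recycling_fraction = recycling_fraction,
                         times = times)
  ids <- attr(traj, "populations")
  levels <- attr(traj, "levels"); species <- attr(traj, "species")
  rows <- lapply(sample_h, function(t0) {
    i <- which.min(abs(traj$time_h - t0))
    .abundance_rows(t0 / 24, t0 / 24,
                    stats::setNames(as.numeric(traj[i, ids]), ids),
                    levels, species, detection_limit)
  })
  out <- .as_competition_series(do.call(rbind, rows), detection_limit)
  attr(out, "trajectory") <- traj
  out
}

#' Resource depletion timecourse across culture configurations
#'
#' Runs each configuration (monoculture or co-culture) as one batch and
#' reports resource concentrations at the sampling times, emulating
#' timed nutrient assays of culture supernatants.
#'
#' @param setups Named list; each element a [population()] or list of
#'   populations.
#' @param medium A [medium()].
#' @param sample_times_h Sampling times in hours (default 6, 12, 24, 48).
#' @param recycling_fraction Passed to [simulate_batch()].
#' @return Data frame with columns `setup`, `time_h`, `resource`,
#'   `concentration`.
#' @export
nutrient_timecourse <- function(setups, medium,
                                sample_times_h = c(6, 12, 24, 48),
                                recycling_fraction = 0) {
  stopifnot(is.list(setups), length(setups) >= 1L)
  if (is.null(names(setups)) || any(names(setups) == ""))
    stop("'setups' must be a named list")
  dur <- max(sample_times_h)
  times <- sort(unique(c(0, sample_times_h,
                         seq(0, dur, length.out = 201L))))
  out <- list()
  for (nm in names(setups)) {
    pops <- setups[[nm]]
    if (inherits(pops, "population")) pops <- list(pops)
    traj <- simulate_batch(pops, medium, dur,
                           recycling_fraction = recycling_fraction,
                           times = times)
    for (t0 in sample_times_h) {
      i <- which.min(abs(traj$time_h - t0))
      for (res in attr(traj, "resources")) {
        out[[length(out) + 1L]] <- data.frame(
          setup = nm, time_h = t0, resource = res,
          concentration = traj[[res]][i], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
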