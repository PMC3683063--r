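#' Calibrated example strains and community members
#'
#' Returns the package's calibrated populations: a gleaner/exploiter pair of
#' *E. coli*-like strains diverging on peptone (the gleaner with low
#' \eqn{K_s}, the exploiter with high \eqn{\mu_{max}}), near-identical on
#' glucose, plus a fast-depleting clostridial background species (maximal
#' rate and hence peptone uptake well above both strains', with fast biomass
#' turnover, so it strips the peptone early and holds it at low
#' concentrations) and a slow background species. Absolute parameter values are illustrative
#' calibrations; the orderings (which strain has the higher maximal rate,
#' which the lower half-saturation constant) are the contract the
#' simulations depend on.
#'
#' On full-strength rich medium (16 g/L peptone, 1 g/L glucose) the
#' calibrated anaerobic doubling times are about 56.5 min for the gleaner,
#' 51 min for the coexister and 49 min for the exploiter, and the
#' gleaner/exploiter peptone Monod curves cross near 5.6 g/L, so dilute
#' media (<= 20% strength) start below the crossover.
#'
#' @param death_rate Death rate (1/h) given to the focal strains (default
#'   0.01).
#' @return Named list of [population()] objects: `gleaner`, `exploiter`,
#'   `coexister` (a second exploiter-type strain that, under gentle 1:10
#'   daily transfers, stably coexists with the gleaner at a minority gleaner
#'   fraction), `fast_background`, `slow_background`.
#' @export
example_strains <- function(death_rate = 0.01) {
  glc <- function(mu) list(glucose = monod_params(mu, 0.1))
  list(
    gleaner = population(
      "gleaner",
      monod = c(list(peptone = monod_params(0.559, 0.15)), glc(0.20)),
      yields = c(peptone = 0.5, glucose = 0.5),
      init_density = 0.01, level = "strain", death_rate = death_rate),
    exploiter = population(
      "exploiter",
      monod = c(list(peptone = monod_params(0.739, 2.0)), glc(0.21)),
      yields = c(peptone = 0.5, glucose = 0.5),
      init_density = 0.01, level = "strain", death_rate = death_rate),
    coexister = population(
      "coexister",
      monod = c(list(peptone = monod_params(0.689, 1.5)), glc(0.205)),
      yields = c(peptone = 0.5, glucose = 0.5),
      init_density = 0.01, level = "strain", death_rate = death_rate),
    fast_background = population(
      "fast_background",
      monod = list(peptone = monod_params(1.6, 2.0)),
      yields = c(peptone = 0.5),
      init_density = 1e-4, level = "species", death_rate = 0.1),
    slow_background = population(
      "slow_background",
      monod = list(peptone = monod_params(0.30, 0.5)),
      yields = c(peptone = 0.5),
      init_density = 1e-4, level = "species", death_rate = 0.02)
  )
}

#' Rich-medium recipe
#'
#' Full-strength anaerobe-broth-like medium: 16 g/L peptone, 1 g/L glucose,
#' scaled by `strength_fraction` for dilution-series media.
#'
#' @param strength_fraction Dimensionless strength in (0, 2].
#' @return A [medium()].
#' @export
rich_medium <- function(strength_fraction = 1) {
  medium(c(peptone = 16, glucose = 1), strength_fraction = strength_fraction)
}

#' Construct a competition scenario
#'
#' A validated bundle of populations, medium, transfer regime, recycling
#' fraction and optional spike events, run by [run_scenario()]. Unknown
#' fields are an error.
#'
#' @param name Scenario name.
#' @param populations List of [population()] objects.
#' @param medium A [medium()].
#' @param regime A [transfer_regime()].
#' @param recycling_fraction Fraction of dead biomass recycled to resources.
#' @param events Optional spike events (see [simulate_serial()]).
#' @param detection_limit Reporting detection limit (default 0.05).
#' @return Object of class `"scenario"`.
#' @export
scenario <- function(name, populations, medium, regime,
                     recycling_fraction = 0, events = NULL,
                     detection_limit = 0.05) {
  if (inherits(populations, "population")) populations <- list(populations)
  if (!length(populations) || !all(vapply(populations, inherits, logical(1), "population")))
    stop("'populations' must be a list of population objects")
  stopifnot(inherits(medium, "medium"), inherits(regime, "transfer_regime"))
  if (!is.null(events)) {
    for (e in events) {
      if (!all(c("day", "population", "dose_ratio") %in% names(e)))
        stop("each event needs fields 'day', 'population', 'dose_ratio'")
      if (!inherits(e$population, "population"))
        stop("event 'population' must be a population object")
      if (e$dose_ratio < 0) stop("event 'dose_ratio' must be >= 0")
    }
  }
  structure(list(name = name, populations = populations, medium = medium,
                 regime = regime, recycling_fraction = recycling_fraction,
                 events = events, detection_limit = detection_limit),
            class = "scenario")
}

#' Run a competition scenario
#'
#' Executes [simulate_serial()] with all of the scenario's populations in
#' one shared resource pool and reports relative abundances at both levels:
#' strain fractions within the focal species and species fractions of the
#' whole community.
#'
#' @param sc A [scenario()] or the name of a [builtin_scenario()].
#' @param keep_trajectories Keep per-cycle trajectories.
#' @return Object of class `"scenario_result"`: list with `series` (the
#'   full `"competition_series"`), `strain_series`, `species_series`,
#'   `winner` (strain with the highest final within-species fraction) and
#'   `scenario`.
#' @export
run_scenario <- function(sc, keep_trajectories = FALSE) {
  if (is.character(sc)) sc <- builtin_scenario(sc)
  stopifnot(inherits(sc, "scenario"))
  series <- simulate_serial(sc$populations, sc$medium, sc$regime,
                            recycling_fraction = sc$recycling_fraction,
                            events = sc$events,
                            detection_limit = sc$detection_limit,
                            keep_trajectories = keep_trajectories)
  structure(list(series = series,
                 strain_series = series[series$level == "strain", ],
                 species_series = series[series$level == "species", ],
                 winner = final_winner(series),
                 scenario = sc),
            class = "scenario_result")
}

#' Strain with the highest final relative abundance
#'
#' @param series A `"competition_series"`.
#' @param level Abundance level to inspect (default `"strain"`).
#' @return Population id.
#' @export
final_winner <- function(series, level = "strain") {
  d <- series[series$level == level & series$index == max(series$index), ]
  d$population[which.max(d$fraction)]
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d transfers, winner (strain level): %s\n",
              x$scenario$name, max(x$series$index), x$winner))
  invisible(x)
}

#' Built-in competition scenarios
#'
#' Ready-made scenarios over the calibrated strains of [example_strains()]:
#' \describe{
#'   \item{`control_pair`}{gleaner vs exploiter, full-strength medium,
#'     1-day transfers: the exploiter takes over.}
#'   \item{`background_flip`}{the same pair plus the fast-depleting
#'     background species, which rises to community dominance and strips the
#'     peptone, flipping the strain-level winner to the gleaner.}
#'   \item{`background_slow`}{the pair plus the slow background species: no
#'     flip.}
#'   \item{`dilution_high` / `dilution_low`}{90% vs 10% medium strength;
#'     the dilute medium starts below the Monod crossover and flips the
#'     winner.}
#'   \item{`peptone_low`}{peptone-only dilute medium (strains divergent on
#'     peptone): flips.}
#'   \item{`glucose_only` / `glucose_only_low`}{glucose-only media (strains
#'     near-identical on glucose): no flip at any strength.}
#'   \item{`coexistence_1d`}{gleaner vs the coexister strain under gentle
#'     (1:10) 1-day transfers: stable coexistence with the gleaner in the
#'     minority.}
#' }
#'
#' @param name Scenario name.
#' @param n_transfers Override the number of transfers.
#' @return A [scenario()].
#' @export
builtin_scenario <- function(name, n_transfers = NULL) {
  st <- example_strains()
  pep_only <- function(p, init = 0.01) {
    population(p$id, monod = p$monod["peptone"],
               yields = p$yields["peptone"], init_density = init,
               level = p$level, species = p$species,
               death_rate = p$death_rate)
  }
  glc_only <- function(p, init = 0.01) {
    population(p$id, monod = p$monod["glucose"],
               yields = p$yields["glucose"], init_density = init,
               level = p$level, species = p$species,
               death_rate = p$death_rate)
  }
  pair <- list(st$gleaner, st$exploiter)
  nt <- function(def) if (is.null(n_transfers)) def else n_transfers
  sc <- switch(
    name,
    control_pair = scenario(name, pair, rich_medium(),
                            transfer_regime(24, 0.01, nt(20)),
                            recycling_fraction = 0.2),
    background_flip = scenario(name, c(pair, list(st$fast_background)),
                               rich_medium(),
                               transfer_regime(24, 0.01, nt(24)),
                               recycling_fraction = 0.2),
    background_slow = scenario(name, c(pair, list(st$slow_background)),
                               rich_medium(),
                               transfer_regime(24, 0.01, nt(24)),
                               recycling_fraction = 0.2),
    dilution_high = scenario(name, pair, rich_medium(0.9),
                             transfer_regime(24, 0.01, nt(16)),
                             recycling_fraction = 0.2),
    dilution_low = scenario(name, pair, rich_medium(0.1),
                            transfer_regime(24, 0.01, nt(16)),
                            recycling_fraction = 0.2),
    peptone_low = scenario(name, lapply(pair, pep_only),
                           medium(c(peptone = 16), strength_fraction = 0.1),
                           transfer_regime(24, 0.01, nt(16)),
                           recycling_fraction = 0.2),
    glucose_only = scenario(name, lapply(pair, glc_only),
                            medium(c(glucose = 4)),
                            transfer_regime(24, 0.01, nt(16)),
                            recycling_fraction = 0.2),
    glucose_only_low = scenario(name, lapply(pair, glc_only),
                                medium(c(glucose = 4), strength_fraction = 0.1),
                                transfer_regime(24, 0.01, nt(16)),
                                recycling_fraction = 0.2),
    coexistence_1d = scenario(name, list(st$gleaner, st$coexister),
                              rich_medium(),
                              transfer_regime(24, 0.1, nt(30)),
                              recycling_fraction = 0.2),
    stop(sprintf("unknown builtin scenario '%s'", name))
  )
  sc
}
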