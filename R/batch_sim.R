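#' Population specification for the consumer-resource simulator
#'
#' One strain or species with Monod parameters on each resource it consumes,
#' yield coefficients closing the mass balance, an optional first-order death
#' rate, and an initial density.
#'
#' @param id Population label.
#' @param monod Named list (by resource) of [monod_params()] (or `c(mu_max=,
#'   k_s=)` vectors).
#' @param yields Named numeric (by resource): biomass produced per unit
#'   resource consumed (g/g), > 0. Defaults to 0.5 for every resource in
#'   `monod`.
#' @param init_density Initial density (g/L), >= 0.
#' @param level `"strain"` or `"species"`. Strains are members of the focal
#'   species; their fractions are reported within that species, while
#'   species-level fractions are reported over the whole community.
#' @param species Species the population belongs to; defaults to
#'   `"focal_species"` for strains and to `id` for species-level populations.
#' @param death_rate First-order death rate (1/h), >= 0.
#' @param recycle_weights Optional named numeric: how dead biomass is
#'   returned to resources when recycling is on; defaults to uniform over the
#'   consumed resources. Normalised to sum to 1.
#' @return Object of class `"population"`.
#' @export
population <- function(id, monod, yields = NULL, init_density = 0.01,
                       level = c("strain", "species"), species = NULL,
                       death_rate = 0, recycle_weights = NULL) {
  level <- match.arg(level)
  if (!is.list(monod) || is.null(names(monod)) || any(names(monod) == ""))
    stop("'monod' must be a named list: resource -> Monod parameters")
  monod <- lapply(monod, as_monod_params)
  res <- names(monod)
  if (is.null(yields)) yields <- stats::setNames(rep(0.5, length(res)), res)
  if (is.null(names(yields)) || !all(res %in% names(yields)))
    stop("'yields' must be named for every resource in 'monod'")
  yields <- yields[res]
  if (any(!is.finite(yields)) || any(yields <= 0))
    stop("yields must be finite and positive")
  if (!is.finite(death_rate) || death_rate < 0)
    stop("'death_rate' must be >= 0")
  if (!is.finite(init_density) || init_density < 0)
    stop("'init_density' must be >= 0")
  if (!any(vapply(monod, `[[`, numeric(1), "mu_max") > 0))
    stop("at least one resource must have positive mu_max")
  if (is.null(recycle_weights)) {
    recycle_weights <- stats::setNames(rep(1 / length(res), length(res)), res)
  } else {
    if (is.null(names(recycle_weights)))
      stop("'recycle_weights' must be named by resource")
    if (any(recycle_weights < 0)) stop("'recycle_weights' must be >= 0")
    recycle_weights <- recycle_weights / sum(recycle_weights)
  }
  if (is.null(species)) species <- if (level == "strain") "focal_species" else id
  structure(list(id = as.character(id), level = level,
                 species = as.character(species), monod = monod,
                 yields = yields, init_density = init_density,
                 death_rate = death_rate, recycle_weights = recycle_weights),
            class = "population")
}

#' Growth medium
#'
#' A set of resources with initial concentrations, optionally scaled by a
#' dimensionless strength fraction to represent dilution-series media (10%,
#' 20%, 50%, 90%, 200% of the full-strength recipe).
#'
#' @param resources Named numeric: resource id -> full-strength initial
#'   concentration (g/L), >= 0.
#' @param strength_fraction Multiplier in (0, 2].
#' @return Object of class `"medium"`; `$concentrations` holds the effective
#'   (scaled) initial concentrations.
#' @export
medium <- function(resources, strength_fraction = 1) {
  if (!is.numeric(resources) || is.null(names(resources)) ||
      any(names(resources) == ""))
    stop("'resources' must be a named numeric vector")
  if (any(!is.finite(resources)) || any(resources < 0))
    stop("resource concentrations must be >= 0")
  if (!is.finite(strength_fraction) || strength_fraction <= 0 ||
      strength_fraction > 2)
    stop("'strength_fraction' must be in (0, 2]")
  structure(list(resources = resources,
                 strength_fraction = strength_fraction,
                 concentrations = resources * strength_fraction),
            class = "medium")
}

#' Serial-transfer regime
#'
#' @param period_h Hours between transfers, > 0.
#' @param dilution_factor Fraction of the culture carried into fresh medium,
#'   in (0, 1). Default 1:100.
#' @param n_transfers Number of transfers, >= 1.
#' @return Object of class `"transfer_regime"`.
#' @export
transfer_regime <- function(period_h, dilution_factor = 0.01, n_transfers) {
  if (!is.finite(period_h) || period_h <= 0) stop("'period_h' must be > 0")
  if (!is.finite(dilution_factor) || dilution_factor <= 0 || dilution_factor >= 1)
    stop("'dilution_factor' must be in (0, 1)")
  if (!is.finite(n_transfers) || n_transfers < 1)
    stop("'n_transfers' must be >= 1")
  structure(list(period_h = period_h, dilution_factor = dilution_factor,
                 n_transfers = as.integer(n_transfers)),
            class = "transfer_regime")
}

# Assemble the vectorised model matrices shared by all simulation entry
# points: mu_max / K_s / 1/yield matrices (population x resource; mu_max = 0
# where a population does not consume a resource), death-rate vector, and
# recycling weight matrix.
.model_matrices <- function(populations, resources) {
  p <- length(populations); r <- length(resources)
  ids <- vapply(populations, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("population ids must be unique")
  mu_max <- ks <- inv_y <- w <- matrix(0, p, r, dimnames = list(ids, resources))
  ks[] <- 1  # placeholder K_s where mu_max = 0 (value irrelevant)
  for (i in seq_len(p)) {
    pop <- populations[[i]]
    for (res in names(pop$monod)) {
      if (!res %in% resources)
        stop(sprintf("population '%s' consumes resource '%s' absent from the medium",
                     pop$id, res))
      mu_max[i, res] <- pop$monod[[res]]$mu_max
      ks[i, res] <- pop$monod[[res]]$k_s
      inv_y[i, res] <- 1 / pop$yields[[res]]
      w[i, res] <- pop$recycle_weights[[res]]
    }
  }
  list(p = p, r = r, ids = ids,
       levels = vapply(populations, `[[`, character(1), "level"),
       species = vapply(populations, `[[`, character(1), "species"),
       mu_max = mu_max, ks = ks, inv_y = inv_y, w = w,
       d = vapply(populations, `[[`, numeric(1), "death_rate"))
}

.batch_deriv <- function(t, y, parms) {
  p <- parms$p; r <- parms$r
  n <- pmax(y[seq_len(p)], 0)
  s <- pmax(y[p + seq_len(r)], 0)
  smat <- matrix(s, p, r, byrow = TRUE)
  mu <- parms$mu_max * smat / (parms$ks + smat)   # per-resource Monod rates
  growth <- rowSums(mu)                           # substitutable resources: additive
  dn <- (growth - parms$d) * n
  cons <- colSums(mu * n * parms$inv_y)
  supply <- if (parms$rho > 0) parms$rho * colSums(parms$w * (parms$d * n)) else 0
  ds <- -cons + supply
  list(c(dn, ds))
}

#' Simulate one batch culture
#'
#' Integrates the Monod consumer-resource closure
#' \deqn{dN_i/dt = \left[\sum_r \mu_{i,r}(s_r)\right] N_i - d_i N_i}
#' \deqn{ds_r/dt = -\sum_i \mu_{i,r}(s_r) N_i / Y_{i,r}
#'   + \rho \sum_i d_i N_i w_{i,r}}
#' with \eqn{\mu_{i,r}} the per-resource Monod rate, \eqn{Y} yields, \eqn{d}
#' death rates and \eqn{\rho} (`recycling_fraction`) the fraction of dead
#' biomass returned to the resource pool (composition weights \eqn{w}).
#' Resources are substitutable (growth terms add). With `d = 0` and
#' `recycling_fraction = 0` the quantity \eqn{s + \sum_i N_i / Y_i} is
#' conserved for a single-resource system.
#'
#' Integration uses an adaptive stiff-capable solver (`vode`, with `lsoda`
#' as fallback; rtol 1e-8, atol 1e-10); states are clipped at zero inside
#' the derivative and tiny negative excursions in the output are set to
#' zero.
#'
#' @param populations List of [population()] objects (may be empty).
#' @param medium A [medium()].
#' @param duration_h Duration in hours, > 0.
#' @param recycling_fraction \eqn{\rho \in [0, 1)}.
#' @param init_densities Optional named numeric overriding each population's
#'   `init_density` (used by the serial driver).
#' @param times Output times (h); default 201 equally spaced points.
#' @return Object of class `"batch_trajectory"`: a data frame with column
#'   `time_h`, one column per population density and one per resource
#'   concentration; attributes `populations` and `resources` name them.
#' @export
simulate_batch <- function(populations, medium, duration_h,
                           recycling_fraction = 0, init_densities = NULL,
                           times = NULL) {
  stopifnot(inherits(medium, "medium"))
  if (!is.finite(duration_h) || duration_h <= 0) stop("'duration_h' must be > 0")
  if (recycling_fraction < 0 || recycling_fraction >= 1)
    stop("'recycling_fraction' must be in [0, 1)")
  if (inherits(populations, "population")) populations <- list(populations)
  resources <- names(medium$concentrations)
  if (is.null(times)) times <- seq(0, duration_h, length.out = 201L)

  if (length(populations) == 0L) {
    out <- data.frame(time_h = times)
    for (res in resources) out[[res]] <- medium$concentrations[[res]]
    return(structure(out, class = c("batch_trajectory", "data.frame"),
                     populations = character(0), resources = resources))
  }

  mm <- .model_matrices(populations, resources)
  mm$rho <- recycling_fraction
  n0 <- vapply(populations, `[[`, numeric(1), "init_density")
  if (!is.null(init_densities)) {
    if (is.null(names(init_densities)) || !all(mm$ids %in% names(init_densities)))
      stop("'init_densities' must be named for every population")
    n0 <- as.numeric(init_densities[mm$ids])
  }
  y0 <- c(n0, as.numeric(medium$concentrations))
  run_ode <- function(method) {
    deSolve::ode(y = y0, times = times, func = .batch_deriv, parms = mm,
                 method = method, rtol = 1e-8, atol = 1e-10)
  }
  # vode first: lsoda's dense-output interpolation can fail once the system
  # goes quiescent after resource exhaustion; lsoda remains the fallback
  sol <- tryCatch(run_ode("vode"), error = function(e) NULL)
  if (is.null(sol) || attr(sol, "istate")[1L] < 0)
    sol <- tryCatch(run_ode("lsoda"), error = function(e) NULL)
  if (is.null(sol))
    stop(sprintf("batch integration failed; initial state: %s",
                 paste(sprintf("%.4g", y0), collapse = ", ")))
  if (attr(sol, "istate")[1L] < 0)
    stop(sprintf("batch integration failed; state at failure: %s",
                 paste(sprintf("%.4g", sol[nrow(sol), -1L]), collapse = ", ")))
  sol <- as.data.frame(sol)
  names(sol) <- c("time_h", mm$ids, resources)
  sol[-1L] <- lapply(sol[-1L], function(v) pmax(v, 0))
  structure(sol, class = c("batch_trajectory", "data.frame"),
            populations = mm$ids, resources = resources,
            levels = mm$levels, species = mm$species)
}

#' @export
plot.batch_trajectory <- function(x, what = c("densities", "resources"), ...) {
  what <- match.arg(what)
  cols <- if (what == "densities") attr(x, "populations") else attr(x, "resources")
  if (length(cols) == 0L) stop("nothing to plot")
  graphics::matplot(x$time_h, as.matrix(x[cols]), type = "l", lty = 1,
                    xlab = "time (h)",
                    ylab = if (what == "densities") "density (g/L)" else "concentration (g/L)",
                    ...)
  graphics::legend("topright", legend = cols, lty = 1,
                   col = seq_along(cols), bty = "n")
  invisible(x)
}
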