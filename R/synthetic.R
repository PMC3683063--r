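# Seeded generators for every input the pipeline consumes. Each generator
# records its ground truth in the "truth" attribute so recovery tests are
# self-contained. Seeding uses R's default generator via a local set.seed;
# identical seed and arguments give identical output.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

#' Generate replicate OD600 growth curves
#'
#' Emulates Bioscreen-style triplicate growth curves: exponential growth at
#' a known doubling time (or Monod batch growth when `params` and `s0` are
#' given) on a constant instrument/medium background, saturating at
#' `od_max`, with multiplicative lognormal noise. The generating parameters
#' are returned in the `"truth"` attribute.
#'
#' @param doubling_min True doubling time in minutes (exponential mode).
#' @param params,s0,yield_ Alternatively, [monod_params()], an initial
#'   resource concentration and a yield: the curve is then the single-strain
#'   batch solution from [simulate_batch()].
#' @param n_replicates Number of replicate wells (default 3).
#' @param times_h Sampling times (default every 10 min for 10 h).
#' @param od0 Initial biomass OD contribution (default 0.005).
#' @param background Constant background OD (default 0.08).
#' @param od_max Saturation OD above background (default 1.2; exponential
#'   mode only).
#' @param noise_sd Multiplicative lognormal noise sd (default 0.01).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param condition Condition label for the curves.
#' @return List of [growth_curve()] objects with attribute `"truth"`.
#' @export
gen_growth_curves <- function(doubling_min = NULL, params = NULL, s0 = NULL,
                              yield_ = 0.5, n_replicates = 3L,
                              times_h = seq(0, 10, by = 1 / 6), od0 = 0.005,
                              background = 0.08, od_max = 1.2,
                              noise_sd = 0.01, seed = NULL,
                              condition = "anaerobic") {
  if (is.null(doubling_min) == is.null(params))
    stop("give exactly one of 'doubling_min' or 'params' (+ 's0')")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.null(doubling_min)) {
    rate <- log(2) / (doubling_min / 60)
    od_true <- pmin(od0 * exp(rate * times_h), od_max) + background
  } else {
    if (is.null(s0)) stop("'s0' is required with 'params'")
    pop <- population("gen", monod = list(res = as_monod_params(params)),
                      yields = c(res = yield_), init_density = od0)
    traj <- simulate_batch(list(pop), medium(c(res = s0)),
                           duration_h = max(times_h), times = times_h)
    od_true <- traj$gen + background
  }
  .with_seed(seed, {
    curves <- lapply(seq_len(n_replicates), function(r) {
      noisy <- od_true * exp(stats::rnorm(length(od_true), 0, noise_sd))
      growth_curve(times_h, noisy, replicate_id = paste0("rep", r),
                   condition = condition)
    })
    attr(curves, "truth") <- list(doubling_min = doubling_min,
                                  params = params, s0 = s0,
                                  od0 = od0, background = background,
                                  noise_sd = noise_sd, seed = seed)
    curves
  })
}

#' Generate a rate-vs-concentration design
#'
#' Monod rates at the given concentrations with multiplicative lognormal
#' noise, replicated; emulates doubling-time measurements across a
#' medium-concentration series. Ground truth in the `"truth"` attribute.
#'
#' @param params True [monod_params()].
#' @param concentrations Design concentrations (>= 1; >= 4 distinct needed
#'   downstream by [fit_monod()] — a single concentration is flagged
#'   unusable).
#' @param reps Replicates per concentration (default 3).
#' @param noise_sd Multiplicative noise sd (default 0.01).
#' @param seed Integer seed.
#' @return A [rate_design()] with attributes `"truth"` and `"usable"`
#'   (`FALSE` when fewer than 4 distinct concentrations).
#' @export
gen_rate_design <- function(params, concentrations, reps = 3L,
                            noise_sd = 0.01, seed = NULL) {
  params <- as_monod_params(params)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  conc <- rep(concentrations, each = reps)
  repl <- rep(paste0("rep", seq_len(reps)), times = length(concentrations))
  .with_seed(seed, {
    mu <- monod_rate(conc, params) *
      exp(stats::rnorm(length(conc), 0, noise_sd))
    d <- rate_design(conc, rate_per_h = mu, replicate = repl)
    attr(d, "truth") <- list(params = params, noise_sd = noise_sd, seed = seed)
    attr(d, "usable") <- length(unique(concentrations)) >= 4L
    d
  })
}

#' Generate unit spectra and a mixed trace
#'
#' Unit spectra are sums of Gaussian peaks at strain-specific positions;
#' the mixed trace is the proportion-weighted sum of the unit spectra
#' (scaled so equal abundance yields equal total signal) plus additive
#' Gaussian noise (truncated at zero). Two strains with identical
#' peak-position sets are rejected as degenerate.
#'
#' @param mixture True mixture proportions (one per strain, summing to 1).
#' @param length Number of positions (default 400).
#' @param n_peaks Peaks per strain (default 10).
#' @param peak_width Gaussian peak sd in positions (default 3).
#' @param noise_sd Additive noise sd as a fraction of the maximum mixed
#'   intensity (default 0.01).
#' @param peak_positions Optional list of integer vectors (one per strain)
#'   fixing the peak positions.
#' @param seed Integer seed.
#' @return A [trace_matrix()] with attribute `"truth"`.
#' @export
gen_traces <- function(mixture, length = 400L, n_peaks = 10L,
                       peak_width = 3, noise_sd = 0.01,
                       peak_positions = NULL, seed = NULL) {
  if (abs(sum(mixture) - 1) > 1e-9)
    stop("'mixture' proportions must sum to 1")
  k <- base::length(mixture)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  .with_seed(seed, {
    if (is.null(peak_positions)) {
      peak_positions <- lapply(seq_len(k), function(i)
        sort(sample.int(length - 20L, n_peaks) + 10L))
    }
    if (base::length(peak_positions) != k)
      stop("'peak_positions' must have one entry per strain")
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      if (identical(sort(peak_positions[[i]]), sort(peak_positions[[j]])))
        stop("degenerate design: two strains share an identical peak-position set")
    }
    pos <- seq_len(length)
    U <- vapply(peak_positions, function(pk) {
      amps <- stats::runif(base::length(pk), 0.5, 1)
      rowSums(vapply(seq_along(pk), function(m)
        amps[m] * exp(-(pos - pk[m])^2 / (2 * peak_width^2)),
        numeric(length)))
    }, numeric(length))
    # equal abundance yields equal total signal: the mixture is composed
    # over unit-sum spectra, while the stored unit spectra keep their
    # arbitrary per-strain intensities (as measured pure traces would)
    mixed_true <- as.numeric(sweep(U, 2L, colSums(U), "/") %*% mixture)
    mixed <- pmax(mixed_true +
                    stats::rnorm(length, 0, noise_sd * max(mixed_true)), 0)
    tm <- trace_matrix(pos, U, mixed,
                       labels = paste0("strain", seq_len(k)))
    attr(tm, "truth") <- list(mixture = mixture,
                              peak_positions = peak_positions,
                              noise_sd = noise_sd, seed = seed)
    tm
  })
}

#' Add sampling noise to a competition series
#'
#' Observation layer for duplicate-flask experiments: at each sampling
#' index and level, draws multinomial counts at the given depth over the
#' true fractions, renormalises, and re-applies the detection-limit flags.
#' True zero fractions stay zero.
#'
#' @param series A `"competition_series"`.
#' @param depth Multinomial sampling depth, >= 1 (default 200).
#' @param seed Integer seed.
#' @return A `"competition_series"` of observed fractions with attribute
#'   `"truth"` (the input series).
#' @export
gen_competition_observations <- function(series, depth = 200L, seed = NULL) {
  stopifnot(inherits(series, "competition_series"))
  if (!is.finite(depth) || depth < 1) stop("'depth' must be >= 1")
  dl <- attr(series, "detection_limit")
  .with_seed(seed, {
    out <- series
    for (ix in unique(series$index)) for (lv in unique(series$level)) {
      sel <- which(series$index == ix & series$level == lv)
      if (!base::length(sel)) next
      fr <- series$fraction[sel]
      if (any(is.na(fr))) next
      counts <- as.numeric(stats::rmultinom(1L, size = depth, prob = fr))
      out$fraction[sel] <- counts / depth
    }
    out$below_detection <- !is.na(out$fraction) & out$fraction < dl
    attr(out, "truth") <- series
    out
  })
}
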