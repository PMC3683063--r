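# Independent oracles, deliberately simple and separate from the package's
# own code paths.

# Fixed-step Euler integration of the same consumer-resource model,
# written directly from the model equations (no shared code with
# simulate_batch). populations: list of population objects.
euler_batch <- function(populations, medium, duration_h, recycling_fraction = 0,
                        dt = 1e-3, init_densities = NULL) {
  ids <- vapply(populations, function(p) p$id, character(1))
  res <- names(medium$concentrations)
  n <- if (is.null(init_densities)) {
    vapply(populations, function(p) p$init_density, numeric(1))
  } else as.numeric(init_densities[ids])
  s <- as.numeric(medium$concentrations)
  names(n) <- ids; names(s) <- res
  steps <- ceiling(duration_h / dt)
  for (step in seq_len(steps)) {
    h <- min(dt, duration_h - (step - 1) * dt)
    dn <- numeric(length(n)); ds <- numeric(length(s))
    for (i in seq_along(populations)) {
      p <- populations[[i]]
      mu_tot <- 0
      for (r in names(p$monod)) {
        sr <- max(s[[r]], 0)
        mu <- p$monod[[r]]$mu_max * sr / (p$monod[[r]]$k_s + sr)
        mu_tot <- mu_tot + mu
        ds[[which(res == r)]] <- ds[[which(res == r)]] - mu * n[[i]] / p$yields[[r]]
      }
      dn[[i]] <- (mu_tot - p$death_rate) * n[[i]]
      if (recycling_fraction > 0) {
        for (r in names(p$recycle_weights)) {
          ds[[which(res == r)]] <- ds[[which(res == r)]] +
            recycling_fraction * p$death_rate * n[[i]] * p$recycle_weights[[r]]
        }
      }
    }
    n <- pmax(n + h * dn, 0)
    s <- pmax(s + h * ds, 0)
  }
  list(densities = n, resources = s)
}

# Serial transfers on top of the Euler oracle.
euler_serial <- function(populations, medium, regime, recycling_fraction = 0,
                         dt = 1e-3) {
  ids <- vapply(populations, function(p) p$id, character(1))
  dens <- setNames(vapply(populations, function(p) p$init_density, numeric(1)), ids)
  shares <- list()
  for (k in seq_len(regime$n_transfers)) {
    out <- euler_batch(populations, medium, regime$period_h,
                       recycling_fraction, dt = dt, init_densities = dens)
    dens <- out$densities
    shares[[k]] <- dens / sum(dens)
    dens <- dens * regime$dilution_factor
  }
  do.call(rbind, shares)
}

# Brute-force exact Mann-Whitney p by recursive enumeration of all
# assignments; U computed by direct pairwise comparison counts.
mw_brute_force <- function(a, b, alternative = "two.sided") {
  u_stat <- function(x, y) {
    u <- 0
    for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  }
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  u_obs <- u_stat(a, b)
  mid <- na * (n - na) / 2
  p <- switch(alternative,
              less = mean(us <= u_obs + 1e-9),
              greater = mean(us >= u_obs - 1e-9),
              two.sided = mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9))
  list(U = u_obs, p = p)
}

# Student-t tail probability by adaptive quadrature of the density.
t_tail_quadrature <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, abs(t), Inf, rel.tol = 1e-12)$value
}

# Bisection root of the Monod rate difference on (lo, hi).
crossover_bisect <- function(a, b, lo = 1e-6, hi = 1e3, tol = 1e-12) {
  f <- function(s) monod_rate(s, a) - monod_rate(s, b)
  if (sign(f(lo)) == sign(f(hi))) return(NULL)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, hi)) break
  }
  (lo + hi) / 2
}
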