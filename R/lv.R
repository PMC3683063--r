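#' Two-strain Lotka-Volterra competition system
#'
#' Parameters of the competitive Lotka-Volterra model
#' \deqn{dN_1/dt = r_1 N_1 (1 - (N_1 + \alpha_{12} N_2)/K_1)}
#' \deqn{dN_2/dt = r_2 N_2 (1 - (N_2 + \alpha_{21} N_1)/K_2)}
#' with carrying capacities \eqn{K_i} (kept in the measurement's own biomass
#' units, e.g. dry weight g per 30 ml) and dimensionless competition
#' coefficients \eqn{\alpha_{ij}} (per-capita effect of strain j on strain
#' i). Intrinsic rates only matter for simulation, not for the equilibrium
#' or its classification.
#'
#' @param K1,K2 Carrying capacities, > 0.
#' @param alpha12,alpha21 Competition coefficients, >= 0 (negative values,
#'   i.e. facilitation, are accepted with a warning).
#' @param r1,r2 Intrinsic rates (1/h), > 0; default 1.
#' @return Object of class `"lv_system"`.
#' @export
lv_system <- function(K1, K2, alpha12, alpha21, r1 = 1, r2 = 1) {
  if (!all(is.finite(c(K1, K2, alpha12, alpha21, r1, r2))))
    stop("all parameters must be finite")
  if (K1 <= 0 || K2 <= 0) stop("carrying capacities must be > 0")
  if (r1 <= 0 || r2 <= 0) stop("intrinsic rates must be > 0")
  if (alpha12 < 0 || alpha21 < 0)
    warning("negative competition coefficient: facilitation, outside the standard competitive model")
  structure(list(K1 = K1, K2 = K2, alpha12 = alpha12, alpha21 = alpha21,
                 r1 = r1, r2 = r2),
            class = "lv_system")
}

#' @export
print.lv_system <- function(x, ...) {
  cat(sprintf("LV system: K1 = %.4g, K2 = %.4g, alpha12 = %.4g, alpha21 = %.4g\n",
              x$K1, x$K2, x$alpha12, x$alpha21))
  cat(sprintf("  classification: %s\n", classify_equilibrium(x)))
  invisible(x)
}

#' Competition coefficients from carrying capacities
#'
#' Derives the Lotka-Volterra competition coefficients from monoculture
#' carrying capacities, the co-culture carrying capacity and the equilibrium
#' proportion of strain 1 in the co-culture. Setting
#' \eqn{N_1^* = p_1 K_{co}}, \eqn{N_2^* = (1-p_1) K_{co}} and requiring the
#' co-culture densities to lie on both zero isoclines,
#' \eqn{N_1^* + \alpha_{12} N_2^* = K_1} and
#' \eqn{N_2^* + \alpha_{21} N_1^* = K_2}, gives the coefficients directly.
#'
#' @param K1,K2 Monoculture carrying capacities, > 0.
#' @param K_co Co-culture carrying capacity, > 0.
#' @param p1 Equilibrium proportion of strain 1 in the co-culture, strictly
#'   inside (0, 1).
#' @param r1,r2 Optional intrinsic rates for the returned system.
#' @return An [lv_system()]; attribute `"equilibrium"` holds
#'   \eqn{(N_1^*, N_2^*)} and `"facilitation"` flags negative coefficients.
#' @export
competition_coefficients <- function(K1, K2, K_co, p1, r1 = 1, r2 = 1) {
  if (!all(is.finite(c(K1, K2, K_co, p1))) || K1 <= 0 || K2 <= 0 || K_co <= 0)
    stop("carrying capacities must be finite and > 0")
  if (p1 <= 0 || p1 >= 1)
    stop("degenerate proportion: 'p1' must be strictly inside (0, 1) for an interior equilibrium")
  n1 <- p1 * K_co; n2 <- (1 - p1) * K_co
  alpha12 <- (K1 - n1) / n2
  alpha21 <- (K2 - n2) / n1
  facil <- alpha12 < 0 || alpha21 < 0
  if (facil)
    warning("solved competition coefficient is negative (facilitation)")
  sys <- suppressWarnings(lv_system(K1, K2, alpha12, alpha21, r1, r2))
  attr(sys, "equilibrium") <- c(N1 = n1, N2 = n2)
  attr(sys, "facilitation") <- facil
  sys
}

#' Classify the Lotka-Volterra equilibrium
#'
#' Mutual-invasibility rule: stable coexistence iff
#' \eqn{\alpha_{12} < K_1/K_2} and \eqn{\alpha_{21} < K_2/K_1}; exclusion
#' when exactly one inequality fails; founder control (either strain can
#' exclude the other depending on initial conditions) when both fail.
#' Boundary equalities are flagged as degenerate.
#'
#' @param sys An [lv_system()].
#' @return One of `"stable_coexistence"`, `"exclusion_of_1"`,
#'   `"exclusion_of_2"`, `"founder_control"` (with attribute
#'   `"degenerate" = TRUE` when an inequality is an equality).
#' @export
classify_equilibrium <- function(sys) {
  stopifnot(inherits(sys, "lv_system"))
  c1 <- sys$alpha12 < sys$K1 / sys$K2  # strain 1 can invade strain 2's monoculture
  c2 <- sys$alpha21 < sys$K2 / sys$K1
  deg <- sys$alpha12 == sys$K1 / sys$K2 || sys$alpha21 == sys$K2 / sys$K1
  out <- if (c1 && c2) "stable_coexistence"
  else if (!c1 && !c2) "founder_control"
  else if (c1) "exclusion_of_2"   # strain 2 cannot invade: strain 1 wins
  else "exclusion_of_1"
  if (deg) attr(out, "degenerate") <- TRUE
  out
}

#' Interior (or boundary) Lotka-Volterra equilibrium
#'
#' Solves the intersection of the two zero isoclines. When the interior
#' solution is not strictly positive, the relevant boundary equilibrium is
#' returned instead.
#'
#' @param sys An [lv_system()].
#' @return List with `N1`, `N2` and `type` (`"interior"`,
#'   `"boundary_only_1"`, `"boundary_only_2"`).
#' @export
equilibrium_point <- function(sys) {
  stopifnot(inherits(sys, "lv_system"))
  det <- 1 - sys$alpha12 * sys$alpha21
  if (det == 0)
    stop("parallel isoclines (alpha12 * alpha21 = 1): no unique equilibrium")
  n1 <- (sys$K1 - sys$alpha12 * sys$K2) / det
  n2 <- (sys$K2 - sys$alpha21 * sys$K1) / det
  if (n1 > 0 && n2 > 0) return(list(N1 = n1, N2 = n2, type = "interior"))
  cls <- classify_equilibrium(sys)
  if (cls == "exclusion_of_2" || (cls == "founder_control" && n1 > 0))
    list(N1 = sys$K1, N2 = 0, type = "boundary_only_1")
  else
    list(N1 = 0, N2 = sys$K2, type = "boundary_only_2")
}

#' Expected co-culture carrying capacity under strain independence
#'
#' The capacity expected from combining the monoculture carrying capacities
#' in the observed co-culture proportions, \eqn{p_1 K_1 + (1-p_1) K_2}. A
#' measured co-culture capacity above this value indicates facilitation
#' (e.g. cross-feeding); comparison against replicate measurements is a
#' one-sample t test ([one_sample_t()]).
#'
#' @param K1,K2 Monoculture carrying capacities.
#' @param p1 Proportion of strain 1, strictly inside (0, 1).
#' @return The expected mixture capacity.
#' @export
expected_mixture_capacity <- function(K1, K2, p1) {
  if (p1 <= 0 || p1 >= 1) stop("'p1' must be strictly inside (0, 1)")
  p1 * K1 + (1 - p1) * K2
}

#' Simulate Lotka-Volterra competition dynamics
#'
#' @param sys An [lv_system()].
#' @param init Numeric length 2: initial densities, > 0 (a zero is allowed
#'   to start on a boundary).
#' @param duration_h Duration.
#' @param times Output times; default 401 points.
#' @return Data frame with columns `time_h`, `N1`, `N2`.
#' @export
simulate_lv <- function(sys, init, duration_h, times = NULL) {
  stopifnot(inherits(sys, "lv_system"), length(init) == 2L)
  if (any(init < 0)) stop("initial densities must be >= 0")
  if (is.null(times)) times <- seq(0, duration_h, length.out = 401L)
  deriv <- function(t, y, p) {
    n1 <- max(y[1], 0); n2 <- max(y[2], 0)
    list(c(p$r1 * n1 * (1 - (n1 + p$alpha12 * n2) / p$K1),
           p$r2 * n2 * (1 - (n2 + p$alpha21 * n1) / p$K2)))
  }
  sol <- tryCatch(
    deSolve::ode(y = c(N1 = init[1], N2 = init[2]), times = times,
                 func = deriv, parms = sys, method = "vode",
                 rtol = 1e-8, atol = 1e-10),
    error = function(e) NULL)
  if (is.null(sol))
    sol <- deSolve::ode(y = c(N1 = init[1], N2 = init[2]), times = times,
                        func = deriv, parms = sys, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1L] < 0) stop("LV integration failed")
  out <- as.data.frame(sol)
  names(out) <- c("time_h", "N1", "N2")
  out
}

#' Full isocline analysis from carrying-capacity measurements
#'
#' Convenience wrapper: derives the competition coefficients, classifies the
#' equilibrium, computes the equilibrium point and the expected mixture
#' capacity.
#'
#' @inheritParams competition_coefficients
#' @return Object of class `"isocline_analysis"`.
#' @export
isocline_analysis <- function(K1, K2, K_co, p1, r1 = 1, r2 = 1) {
  sys <- competition_coefficients(K1, K2, K_co, p1, r1, r2)
  eq <- equilibrium_point(sys)
  structure(list(system = sys,
                 classification = classify_equilibrium(sys),
                 equilibrium = eq,
                 expected_capacity = expected_mixture_capacity(K1, K2, p1),
                 observed_capacity = K_co,
                 inputs = list(K1 = K1, K2 = K2, K_co = K_co, p1 = p1)),
            class = "isocline_analysis")
}

#' @export
print.isocline_analysis <- function(x, ...) {
  s <- x$system
  cat("Isocline analysis from carrying capacities\n")
  cat(sprintf("  inputs: K1 = %.4g, K2 = %.4g, K_co = %.4g, p1 = %.3g\n",
              x$inputs$K1, x$inputs$K2, x$inputs$K_co, x$inputs$p1))
  cat(sprintf("  alpha12 = %.4g, alpha21 = %.4g\n", s$alpha12, s$alpha21))
  cat(sprintf("  equilibrium: N1* = %.4g, N2* = %.4g (%s)\n",
              x$equilibrium$N1, x$equilibrium$N2, x$equilibrium$type))
  cat(sprintf("  classification: %s\n", x$classification))
  cat(sprintf("  expected mixture capacity %.4g vs observed %.4g\n",
              x$expected_capacity, x$observed_capacity))
  invisible(x)
}

#' Plot the zero isoclines and equilibrium of a two-strain LV system
#'
#' @param sys An [lv_system()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_isoclines <- function(sys, ...) {
  stopifnot(inherits(sys, "lv_system"))
  lim2 <- max(sys$K2, sys$K1 / max(sys$alpha12, 1e-12)) * 1.05
  lim1 <- max(sys$K1, sys$K2 / max(sys$alpha21, 1e-12)) * 1.05
  graphics::plot(NA, xlim = c(0, lim2), ylim = c(0, lim1),
                 xlab = "N2", ylab = "N1", ...)
  graphics::abline(a = sys$K1, b = -sys$alpha12, col = 2)          # N1 isocline
  graphics::abline(a = sys$K2 / max(sys$alpha21, 1e-12),
                   b = -1 / max(sys$alpha21, 1e-12), col = 4)      # N2 isocline
  eq <- tryCatch(equilibrium_point(sys), error = function(e) NULL)
  if (!is.null(eq) && eq$type == "interior")
    graphics::points(eq$N2, eq$N1, pch = 19)
  graphics::legend("topright", legend = c("dN1/dt = 0", "dN2/dt = 0"),
                   col = c(2, 4), lty = 1, bty = "n")
  invisible(sys)
}
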