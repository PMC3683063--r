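#' Rate-vs-concentration design
#'
#' Growth rates (or doubling times) measured at several medium
#' concentrations, the design used to parameterise the Monod model for a
#' strain. Concentration may be a dimensionless dilution fraction of
#' full-strength rich medium or an absolute concentration in g/L; doubling
#' times (minutes) are converted to rates via \eqn{\mu = \ln 2 / T_d} with
#' \eqn{T_d} in hours.
#'
#' @param concentration Medium concentrations, positive.
#' @param rate_per_h Specific growth rates (1/h); give this or `doubling_min`.
#' @param doubling_min Doubling times in minutes.
#' @param replicate Optional replicate labels.
#' @return A data frame of class `"rate_design"` with columns
#'   `concentration`, `rate_per_h`, `replicate`.
#' @export
rate_design <- function(concentration, rate_per_h = NULL, doubling_min = NULL,
                        replicate = NULL) {
  if (is.null(rate_per_h) == is.null(doubling_min))
    stop("give exactly one of 'rate_per_h' or 'doubling_min'")
  if (!is.null(doubling_min)) {
    if (any(doubling_min <= 0)) stop("doubling times must be positive")
    rate_per_h <- log(2) / (doubling_min / 60)
  }
  if (length(concentration) != length(rate_per_h))
    stop("'concentration' and rates must have equal length")
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentrations must be finite and positive")
  if (any(!is.finite(rate_per_h)) || any(rate_per_h <= 0))
    stop("rates must be finite and positive")
  if (is.null(replicate)) replicate <- rep("rep1", length(concentration))
  out <- data.frame(concentration = as.numeric(concentration),
                    rate_per_h = as.numeric(rate_per_h),
                    replicate = as.character(replicate))
  class(out) <- c("rate_design", "data.frame")
  out
}

#' Fit the Monod model to a rate-vs-concentration design
#'
#' Nonlinear least squares of \eqn{\mu(s) = \mu_{max} s / (K_s + s)}
#' (Levenberg-Marquardt, positivity-bounded). Starting values follow a
#' Lineweaver-Burk-free heuristic: \eqn{\mu_{max}^{(0)}} = maximum observed
#' rate, \eqn{K_s^{(0)}} = the concentration whose mean rate is nearest
#' \eqn{\mu_{max}^{(0)}/2}; on failure up to `max_restarts` randomly jittered
#' restarts are tried.
#'
#' A saturated design (all rates essentially equal) leaves \eqn{K_s}
#' unidentifiable; the fit then returns `mu_max` = mean rate with
#' `ks_unidentifiable = TRUE` in the diagnostics rather than a spurious
#' estimate.
#'
#' @param design A [rate_design()] (>= 4 distinct concentrations).
#' @param max_restarts Jittered restarts on non-convergence (default 5).
#' @return Object of class `"monod_fit"`: `params` ([monod_params()] or, when
#'   unidentifiable, a list with `k_s = NA`), `se` (approximate standard
#'   errors), `rss`, `fitted`, `residuals`, `diagnostics` (list with
#'   `converged`, `ks_unidentifiable`, `n_restarts`, `message`).
#' @export
fit_monod <- function(design, max_restarts = 5L) {
  if (!inherits(design, "rate_design")) {
    if (is.data.frame(design) && all(c("concentration", "rate_per_h") %in% names(design)))
      design <- rate_design(design$concentration, design$rate_per_h,
                            replicate = design$replicate)
    else stop("'design' must be a rate_design")
  }
  s <- design$concentration; mu <- design$rate_per_h
  if (length(unique(s)) < 4L)
    stop("Monod fitting needs at least 4 distinct concentrations")

  mu_by_s <- tapply(mu, s, mean)
  if (diff(range(mu)) <= 1e-8 * max(mu)) {
    # saturated design: mu(s) flat, K_s unidentifiable
    return(structure(list(
      params = list(mu_max = mean(mu), k_s = NA_real_),
      se = c(mu_max = stats::sd(mu) / sqrt(length(mu)), k_s = NA_real_),
      rss = sum((mu - mean(mu))^2),
      fitted = rep(mean(mu), length(mu)), residuals = mu - mean(mu),
      diagnostics = list(converged = TRUE, ks_unidentifiable = TRUE,
                         n_restarts = 0L,
                         message = "all rates equal: saturated design, K_s unidentifiable")),
      class = "monod_fit"))
  }

  mu0 <- max(mu)
  conc_levels <- as.numeric(names(mu_by_s))
  ks0 <- conc_levels[which.min(abs(mu_by_s - mu0 / 2))]
  starts <- list(c(mu_max = mu0, k_s = max(ks0, min(s) * 1e-3)))
  dat <- data.frame(s = s, mu = mu)
  fit <- NULL; tried <- 0L
  for (attempt in seq_len(1L + max_restarts)) {
    st <- starts[[1L]]
    if (attempt > 1L) {  # multiplicative jitter around the heuristic start
      jit <- stats::runif(2, 0.2, 5)
      st <- st * jit
    }
    tried <- attempt - 1L
    fit <- tryCatch(
      minpack.lm::nlsLM(mu ~ mu_max * s / (k_s + s), data = dat,
                        start = as.list(st),
                        lower = c(mu_max = 1e-12, k_s = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop(sprintf("Monod fit failed to converge after %d restarts (start mu_max=%.3g, K_s=%.3g)",
                 max_restarts, starts[[1L]]["mu_max"], starts[[1L]]["k_s"]))

  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(mu_max = NA_real_, k_s = NA_real_))
  ks_flag <- cf[["k_s"]] < min(s) * 1e-4 ||
    (is.finite(se[["k_s"]]) && se[["k_s"]] > 10 * cf[["k_s"]])
  structure(list(
    params = monod_params(cf[["mu_max"]], cf[["k_s"]]),
    se = c(mu_max = unname(se[["mu_max"]]), k_s = unname(se[["k_s"]])),
    rss = sum(stats::residuals(fit)^2),
    fitted = stats::fitted(fit), residuals = stats::residuals(fit),
    diagnostics = list(converged = TRUE, ks_unidentifiable = ks_flag,
                       n_restarts = tried, message = "ok")),
    class = "monod_fit")
}

#' @export
print.monod_fit <- function(x, ...) {
  if (isTRUE(x$diagnostics$ks_unidentifiable) && is.na(x$params$k_s)) {
    cat(sprintf("Monod fit: mu_max = %.4g /h; K_s unidentifiable (%s)\n",
                x$params$mu_max, x$diagnostics$message))
  } else {
    cat(sprintf("Monod fit: mu_max = %.4g +/- %.2g /h, K_s = %.4g +/- %.2g (RSS %.3g)\n",
                x$params$mu_max, x$se[["mu_max"]],
                x$params$k_s, x$se[["k_s"]], x$rss))
    if (isTRUE(x$diagnostics$ks_unidentifiable))
      cat("  note: K_s weakly identified for this design\n")
  }
  invisible(x)
}
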