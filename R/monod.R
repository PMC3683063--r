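#' Monod growth parameters
#'
#' Container for the two parameters of the Monod growth law
#' \eqn{\mu(s) = \mu_{max} s / (K_s + s)}: the maximal specific growth rate
#' and the half-saturation (Monod) constant, i.e. the resource concentration
#' at which the growth rate equals \eqn{\mu_{max}/2}.
#'
#' @param mu_max Maximal specific growth rate (1/h); finite, > 0.
#' @param k_s Half-saturation constant (resource units, typically g/L);
#'   finite, > 0.
#' @return An object of class `"monod_params"`.
#' @examples
#' p <- monod_params(mu_max = 1.0, k_s = 0.5)
#' monod_rate(0.5, p)  # half saturation: mu_max / 2
#' @export
monod_params <- function(mu_max, k_s) {
  stopifnot(is.numeric(mu_max), length(mu_max) == 1L,
            is.numeric(k_s), length(k_s) == 1L)
  if (!is.finite(mu_max) || mu_max <= 0)
    stop("'mu_max' must be finite and > 0")
  if (!is.finite(k_s) || k_s <= 0)
    stop("'k_s' must be finite and > 0")
  structure(list(mu_max = as.numeric(mu_max), k_s = as.numeric(k_s)),
            class = "monod_params")
}

#' @export
print.monod_params <- function(x, ...) {
  cat(sprintf("Monod parameters: mu_max = %.4g /h, K_s = %.4g\n",
              x$mu_max, x$k_s))
  invisible(x)
}

as_monod_params <- function(x) {
  if (inherits(x, "monod_params")) return(x)
  if (is.numeric(x) && length(x) == 2L) {
    nm <- names(x)
    if (!is.null(nm) && all(c("mu_max", "k_s") %in% nm))
      return(monod_params(x[["mu_max"]], x[["k_s"]]))
    return(monod_params(x[[1L]], x[[2L]]))
  }
  if (is.list(x) && all(c("mu_max", "k_s") %in% names(x)))
    return(monod_params(x$mu_max, x$k_s))
  stop("cannot interpret 'x' as Monod parameters")
}

#' Monod specific growth rate
#'
#' Evaluates \eqn{\mu(s) = \mu_{max} s/(K_s + s)}. The rate is monotone
#' non-decreasing in `s` and bounded above by `mu_max`.
#'
#' @param s Resource concentration(s), >= 0.
#' @param params A [monod_params()] object (or coercible).
#' @return Specific growth rate(s) (1/h), same length as `s`.
#' @export
monod_rate <- function(s, params) {
  params <- as_monod_params(params)
  if (!is.numeric(s) || any(!is.finite(s)))
    stop("'s' must be finite numeric")
  if (any(s < 0))
    stop("resource concentration 's' must be non-negative")
  params$mu_max * s / (params$k_s + s)
}

#' Crossover concentration of two Monod curves
#'
#' For two strains with Monod parameters `a` and `b`, returns the resource
#' concentration \eqn{s^*} at which their growth rates are equal, when one
#' strain has the higher \eqn{\mu_{max}} and the other the lower \eqn{K_s}
#' (a gleaner/exploiter pair). Below \eqn{s^*} the low-\eqn{K_s} strain grows
#' faster; above it the high-\eqn{\mu_{max}} strain does.
#'
#' @param a,b [monod_params()] objects.
#' @return The crossover concentration (same units as `k_s`), or `NULL` when
#'   no strictly positive finite crossover exists (identical curves, or one
#'   strain at least as fast at every `s > 0`).
#' @seealso [classify_pair()]
#' @export
crossover_concentration <- function(a, b) {
  a <- as_monod_params(a); b <- as_monod_params(b)
  if (a$mu_max == b$mu_max) return(NULL)  # curves meet only at s = 0 (or everywhere)
  s_star <- (a$mu_max * b$k_s - b$mu_max * a$k_s) / (b$mu_max - a$mu_max)
  if (is.finite(s_star) && s_star > 0) s_star else NULL
}

#' Classify a strain pair by its Monod curves
#'
#' A pair is a gleaner/exploiter ("sHULK": high-\eqn{\mu_{max}}, low-\eqn{K_s})
#' pair exactly when its Monod curves cross at a positive concentration: one
#' strain (the exploiter) is faster at saturating concentrations (strictly
#' higher \eqn{\mu_{max}}) while the other (the gleaner) is faster at low
#' concentrations (strictly higher initial slope \eqn{\mu_{max}/K_s}, which
#' requires a strictly lower \eqn{K_s}). Note that a higher \eqn{\mu_{max}}
#' together with a higher \eqn{K_s} is not sufficient: if the \eqn{\mu_{max}}
#' advantage outweighs the \eqn{K_s} handicap, that strain is faster at every
#' concentration and the pair is a dominance case, not a crossing pair.
#'
#' @param a,b [monod_params()] objects.
#' @return One of `"sHULK_a_exploiter"`, `"sHULK_b_exploiter"`,
#'   `"a_dominates"`, `"b_dominates"`, `"identical"`. The "exploiter" is the
#'   high-\eqn{\mu_{max}} member, superior when resources are abundant; the
#'   other member is the "gleaner", superior when resources are scarce. A
#'   crossover ([crossover_concentration()]) exists exactly for the two
#'   sHULK labels.
#' @export
classify_pair <- function(a, b) {
  a <- as_monod_params(a); b <- as_monod_params(b)
  if (a$mu_max == b$mu_max && a$k_s == b$k_s) return("identical")
  slope_a <- a$mu_max / a$k_s; slope_b <- b$mu_max / b$k_s
  if (a$mu_max > b$mu_max && slope_a < slope_b) return("sHULK_a_exploiter")
  if (b$mu_max > a$mu_max && slope_b < slope_a) return("sHULK_b_exploiter")
  # remaining cases: one strain at least as fast at every s > 0
  if (a$mu_max >= b$mu_max && slope_a >= slope_b) "a_dominates" else "b_dominates"
}
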