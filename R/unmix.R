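#' Aligned trace matrix for mixture decomposition
#'
#' Pure-strain "unit spectra" (one intensity column per strain) and a mixed
#' trace, all aligned on the same channel/position index — the input of the
#' electropherogram unmixing step.
#'
#' @param positions Ordered position/channel index.
#' @param unit_spectra Numeric matrix, one column per pure strain; all
#'   intensities >= 0; no two columns identical.
#' @param mixed Mixed-trace intensity vector, same length.
#' @param labels Strain ids (default: column names or `strain1`, ...).
#' @return Object of class `"trace_matrix"`.
#' @export
trace_matrix <- function(positions, unit_spectra, mixed, labels = NULL) {
  unit_spectra <- as.matrix(unit_spectra)
  n <- length(positions)
  if (nrow(unit_spectra) != n || length(mixed) != n)
    stop("positions, unit spectra and mixed trace must have equal length")
  if (any(!is.finite(unit_spectra)) || any(unit_spectra < 0) ||
      any(!is.finite(mixed)) || any(mixed < 0))
    stop("intensities must be finite and non-negative")
  k <- ncol(unit_spectra)
  if (n < k + 2L)
    stop("need at least 2 more positions than strains")
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      if (isTRUE(all.equal(unit_spectra[, i], unit_spectra[, j],
                           tolerance = 1e-12)))
        stop("identical unit-spectrum columns: strains are unidentifiable")
    }
  }
  if (is.null(labels)) {
    labels <- colnames(unit_spectra)
    if (is.null(labels)) labels <- paste0("strain", seq_len(k))
  }
  colnames(unit_spectra) <- labels
  structure(list(positions = positions, unit_spectra = unit_spectra,
                 mixed = as.numeric(mixed), labels = labels),
            class = "trace_matrix")
}

#' Decompose a mixed trace into strain relative abundances
#'
#' Regresses the mixed electropherogram trace on the pure-strain unit
#' spectra. Each unit-spectrum column is first scaled to unit sum, so the
#' coefficients are interpretable as signal fractions; the default solver is
#' non-negativity-constrained least squares, with the coefficients
#' renormalised to sum to one. The \eqn{R^2} of the fitted mixture and the
#' overall regression p-value of the corresponding (unconstrained,
#' intercept-free) multiple linear regression are reported as fit
#' diagnostics. Components below the detection limit are flagged, never
#' zeroed.
#'
#' @param tm A [trace_matrix()].
#' @param detection_limit Flagging threshold on proportions (default 0.05).
#' @param constrained If `FALSE`, use the plain (unconstrained) least-squares
#'   coefficients, renormalised to sum to one (negative coefficients are
#'   possible and reported as-is).
#' @param baseline If `TRUE`, subtract a rolling-minimum baseline
#'   (window `baseline_window`) from the mixed trace before fitting.
#' @param baseline_window Rolling-minimum window (positions, default 25).
#' @param max_condition Condition-number threshold above which the
#'   normalised unit-spectra matrix is declared unidentifiable (default 1e6).
#' @return Object of class `"unmix_fit"`: `proportions` (named, summing to
#'   1), `below_detection` flags, `coefficients` (raw scale), `r_squared`,
#'   `p_value`, `fitted`, `residuals`.
#' @export
unmix <- function(tm, detection_limit = 0.05, constrained = TRUE,
                  baseline = FALSE, baseline_window = 25L,
                  max_condition = 1e6) {
  stopifnot(inherits(tm, "trace_matrix"))
  y <- tm$mixed
  if (baseline) y <- y - .rolling_min(y, baseline_window)
  if (all(y == 0)) stop("all-zero mixed trace")
  U <- sweep(tm$unit_spectra, 2L, colSums(tm$unit_spectra), "/")
  if (any(!is.finite(U))) stop("a unit spectrum is all zero")
  kap <- kappa(U, exact = TRUE)
  if (kap > max_condition)
    stop(sprintf("unit spectra are collinear (condition number %.3g > %.3g): proportions unidentifiable",
                 kap, max_condition))
  if (constrained) {
    coefs <- pracma::lsqnonneg(U, y)$x
  } else {
    coefs <- as.numeric(stats::coef(stats::lm(y ~ U - 1)))
  }
  if (sum(coefs) == 0) stop("degenerate fit: all coefficients zero")
  props <- stats::setNames(coefs / sum(coefs), tm$labels)
  fitted <- as.numeric(U %*% coefs)
  res <- y - fitted
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else max(0, 1 - sum(res^2) / tss)
  # overall significance from the unconstrained multiple regression
  lmfit <- stats::lm(y ~ U - 1)
  fs <- suppressWarnings(summary(lmfit))$fstatistic
  p <- if (is.null(fs)) NA_real_ else
    stats::pf(fs[["value"]], fs[["numdf"]], fs[["dendf"]], lower.tail = FALSE)
  structure(list(proportions = props,
                 below_detection = props < detection_limit,
                 coefficients = stats::setNames(coefs, tm$labels),
                 r_squared = r2, p_value = unname(p),
                 fitted = fitted, residuals = res,
                 detection_limit = detection_limit,
                 condition_number = kap, constrained = constrained),
            class = "unmix_fit")
}

.rolling_min <- function(x, window) {
  n <- length(x)
  half <- window %/% 2L
  vapply(seq_len(n), function(i)
    min(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}

#' @export
print.unmix_fit <- function(x, ...) {
  cat(sprintf("Trace unmixing (%s least squares): R2 = %.4f, p = %.3g\n",
              if (x$constrained) "non-negative" else "unconstrained",
              x$r_squared, x$p_value))
  for (i in seq_along(x$proportions)) {
    cat(sprintf("  %-12s %5.1f%%%s\n", names(x$proportions)[i],
                100 * x$proportions[i],
                if (x$below_detection[i]) "  [below detection limit]" else ""))
  }
  invisible(x)
}

#' Flag proportions below the detection limit
#'
#' The trace-decomposition method cannot reliably report components below
#' roughly 5% relative abundance; this marks them while preserving the
#' values (they are never zeroed).
#'
#' @param proportions Named or unnamed numeric proportions summing to 1.
#' @param threshold Detection limit (default 0.05).
#' @return Data frame with columns `component`, `proportion`,
#'   `below_detection`.
#' @export
flag_detection <- function(proportions, threshold = 0.05) {
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("proportions must sum to 1")
  nm <- names(proportions)
  if (is.null(nm)) nm <- paste0("component", seq_along(proportions))
  data.frame(component = nm, proportion = as.numeric(proportions),
             below_detection = as.numeric(proportions) < threshold,
             stringsAsFactors = FALSE)
}

#' Positions expected to show mixed base calls
#'
#' For two aligned marker-gene sequences, the positions at which they differ
#' are exactly those where a mixed template should produce a double peak in
#' the electropherogram. Optionally compares with an observed list of mixed
#' positions.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings over A, C, G, T.
#' @param mixed_positions Optional integer vector of observed mixed-peak
#'   positions.
#' @return List with `positions` (expected mixed positions), `n_positions`,
#'   and — when `mixed_positions` is given — `n_discordant` (size of the
#'   symmetric difference) plus `missed` and `unexpected`.
#' @export
mixed_base_call_check <- function(seq_a, seq_b, mixed_positions = NULL) {
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  if (!all(a %in% c("A", "C", "G", "T")) || !all(b %in% c("A", "C", "G", "T")))
    stop("sequences must be over the alphabet {A, C, G, T}")
  pos <- which(a != b)
  out <- list(positions = pos, n_positions = length(pos))
  if (!is.null(mixed_positions)) {
    mixed_positions <- sort(unique(as.integer(mixed_positions)))
    out$missed <- setdiff(pos, mixed_positions)
    out$unexpected <- setdiff(mixed_positions, pos)
    out$n_discordant <- length(out$missed) + length(out$unexpected)
  }
  out
}
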