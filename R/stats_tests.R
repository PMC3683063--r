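#' Group summary statistics
#'
#' Mean, standard error of the mean, and replicate count — the form in which
#' triplicate generation-time measurements are reported (mean ± s.e., n).
#'
#' @param mean Group mean.
#' @param se Standard error of the mean, >= 0.
#' @param n Replicate count, >= 2.
#' @return Object of class `"group_summary"`.
#' @export
group_summary <- function(mean, se, n) {
  if (!is.finite(mean) || !is.finite(se) || se < 0)
    stop("'mean' must be finite and 'se' finite and >= 0")
  if (!is.finite(n) || n < 2) stop("'n' must be >= 2")
  structure(list(mean = mean, se = se, n = as.integer(n)),
            class = "group_summary")
}

#' Two-sample t test from summary statistics
#'
#' Computes the two-sample t test directly from printed summaries (mean,
#' standard error of the mean, n), so published values suffice as inputs.
#' \eqn{t = (\bar a - \bar b)/\sqrt{se_a^2 + se_b^2}}; degrees of freedom by
#' Welch-Satterthwaite (default) or pooled (\eqn{n_a + n_b - 2}; the t
#' statistic is then recomputed with the pooled variance).
#'
#' @param a,b [group_summary()] objects.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param tails 2 (default) or 1 (one-sided in the direction of the observed
#'   difference).
#' @return List with `t`, `df`, `p`, `variant`, `tails`.
#' @export
t_test_summary <- function(a, b, variant = c("welch", "pooled"), tails = 2) {
  variant <- match.arg(variant)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (!tails %in% c(1, 2)) stop("'tails' must be 1 or 2")
  if (a$se == 0 && b$se == 0 && a$mean == b$mean)
    stop("undefined t statistic: zero variance and equal means")
  if (variant == "welch") {
    se2 <- a$se^2 + b$se^2
    t <- (a$mean - b$mean) / sqrt(se2)
    df <- se2^2 / (a$se^4 / (a$n - 1) + b$se^4 / (b$n - 1))
  } else {
    va <- a$se^2 * a$n; vb <- b$se^2 * b$n   # sample variances
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * va + (b$n - 1) * vb) / df
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  }
  p <- if (tails == 2) 2 * stats::pt(-abs(t), df) else stats::pt(-abs(t), df)
  list(t = t, df = df, p = min(p, 1), variant = variant, tails = tails)
}

#' One-sample t test
#'
#' Standard one-sample t test of `values` against the null mean `mu0`, used
#' e.g. to compare an observed co-culture carrying capacity with the
#' expectation from combining monoculture capacities.
#'
#' @param values Numeric vector, length >= 2.
#' @param mu0 Null-hypothesis mean.
#' @param tails 2 (default) or 1.
#' @return List with `t`, `df`, `p`, `mean`, `se`.
#' @export
one_sample_t <- function(values, mu0, tails = 2) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (!tails %in% c(1, 2)) stop("'tails' must be 1 or 2")
  m <- mean(values); s <- stats::sd(values); n <- length(values)
  if (s == 0 && m == mu0) stop("undefined t statistic: zero variance and mean equal to mu0")
  se <- s / sqrt(n)
  t <- (m - mu0) / se
  df <- n - 1
  p <- if (tails == 2) 2 * stats::pt(-abs(t), df) else stats::pt(-abs(t), df)
  list(t = t, df = df, p = min(p, 1), mean = m, se = se)
}

# Exact distribution of the rank sum of group a over all C(n, na)
# assignments, by dynamic-programming convolution over mid-ranks (doubled to
# integers). Returns support (rank-sum * 2) and counts.
.ranksum_distribution <- function(ranks2, na) {
  n <- length(ranks2)
  smax <- sum(sort(ranks2, decreasing = TRUE)[seq_len(na)])
  # f[k+1, s+1]: number of k-subsets of the first i items with doubled sum s
  f <- matrix(0, nrow = na + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (i in seq_len(n)) {
    r <- ranks2[i]
    kmax <- min(i, na)
    for (k in seq(kmax, 1L)) {
      nz <- which(f[k, ] > 0)
      nz <- nz[nz + r <= smax + 1L]
      if (length(nz)) f[k + 1L, nz + r] <- f[k + 1L, nz + r] + f[k, nz]
    }
  }
  counts <- f[na + 1L, ]
  support <- which(counts > 0) - 1L
  list(support = support, counts = counts[support + 1L],
       total = choose(n, na))
}

#' Exact Mann-Whitney U test
#'
#' Exact test by complete enumeration of all \eqn{C(n_a+n_b, n_a)} group
#' assignments of the pooled observations (computed by an equivalent
#' dynamic-programming convolution), with ties handled by mid-ranks. For
#' samples larger than `max_exact` total observations the normal
#' approximation with tie correction is used and flagged.
#'
#' The statistic is \eqn{U = R_a - n_a(n_a+1)/2}, the number of (a, b) pairs
#' with \eqn{a > b} (ties counting one half). `alternative = "less"` tests
#' whether group `a` tends to be smaller (small U).
#'
#' @param a,b Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param max_exact Largest \eqn{n_a + n_b} for exact enumeration
#'   (default 25).
#' @return List with `U`, `p`, `exact` (logical), `alternative`.
#' @export
mann_whitney_exact <- function(a, b,
                               alternative = c("two.sided", "less", "greater"),
                               max_exact = 25L) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  ranks <- rank(pooled)                     # mid-ranks under ties
  u_obs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  if (n > max_exact) {
    # normal approximation with tie correction
    ties <- table(pooled)
    mu <- na * nb / 2
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                less = stats::pnorm(z),
                greater = stats::pnorm(-z))
    message(sprintf("n = %d exceeds the exact-enumeration bound (%d); using the normal approximation",
                    n, max_exact))
    return(list(U = u_obs, p = min(p, 1), exact = FALSE,
                alternative = alternative))
  }
  ranks2 <- as.integer(round(ranks * 2))
  dist <- .ranksum_distribution(ranks2, na)
  u_vals <- dist$support / 2 - na * (na + 1) / 2
  probs <- dist$counts / dist$total
  mid <- na * nb / 2
  p <- switch(alternative,
              less = sum(probs[u_vals <= u_obs + 1e-9]),
              greater = sum(probs[u_vals >= u_obs - 1e-9]),
              two.sided = sum(probs[abs(u_vals - mid) >= abs(u_obs - mid) - 1e-9]))
  list(U = u_obs, p = min(p, 1), exact = TRUE, alternative = alternative)
}
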