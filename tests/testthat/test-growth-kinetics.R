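test_that("monod_rate matches its closed form and bounds", {
  p <- monod_params(1.0, 1.0)
  expect_equal(monod_rate(0, p), 0)
  expect_equal(monod_rate(1.0, p), 0.5)  # half saturation by definition
  expect_equal(monod_rate(1.6667, p), 1.0 * 1.6667 / 2.6667, tolerance = 1e-12)
  expect_error(monod_rate(-0.1, p), "non-negative")
  # monotone non-decreasing, bounded by mu_max on a log-spaced grid
  s <- 10^seq(-6, 3, length.out = 200)
  r <- monod_rate(s, p)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r <= p$mu_max))
  expect_equal(max(r), p$mu_max, tolerance = 1e-2)
})

test_that("monod_params rejects invalid values", {
  expect_error(monod_params(0, 1), "mu_max")
  expect_error(monod_params(1, -1), "k_s")
  expect_error(monod_params(Inf, 1), "mu_max")
})

test_that("crossover concentration agrees with the bisection oracle", {
  fx <- fixture_pair()
  s_star <- crossover_concentration(fx$a, fx$b)
  expect_equal(s_star, crossover_bisect(fx$a, fx$b), tolerance = 1e-8)
  expect_equal(s_star, 5 / 3, tolerance = 1e-6)
  # identical curves: no crossover
  expect_null(crossover_concentration(fx$a, fx$a))
  # one strain dominates at all s (higher mu_max AND lower K_s): sign of
  # the rate difference is constant on a grid
  a <- monod_params(1.0, 0.2); b <- monod_params(0.7, 1.0)
  grid <- 10^seq(-6, 3, length.out = 100)
  expect_true(all(monod_rate(grid, a) > monod_rate(grid, b)))
  expect_null(crossover_concentration(a, b))
})

test_that("pair classification is consistent with the crossover", {
  fx <- fixture_pair()
  expect_identical(classify_pair(fx$a, fx$b), "sHULK_a_exploiter")
  expect_identical(classify_pair(fx$b, fx$a), "sHULK_b_exploiter")
  expect_identical(classify_pair(monod_params(1.0, 0.2), monod_params(0.7, 1.0)),
                   "a_dominates")
  expect_identical(classify_pair(monod_params(0.7, 1.0), monod_params(1.0, 0.2)),
                   "b_dominates")
  expect_identical(classify_pair(fx$a, fx$a), "identical")
  # property: sHULK <=> positive crossover, and the rate difference flips
  # sign across it
  set.seed(11)
  for (i in 1:50) {
    a <- monod_params(runif(1, 0.2, 2), runif(1, 0.05, 3))
    b <- monod_params(runif(1, 0.2, 2), runif(1, 0.05, 3))
    cls <- classify_pair(a, b)
    s_star <- crossover_concentration(a, b)
    if (startsWith(cls, "sHULK")) {
      expect_true(!is.null(s_star) && s_star > 0)
      dlo <- monod_rate(s_star / 2, a) - monod_rate(s_star / 2, b)
      dhi <- monod_rate(s_star * 2, a) - monod_rate(s_star * 2, b)
      expect_true(dlo * dhi < 0)
      exploiter_is_a <- cls == "sHULK_a_exploiter"
      expect_identical(dhi > 0, exploiter_is_a)  # exploiter faster above s*
    } else {
      expect_null(s_star)
    }
  }
})

test_that("generation_time recovers a noiseless exponential exactly", {
  times <- seq(0, 5, by = 1 / 6)  # every 10 min
  od <- 0.05 * 2^(times * 60 / 50)
  fit <- generation_time(growth_curve(times, od))
  expect_equal(fit$doubling_min, 50, tolerance = 1e-6)
  expect_gt(fit$r_squared, 0.999)
})

test_that("generation_time errors on curves with no exponential phase", {
  times <- seq(0, 5, by = 0.25)
  expect_error(generation_time(growth_curve(times, rep(0.05, length(times)))),
               "no exponential phase")
})

test_that("generation_time is invariant to OD scaling and added background", {
  times <- seq(0, 8, by = 1 / 6)
  od <- pmin(0.01 * 2^(times * 60 / 45), 1.2)
  base <- generation_time(growth_curve(times, od))$doubling_min
  scaled <- generation_time(growth_curve(times, 3.7 * od))$doubling_min
  shifted <- generation_time(growth_curve(times, od + 0.093))$doubling_min
  expect_equal(scaled, base, tolerance = 1e-6)
  # background re-estimation makes offset invariance approximate
  expect_equal(shifted, base, tolerance = 0.01)
})

test_that("generation_time recovers the generator's truth from noisy triplicates", {
  curves <- gen_growth_curves(doubling_min = 56.5, noise_sd = 0.01, seed = 7)
  agg <- generation_time_replicates(curves)
  expect_equal(agg$n, 3L)
  expect_lt(abs(agg$mean_min - 56.5) / 56.5, 0.02)
})

test_that("fit_monod recovers exact parameters from noiseless rates", {
  truth <- monod_params(0.85, 0.15)
  s <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  d <- rate_design(s, rate_per_h = monod_rate(s, truth))
  fit <- fit_monod(d)
  expect_equal(fit$params$mu_max, 0.85, tolerance = 1e-6)
  expect_equal(fit$params$k_s, 0.15, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_false(fit$diagnostics$ks_unidentifiable)
})

test_that("fit_monod recovers noisy parameters within tolerance (median over seeds)", {
  truth <- monod_params(0.85, 0.15)
  s <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  errs <- t(vapply(1:50, function(seed) {
    d <- gen_rate_design(truth, s, reps = 3, noise_sd = 0.01, seed = seed)
    fit <- fit_monod(d)
    c(abs(fit$params$mu_max - 0.85) / 0.85, abs(fit$params$k_s - 0.15) / 0.15)
  }, numeric(2)))
  expect_lt(stats::median(errs[, 1]), 0.10)
  expect_lt(stats::median(errs[, 2]), 0.10)
})

test_that("fit_monod flags degenerate designs", {
  expect_error(fit_monod(rate_design(c(1, 2, 3), rate_per_h = c(0.5, 0.6, 0.7))),
               "4 distinct")
  d <- rate_design(c(1, 2, 4, 8), rate_per_h = rep(0.8, 4))
  fit <- fit_monod(d)
  expect_true(fit$diagnostics$ks_unidentifiable)
  expect_true(is.na(fit$params$k_s))
  expect_equal(fit$params$mu_max, 0.8)
})

test_that("rate_design converts doubling times to rates", {
  d <- rate_design(c(1, 2, 3, 4), doubling_min = rep(41.5888, 4))
  expect_equal(d$rate_per_h, rep(1, 4), tolerance = 1e-4)
  expect_error(rate_design(c(1, 2), rate_per_h = c(1, 2), doubling_min = c(1, 2)),
               "exactly one")
})
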