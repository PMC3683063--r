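test_that("single-strain batch respects mass balance", {
  # growth potential s0 * Y = 0.5 g/L on top of 0.01 initial
  pop <- population("solo", monod = list(r = monod_params(1, 0.5)),
                    yields = c(r = 0.5), init_density = 0.01)
  traj <- simulate_batch(list(pop), medium(c(r = 1.0)), duration_h = 48)
  final <- traj$solo[nrow(traj)]
  expect_equal(final, 0.51, tolerance = 1e-4 / 0.51)
  # conserved quantity s + N/Y at every output time
  conserved <- traj$r + traj$solo / 0.5
  expect_lt(max(abs(conserved - conserved[1])) / conserved[1], 1e-6)
})

test_that("resources stay constant without populations", {
  traj <- simulate_batch(list(), medium(c(a = 2, b = 0.5)), duration_h = 10)
  expect_true(all(traj$a == 2))
  expect_true(all(traj$b == 0.5))
})

test_that("densities and resources never go negative", {
  st <- sharp_pair()
  traj <- simulate_batch(st, peptone_16(), duration_h = 72,
                         recycling_fraction = 0.3)
  expect_true(all(as.matrix(traj[-1]) >= 0))
})

test_that("adaptive integration matches the fixed-step Euler oracle", {
  # two-strain batch, the worked gleaner/exploiter example
  pops <- list(
    population("exploiter", monod = list(r = monod_params(1.0, 1.0)),
               yields = c(r = 0.5), init_density = 0.01),
    population("gleaner", monod = list(r = monod_params(0.7, 0.2)),
               yields = c(r = 0.5), init_density = 0.01))
  med <- medium(c(r = 5))
  traj <- simulate_batch(pops, med, duration_h = 24)
  oracle <- euler_batch(pops, med, 24, dt = 1e-3)
  adaptive <- as.numeric(traj[nrow(traj), c("exploiter", "gleaner")])
  expect_equal(adaptive, as.numeric(oracle$densities), tolerance = 5e-3)
  # exploiter's final share exceeds its initial share (rich start, s0 >> s*)
  expect_gt(adaptive[1] / sum(adaptive), 0.5)
  # with death and recycling too
  pops2 <- sharp_pair(death_rate = 0.02)
  traj2 <- simulate_batch(pops2, peptone_16(), 48, recycling_fraction = 0.4)
  oracle2 <- euler_batch(pops2, peptone_16(), 48, recycling_fraction = 0.4,
                         dt = 1e-3)
  expect_equal(as.numeric(traj2[nrow(traj2), c("gleaner", "exploiter")]),
               as.numeric(oracle2$densities), tolerance = 5e-3)
})

test_that("serial transfers reach a periodic steady state for one strain", {
  pop <- population("solo", monod = list(r = monod_params(0.9, 0.3)),
                    yields = c(r = 0.5), init_density = 0.01)
  s <- simulate_serial(list(pop), medium(c(r = 8)),
                       transfer_regime(24, 0.01, 12), keep_trajectories = TRUE)
  expect_true(all(s$fraction[s$level == "strain"] == 1))
  finals <- vapply(attr(s, "trajectories"),
                   function(tr) tr$solo[nrow(tr)], numeric(1))
  expect_lt(abs(finals[11] - finals[10]) / finals[10], 1e-3)
})

test_that("serial competition matches the Euler serial oracle", {
  pops <- sharp_pair()
  reg <- transfer_regime(24, 0.01, 5)
  s <- simulate_serial(pops, peptone_16(), reg, recycling_fraction = 0.2)
  oracle <- euler_serial(pops, peptone_16(), reg, recycling_fraction = 0.2,
                         dt = 1e-3)
  got <- s[s$level == "strain" & s$population == "gleaner", "fraction"]
  expect_equal(got, unname(oracle[, "gleaner"]), tolerance = 5e-3)
})

test_that("exploiter fixes under short transfers in rich medium", {
  pops <- sharp_pair()
  s <- simulate_serial(pops, peptone_16(),
                       transfer_regime(12, 0.01, 20), recycling_fraction = 0.2)
  fr <- s[s$level == "strain" & s$population == "exploiter", "fraction"]
  expect_gt(fr[20], 0.99)
  # and the gleaner is flagged below detection at the end
  gl <- s[s$level == "strain" & s$population == "gleaner", ]
  expect_true(gl$below_detection[20])
})

test_that("long starvation phases favour the rare gleaner", {
  # constructed regime: 4-day cycles with nutrient recycling sustain a low
  # quasi-steady resource where the low-K_s strain outgrows the exploiter.
  # The gleaner starts rare: its own affinity would otherwise pin the
  # quasi-steady concentration down and cap its advantage.
  pops <- sharp_pair(death_rate = 0.02)
  pops$gleaner$init_density <- 2e-4
  s <- simulate_serial(pops, peptone_16(),
                       transfer_regime(96, 0.01, 4), recycling_fraction = 0.2)
  fr <- s[s$level == "strain" & s$population == "gleaner", "fraction"]
  expect_true(all(diff(fr) > 0))
})

test_that("transfers_to_exclusion finds the first permanent drop", {
  mk <- function(fr) {
    df <- data.frame(index = seq_along(fr), day = seq_along(fr),
                     population = "x", level = "strain", fraction = fr,
                     below_detection = fr < 0.05)
    df2 <- df; df2$population <- "y"; df2$fraction <- 1 - fr
    df2$below_detection <- df2$fraction < 0.05
    structure(rbind(df, df2),
              class = c("competition_series", "data.frame"),
              detection_limit = 0.05)
  }
  fr <- c(0.5, 0.3, 0.2, 0.1, 0.06, 0.055, 0.04, 0.03, 0.02, 0.01)
  expect_identical(transfers_to_exclusion(mk(fr), "x"), 7L)
  expect_null(transfers_to_exclusion(mk(rep(0.5, 10)), "x"))
  # a dip that recovers does not count
  fr2 <- c(0.5, 0.04, 0.3, 0.2, 0.1, 0.04, 0.03, 0.02, 0.01, 0.01)
  expect_identical(transfers_to_exclusion(mk(fr2), "x"), 6L)
  expect_error(transfers_to_exclusion(mk(fr), "nope"), "unknown focal")
})

test_that("exclusion slows as the transfer period lengthens", {
  st <- example_strains()
  pair <- list(st$gleaner, st$exploiter)
  counts <- vapply(c(0.5, 1, 2, 3, 4), function(period_d) {
    reg <- transfer_regime(period_d * 24, 0.01, ceiling(40 / period_d))
    s <- simulate_serial(pair, rich_medium(), reg, recycling_fraction = 0.2)
    ex <- transfers_to_exclusion(s, "gleaner")
    if (is.null(ex)) Inf else as.numeric(ex)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_true(is.finite(counts[1]))  # excluded quickly at 12 h transfers
})

test_that("stationary phase freezes composition without death or recycling", {
  pops <- sharp_pair(death_rate = 0)
  s <- simulate_stationary(pops, peptone_16(), duration_days = 12,
                           recycling_fraction = 0)
  fr <- s[s$level == "strain" & s$population == "gleaner", "fraction"]
  late <- fr[-(1:2)]  # after exhaustion (day >= 4)
  expect_lt(max(late) - min(late), 1e-6)
})

test_that("the gleaner overtakes in long-term stationary culture", {
  st <- example_strains()
  s <- simulate_stationary(list(st$gleaner, st$exploiter), rich_medium(),
                           duration_days = 16, recycling_fraction = 0.5)
  last <- s[s$level == "strain" & s$index == 16, ]
  expect_gt(last$fraction[last$population == "gleaner"],
            last$fraction[last$population == "exploiter"])
})

test_that("a lone population declines at its death rate after exhaustion", {
  pop <- population("solo", monod = list(r = monod_params(1, 0.5)),
                    yields = c(r = 0.5), init_density = 0.01,
                    death_rate = 0.01)
  traj <- simulate_batch(list(pop), medium(c(r = 2)), duration_h = 240,
                         times = seq(0, 240, by = 1))
  # after exhaustion (~day 1), N(t) = N_peak * exp(-d * t)
  n48 <- traj$solo[traj$time_h == 48]
  n240 <- traj$solo[traj$time_h == 240]
  expect_equal(n240 / n48, exp(-0.01 * 192), tolerance = 1e-3)
})

test_that("winner flips with medium strength (dilution series)", {
  hi <- run_scenario("dilution_high")
  lo <- run_scenario("dilution_low")
  expect_identical(hi$winner, "exploiter")
  expect_identical(lo$winner, "gleaner")
})

test_that("peptone-divergent scenario flips but glucose-identical does not", {
  expect_identical(run_scenario("peptone_low")$winner, "gleaner")
  expect_identical(run_scenario("glucose_only")$winner, "exploiter")
  expect_identical(run_scenario("glucose_only_low")$winner, "exploiter")
})

test_that("a fast-depleting background species flips the winner, a slow one does not", {
  ctrl <- run_scenario("control_pair")
  flip <- run_scenario("background_flip")
  slow <- run_scenario("background_slow")
  expect_identical(ctrl$winner, "exploiter")
  expect_identical(flip$winner, "gleaner")
  expect_identical(slow$winner, "exploiter")
  # the flip coincides with background dominance of the community
  sp <- flip$species_series
  bg_final <- sp[sp$index == max(sp$index) & sp$population == "fast_background", ]
  expect_gt(bg_final$fraction, 0.5)
  # strain fractions are reported within the focal species (sum to 1)
  str <- flip$strain_series
  sums <- tapply(str$fraction, str$index, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("spiking the fast species reverses trajectories; dose 0 is a no-op", {
  st <- example_strains()
  ctrl <- run_scenario(builtin_scenario("control_pair", n_transfers = 12))
  state <- attr(ctrl$series, "state")
  before <- ctrl$strain_series[ctrl$strain_series$population == "gleaner", "fraction"]
  expect_lt(before[12], before[6])  # gleaner falling before the spike
  spiked <- spike_species(state, st$fast_background, dose_ratio = 10,
                          n_transfers = 10)
  after <- spiked[spiked$level == "strain" & spiked$population == "gleaner", "fraction"]
  expect_gt(after[10], after[1])    # rising after the spike
  slow <- spike_species(state, st$slow_background, dose_ratio = 10,
                        n_transfers = 10)
  after_slow <- slow[slow$level == "strain" & slow$population == "gleaner", "fraction"]
  expect_lt(after_slow[10], after_slow[1])  # still falling
  # zero dose reproduces the unspiked continuation
  cont <- spike_species(state, st$fast_background, dose_ratio = 0,
                        n_transfers = 8)
  full <- run_scenario(builtin_scenario("control_pair", n_transfers = 20))$series
  a <- cont[cont$level == "strain", "fraction"]
  b <- full[full$level == "strain" & full$index > 12, "fraction"]
  expect_equal(a, b, tolerance = 1e-8)
  expect_error(spike_species(state, st$fast_background, dose_ratio = -1),
               "dose_ratio")
})

test_that("nutrient timecourses mirror consumer efficiency at high and low concentrations", {
  st <- example_strains()
  tc <- nutrient_timecourse(
    list(gleaner = st$gleaner, exploiter = st$exploiter, none = list()),
    medium(c(peptone = 16, glucose = 1)),
    recycling_fraction = 0.2)
  pep <- tc[tc$resource == "peptone", ]
  at <- function(setup, t) pep$concentration[pep$setup == setup & pep$time_h == t]
  # without consumers the resource stays at s0
  expect_true(all(pep$concentration[pep$setup == "none"] == 16))
  # the exploiter strips peptone faster while concentrations are high
  expect_lt(at("exploiter", 6), at("gleaner", 6))
  # the gleaner scavenges deeper once concentrations are low
  expect_lt(at("gleaner", 24), at("exploiter", 24))
  expect_lt(at("gleaner", 48), at("exploiter", 48))
})

test_that("input validation catches bad specifications", {
  expect_error(population("x", monod = list(monod_params(1, 1))), "named")
  expect_error(medium(c(r = -1)), ">= 0")
  expect_error(medium(c(r = 1), strength_fraction = 3), "strength_fraction")
  expect_error(transfer_regime(0, 0.01, 5), "period")
  expect_error(transfer_regime(24, 1.5, 5), "dilution_factor")
  pop <- population("x", monod = list(r = monod_params(1, 1)))
  expect_error(simulate_batch(list(pop), medium(c(other = 1)), 10), "absent")
  expect_error(simulate_batch(list(pop), medium(c(r = 1)), 10,
                              recycling_fraction = 1), "recycling")
})
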