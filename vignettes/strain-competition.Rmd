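---
title: "Gleaners, exploiters, and context-dependent strain competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gleaners, exploiters, and context-dependent strain competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shulk)
```

## The model

A strain growing on a single limiting resource at concentration $s$ follows
the Monod law
$$\mu(s) = \frac{\mu_{max}\, s}{K_s + s},$$
with $\mu_{max}$ the maximal specific growth rate (1/h) and $K_s$ the
half-saturation constant (g/L), the concentration at which the rate is
$\mu_{max}/2$. Two strains form a gleaner/exploiter (sHULK) pair when their
curves cross at a positive concentration $s^*$: the *exploiter* has the
higher $\mu_{max}$ and wins while $s > s^*$; the *gleaner* has the higher
initial slope $\mu_{max}/K_s$ (hence the lower $K_s$) and wins below. Note
the orderings of $\mu_{max}$ and $K_s$ alone do not guarantee a crossing: a
strain whose $\mu_{max}$ advantage outweighs its $K_s$ handicap is faster at
*every* concentration. `classify_pair()` therefore tests the orderings of
$\mu_{max}$ and of the low-concentration slope, which is exactly equivalent
to the existence of $s^*$ returned by `crossover_concentration()`.

Batch dynamics close the mass balance with yields $Y_{i,r}$ (g biomass per g
resource), optional first-order death $d_i$, and a recycling fraction
$\rho$ routing dead biomass back to the resources with weights $w_{i,r}$:
$$\frac{dN_i}{dt} = \Big[\sum_r \mu_{i,r}(s_r)\Big] N_i - d_i N_i, \qquad
\frac{ds_r}{dt} = -\sum_i \frac{\mu_{i,r}(s_r)}{Y_{i,r}} N_i
 + \rho \sum_i d_i N_i w_{i,r}.$$
Resources are substitutable (growth terms add); with $d = \rho = 0$ and one
resource, $s + \sum_i N_i / Y_i$ is conserved, which the tests verify to
$10^{-6}$ relative. Serial transfer multiplies densities by the dilution
factor and resets resources to the fresh medium; the integrator is stopped
and restarted at each transfer, never interpolated across the
discontinuity. The recycling term is the package's mechanism for sustained
low-concentration growth in stationary phase: it keeps the resource at a
low quasi-steady value $s_q$ where consumption balances the recycled flux,
which is what lets the gleaner grind past the exploiter when cultures sit
unfed for weeks. It is a deliberate simplification — one parameter, no new
state variables — of whatever mixture of lysis products and secondary
metabolites feeds real stationary-phase growth.

## Why the winner depends on context

Per transfer cycle the exploiter gains roughly
$(\mu_E - \mu_G)\big|_{s \approx s_0} \cdot T_{log}$ log-units during
regrowth (with $T_{log} \approx \ln(1/\text{dilution}) / \mu$), while the
gleaner gains $(\mu_G - \mu_E)\big|_{s_q} \cdot T_{starve}$ during the
starvation tail. Everything the package reproduces follows from that
balance:

- short transfers and strong media maximise $T_{log}$: the exploiter fixes;
- long periods lengthen $T_{starve}$: exclusion of the gleaner slows with
  the transfer period, and in an un-renewed culture the gleaner eventually
  overtakes;
- media diluted below $s^*$ abolish the exploiter's log-phase edge
  entirely: the winner flips;
- a third species that strips the resource early and then keeps turning
  over (high uptake, high turnover) converts a rich medium into a
  low-concentration environment *for the focal pair*: the winner flips
  even though the medium recipe is unchanged — an environmentally mediated
  indirect interaction. A slow background species changes nothing.

The quasi-steady concentration under a dominant consumer is
$s_q \approx \rho\, d\, Y / (\mu_{max}/K_s)$ of that consumer. Two
consequences informed the calibration. First, the gleaner's *own* affinity
pins $s_q$ down once it is common, capping its advantage — so its
starvation-phase gains are strongest when it is rare. That negative
frequency dependence produces a protected interior equilibrium for the
gleaner/coexister pair under gentle (1:10) daily transfers
(`builtin_scenario("coexistence_1d")`), with the gleaner settling in the
10–15% minority; under harsh 1:100 dilution the same pair sits on a
knife-edge and the faster strain wins. Second, a background species can
only help the gleaner if it holds $s_q$ *low but not too low*; its
turnover rate matters as much as its uptake rate.

## Calibrated defaults

`example_strains()` ships one calibration used by all builtin scenarios.
On the full-strength rich medium (16 g/L peptone + 1 g/L glucose,
`rich_medium()`), the anaerobic doubling times are 56.5 min (gleaner),
51.0 min (coexister) and 49.0 min (exploiter); on peptone the
gleaner/exploiter curves cross at $s^* \approx 5.6$ g/L, so 90%-strength
medium starts well above the crossover and 10% well below; on glucose the
strains are near-identical (exploiter marginally faster), so glucose-only
media produce no flip at any strength. Yields default to 0.5 g/g, strain
death to 0.01/h, transfers to 1:100, and serial scenarios recycle
$\rho = 0.2$ of dead biomass (the stationary scenario uses 0.5, where the
reversal is the point of the experiment). The fast background species
(maximal rate 1.6/h, turnover 0.1/h) reaches community dominance within a
few daily cycles from a trace inoculum and flips the strain-level winner;
the slow species (0.3/h) never does. Absolute
values are illustrative calibrations chosen by the quasi-steady-state
analysis above; the *orderings* — who is faster where — are the contract,
and the shipped synthetic concentration-series fixtures round-trip through
`fit_monod()` to reproduce them.

## Doubling times from OD curves

`generation_time()` fits log-linear windows of at least 5 points and picks
the **longest** window whose $R^2 \ge 0.9995$ and whose fitted rise spans
at least half a doubling, breaking length ties by the steeper slope. Two
design choices deserve justification:

- *Longest, not steepest.* Maximising slope across many short windows
  selects positive noise excursions and biases doubling times short; with
  1% multiplicative noise on 10-minute sampling the bias exceeds the 2%
  recovery tolerance the test suite holds the estimator to. The longest
  sufficiently linear window is an unbiased estimate of the same phase.
  The strict $R^2$ threshold is what keeps long windows honest: genuinely
  exponential stretches sit near $R^2 = 1$ at any length, while lag,
  saturation and background-bend regions fall below the threshold. For
  noisier data, lower `r2_threshold`.
- *Background by self-consistent optimisation.* The background $b$ is the
  value in $[0, \min OD)$ whose subtraction yields the longest (then most
  linear) qualifying window — the estimate optimises exactly the criterion
  used for the fit. For a pure exponential this selects $b = 0$ and
  recovers the doubling time exactly; for growth on a constant instrument
  background it recovers that constant, making the estimate invariant (to
  within grid refinement, ~1%) to adding an offset. Fixed rules such as
  "subtract the minimum of the first readings" mistake initial biomass for
  background whenever the inoculum is visible and badly distort the early
  log phase. `background = "min3"` and `"none"` remain available.

Reported doubling times are in minutes via $T_d = \ln 2 / \mu$; replicates
aggregate as mean ± standard error.

## Monod fitting, unmixing, statistics

`fit_monod()` is Levenberg-Marquardt least squares bounded positive, with
$\mu_{max}^{(0)}$ = the maximum observed rate and $K_s^{(0)}$ = the
concentration nearest half of it, plus up to five randomly jittered
restarts. A design whose rates are flat carries no information about
$K_s$; the fit then reports the mean rate with `ks_unidentifiable = TRUE`
rather than a spurious constant. Medium "concentration" may be a
dimensionless dilution fraction or absolute g/L — the model is scale-free
in $s$ as long as $K_s$ is read in the same units.

`unmix()` scales each unit spectrum to unit sum (so a coefficient is a
signal fraction under equal per-abundance signal yield), solves
non-negative least squares, and renormalises to proportions; the
unconstrained multiple regression supplies the $R^2$ and overall-F
p-value, and is itself available via `constrained = FALSE` since published
decompositions do not always state which variant was used. Collinear unit
spectra (condition number $> 10^6$) are rejected as unidentifiable.
Components under the 5% detection limit are flagged, never zeroed — the
same convention the simulator uses when reporting relative abundances:
simulation state is never censored, only flagged in the report.

The statistics module works from printed summaries: a two-sample t test
from (mean, s.e., n) pairs under Welch (default) or pooled variants, one-
or two-sided; since published reports rarely state the variant, the
acceptance checks require the significance calls to hold under all four
combinations. The exact Mann-Whitney U enumerates all
$\binom{n_a+n_b}{n_a}$ assignments (as a dynamic-programming convolution
over mid-ranks, exact under ties) up to $n_a + n_b = 25$, then falls back
to the flagged tie-corrected normal approximation.

## What the generators emulate — and what they do not

`gen_growth_curves()` produces exponential (or Monod-batch) growth on a
constant background with multiplicative lognormal noise; real plate-reader
curves also contain lag phases, diauxic shifts and condensation artefacts
that are out of scope, so passing recovery tests demonstrate estimator
correctness, not robustness to every pathology. `gen_traces()` builds unit
spectra as Gaussian peak sums and mixes them with additive noise; real
electropherograms add dye crosstalk, mobility shifts and baseline drift,
which the aligned-intensity contract deliberately excludes (an optional
rolling-minimum baseline correction exists but is off by default).
`gen_competition_observations()` applies multinomial sampling at a chosen
depth — the observation layer for duplicate-flask experiments — and
re-derives detection flags on the observed fractions. All generators are
integer-seeded, byte-reproducible, restore the global RNG state, and
attach their ground truth as an attribute.

## Numerical choices

Integration uses `deSolve` with rtol $10^{-8}$, atol $10^{-10}$; `vode` is
tried first because `lsoda`'s dense-output interpolation can fail on long
grids once a culture goes fully quiescent after exhaustion, with `lsoda`
as fallback. States are clipped at zero inside the derivative and
float-level negative excursions zeroed in the output. Fixed-step Euler at
$dt = 10^{-3}$ h, implemented independently in the test helpers, serves as
the integration oracle: adaptive and fixed-step solutions agree within
0.5% on every shipped scenario. Problem sizes in the test-suite and
acceptance runs (4–40 transfers, 16-day stationary horizons, 50-seed
recovery medians) were chosen as the smallest designs at which each
qualitative contrast is decisively resolved.

## Known limitations

Resource competition only: no cross-feeding, no oxygen or pH dynamics, no
toxins or bacteriocins, no spatial structure, no stochastic demography.
Where the underlying biology offers two explanations (crossing Monod
curves vs. facilitative cross-feeding for the coexisting pair), the
simulator implements only the first; the Lotka-Volterra module quantifies
the second phenomenologically from carrying capacities without committing
to a mechanism. The dilution factor and inoculum densities of the
emulated protocols are not public; they are configuration parameters with
declared defaults. The test suite asserts directions of effect —
winners, flips, orderings — rather than absolute trajectories, precisely
because the latter depend on those unpublished constants.
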