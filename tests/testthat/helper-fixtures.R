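# Shared small fixtures built in code.

fixture_pair <- function() {
  list(a = monod_params(1.0, 1.0), b = monod_params(0.7, 0.2))
}

# A deliberately sharp gleaner/exploiter pair for constructed-regime tests
# (stronger low-concentration divergence than the calibrated defaults).
sharp_pair <- function(death_rate = 0.01) {
  list(
    gleaner = population("gleaner",
                         monod = list(peptone = monod_params(0.75, 0.05)),
                         yields = c(peptone = 0.5), init_density = 0.01,
                         death_rate = death_rate),
    exploiter = population("exploiter",
                           monod = list(peptone = monod_params(1.1, 2.0)),
                           yields = c(peptone = 0.5), init_density = 0.01,
                           death_rate = death_rate))
}

peptone_16 <- function(strength = 1) medium(c(peptone = 16), strength_fraction = strength)
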