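# Shared fixtures and independent oracles for the test suite.

# linear O2 profile 280 -> 0 over 0 -> 8 mm at the given step
linear_o2 <- function(step = 0.25, top = 280, zero_at = 8, bottom = 18) {
  d <- seq(0, bottom, by = step)
  depth_profile(d, pmax(top * (1 - d / zero_at), 0), "O2")
}

simple_core <- function(profiles, porosity = 0.34, dic = 5500) {
  sediment_core(profiles, porosity = porosity, temperature = 20, dic = dic)
}

# Independent carbonate-speciation oracle: bisection on the carbon mass
# balance for CO2* (no closed-form fractions), then the equilibria.
oracle_speciation <- function(pH, dic, carb = carbonate_constants()) {
  H <- 10^(-pH)
  if (dic == 0) {
    return(list(co2_star = 0, hco3 = 0, co3 = 0,
                oh = carb$Kw / H * 1e6, h = H * 1e6))
  }
  f <- function(c0) c0 + carb$K1 * c0 / H + carb$K1 * carb$K2 * c0 / H^2 - dic
  c0 <- uniroot(f, c(0, dic), tol = 1e-14 * dic)$root
  hco3 <- carb$K1 * c0 / H
  list(co2_star = c0, hco3 = hco3, co3 = carb$K2 * hco3 / H,
       oh = carb$Kw / H * 1e6, h = H * 1e6)
}

# Brute-force terminal-fragment scanner: character-by-character substring
# comparison from a fixed anchor.
oracle_trf <- function(seq, site = "CCGG", cut_offset = 1) {
  n <- nchar(seq); m <- nchar(site)
  for (i in 1:(n - m + 1)) {
    if (substr(seq, i, i + m - 1) == site) return((i - 1) + cut_offset)
  }
  NA_integer_   # undigested
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

fixture_fasta <- function() {
  system.file("extdata", "synthetic_cable_16s.fasta",
              package = "geobattery", mustWork = TRUE)
}

BA27F <- "AGAGTTTGATCMTGGCTCAG"
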