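# Shared fixtures built in code.

# Printed mutarotation time course of heptose imine 38 in pyridine
# (final point at 7 d by the package's ingestion convention).
imine38_series <- function() {
  mutarotation_series("38",
                      time = c(0, 1, 8, 24, 72, 120, 168),
                      percent_beta = c(85.9, 85.9, 86.0, 85.3, 84.5,
                                       87.9, 86.7),
                      solvent = "pyridine-d5")
}

reference_equilibrium <- function() {
  anomer_equilibrium("121", percent_beta = 47.1, percent_alpha = 52.9,
                     solvent = "DMSO-d6")
}

a_oh <- function() a_value("OH", 1.25)

extdata <- function(file) {
  system.file("extdata", file, package = "anomeric", mustWork = TRUE)
}
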