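# Equilibrium thermodynamics: K_an, free energies, A-values, E_an,
# reverse-anomeric-effect magnitude and Boltzmann beta fractions.

test_that("K_an is the beta/alpha population quotient", {
  expect_equal(k_an(anomer_equilibrium("x", 50, 50)), 1.0)
  expect_equal(k_an(anomer_equilibrium("38", 86.7, 13.3)), 86.7 / 13.3)
  expect_equal(k_an(reference_equilibrium()), 47.1 / 52.9)
})

test_that("equilibrium populations are validated", {
  expect_error(anomer_equilibrium("x", 0, 100), "invalid population")
  expect_error(anomer_equilibrium("x", 105, -5), "invalid population")
  expect_error(anomer_equilibrium("x", 60, 50), "invalid population")
  expect_error(anomer_equilibrium("x", 50, 50, temperature = -1),
               "temperature")
  # single-population form auto-fills the complement
  expect_equal(anomer_equilibrium("x", 86.7)$percent_alpha, 13.3)
})

test_that("anomerization free energy follows -RT ln K_an in both RT modes", {
  expect_equal(delta_g_anomeric(anomer_equilibrium("x", 50, 50)), 0)
  # frozen: -0.6 * log(86.7 / 13.3)
  expect_equal(delta_g_anomeric(anomer_equilibrium("38", 86.7, 13.3)),
               -1.1248139, tolerance = 1e-6)
  # frozen: -0.6 * log(47.1 / 52.9)
  expect_equal(delta_g_anomeric(reference_equilibrium()),
               0.06967820, tolerance = 1e-6)
  # exact mode at an off-298 temperature uses R * T
  eq <- anomer_equilibrium("x", 80, 20, temperature = 310)
  expect_equal(delta_g_anomeric(eq, thermo_constants("exact")),
               -1.987e-3 * 310 * log(4))
})

test_that("hydroxyl A-value derives from the 89:11 cyclohexanol equilibrium", {
  a <- a_value_from_population(89)
  expect_equal(round(a$value, 2), 1.25)
  expect_identical(a$ring_system, "cyclohexane")
  expect_equal(a_value_from_population(50)$value, 0)
  # frozen: 1.987e-3 * 298 * log(3)
  expect_equal(a_value_from_population(75, constants = thermo_constants("exact"))$value,
               0.6505169, tolerance = 1e-6)
  expect_error(a_value_from_population(100), "strictly in")
  expect_error(a_value_from_population(0), "strictly in")
})

test_that("cyclohexane A-values extrapolate linearly to tetrahydropyran", {
  expect_equal(round(a_value_cyclohexane_to_thp(a_oh())$value, 2), 1.93)
  expect_equal(a_value_cyclohexane_to_thp(a_value("X", 0))$value, 0.02)
  expect_equal(a_value_cyclohexane_to_thp(a_value("X", 2))$value, 3.08)
  thp <- a_value_cyclohexane_to_thp(a_oh())
  expect_error(a_value_cyclohexane_to_thp(thp), "double conversion")
})

test_that("anomeric stabilization reproduces the reference and derived values", {
  expect_equal(round(anomeric_stabilization(reference_equilibrium(),
                                            a_oh())$e_an, 2), 1.32)
  expect_equal(anomeric_stabilization(anomer_equilibrium("x", 50, 50),
                                      a_oh())$e_an, 1.25)
  # frozen: -0.6 * log(86.7 / 13.3) + 1.25
  expect_equal(anomeric_stabilization(anomer_equilibrium("38", 86.7, 13.3),
                                      a_oh())$e_an,
               0.1251861, tolerance = 1e-6)
})

test_that("RAE magnitude is the difference of stabilizations", {
  expect_equal(rae_magnitude(1.32, 1.32)$dg_rae, 0)
  expect_equal(rae_magnitude(1.32, 0.125)$dg_rae, 1.195)
  expect_equal(rae_magnitude(1.32, -0.6)$dg_rae, 1.92)
  st <- anomeric_stabilization(reference_equilibrium(), a_oh())
  expect_equal(rae_magnitude(st, st)$dg_rae, 0)
})

test_that("Boltzmann beta fraction is 50% at dG = 0 and matches the logistic", {
  ex <- thermo_constants("exact")
  expect_equal(beta_fraction_from_dg(0), 50)
  expect_equal(beta_fraction_from_dg(-1, constants = ex),
               84.40702, tolerance = 1e-5)
  expect_equal(beta_fraction_from_dg(-0.315, constants = ex),
               62.99451, tolerance = 1e-5)
})

test_that("dG <-> beta fraction round-trips to 1e-9 over [-5, 5] kcal/mol", {
  for (constants in list(thermo_constants(), thermo_constants("exact"))) {
    dg <- seq(-5, 5, by = 0.25)
    back <- dg_from_beta_fraction(
      beta_fraction_from_dg(dg, constants = constants),
      constants = constants)
    expect_true(all(abs(back - dg) < 1e-9))
  }
  expect_error(dg_from_beta_fraction(0), "strictly in")
  expect_error(dg_from_beta_fraction(100), "strictly in")
})

test_that("beta fraction decreases in dG; E_an decreases in percent_beta", {
  bf <- beta_fraction_from_dg(seq(-4, 4, by = 0.5))
  expect_true(all(diff(bf) < 0))
  e_an <- vapply(seq(5, 95, by = 5), function(b)
    anomeric_stabilization(anomer_equilibrium("x", b), a_oh())$e_an,
    numeric(1))
  expect_true(all(diff(e_an) < 0))
})

test_that("THP-referenced stabilization exceeds the cyclohexane one by 0.68", {
  a_thp <- a_value("OH", 1.93, "tetrahydropyran")
  for (b in c(10, 25, 47.1, 50, 86.7, 95)) {
    eq <- anomer_equilibrium("x", b)
    expect_equal(anomeric_stabilization(eq, a_thp)$e_an -
                   anomeric_stabilization(eq, a_oh())$e_an, 0.68)
  }
})

test_that("one-step and decomposed E_an agree to 1e-12 on random equilibria", {
  set.seed(11)
  beta <- runif(1000, 0.5, 99.5)
  for (mode in c("paper_rounded", "exact")) {
    constants <- thermo_constants(mode)
    rt <- if (mode == "paper_rounded") 0.6 else 1.987e-3 * 298
    one_step <- -rt * log(beta / (100 - beta)) + 1.25
    dec <- vapply(beta, function(b)
      anomeric_stabilization(anomer_equilibrium("x", b, 100 - b),
                             a_oh(), constants)$e_an, numeric(1))
    expect_true(all(abs(one_step - dec) < 1e-12))
  }
})

test_that("rounded and exact RT modes differ below 0.02 kcal/mol in [10, 90]%", {
  for (b in seq(10, 90, by = 2)) {
    eq <- anomer_equilibrium("x", b)
    d <- abs(delta_g_anomeric(eq) -
               delta_g_anomeric(eq, thermo_constants("exact")))
    expect_lt(d, 0.02)
  }
})
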