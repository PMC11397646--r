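# Equilibrium thermodynamics of the anomeric effect: populations <-> K_an
# <-> standard free energies, conformational A-values, anomeric
# stabilization E_an and the reverse-anomeric-effect magnitude.

#' Gas constant in kcal/(mol K)
#'
#' @keywords internal
R_KCAL <- 1.987e-3

#' Thermodynamic constants and RT-handling mode
#'
#' The literature on anomeric equilibria commonly rounds the RT factor at
#' 298 K to 0.6 kcal/mol when converting an anomerization constant into a
#' free energy, while A-value derivations use the coefficient
#' 0.002 x T.  `paper_rounded` reproduces those printed coefficients
#' bit-for-bit; `exact` uses R = 1.987e-3 kcal/(mol K) throughout.
#'
#' @param rt_mode Either `"paper_rounded"` (rounded literature
#'   coefficients: RT = 0.6 at 298 K for free energies, 0.002 x T for
#'   A-values) or `"exact"` (RT = 1.987e-3 x T everywhere).
#' @param gas_constant Gas constant in kcal/(mol K); only used in
#'   `exact` mode.
#' @return An object of class `thermo_constants`.
#' @export
#' @examples
#' thermo_constants("exact")
thermo_constants <- function(rt_mode = c("paper_rounded", "exact"),
                             gas_constant = R_KCAL) {
  rt_mode <- match.arg(rt_mode)
  stopifnot(is.numeric(gas_constant), length(gas_constant) == 1L,
            is.finite(gas_constant), gas_constant > 0)
  structure(list(rt_mode = rt_mode, gas_constant = gas_constant),
            class = "thermo_constants")
}

# RT used for K_an <-> free-energy conversion, in kcal/mol.
rt_for_dg <- function(constants, temperature) {
  if (constants$rt_mode == "paper_rounded" &&
      isTRUE(all.equal(temperature, 298, tolerance = 1e-8))) {
    0.6
  } else {
    constants$gas_constant * temperature
  }
}

# RT used in A-value derivations (the 0.002 x T convention), in kcal/mol.
rt_for_avalue <- function(constants, temperature) {
  if (constants$rt_mode == "paper_rounded") {
    0.002 * temperature
  } else {
    constants$gas_constant * temperature
  }
}

#' Observed anomer equilibrium for one compound in one solvent
#'
#' Holds the alpha/beta anomer populations of a freely mutarotating
#' reducing sugar (or sugar imine) at equilibrium.  When only
#' `percent_beta` is given, `percent_alpha` is filled in as its
#' complement.
#'
#' @param compound_id Character label for the compound.
#' @param percent_beta Beta-anomer population, strictly inside (0, 100).
#' @param percent_alpha Alpha-anomer population; defaults to
#'   `100 - percent_beta`.  The two must sum to 100 within 0.2 points
#'   (slack for printed rounding).
#' @param solvent Character label, e.g. `"DMSO-d6"` or `"pyridine-d5"`.
#' @param temperature Absolute temperature in kelvin (default 298).
#' @return An object of class `anomer_equilibrium`.
#' @export
#' @examples
#' anomer_equilibrium("ref-THP-ol", percent_beta = 47.1,
#'                    percent_alpha = 52.9, solvent = "DMSO-d6")
anomer_equilibrium <- function(compound_id, percent_beta,
                               percent_alpha = 100 - percent_beta,
                               solvent = "unspecified",
                               temperature = 298) {
  stopifnot(is.character(compound_id), length(compound_id) == 1L,
            is.numeric(percent_beta), length(percent_beta) == 1L,
            is.numeric(percent_alpha), length(percent_alpha) == 1L,
            is.numeric(temperature), length(temperature) == 1L)
  if (!is.finite(percent_beta) || percent_beta <= 0 || percent_beta >= 100)
    stop("invalid population: percent_beta must lie strictly in (0, 100)")
  if (!is.finite(percent_alpha) || percent_alpha <= 0 || percent_alpha >= 100)
    stop("invalid population: percent_alpha must lie strictly in (0, 100)")
  if (abs(percent_alpha + percent_beta - 100) > 0.2)
    stop("invalid population: percent_alpha + percent_beta must be 100 (+/- 0.2)")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive (kelvin)")
  structure(list(compound_id = compound_id,
                 solvent = solvent,
                 temperature = temperature,
                 percent_beta = percent_beta,
                 percent_alpha = percent_alpha),
            class = "anomer_equilibrium")
}

#' @export
print.anomer_equilibrium <- function(x, ...) {
  cat(sprintf("<anomer_equilibrium> %s in %s at %g K: beta %.1f%% / alpha %.1f%%\n",
              x$compound_id, x$solvent, x$temperature,
              x$percent_beta, x$percent_alpha))
  invisible(x)
}

#' Conformational A-value of a substituent
#'
#' The free-energy penalty (kcal/mol) for placing the substituent axial,
#' on either a cyclohexane or a tetrahydropyran ring system.
#'
#' @param substituent Character label, e.g. `"OH"`.
#' @param value A-value in kcal/mol (positive favors equatorial).
#' @param ring_system `"cyclohexane"` or `"tetrahydropyran"`.
#' @return An object of class `a_value`.
#' @export
a_value <- function(substituent, value,
                    ring_system = c("cyclohexane", "tetrahydropyran")) {
  ring_system <- match.arg(ring_system)
  stopifnot(is.character(substituent), length(substituent) == 1L,
            is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(substituent = substituent, ring_system = ring_system,
                 value = value),
            class = "a_value")
}

#' @export
print.a_value <- function(x, ...) {
  cat(sprintf("<a_value> A_%s (%s) = %.2f kcal/mol\n",
              x$substituent, x$ring_system, x$value))
  invisible(x)
}

#' Anomerization equilibrium constant K_an = [beta]/[alpha]
#'
#' @param eq An [anomer_equilibrium()].
#' @return Dimensionless, strictly positive ratio.
#' @export
#' @examples
#' k_an(anomer_equilibrium("x", 86.7, 13.3))
k_an <- function(eq) {
  stopifnot(inherits(eq, "anomer_equilibrium"))
  eq$percent_beta / eq$percent_alpha
}

#' Standard anomerization free energy from populations
#'
#' Computes the free energy of the beta anomer relative to the alpha
#' anomer, -RT ln K_an, with RT resolved by the constants' `rt_mode`.
#'
#' @param eq An [anomer_equilibrium()].
#' @param constants A [thermo_constants()] object.
#' @return Free energy in kcal/mol (negative when beta predominates).
#' @export
#' @examples
#' delta_g_anomeric(anomer_equilibrium("x", 86.7, 13.3))
delta_g_anomeric <- function(eq, constants = thermo_constants()) {
  stopifnot(inherits(eq, "anomer_equilibrium"),
            inherits(constants, "thermo_constants"))
  -rt_for_dg(constants, eq$temperature) * log(k_an(eq))
}

#' A-value from an equatorial/axial equilibrium population
#'
#' A = RT ln([equatorial]/[axial]), positive when the equatorial form
#' predominates.  In `paper_rounded` mode the RT coefficient is
#' 0.002 x T, the convention used when the hydroxyl A-value of 1.25
#' kcal/mol is derived from an 89:11 cyclohexanol equilibrium.
#'
#' @param percent_equatorial Equatorial population in (0, 100).
#' @param temperature Kelvin (default 298).
#' @param constants A [thermo_constants()] object.
#' @param substituent Label stored on the result (default `"OH"`).
#' @return An [a_value()] on the cyclohexane ring system.
#' @export
#' @examples
#' a_value_from_population(89)  # 1.25 kcal/mol
a_value_from_population <- function(percent_equatorial, temperature = 298,
                                    constants = thermo_constants(),
                                    substituent = "OH") {
  stopifnot(is.numeric(percent_equatorial), length(percent_equatorial) == 1L)
  if (!is.finite(percent_equatorial) ||
      percent_equatorial <= 0 || percent_equatorial >= 100)
    stop("percent_equatorial must lie strictly in (0, 100): A diverges at 0/100")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive (kelvin)")
  rt <- rt_for_avalue(constants, temperature)
  val <- rt * log(percent_equatorial / (100 - percent_equatorial))
  a_value(substituent, val, "cyclohexane")
}

#' Extrapolate a cyclohexane A-value to tetrahydropyran
#'
#' Applies the linear map A_THP = 1.53 A_cyclohexane + 0.02 relating
#' substituent A-values on the two ring systems (the shorter C-O bonds of
#' tetrahydropyran amplify 1,3-diaxial strain).
#'
#' @param a An [a_value()] with `ring_system = "cyclohexane"`.
#' @return An [a_value()] on tetrahydropyran.
#' @export
#' @examples
#' a_value_cyclohexane_to_thp(a_value("OH", 1.25))  # 1.93
a_value_cyclohexane_to_thp <- function(a) {
  stopifnot(inherits(a, "a_value"))
  if (a$ring_system != "cyclohexane")
    stop("A-value is already on tetrahydropyran; refusing double conversion")
  a_value(a$substituent, 1.53 * a$value + 0.02, "tetrahydropyran")
}

#' Anomeric stabilization energy E_an
#'
#' Decomposes the observed anomerization free energy into steric and
#' stereoelectronic parts: E_an = dG_an - dG_steric = -RT ln K_an + A,
#' where A is the substituent's A-value on the chosen ring system.  A
#' large positive E_an signals a strong axial (alpha) stereoelectronic
#' preference beyond what sterics predict.
#'
#' @param eq An [anomer_equilibrium()].
#' @param a An [a_value()]; its ring system selects the reported mode.
#' @param constants A [thermo_constants()] object.
#' @return An object of class `anomeric_stabilization` with fields
#'   `compound_id`, `e_an` (kcal/mol), `dg_an`, `a_value_used`, `mode`.
#' @export
#' @examples
#' eq <- anomer_equilibrium("ref", 47.1, 52.9, "DMSO-d6")
#' anomeric_stabilization(eq, a_value("OH", 1.25))  # E_an = 1.32
anomeric_stabilization <- function(eq, a, constants = thermo_constants()) {
  stopifnot(inherits(eq, "anomer_equilibrium"), inherits(a, "a_value"))
  dg_an <- delta_g_anomeric(eq, constants)
  structure(list(compound_id = eq$compound_id,
                 e_an = dg_an + a$value,
                 dg_an = dg_an,
                 a_value_used = a,
                 mode = if (a$ring_system == "cyclohexane")
                   "eq_cyclohexane" else "eq_thp"),
            class = "anomeric_stabilization")
}

#' @export
print.anomeric_stabilization <- function(x, ...) {
  cat(sprintf("<anomeric_stabilization> %s: E_an = %.2f kcal/mol (A = %.2f, %s)\n",
              x$compound_id, x$e_an, x$a_value_used$value, x$mode))
  invisible(x)
}

#' Reverse-anomeric-effect magnitude
#'
#' dG_rae = E_an(reference) - E_an(imine).  A positive value means the
#' imine's beta (equatorial) anomer is favored beyond the steric
#' prediction, i.e. the reverse anomeric effect is operative.
#'
#' @param e_an_reference Anomeric stabilization of the reference
#'   2-hydroxytetrahydropyranol equilibrium, kcal/mol (or an
#'   `anomeric_stabilization` object).
#' @param e_an_imine Anomeric stabilization of the imine, kcal/mol (or an
#'   `anomeric_stabilization` object).
#' @param compound_id Label stored on the result.
#' @return An object of class `rae_result` with field `dg_rae`.
#' @export
#' @examples
#' rae_magnitude(1.32, 0.125)
rae_magnitude <- function(e_an_reference, e_an_imine,
                          compound_id = "unspecified") {
  ref <- if (inherits(e_an_reference, "anomeric_stabilization"))
    e_an_reference$e_an else e_an_reference
  imi <- if (inherits(e_an_imine, "anomeric_stabilization")) {
    if (identical(compound_id, "unspecified"))
      compound_id <- e_an_imine$compound_id
    e_an_imine$e_an
  } else e_an_imine
  stopifnot(is.numeric(ref), is.finite(ref), is.numeric(imi), is.finite(imi))
  structure(list(compound_id = compound_id,
                 e_an_reference = ref,
                 e_an_imine = imi,
                 dg_rae = ref - imi),
            class = "rae_result")
}

#' @export
print.rae_result <- function(x, ...) {
  cat(sprintf("<rae_result> %s: dG_rae = %.2f kcal/mol (ref %.2f - imine %.2f)\n",
              x$compound_id, x$dg_rae, x$e_an_reference, x$e_an_imine))
  invisible(x)
}

#' Boltzmann beta-anomer fraction from a relative free energy
#'
#' Two-state Boltzmann population: with dG = G(beta) - G(alpha),
#' beta% = 100 exp(-dG/RT) / (1 + exp(-dG/RT)).  Negative dG therefore
#' yields beta-majorities.
#'
#' @param dg Free energy of beta relative to alpha, kcal/mol.
#' @param temperature Kelvin (default 298).
#' @param constants A [thermo_constants()] object; RT resolution follows
#'   its `rt_mode` as in [delta_g_anomeric()].
#' @return Beta percentage in (0, 100); 50 at `dg = 0`.
#' @export
#' @examples
#' beta_fraction_from_dg(-1, constants = thermo_constants("exact"))
beta_fraction_from_dg <- function(dg, temperature = 298,
                                  constants = thermo_constants()) {
  stopifnot(is.numeric(dg), all(is.finite(dg)))
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive (kelvin)")
  rt <- rt_for_dg(constants, temperature)
  100 * stats::plogis(-dg / rt)
}

#' Relative free energy from a beta-anomer percentage
#'
#' Exact inverse of [beta_fraction_from_dg()]:
#' dG = -RT ln(beta / (100 - beta)).
#'
#' @param percent_beta Beta percentage strictly in (0, 100).
#' @inheritParams beta_fraction_from_dg
#' @return Free energy in kcal/mol.
#' @export
dg_from_beta_fraction <- function(percent_beta, temperature = 298,
                                  constants = thermo_constants()) {
  stopifnot(is.numeric(percent_beta))
  if (any(!is.finite(percent_beta) | percent_beta <= 0 | percent_beta >= 100))
    stop("percent_beta must lie strictly in (0, 100)")
  rt <- rt_for_dg(constants, temperature)
  -rt * log(percent_beta / (100 - percent_beta))
}
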