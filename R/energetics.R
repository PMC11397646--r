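# Structure-derived energetics consumed as tables: empirical H-bond
# strength from donor-acceptor distance, NBO second-order stabilization
# energies, and periodic torsional-scan profile analysis.

# E_HB prefactor (kcal/mol) and exponential slope (1/Angstrom) of the
# empirical donor-acceptor distance correlation.
HB_PREFACTOR <- 5.554e5
HB_SLOPE <- 4.12

#' Hartree to kcal/mol conversion factor
#' @keywords internal
HARTREE_KCAL <- 627.5095

#' Hydrogen-bond donor-acceptor geometry
#'
#' @param donor_label,acceptor_label Atom labels (e.g. `"O35"`, `"N"`).
#' @param d_da Donor-acceptor distance in Angstrom; sane O...N contacts
#'   fall in (1.5, 5.0).
#' @param strict Error (rather than warn) on distances outside the
#'   sanity window.
#' @return Object of class `hbond_geometry`.
#' @export
hbond_geometry <- function(donor_label, acceptor_label, d_da,
                           strict = FALSE) {
  stopifnot(is.numeric(d_da), length(d_da) == 1L, is.finite(d_da))
  if (d_da <= 1.5 || d_da >= 5.0) {
    msg <- sprintf("distance %.3f A is outside the 1.5-5.0 A sanity window",
                   d_da)
    if (strict) stop(msg) else warning(msg)
  }
  structure(list(donor_label = donor_label,
                 acceptor_label = acceptor_label, d_da = d_da),
            class = "hbond_geometry")
}

#' Empirical hydrogen-bond strength from donor-acceptor distance
#'
#' E_HB = 5.554e5 exp(-4.12 d) kcal/mol, the exponential correlation
#' between hydrogen-bond energy and the donor-acceptor separation d (in
#' Angstrom).  The value is returned as a positive stabilization
#' magnitude; bond formation is stabilizing, recorded in the
#' `"stabilizing"` sign-convention attribute.
#'
#' @param geom An [hbond_geometry()] (or bare numeric distance in A).
#' @return Stabilization magnitude in kcal/mol, with attribute
#'   `sign_convention = "stabilizing"`.
#' @export
#' @examples
#' hbond_energy(hbond_geometry("O", "N", 2.756))  # ~6.5 kcal/mol
hbond_energy <- function(geom) {
  d <- if (inherits(geom, "hbond_geometry")) geom$d_da else geom
  stopifnot(is.numeric(d), all(is.finite(d)), all(d > 0))
  structure(HB_PREFACTOR * exp(-HB_SLOPE * d),
            sign_convention = "stabilizing")
}

#' Donor-acceptor distance implied by a hydrogen-bond energy
#'
#' Inverse of [hbond_energy()]: d = ln(5.554e5 / E) / 4.12.
#'
#' @param energy Stabilization magnitude in kcal/mol, strictly positive.
#' @return Distance in Angstrom.
#' @export
#' @examples
#' hbond_distance(6.5)
hbond_distance <- function(energy) {
  stopifnot(is.numeric(energy))
  if (any(!is.finite(energy) | energy <= 0))
    stop("energy must be strictly positive")
  log(HB_PREFACTOR / energy) / HB_SLOPE
}

#' NBO donor-acceptor interaction parameters
#'
#' Inputs to the second-order perturbative stabilization estimate, all in
#' atomic units: donor occupancy q (electrons, in (0, 2]), off-diagonal
#' Fock element F_ij, and the donor/acceptor orbital energies.
#'
#' @param donor_orbital,acceptor_orbital Orbital labels, e.g.
#'   `"n_O35"`, `"sigma*_C1-O10"`.
#' @param occupancy_q Donor occupancy in electrons, (0, 2].
#' @param fock_f_ij Fock matrix element, hartree.
#' @param eps_donor,eps_acceptor Orbital energies, hartree; must differ.
#' @return Object of class `nbo_interaction`.
#' @export
nbo_interaction <- function(donor_orbital, acceptor_orbital,
                            occupancy_q, fock_f_ij,
                            eps_donor, eps_acceptor) {
  stopifnot(is.numeric(occupancy_q), occupancy_q >= 0, occupancy_q <= 2,
            is.numeric(fock_f_ij), is.finite(fock_f_ij),
            is.numeric(eps_donor), is.numeric(eps_acceptor))
  if (eps_donor == eps_acceptor)
    stop("degenerate orbital energies: eps_donor must differ from eps_acceptor")
  structure(list(donor_orbital = donor_orbital,
                 acceptor_orbital = acceptor_orbital,
                 occupancy_q = occupancy_q, fock_f_ij = fock_f_ij,
                 eps_donor = eps_donor, eps_acceptor = eps_acceptor),
            class = "nbo_interaction")
}

#' Second-order NBO stabilization energy
#'
#' E2 = -q F_ij^2 / (eps_donor - eps_acceptor), evaluated in hartree and
#' converted to kcal/mol (x 627.5095).  For a filled donor below an empty
#' acceptor (eps_donor < eps_acceptor) the result is positive, i.e.
#' stabilizing delocalization.
#'
#' @param x An [nbo_interaction()].
#' @return Stabilization energy in kcal/mol.
#' @export
#' @examples
#' nbo_e2(nbo_interaction("n_O", "sigma*", 2, 0.05, -0.5, 0))  # 6.275
nbo_e2 <- function(x) {
  stopifnot(inherits(x, "nbo_interaction"))
  e2_hartree <- -x$occupancy_q * x$fock_f_ij^2 / (x$eps_donor - x$eps_acceptor)
  e2_hartree * HARTREE_KCAL
}

#' Periodic dihedral-scan energy profile
#'
#' A relative-energy profile on a uniform angular grid covering one full
#' rotation, e.g. a 15-degree scan of the N=C-C1-C2 aryl torsion of a
#' polyaromatic imine.  Angles are wrapped into [0, 360) and energies
#' re-zeroed to their minimum.
#'
#' @param angles Dihedral angles in degrees, uniform grid over one
#'   period (no duplicated 0/360 endpoint).
#' @param energies Relative energies in kcal/mol, one per angle.
#' @param period_hint Optional expected repeat period in degrees
#'   (metadata only).
#' @return Object of class `torsion_profile`.
#' @export
#' @examples
#' th <- seq(0, 345, by = 15)
#' torsion_profile(th, 1 - cospi(2 * th / 180))
torsion_profile <- function(angles, energies, period_hint = NULL) {
  stopifnot(is.numeric(angles), is.numeric(energies),
            length(angles) == length(energies), length(angles) >= 4L,
            all(is.finite(angles)), all(is.finite(energies)))
  ord <- order(angles %% 360)
  angles <- (angles %% 360)[ord]
  energies <- energies[ord]
  if (anyDuplicated(angles))
    stop("duplicated angles after wrapping into [0, 360)")
  steps <- diff(angles)
  step <- 360 / length(angles)
  if (any(abs(steps - step) > 1e-6))
    stop("angles must form a uniform grid covering [0, 360)")
  structure(list(angles = angles, energies = energies - min(energies),
                 step = step, period_hint = period_hint),
            class = "torsion_profile")
}

# Parabolic vertex through (x-1, x, x+1) grid triplet; returns offset in
# grid units (in [-0.5, 0.5]) and the refined energy.
quad_vertex <- function(e_prev, e0, e_next) {
  denom <- e_prev - 2 * e0 + e_next
  if (abs(denom) < .Machine$double.eps * 10)
    return(list(offset = 0, energy = e0))
  offset <- 0.5 * (e_prev - e_next) / denom
  energy <- e0 - 0.25 * (e_prev - e_next) * offset
  list(offset = offset, energy = energy)
}

#' Locate stationary points of a periodic torsion profile
#'
#' Finds grid minima and maxima with periodic wrap-around, refining each
#' by the vertex of the parabola through the point and its two
#' neighbors — scans sampled every 15 degrees routinely have true minima
#' between grid nodes (e.g. near 40-50 degrees).
#'
#' @param profile A [torsion_profile()].
#' @return Data frame with columns `angle` (degrees, refined), `energy`
#'   (kcal/mol, refined) and `type` (`"minimum"`/`"maximum"`), ordered by
#'   angle.  A flat profile returns zero rows with attribute
#'   `flat = TRUE`.
#' @export
#' @examples
#' th <- seq(0, 345, by = 15)
#' scan_extrema(torsion_profile(th, 1 - cospi(2 * th / 180)))
scan_extrema <- function(profile) {
  stopifnot(inherits(profile, "torsion_profile"))
  e <- profile$energies
  n <- length(e)
  if (diff(range(e)) < .Machine$double.eps * 100) {
    out <- data.frame(angle = numeric(), energy = numeric(),
                      type = character())
    attr(out, "flat") <- TRUE
    return(out)
  }
  prev <- e[c(n, seq_len(n - 1L))]
  nxt <- e[c(seq.int(2L, n), 1L)]
  rows <- list()
  for (i in seq_len(n)) {
    type <- if (e[i] < prev[i] && e[i] < nxt[i]) "minimum"
            else if (e[i] > prev[i] && e[i] > nxt[i]) "maximum"
            else next
    v <- quad_vertex(prev[i], e[i], nxt[i])
    rows[[length(rows) + 1L]] <- data.frame(
      angle = (profile$angles[i] + v$offset * profile$step) %% 360,
      energy = v$energy, type = type, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$angle), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flat") <- FALSE
  out
}

#' Periodicity score of a torsion profile
#'
#' Measures how exactly the profile repeats after a shift of `period`
#' degrees: 1 - RMS(E(theta) - E(theta + period)) / range(E), clamped to
#' [0, 1].  A score of 1 means exact repetition (always true for a
#' 360-degree shift); profiles dominated by odd-multiplicity terms score
#' well below 1 for a 180-degree shift.
#'
#' @param profile A [torsion_profile()].
#' @param period Shift in degrees; must be a positive multiple of the
#'   grid step dividing 360.
#' @return Score in [0, 1].
#' @export
#' @examples
#' th <- seq(0, 345, by = 15)
#' periodicity_score(torsion_profile(th, 1 - cospi(2 * th / 180)), 180)
periodicity_score <- function(profile, period) {
  stopifnot(inherits(profile, "torsion_profile"),
            is.numeric(period), length(period) == 1L, period > 0)
  if (abs(360 %% period) > 1e-9 && abs(360 %% period - period) > 1e-9)
    stop("period must divide 360 degrees")
  shift <- period / profile$step
  if (abs(shift - round(shift)) > 1e-9)
    stop("period must be a multiple of the grid step (",
         profile$step, " degrees)")
  shift <- as.integer(round(shift)) %% length(profile$energies)
  e <- profile$energies
  if (diff(range(e)) < .Machine$double.eps * 100) return(1)
  e_shift <- e[((seq_along(e) - 1L + shift) %% length(e)) + 1L]
  rms <- sqrt(mean((e - e_shift)^2))
  max(0, min(1, 1 - rms / diff(range(e))))
}
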