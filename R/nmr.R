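# Rule-based anomeric-configuration and imine-geometry assignment from
# NMR observables of 2-iminoaldoses.

#' NMR observables for one species
#'
#' Collects the spectroscopic diagnostics used for anomer assignment of
#' glucosamine-type pyranoses and their Schiff bases.  All fields except
#' `species_id` are optional; `NA` means "not measured".
#'
#' @param species_id Character label.
#' @param j_h1_h2 Three-bond H1-H2 coupling in Hz (small for axial H1,
#'   i.e. alpha; ~7-9 Hz for the trans-diaxial beta arrangement).
#' @param one_bond_j_c1_h1 One-bond C1-H1 coupling in Hz (~170 Hz alpha /
#'   ~160 Hz beta for free sugars; ~177 / ~166 Hz once per-O-acetylated).
#' @param delta_c1 Anomeric carbon shift in ppm (carried for reporting).
#' @param j_ch_eq_ch Vinylic CH=CH coupling in Hz (~16 Hz for E double
#'   bonds of cinnamylidene-type imines).
#' @param j_ch_chn Coupling between the imine proton and the adjacent
#'   vinylic proton in Hz (~8.8 Hz for an antiperiplanar arrangement).
#' @param optical_rotation_d Specific rotation at the sodium D line, deg.
#' @param rotation_solvent Solvent of the rotation measurement; the
#'   rotation rule only fires in pyridine, where the thresholds hold.
#' @param acetylated Logical; selects the acetylated one-bond coupling
#'   reference values.
#' @param extra_h_shifts,extra_c_shifts Numeric vectors of additional
#'   proton / carbon shifts (ppm), scanned for oxazolidine markers.
#' @return An object of class `nmr_observables`.
#' @export
#' @examples
#' nmr_observables("108", j_h1_h2 = 3.3, one_bond_j_c1_h1 = 165.5)
nmr_observables <- function(species_id,
                            j_h1_h2 = NA_real_,
                            one_bond_j_c1_h1 = NA_real_,
                            delta_c1 = NA_real_,
                            j_ch_eq_ch = NA_real_,
                            j_ch_chn = NA_real_,
                            optical_rotation_d = NA_real_,
                            rotation_solvent = NA_character_,
                            acetylated = FALSE,
                            extra_h_shifts = NULL,
                            extra_c_shifts = NULL) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  couplings <- c(j_h1_h2 = j_h1_h2, one_bond_j_c1_h1 = one_bond_j_c1_h1,
                 j_ch_eq_ch = j_ch_eq_ch, j_ch_chn = j_ch_chn)
  bad <- !is.na(couplings) & couplings < 0
  if (any(bad))
    stop("coupling constants must be non-negative: ",
         paste(names(couplings)[bad], collapse = ", "))
  structure(list(species_id = species_id,
                 j_h1_h2 = j_h1_h2,
                 one_bond_j_c1_h1 = one_bond_j_c1_h1,
                 delta_c1 = delta_c1,
                 j_ch_eq_ch = j_ch_eq_ch,
                 j_ch_chn = j_ch_chn,
                 optical_rotation_d = optical_rotation_d,
                 rotation_solvent = rotation_solvent,
                 acetylated = isTRUE(acetylated),
                 extra_h_shifts = extra_h_shifts,
                 extra_c_shifts = extra_c_shifts),
            class = "nmr_observables")
}

#' Default decision windows of the anomer classifier
#'
#' The windows bracket the field's "approximately" reference values so
#' that every textbook example separates cleanly; all are adjustable.
#'
#' @param j12_alpha_max J(H1,H2) below which the vote is alpha (Hz).
#' @param j12_beta_min J(H1,H2) above which the vote is beta (Hz).
#' @param one_bond_refs Named list with alpha/beta one-bond C1-H1
#'   references for free and acetylated species (Hz).
#' @param one_bond_band Half-width of the confident band around each
#'   reference (Hz).
#' @param one_bond_abstain Distance beyond which the rule abstains (Hz).
#' @param rotation_alpha_min,rotation_beta_max Specific-rotation
#'   thresholds in pyridine (degrees).
#' @param j12_weight Weight of the J(H1,H2) vote (it is the dominant
#'   diagnostic and breaks conflicts with the one-bond rule).
#' @return A list of classifier settings.
#' @export
classifier_windows <- function(j12_alpha_max = 4.5,
                               j12_beta_min = 6.5,
                               one_bond_refs = list(
                                 free = c(alpha = 170, beta = 160),
                                 acetylated = c(alpha = 177, beta = 166)),
                               one_bond_band = 4,
                               one_bond_abstain = 10,
                               rotation_alpha_min = 100,
                               rotation_beta_max = 50,
                               j12_weight = 2) {
  one_bond_refs <- lapply(one_bond_refs, unlist)
  stopifnot(j12_alpha_max < j12_beta_min,
            one_bond_band <= one_bond_abstain)
  list(j12_alpha_max = j12_alpha_max, j12_beta_min = j12_beta_min,
       one_bond_refs = one_bond_refs, one_bond_band = one_bond_band,
       one_bond_abstain = one_bond_abstain,
       rotation_alpha_min = rotation_alpha_min,
       rotation_beta_max = rotation_beta_max,
       j12_weight = j12_weight)
}

vote_row <- function(rule, observed, vote, weight) {
  data.frame(rule = rule, observed = observed, vote = vote,
             weight = weight, stringsAsFactors = FALSE)
}

#' Classify the anomeric configuration from NMR observables
#'
#' Weighted vote over three diagnostics: the H1-H2 coupling (dominant),
#' the one-bond C1-H1 coupling against context-appropriate alpha/beta
#' references, and the specific rotation (in pyridine only).  A tie or a
#' full abstention yields `"ambiguous"`.
#'
#' @param obs An [nmr_observables()] object.
#' @param windows Decision windows from [classifier_windows()].
#' @return An object of class `anomer_call` with fields `species_id`,
#'   `call` (`"alpha"`, `"beta"` or `"ambiguous"`), `evidence`
#'   (data frame of rule votes) and `flags` (from [geometry_flags()]).
#' @export
#' @examples
#' classify_anomer(nmr_observables("48", j_h1_h2 = 8.4,
#'                                 one_bond_j_c1_h1 = 153.7))
classify_anomer <- function(obs, windows = classifier_windows()) {
  stopifnot(inherits(obs, "nmr_observables"))
  has_rot <- !is.na(obs$optical_rotation_d) &&
    !is.na(obs$rotation_solvent) &&
    tolower(obs$rotation_solvent) == "pyridine"
  if (is.na(obs$j_h1_h2) && is.na(obs$one_bond_j_c1_h1) && !has_rot)
    stop("insufficient evidence: no diagnostic observable present for ",
         obs$species_id)

  ev <- list()

  if (!is.na(obs$j_h1_h2)) {
    v <- if (obs$j_h1_h2 < windows$j12_alpha_max) "alpha"
         else if (obs$j_h1_h2 > windows$j12_beta_min) "beta"
         else "abstain"
    ev[[length(ev) + 1L]] <- vote_row("j_h1_h2", obs$j_h1_h2, v,
                                      windows$j12_weight)
  }

  if (!is.na(obs$one_bond_j_c1_h1)) {
    refs <- windows$one_bond_refs[[if (obs$acetylated) "acetylated" else "free"]]
    d_alpha <- abs(obs$one_bond_j_c1_h1 - refs[["alpha"]])
    d_beta <- abs(obs$one_bond_j_c1_h1 - refs[["beta"]])
    v <- if (d_alpha <= windows$one_bond_band) "alpha"
         else if (d_beta <= windows$one_bond_band) "beta"
         else if (min(d_alpha, d_beta) > windows$one_bond_abstain) "abstain"
         else if (d_alpha < d_beta) "alpha" else "beta"
    ev[[length(ev) + 1L]] <- vote_row("one_bond_j_c1_h1",
                                      obs$one_bond_j_c1_h1, v, 1)
  }

  if (has_rot) {
    v <- if (obs$optical_rotation_d > windows$rotation_alpha_min) "alpha"
         else if (obs$optical_rotation_d < windows$rotation_beta_max) "beta"
         else "abstain"
    ev[[length(ev) + 1L]] <- vote_row("optical_rotation_d",
                                      obs$optical_rotation_d, v, 1)
  }

  evidence <- do.call(rbind, ev)
  w_alpha <- sum(evidence$weight[evidence$vote == "alpha"])
  w_beta <- sum(evidence$weight[evidence$vote == "beta"])
  call <- if (w_alpha > w_beta) "alpha"
          else if (w_beta > w_alpha) "beta"
          else "ambiguous"

  structure(list(species_id = obs$species_id,
                 call = call,
                 evidence = evidence,
                 flags = geometry_flags(obs)),
            class = "anomer_call")
}

#' @export
print.anomer_call <- function(x, ...) {
  cat(sprintf("<anomer_call> %s -> %s\n", x$species_id, x$call))
  if (nrow(x$evidence))
    print(x$evidence, row.names = FALSE)
  if (length(x$flags))
    cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Geometry findings from NMR observables
#'
#' Emits structural flags: `E_double_bond` when the vinylic CH=CH
#' coupling falls in the trans window (14-18 Hz), `antiperiplanar_imine`
#' when the imine-vinyl coupling lies in 7.5-10 Hz, and an oxazolidine
#' assessment from the extra shift lists (`oxazolidine_suspected` when a
#' proton in 5-6 ppm coincides with a carbon in 90-97 ppm;
#' `oxazolidine_absent` when both lists were supplied and the marker
#' windows are clear — the check that rules out ring-closed side
#' products during mutarotation).
#'
#' @param obs An [nmr_observables()] object.
#' @return Character vector of findings (possibly empty).
#' @export
#' @examples
#' geometry_flags(nmr_observables("45", j_ch_eq_ch = 16.1))
geometry_flags <- function(obs) {
  stopifnot(inherits(obs, "nmr_observables"))
  flags <- character()
  if (!is.na(obs$j_ch_eq_ch) && obs$j_ch_eq_ch >= 14 && obs$j_ch_eq_ch <= 18)
    flags <- c(flags, "E_double_bond")
  if (!is.na(obs$j_ch_chn) && obs$j_ch_chn >= 7.5 && obs$j_ch_chn <= 10)
    flags <- c(flags, "antiperiplanar_imine")
  if (!is.null(obs$extra_h_shifts) && !is.null(obs$extra_c_shifts)) {
    h_hit <- any(obs$extra_h_shifts >= 5 & obs$extra_h_shifts <= 6)
    c_hit <- any(obs$extra_c_shifts >= 90 & obs$extra_c_shifts <= 97)
    flags <- c(flags,
               if (h_hit && c_hit) "oxazolidine_suspected"
               else "oxazolidine_absent")
  }
  flags
}
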