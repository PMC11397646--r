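# Seeded synthetic-data generators emulating the statistical structure of
# the study's observables: two-state anomer equilibria with known
# anomeric stabilization, first-order mutarotation time courses, bimodal
# NMR-observable distributions for alpha vs beta species, and periodic
# torsion profiles.  Distributional forms are fixture conventions, not
# experimental claims.

#' Configuration of the synthetic-data generators
#'
#' One seed fixes every downstream draw; each generator derives its own
#' substream deterministically so tables can be produced independently or
#' together with identical results.
#'
#' @param seed Integer seed for the random stream.
#' @param n_compounds Number of synthetic compounds per table.
#' @param e_an_range Interval (kcal/mol) from which true anomeric
#'   stabilizations are drawn uniformly.  The default \[-0.8, 1.4\] spans
#'   the region from strongly reverse-anomeric imines (large beta
#'   excess) up to the reference hydroxyl equilibrium.
#' @param a_value_kcal A-value used to invert stabilization into
#'   populations (default 1.25, the hydroxyl value on cyclohexane).
#' @param temperature Kelvin.
#' @param noise_sigma_points Gaussian noise (percentage points) added to
#'   mutarotation observations; 0.5 mimics integration scatter of
#'   quantitative NMR.
#' @param rate_range Interval (per hour) for true anomerization rate
#'   constants; spans slow DMSO-like to fast pyridine-like behavior.
#' @param nmr_alpha_params,nmr_beta_params Named lists of `c(mean, sd)`
#'   per observable (`j_h1_h2`, `one_bond_j`, `one_bond_j_ac`,
#'   `rotation`).  Defaults center on the field's diagnostic values:
#'   alpha J(H1,H2) ~ N(3.8, 0.4) Hz vs beta ~ N(8.0, 0.7) Hz; one-bond
#'   C1-H1 ~ N(170, 2) vs N(160, 2) Hz (177/166 acetylated); rotations
#'   ~ N(+120, 15) vs N(+35, 10) degrees in pyridine.
#' @param torsion_terms Data frame of cosine terms (columns `amplitude`
#'   kcal/mol, `multiplicity`, `phase` degrees); the default single term
#'   of multiplicity 2 phased at 45 degrees gives minima at 45/225
#'   degrees and exact 180-degree periodicity, the shape reported for
#'   N=C-C1-C2 aryl scans.
#' @param torsion_noise_kcal Gaussian noise on profile energies.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_compounds = 20L,
                              e_an_range = c(-0.8, 1.4),
                              a_value_kcal = 1.25,
                              temperature = 298,
                              noise_sigma_points = 0.5,
                              rate_range = c(0.05, 5),
                              nmr_alpha_params = list(
                                j_h1_h2 = c(3.8, 0.4),
                                one_bond_j = c(170, 2),
                                one_bond_j_ac = c(177, 2),
                                rotation = c(120, 15)),
                              nmr_beta_params = list(
                                j_h1_h2 = c(8.0, 0.7),
                                one_bond_j = c(160, 2),
                                one_bond_j_ac = c(166, 2),
                                rotation = c(35, 10)),
                              torsion_terms = data.frame(
                                amplitude = 2.0, multiplicity = 2,
                                phase = 45),
                              torsion_noise_kcal = 0) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_compounds >= 1L,
            length(e_an_range) == 2L, diff(e_an_range) > 0,
            length(rate_range) == 2L, diff(rate_range) > 0,
            noise_sigma_points >= 0, temperature > 0,
            is.data.frame(torsion_terms),
            all(c("amplitude", "multiplicity", "phase") %in%
                  names(torsion_terms)))
  structure(list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
                 e_an_range = e_an_range, a_value_kcal = a_value_kcal,
                 temperature = temperature,
                 noise_sigma_points = noise_sigma_points,
                 rate_range = rate_range,
                 nmr_alpha_params = nmr_alpha_params,
                 nmr_beta_params = nmr_beta_params,
                 torsion_terms = torsion_terms,
                 torsion_noise_kcal = torsion_noise_kcal),
            class = "simulation_config")
}

# Seed the session RNG for one generator substream, restoring on exit in
# the caller via withr-free on.exit pattern.
with_substream <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed + offset)
  force(expr)
}

#' Synthetic anomer-equilibrium table with known stabilization energies
#'
#' Draws a true anomeric stabilization E_an per compound, inverts the
#' decomposition E_an = -RT ln K_an + A to an anomerization constant and
#' populations, and returns both observables and ground truth.  Draws
#' implying populations outside (0.1, 99.9)% are resampled (and
#' counted).
#'
#' @param cfg A [simulation_config()].
#' @param constants A [thermo_constants()] object used for the
#'   inversion.
#' @return Data frame with columns `compound_id`, `solvent`,
#'   `temperature_K`, `percent_beta`, `percent_alpha`, `true_e_an`;
#'   attribute `resampled` counts rejected draws.
#' @export
#' @examples
#' head(gen_equilibrium_dataset(simulation_config(seed = 7)))
gen_equilibrium_dataset <- function(cfg, constants = thermo_constants()) {
  stopifnot(inherits(cfg, "simulation_config"))
  rt <- rt_for_dg(constants, cfg$temperature)
  with_substream(cfg, 101L, {
    n <- cfg$n_compounds
    e_an <- numeric(n)
    beta <- numeric(n)
    resampled <- 0L
    for (i in seq_len(n)) {
      repeat {
        cand <- stats::runif(1, cfg$e_an_range[1], cfg$e_an_range[2])
        dg <- cand - cfg$a_value_kcal
        b <- 100 * stats::plogis(-dg / rt)
        if (b > 0.1 && b < 99.9) { e_an[i] <- cand; beta[i] <- b; break }
        resampled <- resampled + 1L
      }
    }
    out <- data.frame(
      compound_id = sprintf("syn-%03d", seq_len(n)),
      solvent = "DMSO-d6",
      temperature_K = cfg$temperature,
      percent_beta = beta,
      percent_alpha = 100 - beta,
      true_e_an = e_an,
      stringsAsFactors = FALSE)
    attr(out, "resampled") <- resampled
    out
  })
}

#' Synthetic mutarotation time course with ground truth
#'
#' beta(t) = beta_eq + (beta_0 - beta_eq) exp(-k t) plus Gaussian noise.
#' Starting compositions are pure anomers (beta_0 of 0 or 100),
#' mirroring crystallization as a single anomer before dissolution.
#'
#' @param cfg A [simulation_config()].
#' @param beta_eq True equilibrium beta percentage (default drawn
#'   uniformly in (20, 95)).
#' @param rate_k True rate constant per hour (default drawn from
#'   `cfg$rate_range` log-uniformly).
#' @param beta_0 Starting beta percentage, 0 or 100 (default drawn).
#' @param times Sampling times in hours.
#' @return A list with `series` (a [mutarotation_series()], noisy values
#'   clamped to \[0, 100\]) and `truth` (list of beta_eq, beta_0,
#'   rate_k, sigma).
#' @export
gen_mutarotation_series <- function(cfg,
                                    beta_eq = NULL, rate_k = NULL,
                                    beta_0 = NULL,
                                    times = c(0, 1, 2, 4, 8, 24, 48, 72,
                                              120, 168)) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_substream(cfg, 202L, {
    if (is.null(beta_eq)) beta_eq <- stats::runif(1, 20, 95)
    if (is.null(rate_k))
      rate_k <- exp(stats::runif(1, log(cfg$rate_range[1]),
                                 log(cfg$rate_range[2])))
    if (is.null(beta_0)) beta_0 <- if (stats::runif(1) < 0.5) 100 else 0
    mu <- beta_eq + (beta_0 - beta_eq) * exp(-rate_k * times)
    y <- mu + stats::rnorm(length(times), 0, cfg$noise_sigma_points)
    y <- pmin(pmax(y, 0), 100)
    list(series = mutarotation_series("syn-mut", times, y,
                                      solvent = "synthetic"),
         truth = list(beta_eq = beta_eq, beta_0 = beta_0,
                      rate_k = rate_k, sigma = cfg$noise_sigma_points))
  })
}

truncnorm1 <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Synthetic NMR-observable table with true anomer labels
#'
#' Draws per-species observables from the configured alpha/beta
#' distributions (Gaussians centered on the diagnostic reference values,
#' truncated at physical bounds), for use as classifier
#' ground-truth fixtures.
#'
#' @param cfg A [simulation_config()].
#' @param n Number of species (default `cfg$n_compounds`).
#' @param p_alpha Probability a species is an alpha anomer.
#' @param acetylated Logical; draw acetylated-context couplings.
#' @return Data frame with columns `species_id`, `true_label`,
#'   `j_h1_h2`, `one_bond_j_c1_h1`, `optical_rotation_d`,
#'   `rotation_solvent`, `acetylated`.
#' @export
gen_nmr_observables <- function(cfg, n = cfg$n_compounds, p_alpha = 0.5,
                                acetylated = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"), n >= 1)
  with_substream(cfg, 303L, {
    lab <- ifelse(stats::runif(n) < p_alpha, "alpha", "beta")
    pick <- function(label, field)
      if (label == "alpha") cfg$nmr_alpha_params[[field]]
      else cfg$nmr_beta_params[[field]]
    jf <- if (acetylated) "one_bond_j_ac" else "one_bond_j"
    j12 <- vapply(lab, function(l) {
      p <- pick(l, "j_h1_h2"); truncnorm1(1, p[1], p[2], 0, 15)
    }, numeric(1))
    j1 <- vapply(lab, function(l) {
      p <- pick(l, jf); truncnorm1(1, p[1], p[2], 120, 200)
    }, numeric(1))
    rot <- vapply(lab, function(l) {
      p <- pick(l, "rotation"); stats::rnorm(1, p[1], p[2])
    }, numeric(1))
    data.frame(species_id = sprintf("nmr-%04d", seq_len(n)),
               true_label = unname(lab),
               j_h1_h2 = unname(j12),
               one_bond_j_c1_h1 = unname(j1),
               optical_rotation_d = unname(rot),
               rotation_solvent = "pyridine",
               acetylated = acetylated,
               stringsAsFactors = FALSE)
  })
}

#' Synthetic periodic torsion profile with known extrema
#'
#' E(theta) = sum over terms of amplitude (1 - cos(multiplicity
#' (theta - phase))), sampled on a uniform grid, plus optional noise.
#' Terms with only even multiplicities repeat exactly every 180 degrees.
#'
#' @param cfg A [simulation_config()].
#' @param step Grid step in degrees (default 15, the scan resolution).
#' @return A list with `profile` (a [torsion_profile()]) and
#'   `true_minima` (angles in degrees of the noiseless minima).
#' @export
#' @examples
#' gen_torsion_profile(simulation_config())$true_minima  # 45, 225
gen_torsion_profile <- function(cfg, step = 15) {
  stopifnot(inherits(cfg, "simulation_config"),
            nrow(cfg$torsion_terms) >= 1L)
  th <- seq(0, 360 - step, by = step)
  shape <- function(theta) {
    e <- numeric(length(theta))
    for (i in seq_len(nrow(cfg$torsion_terms))) {
      a <- cfg$torsion_terms$amplitude[i]
      m <- cfg$torsion_terms$multiplicity[i]
      ph <- cfg$torsion_terms$phase[i]
      e <- e + a * (1 - cos(m * (theta - ph) * pi / 180))
    }
    e
  }
  e <- shape(th)
  if (cfg$torsion_noise_kcal > 0)
    e <- e + with_substream(cfg, 404L,
      stats::rnorm(length(th), 0, cfg$torsion_noise_kcal))
  fine <- seq(0, 360 - 0.01, by = 0.01)
  ef <- shape(fine)
  is_min <- ef < c(ef[length(ef)], ef[-length(ef)]) &
            ef < c(ef[-1], ef[1])
  list(profile = torsion_profile(th, e),
       true_minima = fine[is_min])
}
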