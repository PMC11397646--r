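Package: anomeric
Title: Thermodynamic Analysis of Anomeric Equilibria in 2-Iminoaldoses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the (reverse) anomeric effect from observed
    alpha/beta anomer populations of sugar-derived Schiff bases.
    Converts populations to anomerization constants and standard free
    energies, derives conformational A-values on cyclohexane and
    tetrahydropyran rings, computes anomeric stabilization energies and
    the magnitude of the reverse anomeric effect, and predicts Boltzmann
    beta-anomer fractions from relative free energies.  Companion tools
    cover rule-based anomer assignment from NMR observables (J couplings,
    one-bond C-H couplings, optical rotations), mutarotation time-course
    fitting with reversible first-order kinetics, empirical hydrogen-bond
    strength from donor-acceptor distance, natural-bond-orbital
    second-order stabilization energies, and periodic torsional-scan
    analysis.  A seeded synthetic-data generator emulates two-state
    anomer equilibria, noisy approach-to-equilibrium time courses,
    bimodal NMR-observable distributions and periodic torsion profiles so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
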