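# Rule-based anomer classification and geometry flags.

test_that("printed alpha/beta exemplars classify correctly", {
  # alpha anomer: small J12 overrides the between-references one-bond J
  call_a <- classify_anomer(nmr_observables("108", j_h1_h2 = 3.3,
                                            one_bond_j_c1_h1 = 165.5))
  expect_identical(call_a$call, "alpha")
  expect_true(nrow(call_a$evidence) >= 2)
  # beta anomer: large J12 and beta-side one-bond J agree
  call_b <- classify_anomer(nmr_observables("48", j_h1_h2 = 8.4,
                                            one_bond_j_c1_h1 = 153.7))
  expect_identical(call_b$call, "beta")
})

test_that("J12 alone inside the abstention window is ambiguous", {
  expect_identical(classify_anomer(nmr_observables("x", j_h1_h2 = 5.5))$call,
                   "ambiguous")
})

test_that("acetylated context switches the one-bond references", {
  expect_identical(
    classify_anomer(nmr_observables("ac", one_bond_j_c1_h1 = 177,
                                    acetylated = TRUE))$call, "alpha")
  expect_identical(
    classify_anomer(nmr_observables("ac", one_bond_j_c1_h1 = 166,
                                    acetylated = TRUE))$call, "beta")
  # 166 Hz reads beta when acetylated but sits between the free references
  expect_identical(
    classify_anomer(nmr_observables("fr", one_bond_j_c1_h1 = 166))$call,
    "alpha")  # nearest free reference is 170
})

test_that("rotation rule fires only in pyridine", {
  expect_identical(
    classify_anomer(nmr_observables("r", optical_rotation_d = 154,
                                    rotation_solvent = "pyridine"))$call,
    "alpha")
  expect_identical(
    classify_anomer(nmr_observables("r", optical_rotation_d = 31,
                                    rotation_solvent = "pyridine"))$call,
    "beta")
  expect_error(
    classify_anomer(nmr_observables("r", optical_rotation_d = 154,
                                    rotation_solvent = "chloroform")),
    "insufficient evidence")
})

test_that("no diagnostic observable raises an insufficient-evidence error", {
  expect_error(classify_anomer(nmr_observables("none", delta_c1 = 92.8)),
               "insufficient evidence")
})

test_that("classification is deterministic and invariant under repetition", {
  obs <- nmr_observables("d", j_h1_h2 = 3.9, one_bond_j_c1_h1 = 171,
                         optical_rotation_d = 120,
                         rotation_solvent = "pyridine")
  first <- classify_anomer(obs)
  for (i in 1:5) expect_identical(classify_anomer(obs)$call, first$call)
})

test_that("removing losing or abstaining evidence never flips a call", {
  cases <- list(
    nmr_observables("a", j_h1_h2 = 3.3, one_bond_j_c1_h1 = 165.5),
    nmr_observables("b", j_h1_h2 = 8.4, one_bond_j_c1_h1 = 153.7),
    nmr_observables("c", j_h1_h2 = 3.5, one_bond_j_c1_h1 = 171,
                    optical_rotation_d = 40,
                    rotation_solvent = "pyridine"))
  for (obs in cases) {
    full <- classify_anomer(obs)
    if (full$call == "ambiguous") next
    losing <- full$evidence$rule[full$evidence$vote != full$call]
    for (rule in losing) {
      reduced <- obs
      reduced[[if (rule == "optical_rotation_d") "optical_rotation_d"
               else rule]] <- NA_real_
      got <- tryCatch(classify_anomer(reduced)$call,
                      error = function(e) "insufficient")
      expect_false(got == setdiff(c("alpha", "beta"), full$call))
    }
  }
})

test_that("geometry flags pick up E double bonds, antiperiplanar imines and oxazolidines", {
  expect_identical(geometry_flags(nmr_observables("45", j_ch_eq_ch = 16.1)),
                   "E_double_bond")
  expect_identical(geometry_flags(nmr_observables("45", j_ch_chn = 8.8)),
                   "antiperiplanar_imine")
  expect_identical(geometry_flags(nmr_observables("x")), character(0))
  expect_identical(
    geometry_flags(nmr_observables("ox", extra_h_shifts = 5.4,
                                   extra_c_shifts = 93.5)),
    "oxazolidine_suspected")
  expect_identical(
    geometry_flags(nmr_observables("ok", extra_h_shifts = c(3.8, 4.9),
                                   extra_c_shifts = c(61.5, 74.9))),
    "oxazolidine_absent")
  both <- geometry_flags(nmr_observables("45", j_ch_eq_ch = 16.1,
                                         j_ch_chn = 8.8))
  expect_setequal(both, c("E_double_bond", "antiperiplanar_imine"))
})

test_that("classifier separates the generator's alpha/beta distributions", {
  cfg <- simulation_config(seed = 2024, n_compounds = 10000)
  tab <- gen_nmr_observables(cfg)
  calls <- vapply(seq_len(nrow(tab)), function(i)
    classify_anomer(nmr_observables(
      tab$species_id[i], j_h1_h2 = tab$j_h1_h2[i],
      one_bond_j_c1_h1 = tab$one_bond_j_c1_h1[i],
      optical_rotation_d = tab$optical_rotation_d[i],
      rotation_solvent = tab$rotation_solvent[i]))$call,
    character(1))
  expect_gte(mean(calls == tab$true_label), 0.99)
})
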