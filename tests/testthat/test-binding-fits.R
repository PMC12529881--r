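test_that("hill_logistic has the textbook midpoint, asymptotes and shape", {
  expect_equal(hill_logistic(1e-6, 10, 70, 1e-6, 1.3), 40)  # midpoint
  expect_identical(hill_logistic(0, 10, 70, 1e-6, 1.3), 10)
  expect_equal(hill_logistic(1, 10, 70, 1e-6, 1.3), 70, tolerance = 1e-6)

  # arithmetic check at the study's substrate curve parameters
  x <- 100e-6
  expected <- 68.3 * (x / 34.6e-6)^1.3 / (1 + (x / 34.6e-6)^1.3)
  expect_equal(hill_logistic(x, 0, 68.3, 34.6e-6, 1.3), expected,
               tolerance = 1e-12)

  # n = 1 is the rectangular hyperbola
  xx <- 10^seq(-9, -3, length.out = 40)
  expect_equal(hill_logistic(xx, 0, 100, 2e-6, 1),
               100 * xx / (2e-6 + xx), tolerance = 1e-12)

  # decreasing orientation via top < bottom
  expect_true(all(diff(hill_logistic(xx, 90, 5, 1e-6, 1.3)) < 0))
})

test_that("fit_hill recovers noise-free parameters to high precision", {
  x <- 10^seq(-8, -4, length.out = 9)
  y <- hill_logistic(x, 0, 70, 1e-6, 1.3)
  fit <- fit_hill(titration_series(x, y, axis_kind = "substrate"))
  expect_false(fit$flagged)
  expect_equal(unname(fit$estimates["bottom"]), 0, tolerance = 1e-5)
  expect_equal(unname(fit$estimates["top"]), 70, tolerance = 1e-6)
  expect_equal(unname(fit$estimates["K"]), 1e-6, tolerance = 1e-6)
  expect_equal(unname(fit$estimates["n"]), 1.3, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("fit_hill honors fixed Hill coefficients and plateau boxes", {
  x <- 10^seq(-8, -4, length.out = 9)
  y <- hill_logistic(x, 0, 70, 1e-6, 1.3)
  fit <- fit_hill(titration_series(x, y, axis_kind = "substrate"),
                  fix_n = 1.3, bottom = 0, top = 68,
                  plateau_halfwidth = 5)
  expect_identical(fit$constraints$fix_n, 1.3)
  expect_equal(unname(fit$estimates["n"]), 1.3)
  expect_true(fit$estimates["top"] >= 63 && fit$estimates["top"] <= 73)
  expect_equal(unname(fit$estimates["K"]), 1e-6, tolerance = 0.05)
})

test_that("fit_hill is scale-equivariant in the concentration axis", {
  x <- 10^seq(-8, -4, length.out = 9)
  y <- hill_logistic(x, 5, 80, 3e-6, 1.1)
  k1 <- fit_hill(titration_series(x, y, axis_kind = "substrate"))$estimates["K"]
  k2 <- fit_hill(titration_series(1e3 * x, y,
                                  axis_kind = "substrate"))$estimates["K"]
  expect_equal(unname(k2 / k1), 1e3, tolerance = 1e-6)
})

test_that("decreasing inhibitor series keep their orientation and report IC50", {
  x <- 10^seq(-8, -4, length.out = 9)
  y <- hill_logistic(x, 55, 4, 3.1e-6, 1.3)  # top < bottom: inhibition
  fit <- fit_hill(titration_series(x, y, axis_kind = "inhibitor"))
  expect_identical(fit$orientation, "decreasing")
  expect_equal(unname(fit$estimates["K"]), 3.1e-6, tolerance = 1e-4)
})

test_that("degenerate flat series are flagged with no usable midpoint", {
  x <- 10^seq(-8, -4, length.out = 8)
  y <- rep(42, 8) + c(-0.01, 0.01)
  fit <- fit_hill(titration_series(x, y, axis_kind = "protein"))
  expect_true(fit$flagged)
})

test_that("free-species axes follow the fraction conventions", {
  fr <- fractions_from_counts(c(18, 31, 1))
  fs <- free_species_concentrations(fr, 50e-9)
  expect_equal(fs$M_free, (18 / 84) * 50e-9, tolerance = 1e-12)
  expect_equal(fs$D_free, (62 / 84) * 50e-9 / 2, tolerance = 1e-12)

  pure_m <- c(f_M = 1, f_D = 0, f_T = 0)
  expect_equal(free_species_concentrations(pure_m, 1e-6)$M_free, 1e-6)
  expect_equal(free_species_concentrations(pure_m, 1e-6)$D_free, 0)
  pure_d <- c(f_M = 0, f_D = 1, f_T = 0)
  expect_equal(free_species_concentrations(pure_d, 1e-6)$D_free, 0.5e-6)
})

test_that("assembly affinities are exact on noise-free model fractions", {
  p <- truth_params()
  conds <- titration_design("protein_dilution")
  tab <- do.call(rbind, lapply(conds$c_tot, function(C) {
    fr <- predict_fractions(p, NULL, assay_condition(C))
    data.frame(c_tot = C, conc_f_M = fr$f_M, conc_f_D = fr$f_D,
               conc_f_T = fr$f_T)
  }))
  aff <- fit_assembly_affinities(tab)
  expect_equal(aff$Kd_MM, p$K1_0, tolerance = 1e-4)
  expect_equal(aff$Kd_DD, p$K2_0, tolerance = 1e-4)

  # with substrate: effective constants recovered, then extrapolated to
  # saturation by inverting the linkage
  S <- 100e-6
  tab_s <- do.call(rbind, lapply(conds$c_tot, function(C) {
    fr <- predict_fractions(p, NULL, assay_condition(C, S = S))
    data.frame(c_tot = C, conc_f_M = fr$f_M, conc_f_D = fr$f_D,
               conc_f_T = fr$f_T)
  }))
  aff_s <- fit_assembly_affinities(tab_s, S = S, params = p)
  eff <- effective_constants(p, NULL, assay_condition(800e-9, S = S))
  expect_equal(aff_s$Kd_MM, eff$K1_eff, tolerance = 1e-3)
  expect_equal(aff_s$Kd_DD, eff$K2_eff, tolerance = 1e-3)
  expect_equal(aff_s$Kd_MM_sat, p$K1_S, tolerance = 1e-3)
  expect_equal(aff_s$Kd_DD_sat, p$K2_S, tolerance = 1e-3)

  # fold-stabilization of the dimer-dimer interface by substrate
  expect_equal(aff$Kd_DD / aff_s$Kd_DD_sat, p$K2_0 / p$K2_S,
               tolerance = 0.01)
  expect_equal(round(aff$Kd_DD / aff_s$Kd_DD_sat), 98)
})

test_that("flat fraction tables give flagged affinities, not numbers", {
  tab <- data.frame(c_tot = 10^seq(-8, -5, length.out = 8),
                    conc_f_M = 0.5, conc_f_D = 0.5, conc_f_T = 0)
  aff <- fit_assembly_affinities(tab)
  expect_true(is.na(aff$Kd_MM))
  expect_true(aff$fits$MM$flagged)
})

test_that("substrate titration recovers K_S and the tetramer Hill slope", {
  p <- truth_params()
  evs <- simulate_titration("substrate_titration", p, n_events = 8000,
                            seed = 37)
  tab <- do.call(rbind, lapply(evs, quantify_events))
  fit <- fit_hill(titration_series(tab$s, 100 * tab$conc_f_T,
                                   axis_kind = "substrate"), fix_n = 1.3)
  expect_false(fit$flagged)
  expect_equal(unname(fit$estimates["K"]), p$K_S, tolerance = 0.20)
})
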