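test_that("stoichiometric-limit isotherm is a step at molar ratio N", {
  sch <- ref_titration_scheme()
  par <- binding_parameters(N = 1, KD_M = 1e-15, dH_kcal_mol = -6.58,
                            dilution_offset_kcal_mol = -0.1)
  iso <- simulate_isotherm(sch, par)
  before <- iso$q_per_mol[iso$molar_ratio < 0.9]
  after <- iso$q_per_mol[iso$molar_ratio > 1.1]
  expect_true(all(abs(before - (-6.58 - 0.1)) < 0.01))
  expect_true(all(abs(after - (-0.1)) < 0.01))
})

test_that("null-enthalpy titration returns only the dilution offset", {
  sch <- ref_titration_scheme()
  par <- binding_parameters(N = 1, KD_M = 1e-7, dH_kcal_mol = 0,
                            dilution_offset_kcal_mol = 0.25)
  iso <- simulate_isotherm(sch, par)
  expect_equal(iso$q_per_mol, rep(0.25, 16))
})

test_that("noise-free simulate -> fit round trip recovers all parameters", {
  sch <- ref_titration_scheme()
  iso <- simulate_isotherm(sch, ref_titration_params())
  fit <- fit_isotherm(iso, sch)
  expect_true(fit$converged)
  expect_equal(fit$params$KD_M, 52.83e-9, tolerance = 1e-6)
  expect_equal(fit$params$dH_kcal_mol, -6.58, tolerance = 1e-6)
  expect_equal(fit$params$N, 1, tolerance = 1e-6)
})

test_that("round-trip identity holds across the fittable c range", {
  cases <- expand.grid(KD = c(1e-8, 1e-7, 5e-7), dH = c(-6.58, 3.2),
                       offset = c(0, -0.15))
  for (r in seq_len(nrow(cases))) {
    sch <- titration_scheme(syringe_conc_uM = 100, cell_conc_uM = 10)
    cv <- c_value(sch, cases$KD[r])
    expect_true(cv >= 5 && cv <= 2000)
    par <- binding_parameters(N = 1, KD_M = cases$KD[r],
                              dH_kcal_mol = cases$dH[r],
                              dilution_offset_kcal_mol = cases$offset[r])
    fit <- fit_isotherm(simulate_isotherm(sch, par), sch)
    expect_equal(fit$params$KD_M, cases$KD[r], tolerance = 1e-6)
    expect_equal(fit$params$N, 1, tolerance = 1e-6)
    expect_equal(fit$params$dH_kcal_mol, cases$dH[r], tolerance = 1e-6)
    expect_equal(fit$params$dilution_offset_kcal_mol, cases$offset[r],
                 tolerance = 1e-5)
  }
})

test_that("thermodynamic identity dG = dH + (-TdS) holds for every fit", {
  sch <- ref_titration_scheme()
  fit <- fit_isotherm(simulate_isotherm(sch, ref_titration_params()), sch)
  expect_equal(fit$dG_kcal_mol,
               fit$params$dH_kcal_mol + fit$minus_TdS_kcal_mol,
               tolerance = 1e-9)
  R <- 1.98720425e-3
  expect_equal(fit$dG_kcal_mol, R * 293.15 * log(fit$params$KD_M),
               tolerance = 1e-9)
})

test_that("thermo_decompose matches closed forms and rejects bad input", {
  # arbitrary-precision closed form: R*T*ln(255e-9) at 293.15 K
  td <- thermo_decompose(255e-9, -5, 20)
  expect_equal(td$dG_kcal_mol, 1.98720425e-3 * 293.15 * log(255e-9),
               tolerance = 1e-12)
  expect_equal(td$dG_kcal_mol, -8.845, tolerance = 1e-3)
  # standard state: KD = 1 M gives dG = 0 and -TdS = -dH
  td1 <- thermo_decompose(1, -6.58, 20)
  expect_equal(td1$dG_kcal_mol, 0)
  expect_equal(td1$minus_TdS_kcal_mol, 6.58)
  expect_error(thermo_decompose(-1e-9, -6.58, 20), "positive")
})

test_that("c_value is the direct concentration ratio", {
  expect_equal(c_value(ref_titration_scheme(), 52.83e-9), 5e-6 / 52.83e-9,
               tolerance = 1e-12)
  expect_equal(c_value(ref_titration_scheme(), 52.83e-9), 94.64, tolerance = 1e-3)
  sch20 <- titration_scheme(syringe_conc_uM = 312, cell_conc_uM = 20)
  expect_equal(c_value(sch20, 255e-9), 78.43, tolerance = 1e-3)
  expect_equal(c_value(titration_scheme(syringe_conc_uM = 10,
                                        cell_conc_uM = 1), 1e-6), 1)
})

test_that("degenerate heats give an honest non-converged fit", {
  sch <- ref_titration_scheme()
  iso <- simulate_isotherm(sch, ref_titration_params())
  iso$q_per_mol <- rep(0, nrow(iso))
  fit <- fit_isotherm(iso, sch)
  expect_false(fit$converged)
})

test_that("a c-value outside the designable window is flagged", {
  sch <- titration_scheme(syringe_conc_uM = 50, cell_conc_uM = 5)
  par <- binding_parameters(N = 1, KD_M = 3e-5, dH_kcal_mol = -6.58)
  fit <- fit_isotherm(simulate_isotherm(sch, par), sch)
  expect_true(length(fit$warnings) > 0)
  expect_match(fit$warnings[1], "c-value")
})

test_that("too few included injections is an error", {
  sch <- titration_scheme(syringe_conc_uM = 50, cell_conc_uM = 5,
                          injection_volumes_ul = rep(2, 5))
  iso <- simulate_isotherm(sch, ref_titration_params())
  expect_error(fit_isotherm(iso, sch), "at least 5")
})

test_that("raw injection heats conserve total binding enthalpy", {
  # small injected fraction, saturating titration: the summed raw heats
  # approach N * M0 * V0 * dH; an independent mole-tracking oracle agrees
  sch <- titration_scheme(syringe_conc_uM = 500, cell_conc_uM = 5,
                          injection_volumes_ul = rep(0.5, 16),
                          exclude_first = FALSE)
  iso <- simulate_isotherm(
    sch, binding_parameters(N = 1, KD_M = 1e-12, dH_kcal_mol = -6.58))
  raw <- iso$q_per_mol * 500e-6 * iso$volume_ul * 1e-6   # kcal per injection
  expect_equal(sum(raw), 1 * 5e-6 * 200e-6 * -6.58, tolerance = 0.01)

  # oracle: with KD -> 0 every injected mole binds until sites run out
  sites <- 5e-6 * 200e-6
  injected <- cumsum(500e-6 * iso$volume_ul * 1e-6)
  bound <- pmin(injected, sites)
  oracle <- diff(c(0, bound)) * -6.58
  expect_equal(sum(raw), sum(oracle), tolerance = 0.01)
})

test_that("transition steepness grows monotonically with c", {
  sch <- titration_scheme(syringe_conc_uM = 100, cell_conc_uM = 5)
  steep <- vapply(10^seq(-6, -9, by = -0.5), function(kd) {
    iso <- simulate_isotherm(
      sch, binding_parameters(N = 1, KD_M = kd, dH_kcal_mol = -6.58))
    max(abs(diff(iso$q_per_mol)))
  }, numeric(1))
  expect_true(all(diff(steep) > 0))
})

test_that("noisy simulation is seeded and reproducible", {
  sch <- ref_titration_scheme()
  a <- simulate_isotherm(sch, ref_titration_params(), noise_sd_kcal_mol = 0.05,
                         seed = 11)
  b <- simulate_isotherm(sch, ref_titration_params(), noise_sd_kcal_mol = 0.05,
                         seed = 11)
  d <- simulate_isotherm(sch, ref_titration_params(), noise_sd_kcal_mol = 0.05,
                         seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$q_per_mol, d$q_per_mol))
  expect_error(simulate_isotherm(sch, ref_titration_params(),
                                 noise_sd_kcal_mol = 0.05), "seed")
})

test_that("isotherm CSV round trip preserves the table", {
  iso <- simulate_isotherm(ref_titration_scheme(), ref_titration_params())
  f <- withr::local_tempfile(fileext = ".csv")
  write_isotherm_csv(iso, f)
  back <- read_isotherm_csv(f)
  expect_equal(back$q_per_mol, iso$q_per_mol, tolerance = 1e-12)
  expect_equal(back$included, iso$included)
})

test_that("tidy and glance expose the fitted quantities", {
  sch <- ref_titration_scheme()
  fit <- fit_isotherm(simulate_isotherm(sch, ref_titration_params()), sch)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_equal(gl$KD_nM, 52.83, tolerance = 1e-5)
  expect_equal(gl$minus_TdS_kcal_mol, -3.18, tolerance = 0.01)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("over-filling the cell is rejected", {
  expect_error(titration_scheme(syringe_conc_uM = 50, cell_conc_uM = 5,
                                injection_volumes_ul = rep(20, 11)),
               "cell volume")
})
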