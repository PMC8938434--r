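test_that("repeat sequences are built and motif-counted correctly", {
  rs <- build_repeat_sequence(repeat_unit, 52)
  expect_equal(nchar(rs$full_sequence), 624)
  expect_equal(count_motif(rs, "FG"), 52L)

  rs7 <- build_repeat_sequence(repeat_unit, 7)
  expect_equal(nchar(rs7$full_sequence), 84)
  expect_equal(count_motif(rs7, "FG"), 7L)

  g <- build_repeat_sequence("G", 1)
  expect_equal(g$full_sequence, "G")
  expect_equal(count_motif(g, "FG"), 0L)

  expect_error(build_repeat_sequence("GGXZ", 2), "X")
  expect_error(build_repeat_sequence(repeat_unit, 0), "positive")
})

test_that("molecular weights match independent residue-mass summation", {
  # frozen from an independent sum over a published average-mass table
  expect_equal(molecular_weight(repeat_unit), 1119.2, tolerance = 1e-4)
  expect_equal(molecular_weight("G"), 75.07, tolerance = 1e-4)

  mw52 <- molecular_weight(build_repeat_sequence(repeat_unit, 52))
  expect_equal(mw52, 57280, tolerance = 1e-3)
  # consistent with the ~60 ug/ul calibration of a 1 mM stock (within 5%)
  expect_lt(rel_err(molar_to_mass_conc(1e-3, mw52), 60), 0.05)
})

test_that("peptide-bond additivity of molecular weight holds", {
  set.seed(11)
  for (i in 1:10) {
    a <- paste(sample(c("G", "L", "F", "N", "T", "Q", "P", "A"), 6,
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("G", "S", "Y", "W", "K", "D"), 5,
                      replace = TRUE), collapse = "")
    expect_equal(molecular_weight(paste0(a, b)),
                 molecular_weight(a) + molecular_weight(b) - 18.0153,
                 tolerance = 1e-9)
  }
})

test_that("molar/mass conversions are exact and invert each other", {
  expect_equal(molar_to_mass_conc(1e-3, 60000), 60)
  expect_equal(molar_to_mass_conc(0, 12345), 0)
  expect_error(molar_to_mass_conc(-1, 100), ">= 0")
  for (c0 in c(1e-6, 4.5e-3, 0.2)) {
    expect_equal(mass_to_molar_conc(molar_to_mass_conc(c0, 57280), 57280),
                 c0, tolerance = 1e-12)
  }
})

test_that("motif molarity and sphere-confined concentration scale as expected", {
  expect_equal(motif_molarity(4.5, 52), 234)
  expect_equal(motif_molarity(3, 0), 0)
  expect_equal(motif_molarity(1e-6, 52), 52e-6)

  c5 <- sphere_local_concentration(52, 5)
  expect_equal(c5 * 1000, 165, tolerance = 0.03)      # ~165 mM
  expect_equal(sphere_local_concentration(52, 10), c5 / 8,
               tolerance = 1e-12)                      # r^3 scaling
  expect_equal(sphere_local_concentration(1, 1), 0.3965, tolerance = 1e-3)
  expect_equal(sphere_local_concentration(2, 5),
               2 * sphere_local_concentration(1, 5), tolerance = 1e-12)
  expect_error(sphere_local_concentration(52, -1), "> 0")
})

test_that("water viscosity matches handbook values and decreases with T", {
  expect_lt(rel_err(water_viscosity(20), 1.002e-3), 0.01)
  expect_lt(rel_err(water_viscosity(24), 0.911e-3), 0.01)
  temps <- seq(1, 40, by = 1)
  expect_true(all(diff(water_viscosity(temps)) < 0))
  expect_error(water_viscosity(-5), "between")
  expect_error(water_viscosity(120), "between")
})

test_that("hydrated radius matches hand evaluation of the sphere formula", {
  expect_equal(hydrated_radius(57280, 0.73, 3.2), 28.70, tolerance = 1e-3)
  expect_equal(hydrated_radius(7726, 0.73, 3.2), 16.28, tolerance = 1e-3)
  expect_equal(hydrated_radius(57280, 0.73, 3.2) -
                 hydrated_radius(57280, 0.73, 0), 3.2, tolerance = 1e-12)
})

test_that("Stokes-Einstein-Debye relations hold exactly and match references", {
  # D * tau_c = (2/9) r^2 for the same sphere, temperature and viscosity
  for (r_a in c(10, 28.7, 50)) {
    tau_s <- stokes_tau_c(r_a, 24) * 1e-9
    d_m2 <- stokes_einstein_d(r_a / 10, 24) * 1e-12
    expect_equal(d_m2 * tau_s, (2 / 9) * (r_a * 1e-10)^2,
                 tolerance = 1e-12)
  }
  expect_equal(stokes_tau_c(2 * 28.7, 24) / stokes_tau_c(28.7, 24), 8,
               tolerance = 1e-12)
  expect_equal(stokes_einstein_d(2, 21) / stokes_einstein_d(1, 21), 0.5,
               tolerance = 1e-12)
  expect_equal(stokes_einstein_d(1, 20), 214, tolerance = 5e-3)
})

test_that("hydrodynamic prediction table is self-consistent", {
  pred <- hydrodynamic_predictions(repeat_unit, 52, temp_c = 24)
  expect_equal(pred$n_residues, 624)
  expect_equal(pred$n_motifs, 52L)
  expect_equal(pred$tau_c_ns,
               stokes_tau_c(hydrated_radius(pred$mw_da), 24),
               tolerance = 1e-12)
})
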