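test_that("volumetric rates follow delta-n over V times dt with sign kept", {
  expect_equal(uptake_rate(-5e-4, 0.05, 20), -0.5)
  expect_equal(uptake_rate(0, 0.05, 20), 0)
  # the magnitude behind the highest reported NUR: 6.2e-4 mol over 50 mL x 20 h
  expect_equal(uptake_rate(-6.2e-4, 0.05, 20), -0.62)
  expect_error(uptake_rate(1e-3, 0, 1), "positive")
  expect_error(uptake_rate(1e-3, 0.05, 0), "positive")
})

test_that("specific rates divide magnitude by biomass", {
  # 0.62 mmol/L/h at 0.0605 g/L is a qN2 of about 10.25 mmol/h/g
  expect_equal(specific_rate(-0.62, 0.0605), 10.2479, tolerance = 1e-4)
  expect_equal(specific_rate(1, 0.5), 2)
  expect_equal(specific_rate(0, 0.3), 0)
  expect_error(specific_rate(1, 0), "positive")
})

test_that("biomass conversion is linear in OD and needs a coefficient", {
  expect_equal(biomass_from_od(0.2, 0.3), 0.06)
  expect_equal(biomass_from_od(0, 0.3), 0)
  expect_equal(biomass_from_od(2 * 0.35, 0.3), 2 * biomass_from_od(0.35, 0.3))
  expect_error(biomass_from_od(0.2), "coefficient")
  expect_error(biomass_from_od(0.2, NA), "coefficient")
})

test_that("interval rates keep stoichiometric ratios and sign conventions", {
  zero <- interval_rates(rate_interval(0, 10, 0.05, 0.06,
    c(H2 = 0, CO2 = 0, N2 = 0, CH4 = 0)))
  expect_equal(c(zero$nur, zero$hur, zero$cur, zero$mer), rep(0, 4))

  r <- interval_rates(rate_interval(0, 20, 0.05, 0.06,
    c(H2 = -4e-3, CO2 = -1e-3, CH4 = 1e-3, N2 = 0)))
  expect_equal(r$hur / r$cur, 4)
  expect_true(r$hur < 0 && r$cur < 0 && r$mer > 0)

  partial <- interval_rates(rate_interval(0, 20, 0.05, 0.06,
    c(H2 = -4e-3, CO2 = -1e-3, CH4 = 1e-3)))
  expect_true(is.na(partial$nur))
  expect_false(is.na(partial$hur))
})

test_that("qN2 times biomass recovers the NUR magnitude exactly", {
  set.seed(31)
  for (i in 1:25) {
    dn2 <- -stats::runif(1, 1e-5, 1e-3)
    x <- stats::runif(1, 0.01, 0.3)
    r <- interval_rates(rate_interval(0, stats::runif(1, 5, 50), 0.05, x,
      c(H2 = 0, CO2 = 0, CH4 = 0, N2 = dn2)))
    expect_equal(r$qn2 * x, abs(r$nur))
  }
})

test_that("carbon balance closes as the sum of the two yields", {
  r <- interval_rates(rate_interval(0, 1, 0.05, 0.06,
    c(H2 = -2e-3, CO2 = -0.5e-3, CH4 = 0.4e-3, N2 = 0)))
  # mer 8, cur -10, rx 2 (after the mmol scaling)
  mb <- mass_balance(r, rx = 2)
  expect_equal(mb$y_ch4_co2, 0.8)
  expect_equal(mb$y_x_co2, 0.2)
  expect_equal(mb$c_balance, 1.0)
  expect_equal(mb$c_balance, mb$y_ch4_co2 + mb$y_x_co2)
  expect_equal(mb$hur_cur_ratio, 4)

  pure <- interval_rates(rate_interval(0, 1, 0.05, 0.06,
    c(H2 = -2e-3, CO2 = -0.5e-3, CH4 = 0.5e-3, N2 = 0)))
  expect_equal(mass_balance(pure, rx = 0)$y_ch4_co2, 1.0)

  flat <- interval_rates(rate_interval(0, 1, 0.05, 0.06,
    c(H2 = 0, CO2 = 0, CH4 = 0, N2 = 0)))
  expect_error(mass_balance(flat, rx = 0), "non-zero")
})

test_that("biomass productivity scales biomass change by carbon content", {
  expect_equal(biomass_productivity(0.06, 20, 37.7), 0.06 / 20 * 37.7)
  expect_equal(biomass_productivity(0, 20, 37.7), 0)
  expect_equal(biomass_productivity(0.12, 20, 37.7),
               2 * biomass_productivity(0.06, 20, 37.7))
  expect_error(biomass_productivity(0.1, 0), "positive")
})

test_that("amino-acid mass conversion uses the molecular-weight table", {
  # Glu at 0.04484 g/L corresponds to 0.04484/147.13 mol/m3
  conc <- 0.04484 / 147.13 * 1e6
  expect_equal(aa_mass_concentration(conc, "Glu"), 0.04484)
  expect_equal(aa_mass_concentration(0, "Ala"), 0)
  expect_error(aa_mass_concentration(10, "Xyz"), "unknown amino-acid")
  # unit round trip: 1e6 umol/L (1 mol/L) weighs one molar mass per litre
  expect_equal(aa_mass_concentration(1e6, "Gly"), aa_molar_masses[["Gly"]])
})
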