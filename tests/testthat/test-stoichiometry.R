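test_that("methanogenesis has the canonical coefficients and balances", {
  rx <- methanogenesis()
  expect_equal(rx$gas, c(H2 = -4, CO2 = -1, CH4 = 1))
  expect_equal(rx$non_gas, c(H2O = 2))
  expect_equal(sum(rx$gas), -4) # net gas-mole change per extent
  expect_equal(abs(rx$gas[["H2"]]) / abs(rx$gas[["CO2"]]), 4)
  # H balance: 8 H in, 4 (CH4) + 4 (2 H2O) out — enforced at construction
  expect_error(reaction("broken", gas = c(H2 = -4, CO2 = -1, CH4 = 1)),
               "balanced")
})

test_that("net nitrogenase reaction consumes 3 H2 per N2 and keeps N in NH3", {
  rx <- nitrogenase_net()
  expect_equal(rx$gas, c(N2 = -1, H2 = -3))
  expect_equal(rx$non_gas, c(NH3 = 2))
  expect_equal(sum(rx$gas), -4)
  expect_equal(abs(rx$gas[["H2"]]) / abs(rx$gas[["N2"]]), 3)
  # 2 N consumed as N2, 2 N excreted as NH3
  expect_equal(2 * abs(rx$gas[["N2"]]), rx$non_gas[["NH3"]])
})

test_that("combining reactions reproduces the diazotrophic feed ratios", {
  both <- combine_reactions(list(methanogenesis(), nitrogenase_net()))
  expect_equal(feed_ratio(both), c(H2 = 7, CO2 = 1, N2 = 1))
  expect_equal(feed_ratio(methanogenesis()), c(H2 = 4, CO2 = 1))
  tilted <- combine_reactions(list(methanogenesis(), nitrogenase_net()),
                              weights = c(1, 2))
  expect_equal(feed_ratio(tilted), c(H2 = 10, CO2 = 1, N2 = 2))
  expect_error(combine_reactions(list()), "empty")
})

test_that("full-conversion residuals match the worked gas mixtures", {
  r41 <- full_conversion_residual(gas_mixture(c(H2 = 4, CO2 = 1)), 3,
                                  methanogenesis())
  expect_equal(r41$threshold_abs_bar, 0.6)
  expect_equal(r41$residual_composition$fractions[["CH4"]], 1)

  r711 <- full_conversion_residual(gas_mixture(c(H2 = 7, CO2 = 1, N2 = 1)), 3,
                                   methanogenesis())
  expect_equal(r711$threshold_abs_bar, 5 / 3)
  expect_equal(r711$limiting_species, "CO2")
  expect_equal(r711$residual_composition$fractions[c("CH4", "H2", "N2")],
               c(CH4 = 1, H2 = 3, N2 = 1) / 5)

  rboth <- full_conversion_residual(gas_mixture(c(H2 = 7, CO2 = 1, N2 = 1)), 3,
                                    list(methanogenesis(), nitrogenase_net()))
  expect_equal(rboth$threshold_abs_bar, 1 / 3)
  expect_equal(rboth$residual_composition$fractions[["CH4"]], 1)

  noh2 <- full_conversion_residual(gas_mixture(c(CO2 = 1, N2 = 1)), 3,
                                   methanogenesis())
  expect_equal(noh2$threshold_abs_bar, 3)
  expect_equal(noh2$extent, 0)
})

test_that("THp_N2fix is the methanogenesis-only residual and needs N2", {
  thp <- thp_n2fix(gas_mixture(c(H2 = 7, CO2 = 1, N2 = 1)), 3)
  expect_true(thp$fraction_of_initial == rational(5, 9))
  expect_equal(thp$threshold_abs_bar, 5 / 3)
  # 8:1:1 leaves 4 parts H2 + 1 CH4 + 1 N2 of 10
  expect_equal(thp_n2fix(gas_mixture(c(H2 = 8, CO2 = 1, N2 = 1)), 3)$threshold_abs_bar,
               1.8)
  expect_equal(thp_n2fix(gas_mixture(c(H2 = 7, CO2 = 1, N2 = 1)), 2)$threshold_abs_bar,
               10 / 9)
  expect_error(thp_n2fix(gas_mixture(c(H2 = 4, CO2 = 1)), 3), "no N2")
})

test_that("thresholds scale with pressure and are invariant to part scaling", {
  set.seed(11)
  for (i in 1:50) {
    parts <- random_parts()
    p0 <- stats::runif(1, 0.5, 5)
    a <- full_conversion_residual(gas_mixture(parts), p0, methanogenesis())
    b <- full_conversion_residual(gas_mixture(parts), 2 * p0, methanogenesis())
    expect_equal(b$threshold_abs_bar, 2 * a$threshold_abs_bar)
    d <- full_conversion_residual(gas_mixture(parts * 3), p0, methanogenesis())
    expect_equal(d$threshold_abs_bar, a$threshold_abs_bar)
  }
})

test_that("4:1 mixtures without N2 reduce to pure CH4 at one fifth pressure", {
  set.seed(12)
  for (k in c(1, 2, 5, 13)) {
    res <- full_conversion_residual(gas_mixture(c(H2 = 4 * k, CO2 = k)),
                                    p0 <- stats::runif(1, 1, 4),
                                    methanogenesis())
    expect_equal(res$threshold_abs_bar, p0 / 5)
    expect_equal(res$residual_composition$fractions[["CH4"]], 1)
  }
})

test_that("methanogenesis-only threshold exceeds the dual-reaction residual", {
  set.seed(13)
  for (i in 1:25) {
    parts <- c(H2 = sample(4:20, 1), CO2 = sample(1:4, 1), N2 = sample(1:4, 1))
    mix <- gas_mixture(parts)
    only_meth <- thp_n2fix(mix, 3)$threshold_abs_bar
    both <- full_conversion_residual(mix, 3,
      list(methanogenesis(), nitrogenase_net()))$threshold_abs_bar
    if (parts[["H2"]] > 4 * parts[["CO2"]]) {
      expect_true(both < only_meth) # leftover H2 feeds nitrogenase
    } else {
      expect_true(both <= only_meth)
    }
  }
})

test_that("residual agrees with the brute-force advancement oracle", {
  set.seed(14)
  orders <- list(list(methanogenesis(), nitrogenase_net()),
                 list(nitrogenase_net(), methanogenesis()))
  for (i in 1:100) {
    parts <- random_parts()
    for (ord in orders) {
      got <- full_conversion_residual(gas_mixture(parts), 3, ord)
      ref <- oracle_residual(parts, ord, 3)
      expect_equal(got$threshold_abs_bar, ref$threshold_abs_bar,
                   tolerance = 1e-9)
    }
  }
})

test_that("N2 fixed from pressure follows the four-gas-moles rule", {
  thp <- thp_n2fix(gas_mixture(c(H2 = 7, CO2 = 1, N2 = 1)), 3)
  ves <- vessel_state(117, 50, temperature_k = 298.15)
  expect_equal(n2_fixed_from_pressure(thp$threshold_abs_bar, thp, ves), 0)
  # 0.2 bar deficit in 67 mL at 298.15 K
  dn <- (0.2e5 * 67e-6) / (8.314 * 298.15) / 4
  expect_equal(n2_fixed_from_pressure(thp$threshold_abs_bar - 0.2, thp, ves),
               dn, tolerance = 1e-6)
  expect_equal(n2_fixed_from_pressure(thp$threshold_abs_bar - 0.1, thp, ves),
               dn / 2, tolerance = 1e-6)
  expect_error(n2_fixed_from_pressure(2, thp, ves), "above the threshold")
})

test_that("mixture parsing accepts part and fraction spellings", {
  m <- parse_mixture("H2:CO2:N2=7:1:1")
  expect_equal(m$fractions[["H2"]], 7 / 9)
  m2 <- parse_mixture("0.8,0.1,0.1")
  expect_equal(m2$fractions[["N2"]], 0.1)
  expect_error(parse_mixture("H2:CO2=1:2:3"))
  expect_error(gas_mixture(c(Xe = 1)), "unknown species")
  expect_error(gas_mixture(c(H2 = -1, CO2 = 1)), "non-negative")
})
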