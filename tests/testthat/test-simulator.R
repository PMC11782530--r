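test_that("simulation is deterministic given a seed", {
  cfg <- sim_config(nh4_fraction = 0.05)
  a <- simulate_closed_batch(cfg, n_bottles = 2, seed = 5)
  b <- simulate_closed_batch(cfg, n_bottles = 2, seed = 5)
  expect_identical(a$observations, b$observations)
  d <- simulate_closed_batch(cfg, n_bottles = 2, seed = 6)
  expect_false(identical(a$observations, d$observations))
})

test_that("nitrogen and carbon are conserved along trajectories", {
  for (frac in c(0, 0.05, 0.5)) {
    sim <- simulate_closed_batch(sim_config(nh4_fraction = frac),
                                 n_bottles = 1, seed = 2)
    for (tr in list(sim$trajectory, sim$zero_trajectory)) {
      expect_lt(max(abs(tr$n_total_mol - tr$n_total_mol[1])) / tr$n_total_mol[1],
                1e-6)
      expect_lt(max(abs(tr$c_total_mol - tr$c_total_mol[1])) / tr$c_total_mol[1],
                1e-6)
    }
  }
})

test_that("trajectory pressures equal the ideal-gas recomputation", {
  sim <- simulate_closed_batch(sim_config(nh4_fraction = 0.075),
                               n_bottles = 1, seed = 3)
  tr <- sim$trajectory
  p <- pressure_from_moles(tr$n_h2 + tr$n_co2 + tr$n_ch4 + tr$n_n2,
                           tr$v_head_ml, sim$config$temperature_measurement_k)
  expect_equal(tr$p_abs_bar, p, tolerance = 1e-12)
})

test_that("a 4:1 feed without fixation converges to 0.6 bar at full conversion", {
  # biomass carbon set to zero: the textbook figure neglects carbon
  # routed to biomass
  cfg <- noiseless_config(
    mixture = gas_mixture(c(H2 = 4, CO2 = 1)),
    nh4_fraction = 1,
    nitrogenase = list(enabled = FALSE),
    biomass_carbon_cmmol_g = 0,
    events = data.frame(time_h = numeric(0), withdrawal_ml = numeric(0),
                        regas = logical(0)),
    t_end_h = 300, dt_h = 0.2
  )
  sim <- simulate_closed_batch(cfg, n_bottles = 1, seed = 1)
  expect_equal(utils::tail(sim$trajectory$p_abs_bar, 1), 0.6, tolerance = 5e-3)
})

test_that("without nitrogenase, exhausting NH4+ halts growth above THp", {
  cfg <- noiseless_config(
    nh4_fraction = 0.1 / 40, # 0.1 mmol/L: nitrogen exhausts well before the gas
    nitrogenase = list(enabled = FALSE),
    events = data.frame(time_h = numeric(0), withdrawal_ml = numeric(0),
                        regas = logical(0)),
    t_end_h = 200, dt_h = 0.2
  )
  sim <- simulate_closed_batch(cfg, n_bottles = 1, seed = 1)
  tr <- sim$trajectory
  thp <- thp_n2fix(cfg$mixture, cfg$pressure_abs_bar)$threshold_abs_bar
  expect_gt(min(tr$p_abs_bar), thp)
  # growth plateaus once the nitrogen pool is effectively gone
  exhausted <- which(tr$nh4_mmol_l < 1e-9)[1]
  expect_false(is.na(exhausted))
  expect_equal(utils::tail(tr$x_g_l, 1), tr$x_g_l[exhausted],
               tolerance = 1e-3)
})

test_that("zero NH4+ means no growth even with nitrogenase enabled", {
  cfg <- noiseless_config(nh4_fraction = 0,
                          events = data.frame(time_h = numeric(0),
                                              withdrawal_ml = numeric(0),
                                              regas = logical(0)),
                          t_end_h = 150, dt_h = 0.2)
  sim <- simulate_closed_batch(cfg, n_bottles = 1, seed = 1)
  tr <- sim$trajectory
  expect_equal(utils::tail(tr$x_g_l, 1), cfg$biomass_init_g_l)
  expect_equal(utils::tail(tr$p_abs_bar, 1), tr$p_abs_bar[1], tolerance = 1e-9)
})

test_that("NH4+-limited runs with nitrogenase undercut the threshold", {
  cfg <- noiseless_config(nh4_fraction = 0.05)
  sim <- simulate_closed_batch(cfg, n_bottles = 1, seed = 1)
  thp <- thp_n2fix(cfg$mixture, cfg$pressure_abs_bar)$threshold_abs_bar
  expect_lt(min(sim$samples$p_abs_bar), thp - 0.05)
  expect_gt(utils::tail(sim$trajectory$xi_fix, 1), 0)
})

test_that("ground-truth rates difference the exact extents", {
  cfg <- noiseless_config(nh4_fraction = 0.075)
  sim <- simulate_closed_batch(cfg, n_bottles = 1, seed = 1)
  gt <- sim$truth
  expect_equal(nrow(gt), length(sim$obs_times) - 1L)
  # NUR must equal the finite difference of the fixation extent
  for (k in seq_len(nrow(gt))) {
    a <- sim$samples[k, ]; b <- sim$samples[k + 1, ]
    expect_equal(gt$nur[k],
                 -1000 * (b$xi_fix - a$xi_fix) /
                   ((a$v_liq_ml / 1000) * (b$time_h - a$time_h)))
  }
  # consumption non-positive, evolution non-negative everywhere
  expect_true(all(gt$nur <= 1e-12) && all(gt$hur <= 1e-12) &&
                all(gt$cur <= 1e-12) && all(gt$mer >= -1e-12))
  expect_error(ground_truth_rates(sim, times = c(0, 500)), "outside")
})

test_that("early-phase rates scale close to linearly with mu_max", {
  base <- noiseless_config(nh4_fraction = 1,
                           nitrogenase = list(enabled = FALSE),
                           events = data.frame(time_h = 2, withdrawal_ml = 0,
                                               regas = FALSE),
                           t_end_h = 2)
  fast <- noiseless_config(nh4_fraction = 1, mu_max = 2 * base$mu_max,
                           nitrogenase = list(enabled = FALSE),
                           events = data.frame(time_h = 2, withdrawal_ml = 0,
                                               regas = FALSE),
                           t_end_h = 2)
  m1 <- simulate_closed_batch(base, 1, seed = 1)$truth$mer[1]
  m2 <- simulate_closed_batch(fast, 1, seed = 1)$truth$mer[1]
  expect_equal(m2 / m1, 2, tolerance = 0.15)
})
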