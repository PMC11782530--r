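test_that("collinear standards fit perfectly; OLS matches the closed form", {
  conc <- seq(100, 1000, by = 100)
  resp <- 0.002 * conc + 0.05
  curve <- fit_standard_curve(conc, resp)
  expect_equal(curve$r_squared, 1)
  expect_equal(curve$slope, 0.002)
  expect_equal(curve$intercept, 0.05)
  expect_equal(curve$valid_range, c(100, 1000))

  # small noise: compare against the closed-form least-squares solution
  set.seed(41)
  conc9 <- seq(100, 1000, length.out = 9)
  resp9 <- 0.0015 * conc9 + 0.02 + stats::rnorm(9, 0, 1e-4)
  c9 <- fit_standard_curve(conc9, resp9)
  slope_ref <- sum((conc9 - mean(conc9)) * (resp9 - mean(resp9))) /
    sum((conc9 - mean(conc9))^2)
  expect_equal(c9$slope, slope_ref)
  expect_equal(c9$intercept, mean(resp9) - slope_ref * mean(conc9))
  expect_equal(c9$n_standards, 9L)
})

test_that("noisy calibrations below the R-squared gate are rejected", {
  set.seed(42)
  conc <- seq(100, 1000, by = 100)
  resp <- 0.002 * conc + stats::rnorm(10, 0, 0.15) # R^2 well below 0.999
  expect_error(fit_standard_curve(conc, resp), "R\\^2")
  # but the same data pass a permissive gate
  expect_s3_class(fit_standard_curve(conc, resp, r2_min = 0.5),
                  "calibration_curve")
  expect_error(fit_standard_curve(rep(500, 5), stats::runif(5)), "distinct")
})

test_that("quantification inverts the curve and honours dilution", {
  curve <- fit_standard_curve(seq(100, 1000, 100),
                              0.002 * seq(100, 1000, 100) + 0.05)
  mid <- 0.002 * 550 + 0.05
  expect_equal(quantify(mid, curve), 550)
  expect_equal(quantify(mid, curve, dilution_factor = 4), 2200)
  expect_equal(quantify(curve$intercept, curve), 0)
  # round trip over the full standard range
  set.seed(43)
  for (i in 1:25) {
    true_conc <- stats::runif(1, 100, 1000)
    expect_equal(quantify(0.002 * true_conc + 0.05, curve), true_conc)
  }
  expect_error(quantify(0.002 * 50 + 0.05, curve), "re-dilute")
  expect_error(quantify(0.002 * 1500 + 0.05, curve), "re-dilute")
  expect_error(quantify(curve$intercept - 0.01, curve), "re-dilute")
})

test_that("amino-acid panels quantify per analyte and exclude Val/Met", {
  aas <- c("Glu", "Ala", "Gly", "Asn", "Val")
  curves <- setNames(lapply(seq_along(aas), function(i) {
    fit_standard_curve(seq(1, 15, length.out = 6),
                       (0.5 + 0.1 * i) * seq(1, 15, length.out = 6))
  }), aas)
  true_conc <- c(Glu = 10, Ala = 4, Gly = 3, Asn = 2, Val = 8)
  areas <- vapply(aas, function(a) curves[[a]]$slope * true_conc[[a]], numeric(1))
  expect_message(panel <- panel_from_peaks(areas, curves), "Val")
  expect_equal(panel$excluded, "Val")
  expect_false("Val" %in% names(panel$concentrations_umol_l))
  expect_equal(panel$concentrations_umol_l[c("Glu", "Ala", "Gly", "Asn")],
               true_conc[c("Glu", "Ala", "Gly", "Asn")])
  expect_equal(panel$total_umol_l, sum(true_conc[c("Glu", "Ala", "Gly", "Asn")]))
  # order invariance of the total
  expect_message(rev_panel <- panel_from_peaks(rev(areas), curves))
  expect_equal(rev_panel$total_umol_l, panel$total_umol_l)

  zero_areas <- vapply(curves[c("Glu", "Ala")], function(cv) cv$intercept, numeric(1))
  zero_panel <- panel_from_peaks(zero_areas, curves)
  expect_equal(unname(zero_panel$concentrations_umol_l), c(0, 0))
  expect_error(panel_from_peaks(c(Trp = 1), curves), "no calibration curve")
  expect_error(panel_from_peaks(c(Zzz = 1), curves), "unknown amino-acid")
})
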