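test_that("expected_per_disc applies the area formula with unit conversion", {
  expect_identical(expected_per_disc(0, 25), 0)
  # 253 molecules/um^2 in a 25 nm disc
  expect_equal(expected_per_disc(253, 25), 253 * pi * 0.0125^2,
               tolerance = 1e-12)
  expect_equal(expected_per_disc(253, 25), 0.1241911, tolerance = 1e-6)
  # doubling the diameter quadruples the expectation
  expect_equal(expected_per_disc(100, 50), 4 * expected_per_disc(100, 25),
               tolerance = 1e-12)
  expect_error(expected_per_disc(-1, 25), ">= 0")
  expect_error(expected_per_disc(100, 0), "> 0")
})

test_that("co-capture probability has the right limits and monotonicity", {
  expect_identical(cocapture_probability(0, 25)$p_cocapture, 0)
  # small-lambda series: P -> lambda/2
  lam <- 1e-6
  d <- sqrt(lam / pi) * 2000  # diameter giving this lambda at density 1
  cc <- cocapture_probability(1, d)
  expect_equal(cc$lambda, lam, tolerance = 1e-9)
  expect_lt(abs(cc$p_cocapture - 5e-7), 1e-9)
  # frozen value at the experimental density and disc size
  cc253 <- cocapture_probability(253, 25)
  expect_equal(cc253$p_cocapture, 0.06081059, tolerance = 1e-6)
  # strictly increasing in density and diameter, bounded in [0, 1)
  ps_density <- vapply(c(50, 100, 250, 500, 1000),
                       function(d) cocapture_probability(d, 25)$p_cocapture,
                       numeric(1))
  ps_diameter <- vapply(c(10, 25, 50, 100, 200),
                        function(dd) cocapture_probability(253, dd)$p_cocapture,
                        numeric(1))
  expect_true(all(diff(ps_density) > 0))
  expect_true(all(diff(ps_diameter) > 0))
  expect_true(all(c(ps_density, ps_diameter) >= 0 &
                    c(ps_density, ps_diameter) < 1))
})

test_that("Poisson co-capture formula matches a placement simulation", {
  set.seed(202)
  for (lam in c(0.1, 0.5)) {
    mc <- cocapture_mc(lam, n_discs = 2e4)
    p <- (-expm1(-lam) - lam * exp(-lam)) / (-expm1(-lam))
    se <- sqrt(p * (1 - p) / mc$n_occupied)
    expect_lt(abs(mc$p_hat - p), 3 * se + 1e-12)
  }
})

test_that("GPMV density calibration inverts a constructed measurement", {
  # place a known density on a simulated zone and regenerate the intensity
  avogadro <- 6.02214076e23
  cal_int <- 5e5
  cal_conc <- 100e-9
  cal_vol <- 2000       # um^3
  ipm <- cal_int / (cal_conc * avogadro * cal_vol * 1e-15)
  d_true <- 253
  ves_d <- 8            # um
  slice <- 1.2          # um
  area <- pi * ves_d * slice
  roi <- d_true * area * ipm
  got <- density_from_gpmv(roi, ves_d, slice, cal_int, cal_conc, cal_vol)
  expect_equal(got, d_true, tolerance = 1e-9)
  # linearity in ROI intensity
  expect_equal(density_from_gpmv(2 * roi, ves_d, slice, cal_int, cal_conc,
                                 cal_vol), 2 * d_true, tolerance = 1e-9)
  # invariance to a common intensity rescaling
  expect_equal(density_from_gpmv(7 * roi, ves_d, slice, 7 * cal_int,
                                 cal_conc, cal_vol), d_true,
               tolerance = 1e-9)
  # slice thicker than the vesicle: full sphere area pi d^2
  full <- density_from_gpmv(roi, ves_d, 20, cal_int, cal_conc, cal_vol)
  expect_equal(full, roi / ipm / (pi * ves_d^2), tolerance = 1e-9)
  # clamped negative intensity warns and yields zero
  expect_warning(z <- density_from_gpmv(-5, ves_d, slice, cal_int,
                                        cal_conc, cal_vol), "clamped")
  expect_identical(z, 0)
  expect_error(density_from_gpmv(roi, ves_d, slice, 0, cal_conc, cal_vol),
               "calibration")
})

test_that("lipid quantitation follows the internal-standard formula", {
  expect_equal(lipid_pmol(0.5, 1000, 1000, 40), 20, tolerance = 1e-12)
  expect_identical(lipid_pmol(0.5, 0, 1000, 40), 0)
  # halving the standard peak area doubles the result
  expect_equal(lipid_pmol(0.5, 800, 500, 40),
               2 * lipid_pmol(0.5, 800, 1000, 40), tolerance = 1e-12)
  expect_error(lipid_pmol(0.5, 100, 0), "division error")
})
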