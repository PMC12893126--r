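test_that("1/e diameter is the 1/e^2 diameter over sqrt(2)", {
  expect_equal(d1e_from_d1e2(98.25), 69.47, tolerance = 1e-4)
  expect_identical(d1e_from_d1e2(0), 0)
  expect_equal(d1e_from_d1e2(141.4214), 100.0, tolerance = 1e-6)
  expect_error(d1e_from_d1e2(-1), "non-negative")
})

test_that("beam_profile enforces its invariants", {
  b <- beam_profile(98.25, rel_u_d = 0.035)
  expect_equal(b$d_1e_um, b$d_1e2_um / sqrt(2), tolerance = 1e-9)
  expect_error(beam_profile(0), "positive")
  expect_error(beam_profile(100, rel_u_d = -0.1), "non-negative")
})

test_that("peak radiant exposure reproduces the worked energy examples", {
  b <- beam_profile(98.25)
  expect_equal(peak_radiant_exposure(3.86, b)$value, 102, tolerance = 0.005)
  expect_equal(peak_radiant_exposure(13.25, b)$value, 349.5,
               tolerance = 0.005)
  expect_identical(peak_radiant_exposure(0, b)$value, 0)
  expect_identical(peak_radiant_exposure(3.86, b)$convention, "peak_1e")
})

test_that("the 1/e-diameter and 1/e^2-radius forms of the peak agree", {
  for (E in c(0.5, 3.86, 13.25)) {
    for (d in c(50, 98.25, 500)) {
      b <- beam_profile(d)
      via_1e <- peak_radiant_exposure(E, b)$value
      w_cm <- (d / 2) / 1e4
      via_w <- 2 * (E / 1e3) / (pi * w_cm^2)
      expect_equal(via_1e, via_w, tolerance = 1e-12)
    }
  }
})

test_that("encircled energy fraction matches numeric radial integration", {
  w <- 98.25 / 2
  for (ratio in c(0.1, 0.5, 1, 2, 5)) {
    expect_equal(
      encircled_energy_fraction(ratio * w, 98.25),
      numeric_encircled_fraction(ratio * w, w),
      tolerance = 1e-8
    )
  }
  expect_identical(encircled_energy_fraction(0, 98.25), 0)
  expect_equal(encircled_energy_fraction(49.125, 98.25), 1 - exp(-2),
               tolerance = 1e-12)
  expect_equal(encircled_energy_fraction(500, 98.25), 1, tolerance = 1e-15)
  r <- seq(0, 300, by = 10)
  expect_true(all(diff(encircled_energy_fraction(r, 98.25)) >= 0))
})

test_that("aperture-averaged radiant exposure follows the ANSI convention", {
  b <- beam_profile(98.25)
  expect_equal(average_radiant_exposure(3.86, b, aperture_mm = 1)$value,
               0.49, tolerance = 0.005)
  # energy numerically equal to the 1-mm aperture area in J/cm^2 units
  tiny <- beam_profile(1)
  expect_equal(average_radiant_exposure(7.85398163397448, tiny, 1)$value,
               1.0, tolerance = 1e-6)
  # aperture shrunk to the beam's own 1/e^2 diameter: (1 - e^-2) E / A
  ap_mm <- 98.25 / 1e3
  A <- pi * (ap_mm / 10 / 2)^2
  expect_equal(
    average_radiant_exposure(3.86, b, aperture_mm = ap_mm)$value,
    (1 - exp(-2)) * (3.86 / 1e3) / A,
    tolerance = 1e-10
  )
  expect_error(average_radiant_exposure(3.86, b, aperture_mm = 0),
               "positive")
})

test_that("average exposure is nonincreasing in aperture once beam is contained", {
  b <- beam_profile(98.25)
  ap <- seq(0.3, 3, by = 0.1)
  vals <- vapply(ap, function(a) average_radiant_exposure(1, b, a)$value,
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("averaging over the 1/e^2 diameter halves the peak exactly", {
  b <- beam_profile(98.25)
  peak <- peak_radiant_exposure(3.86, b)
  avg <- average_over_1e2(peak)
  expect_identical(avg$value, 0.5 * peak$value)
  expect_identical(avg$convention, "average_1e2")
  expect_equal(avg$value, 51, tolerance = 0.01)
  expect_error(average_over_1e2(avg), "peak_1e")
  for (x in c(0, 1, 7.7)) {
    p <- peak_radiant_exposure(x, b)
    expect_identical(average_over_1e2(p)$value * 2, p$value)
  }
})

test_that("quadrature uncertainty combination matches the budget arithmetic", {
  expect_equal(combine_relative_uncertainties(c(0.02, 0.01)),
               0.022, tolerance = 0.03)
  expect_equal(round(combine_relative_uncertainties(c(0.022, 0.035)), 3),
               0.041)
  expect_identical(combine_relative_uncertainties(0.017), 0.017)
  # permutation invariance and triangle property
  u <- c(0.02, 0.01, 0.018, 0.035)
  expect_identical(combine_relative_uncertainties(u),
                   combine_relative_uncertainties(rev(u)))
  expect_gte(combine_relative_uncertainties(u), max(u))
  expect_error(combine_relative_uncertainties(c(0.02, -0.01)),
               "non-negative")
})

test_that("uncertainty modes differ by the diameter sensitivity factor", {
  b <- beam_profile(98.25, rel_u_d = 0.035)
  direct <- peak_radiant_exposure(3.86, b, rel_u_energy = 0.022)$rel_u
  strict <- peak_radiant_exposure(3.86, b, rel_u_energy = 0.022,
                                  uncertainty_mode = "strict")$rel_u
  expect_equal(direct, sqrt(0.022^2 + 0.035^2), tolerance = 1e-12)
  expect_equal(strict, sqrt(0.022^2 + (2 * 0.035)^2), tolerance = 1e-12)
  expect_equal(round(direct, 3), 0.041)
})

test_that("energy-ratio calibration recovers the true ratio and its noise", {
  ref <- c(0.1, 0.11, 0.09, 0.105)
  cal <- calibrate_energy_ratio(ref, 50 * ref)
  expect_equal(cal$ratio, 50)
  expect_equal(cal$rel_u, 0)
  one <- calibrate_energy_ratio(0.1, 5)
  expect_equal(one$ratio, 50)
  expect_true(is.na(one$rel_u))
  # multiplicative calibration noise shows up as the relative spread
  set.seed(7)
  spreads <- replicate(200, {
    r <- runif(20, 0.08, 0.12)
    calibrate_energy_ratio(r, 50 * r * (1 + rnorm(20, 0, 0.018)))$rel_u
  })
  expect_equal(mean(spreads), 0.018, tolerance = 0.1)
  expect_error(calibrate_energy_ratio(c(0.1, -0.1), c(5, 5)), "positive")
})

test_that("dosimetry_summary reports all three conventions consistently", {
  b <- beam_profile(98.25, rel_u_d = 0.035)
  s <- dosimetry_summary(3.86, b, rel_u_energy = 0.022)
  expect_setequal(s$convention,
                  c("peak_1e", "average_aperture", "average_1e2"))
  expect_equal(s$value[s$convention == "average_1e2"],
               0.5 * s$value[s$convention == "peak_1e"])
})
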