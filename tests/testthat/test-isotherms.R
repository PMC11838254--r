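test_that("energy/factor conversions follow Boltzmann's relation and round-trip", {
  th <- thermo_context()
  expect_equal(factor_from_energy(0, th), 1)
  # a factor of 10 corresponds to about -1.4 kcal/mol at room temperature
  expect_equal(energy_from_factor(10, th), -1.364247, tolerance = 1e-6)
  expect_equal(factor_from_energy(energy_from_factor(10, th), th), 10,
               tolerance = 1e-12)
  for (a in c(0.01, 0.5, 1, 7, 300)) {
    expect_equal(factor_from_energy(energy_from_factor(a, th), th), a,
                 tolerance = 1e-12)
  }
  expect_error(factor_from_energy(NaN, th))
  expect_error(energy_from_factor(-1, th))
  expect_error(thermo_context(-5))
})

test_that("langmuir and cooperative saturation fractions have the exact closed forms", {
  expect_equal(langmuir_fraction(0), 0)
  expect_equal(langmuir_fraction(1), 0.5)
  expect_equal(langmuir_fraction(9), 0.9)
  expect_error(langmuir_fraction(-1))

  expect_equal(saturation_fraction(1, 1), 0.5)
  # midpoint shifts to c = 1/alpha
  expect_equal(saturation_fraction(0.1, 10), 0.5)
  # frozen from direct evaluation of the closed form
  expect_equal(saturation_fraction(1, 10), 0.98809352, tolerance = 1e-7)
  expect_equal(saturation_fraction(0, 5), 0)
  expect_equal(saturation_fraction(0, 0), 0)
})

test_that("saturation isotherm reduces to Langmuir at alpha = 1 and obeys particle-hole symmetry", {
  withr::with_seed(11, {
    cs <- 10^stats::runif(2000, -4, 4)
    expect_lt(max(abs(saturation_fraction(cs, 1) - langmuir_fraction(cs))),
              1e-12)
    alphas <- 10^stats::runif(200, -1.5, 1.5)
    cs2 <- 10^stats::runif(200, -3, 3)
    err <- vapply(seq_along(cs2), function(i) {
      a <- alphas[i]
      abs(saturation_fraction(cs2[i], a) +
            saturation_fraction(1 / (a^2 * cs2[i]), a) - 1)
    }, numeric(1))
    expect_lt(max(err), 1e-10)
  })
})

test_that("saturation fraction is strictly increasing in concentration", {
  for (a in c(0.2, 1, 10, 100)) {
    f <- saturation_fraction(10^seq(-4, 4, length.out = 400), a)
    expect_true(all(diff(f) > 0))
  }
})

test_that("midpoint relations: EC50 = KD/alpha and midpoint slope sqrt(alpha)/4", {
  expect_equal(ec50_saturation(1e-9, 1), 1e-9)
  expect_equal(ec50_saturation(1e-9, 10), 1e-10)
  expect_error(ec50_saturation(0, 1))
  for (a in c(0.5, 1, 4, 25, 100)) {
    kd <- 3.7e-9
    expect_equal(saturation_fraction(ec50_saturation(kd, a) / kd, a), 0.5,
                 tolerance = 1e-12)
    # numerical log-slope at the midpoint vs sqrt(alpha)/4
    h <- 1e-5
    slope <- (saturation_fraction(exp(h) / a, a) -
                saturation_fraction(exp(-h) / a, a)) / (2 * h)
    expect_equal(slope, sqrt(a) / 4, tolerance = 1e-6)
  }
})

test_that("competition isotherm: midpoint, beta = 1 reduction, log-symmetry, monotonicity", {
  for (b in c(0.1, 1, 5, 50)) expect_equal(competition_fraction(1, b), 0.5)
  expect_equal(competition_fraction(10, 1), 1 / 11)
  # frozen from direct evaluation
  expect_equal(competition_fraction(10, 100), 0.42955840, tolerance = 1e-7)
  expect_equal(competition_fraction(0, 0), 1)
  expect_equal(competition_fraction(2, 0), 0)
  expect_equal(competition_fraction(1, 0), 0.5)

  xs <- 10^seq(-3, 3, length.out = 500)
  expect_lt(max(abs(competition_fraction(xs, 1) - 1 / (1 + xs))), 1e-12)
  withr::with_seed(7, {
    for (i in 1:50) {
      b <- 10^stats::runif(1, -1.5, 2)
      x <- 10^stats::runif(1, -3, 3)
      expect_equal(competition_fraction(x, b) + competition_fraction(1 / x, b),
                   1, tolerance = 1e-10)
    }
  })
  for (b in c(0.2, 1, 3, 20)) {
    f <- competition_fraction(xs, b)
    expect_true(all(diff(f) < 0))
  }
})

test_that("smaller beta gives steeper displacement just past the midpoint", {
  x <- 1.5
  f <- vapply(c(0.1, 0.5, 1, 3, 10), competition_fraction, numeric(1), x = x)
  # lower beta displaces more at the same x > 1 (steeper curve)
  expect_true(all(diff(f) > 0))
})

test_that("IC50 relations: saturated lattice vs Cheng-Prusoff", {
  expect_equal(ic50_saturated(2e-9, 1e-9, 1e-9), 2e-9)
  expect_equal(ic50_saturated(1e-9, 5e-10, 1e-9), 5e-10)
  expect_error(ic50_saturated(0, 1, 1))
  # ratio law at equal radioligand concentration
  r <- ic50_saturated(4e-9, 1e-9, 1e-9) / ic50_saturated(1e-9, 1e-9, 1e-9)
  expect_equal(r, 4)

  expect_equal(cheng_prusoff_ic50(1e-9, 1e-9, 1e-9), 2e-9)
  expect_equal(cheng_prusoff_ic50(1e-9, 1e-15, 1e-9), 1e-9, tolerance = 1e-5)
  # the "+1" difference vanishes at saturating radioligand
  conc_l <- 1e-4; kd <- 1e-9; ki <- 3e-9
  expect_equal(cheng_prusoff_ic50(ki, conc_l, kd) /
                 ic50_saturated(ki, conc_l, kd), 1, tolerance = 1e-4)
})

test_that("hot/cold displacement is the hot mole fraction", {
  expect_equal(hot_cold_fraction(1e-9, 1e-9), 0.5)
  expect_equal(hot_cold_fraction(1e-9, 0), 1)
  expect_error(hot_cold_fraction(0, 0))
  expect_equal(hot_cold_fraction(2e-9, 6e-9),
               competition_fraction(3, 1))
})

test_that("beta from Boltzmann factors, and the arithmetic-mean energy rule", {
  for (a in c(0.3, 1, 12)) expect_equal(beta_from_factors(a, a, a), 1)
  expect_equal(beta_from_factors(1, 1, 2), 4)
  expect_error(beta_from_factors(0, 1, 1))
  th <- thermo_context()
  b <- beta_from_factors(factor_from_energy(-2, th), factor_from_energy(0, th),
                         factor_from_energy(-1, th))
  expect_equal(b, 1, tolerance = 1e-12)
})

test_that("midpoint log-derivatives match the series closed forms", {
  expect_equal(midpoint_log_derivative(1, 1), -0.25, tolerance = 1e-8)
  expect_equal(midpoint_log_derivative(4, 1), -0.125, tolerance = 1e-8)
  for (b in c(0.3, 1, 2, 3, 5, 20)) {
    expect_equal(midpoint_log_derivative(b, 1), -1 / (4 * sqrt(b)),
                 tolerance = 1e-7)
    expect_equal(midpoint_log_derivative(b, 3), (3 - b) / (16 * b^1.5),
                 tolerance = 1e-5)
  }
  expect_error(midpoint_log_derivative(1, 2))
})

test_that("third derivative changes sign at beta = 3 and the root is stable", {
  # plateau onset: positive below, negative above (the curve flattens at
  # the midpoint as beta grows past 3)
  expect_gt(midpoint_log_derivative(2.9, 3), 0)
  expect_lt(midpoint_log_derivative(3.1, 3), 0)
  expect_equal(critical_beta(), 3, tolerance = 1e-6)
  # step-size independence of the underlying differentiation
  d_a <- midpoint_log_derivative(3, 3, h = 0.05)
  d_b <- midpoint_log_derivative(3, 3, h = 0.02)
  expect_lt(abs(d_a - d_b), 1e-7)
})
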