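# random lattice models for property-style tests
random_lattice_model <- function(three_state = FALSE,
                                 weight_range = c(1e-2, 1e2),
                                 factor_range = c(1e-1, 1e1)) {
  rw <- function() exp(stats::runif(1, log(weight_range[1]), log(weight_range[2])))
  rf <- function() exp(stats::runif(1, log(factor_range[1]), log(factor_range[2])))
  if (three_state) {
    lattice_model(conc_ratio_l = rw(), alpha_l = rf(),
                  conc_ratio_i = rw(), alpha_i = rf(), chi = rf())
  } else {
    lattice_model(conc_ratio_l = rw(), alpha_l = rf())
  }
}

expect_occupancy_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$mean_fraction, b$mean_fraction, tolerance = tol)
  if (!is.null(a$pair_fraction) && !is.null(b$pair_fraction)) {
    expect_equal(a$pair_fraction, b$pair_fraction, tolerance = tol)
  }
}
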