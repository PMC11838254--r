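test_that("binding_curve enforces its contract", {
  expect_s3_class(binding_curve(c(1e-9, 2e-9), c(10, 20)), "binding_curve")
  expect_error(binding_curve(c(1e-9, 1e-9), c(1, 2)), "strictly increasing")
  expect_error(binding_curve(c(-1e-9, 1e-9), c(1, 2)))
  expect_error(binding_curve(1e-9, 1, assay_type = "competition"),
               "radioligand_conc")
  # rows are sorted by concentration
  b <- binding_curve(c(2e-9, 1e-9), c(20, 10))
  expect_equal(b$concentration, c(1e-9, 2e-9))
})

test_that("theoretical_curve spans the requested fraction range", {
  tab <- theoretical_curve(function(c) saturation_fraction(c, 10))
  expect_equal(nrow(tab), 200)
  expect_equal(range(tab$fraction), c(0.01, 0.99), tolerance = 1e-6)
  tabd <- theoretical_curve(function(x) competition_fraction(x, 1))
  expect_equal(sort(range(tabd$fraction)), c(0.01, 0.99), tolerance = 1e-6)
})

test_that("Hill fits recover exact Hill curves and grade cooperative steepness", {
  # a Langmuir curve is exactly Hill with n = 1
  tab1 <- theoretical_curve(function(c) saturation_fraction(c, 1))
  h1 <- fit_hill(tab1)
  expect_equal(unname(h1$estimates["hill_n"]), 1, tolerance = 1e-6)
  expect_equal(unname(h1$estimates["midpoint"]), 1, tolerance = 1e-6)

  # alpha = 10 looks like an effective Hill coefficient between 2 and 3
  h10 <- fit_hill(theoretical_curve(function(c) saturation_fraction(c, 10)))
  expect_gt(unname(h10$estimates["hill_n"]), 2)
  expect_lt(unname(h10$estimates["hill_n"]), 3)

  # beta = 1 competition is exactly non-steep (n = 1), descending form
  hb <- fit_hill(theoretical_curve(function(x) competition_fraction(x, 1)))
  expect_equal(unname(hb$estimates["hill_n"]), 1, tolerance = 1e-6)

  # effective steepness grows with cooperativity
  ns <- vapply(c(1, 3, 10, 30), function(a) {
    unname(fit_hill(theoretical_curve(
      function(c) saturation_fraction(c, a)))$estimates["hill_n"])
  }, numeric(1))
  expect_true(all(diff(ns) > 0))
})

test_that("Hill fit flags data that never cross the midpoint", {
  x <- 10^seq(-3, -1, length.out = 10)
  h <- fit_hill(data.frame(concentration = x,
                           fraction = langmuir_fraction(x)))
  expect_false(h$converged)
})

test_that("saturation fits recover generating parameters exactly at zero noise", {
  cur <- generate_saturation_dataset(
    saturation_params(1e-9, 1), signal_model(1000),
    experiment_design(1e-11, 1e-7, 12), noise_model(scale = 0))
  ft <- fit_saturation(cur)
  expect_equal(unname(ft$estimates["kd"]), 1e-9, tolerance = 1e-6)
  expect_equal(unname(ft$estimates["alpha_l"]), 1, tolerance = 1e-6)
  expect_equal(unname(ft$estimates["bmax"]), 1000, tolerance = 1e-6)
  expect_lt(ft$objective, 1e-10)

  # cooperative curve with non-specific slope and baseline
  cur2 <- generate_saturation_dataset(
    saturation_params(1e-9, 10), signal_model(1000, ns_slope = 1e9,
                                              baseline = 30),
    experiment_design(1e-12, 1e-7, 15), noise_model(scale = 0))
  ft2 <- fit_saturation(cur2, include_ns = TRUE, include_baseline = TRUE)
  expect_equal(unname(ft2$estimates["kd"]), 1e-9, tolerance = 1e-5)
  expect_equal(unname(ft2$estimates["alpha_l"]), 10, tolerance = 1e-5)
  expect_equal(unname(ft2$estimates["ns_slope"]), 1e9, tolerance = 1e-5)
  expect_equal(unname(ft2$estimates["baseline"]), 30, tolerance = 1e-4)

  # fixed-alpha variant
  ft3 <- fit_saturation(cur, fix_alpha = 1)
  expect_equal(unname(ft3$estimates["kd"]), 1e-9, tolerance = 1e-6)
})

test_that("95% intervals cover the truth in at least 90 of 100 noisy replicates", {
  truth <- c(kd = 1e-9, alpha_l = 10, bmax = 1000)
  covered <- matrix(FALSE, 100, 3, dimnames = list(NULL, names(truth)))
  for (s in 1:100) {
    cur <- generate_saturation_dataset(
      saturation_params(1e-9, 10), signal_model(1000),
      experiment_design(1e-12, 1e-7, 12),
      noise_model("gaussian_proportional", 0.05, seed = s))
    ft <- tryCatch(fit_saturation(cur, weights = "proportional", seed = s),
                   error = function(e) NULL)
    if (is.null(ft)) next
    covered[s, ] <- truth >= ft$ci[names(truth), 1] &
      truth <= ft$ci[names(truth), 2]
  }
  expect_true(all(colSums(covered) >= 90))
})

test_that("competition fits recover (IC50, beta) and detect cooperativity shape", {
  cur <- generate_competition_dataset(
    competition_params(1e-9, 2e-9, beta = 1), 1e-9, signal_model(800),
    experiment_design(1e-11, 1e-6, 15), noise_model(scale = 0))
  fc <- fit_competition(cur)
  expect_equal(unname(fc$estimates["ic50"]), 2e-9, tolerance = 1e-6)
  expect_equal(unname(fc$estimates["beta"]), 1, tolerance = 1e-6)
  expect_equal(unname(fc$estimates["bmax"]), 800, tolerance = 1e-6)

  cur10 <- generate_competition_dataset(
    competition_params(1e-9, 2e-9, beta = 10), 1e-9, signal_model(800),
    experiment_design(1e-11, 1e-6, 15), noise_model(scale = 0))
  fc10 <- fit_competition(cur10)
  expect_equal(unname(fc10$estimates["beta"]), 10, tolerance = 1e-5)
  # a beta = 1 refit of the biphasic curve is visibly worse
  d <- data.frame(x = cur10$concentration / unname(fc10$estimates["ic50"]))
  pred_b1 <- unname(fc10$estimates["bmax"]) * competition_fraction(d$x, 1)
  expect_gt(sum((cur10$signal - pred_b1)^2), 100 * fc10$objective + 1)
})

test_that("hot/cold competition puts the IC50 at the radioligand concentration", {
  conc_l <- 1e-9
  cur <- generate_competition_dataset(
    competition_params(ec50_l = 1e-9, ec50_i = 1e-9, beta = 1), conc_l,
    signal_model(500), experiment_design(1e-11, 1e-7, 13),
    noise_model(scale = 0))
  fc <- fit_competition(cur)
  expect_equal(unname(fc$estimates["ic50"]), conc_l, tolerance = 1e-6)
})

test_that("IC50 ratio of two inhibitors at equal radioligand equals their EC50 ratio", {
  conc_l <- 2e-9
  fits <- lapply(c(1e-9, 5e-9), function(ec50_i) {
    cur <- generate_competition_dataset(
      competition_params(1e-9, ec50_i, beta = 1), conc_l, signal_model(600),
      experiment_design(1e-11, 1e-6, 15), noise_model(scale = 0))
    fit_competition(cur)
  })
  ratio <- fits[[2]]$estimates["ic50"] / fits[[1]]$estimates["ic50"]
  expect_equal(unname(ratio), 5, tolerance = 0.01)
})

test_that("competition fits cannot decompose KD from alpha: the ridge is flat", {
  cur <- generate_competition_dataset(
    competition_params(1e-9, 2e-9, beta = 1), 1e-9, signal_model(800),
    experiment_design(1e-11, 1e-6, 15),
    noise_model("gaussian_absolute", 5, seed = 21))
  fc <- fit_competition(cur)
  prof <- identifiability_profile(cur, fc,
                                  alpha_grid = 10^seq(-1.5, 1.5, length.out = 25))
  rel_spread <- diff(range(prof$objective)) / max(prof$objective)
  expect_lt(rel_spread, 1e-8)
})

test_that("saturation data with wide dynamic range break the (KD, alpha) degeneracy", {
  cur <- generate_saturation_dataset(
    saturation_params(1e-9, 10), signal_model(1000),
    experiment_design(1e-12, 1e-7, 15), noise_model(scale = 0))
  ft <- fit_saturation(cur)
  prof <- identifiability_profile(cur, ft,
                                  alpha_grid = 10^seq(-1, 1, length.out = 15))
  rel_spread <- diff(range(prof$objective)) / max(prof$objective)
  expect_gt(rel_spread, 0.5)
  # the profile bottoms out at the generating alpha
  expect_equal(prof$alpha_l[which.min(prof$objective)], 10, tolerance = 0.2)
})
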