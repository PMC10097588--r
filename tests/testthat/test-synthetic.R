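# The seeded generators that stand in for the (undeposited) raw recordings.

test_that("the default truth encodes the qualitative stiffness orderings", {
  tr <- default_truth()
  k <- unclass(tr$params)
  expect_true(k["k_cw_gm"] / k["k_cw_ps"] >= 1.8 && k["k_cw_gm"] / k["k_cw_ps"] <= 2.2)
  expect_true(k["k_mt"] / k["k_af"] >= 1.8 && k["k_mt"] / k["k_af"] <= 2.2)
  expect_gt(k["k_gm"], k["k_ps"])
  expect_identical(default_truth(), default_truth()) # fixed defaults
})

test_that("treatment samples are Gaussian around the model means, seeded and truncated", {
  sc <- default_truth()
  d1 <- simulate_treatment_stiffness(sc)
  d2 <- simulate_treatment_stiffness(sc)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 6 * 65)

  # cv = 0: every value equals its model mean exactly
  d0 <- simulate_treatment_stiffness(truth_scenario(sc$params, noise_cv = 0))
  means <- model_means(sc$params)
  for (t in treatment_levels()) {
    expect_true(all(d0$stiffness[d0$treatment == t] == means[[t]]))
  }

  # CLT bound: at n = 10000 each sample mean is within 3 standard errors
  big <- simulate_treatment_stiffness(
    truth_scenario(sc$params, noise_cv = 0.1, n_per_treatment = 10000, seed = 77)
  )
  ds <- treatment_datasets(big)
  for (i in 1:6) {
    mu <- means[[ds$treatment[i]]]
    expect_lt(abs(ds$mean[i] - mu), 3 * 0.1 * mu / sqrt(10000))
  }

  # heavy truncation warns (once per affected treatment)
  w <- testthat::capture_warnings(
    simulate_treatment_stiffness(truth_scenario(sc$params, noise_cv = 0.6, n_per_treatment = 5))
  )
  expect_true(all(grepl("truncation biases", w)))
  expect_gte(length(w), 1)
})

test_that("micro curves embed their ground truth and close the recovery loop", {
  rec <- curve_recipe(true_stiffness = 12, baseline_sd = 0)
  fc <- simulate_micro_curve(rec)
  ann <- detect_contact(fc)
  expect_lt(abs(fit_initial_stiffness(fc, ann) - 12) / 12, 1e-6)

  # zero hysteresis: zero dissipated energy through the pipeline
  fc0 <- simulate_micro_curve(curve_recipe(true_stiffness = 12, baseline_sd = 0,
                                           hysteresis_factor = 0))
  expect_equal(dissipated_energy(fc0), 0, tolerance = 1e-15)

  # enclosed area matches the closed form h*k*dmax^2/3 at 2000 samples
  fc2 <- simulate_micro_curve(curve_recipe(true_stiffness = 15, baseline_sd = 0,
                                           hysteresis_factor = 0.4, n_samples = 2000))
  tr <- attr(fc2, "truth")
  expect_equal(dissipated_energy(fc2), tr$area, tolerance = 5e-3)

  # same seed, same curve
  r <- curve_recipe(true_stiffness = 9, baseline_sd = 1e-7, seed = 4)
  expect_identical(simulate_micro_curve(r), simulate_micro_curve(r))
})

test_that("AFM curves follow the Hertz law and recover the modulus", {
  rec <- curve_recipe(true_modulus = 3e6, baseline_sd = 0, contact_offset = 5e-8,
                      n_samples = 500, max_force = 5e-8, hysteresis_factor = 0)
  ac <- simulate_afm_curve(rec)
  expect_identical(attr(ac, "instrument"), "afm")
  e <- fit_hertz_modulus(ac, detect_contact(ac))
  expect_lt(abs(e - 3e6) / 3e6, 1e-3)

  # default peak force drawn in the instrument's 15-70 nN range
  ac2 <- simulate_afm_curve(curve_recipe(true_modulus = 2e6, max_force = NULL,
                                         contact_offset = 5e-8, n_samples = 300,
                                         cell_id = "draw-1"))
  expect_true(attr(ac2, "truth")$max_force >= 15e-9 &&
                attr(ac2, "truth")$max_force <= 70e-9)

  # noisy replicates: median recovered modulus within 5%
  errs <- vapply(1:40, function(i) {
    a <- simulate_afm_curve(curve_recipe(true_modulus = 3e6, baseline_sd = 5e-11,
                                         contact_offset = 5e-8, n_samples = 500,
                                         max_force = NULL, hysteresis_factor = 0,
                                         seed = i, cell_id = paste0("n", i)))
    e <- tryCatch(fit_hertz_modulus(a, detect_contact(a)), error = function(err) NA_real_)
    abs(e - 3e6) / 3e6
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.05)
})

test_that("seed derivation is stable and produces distinct streams", {
  expect_identical(derive_seed(1, "GM"), derive_seed(1, "GM"))
  expect_false(derive_seed(1, "GM") == derive_seed(1, "PS"))
  expect_false(derive_seed(1, "GM") == derive_seed(2, "GM"))
  expect_true(derive_seed(12345, "x") > 0 && derive_seed(12345, "x") < 2^31)
})

test_that("a curve set directory carries a manifest that matches its files", {
  dir <- withr::local_tempdir()
  man <- simulate_curve_set(dir, n_per_treatment = 1)
  expect_equal(nrow(man), 6)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_setequal(list.files(dir, pattern = "\\.csv$"), man$file)
  js <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_equal(js$curves$cell_id, man$cell_id)
})
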