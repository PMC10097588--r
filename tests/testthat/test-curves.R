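# Force-curve processing: sensor calibration, compliance correction, contact
# detection, stiffness and Hertz fits, dissipated energy.

test_that("sensor stiffness is the slope of the rigid-substrate reference", {
  expect_equal(estimate_sensor_stiffness(line_curve(1000)), 1000)

  # noisy reference: recovered slope within 3 closed-form OLS standard errors
  withr::with_seed(7, {
    d <- seq(2e-6, 3e-6, length.out = 200)
    noise <- rnorm(200, 0, 1e-9)
    fc <- force_curve(d, 500 * d + noise, instrument = "micro")
    s <- estimate_sensor_stiffness(fc, window_length = 1e-6)
    se_slope <- 1e-9 / sqrt(sum((d - mean(d))^2)) # sigma / sqrt(Sxx)
    expect_lt(abs(s - 500), 3 * se_slope)
  })

  flat <- force_curve(seq(0, 3e-6, length.out = 100), rep(1e-6, 100))
  expect_error(estimate_sensor_stiffness(flat), class = "cellspring_error_invalid_reference")
  expect_error(estimate_sensor_stiffness(line_curve(n = 5), window_length = 1e-6),
               class = "cellspring_error_degenerate_window")
})

test_that("compliance correction subtracts F/S and is exactly invertible", {
  fc <- force_curve(c(0, 2e-6), c(0, 100e-6), instrument = "micro")
  out <- correct_compliance(fc, 100)
  expect_equal(out$displacement[2], 1e-6) # delta - F/S = 2um - 1um

  # S -> very large leaves the curve unchanged to 1e-12 relative
  fcn <- force_curve(c(1e-6, 2e-6), c(0.5e-6, 1e-6), instrument = "micro")
  big <- correct_compliance(fcn, 1e12)
  expect_lt(max(abs(big$displacement - fcn$displacement) / fcn$displacement), 1e-12)

  # zero force: unchanged
  fz <- force_curve(c(0, 1e-6), c(0, 0))
  expect_identical(correct_compliance(fz, 50)$displacement, fz$displacement)

  # round trip: add sensor deflection, correct, recover original
  fc2 <- simulate_micro_curve(curve_recipe(true_stiffness = 8, baseline_sd = 0,
                                           sensor_stiffness = 120))
  rec <- correct_compliance(fc2, 120)
  truth_disp <- rec$displacement + rec$force / 120
  expect_equal(truth_disp, fc2$displacement, tolerance = 1e-12)

  expect_error(correct_compliance(fc, -1), class = "cellspring_error_invalid_parameter")
})

test_that("contact detection is exact on noiseless steps and errors on all-baseline input", {
  n <- 200
  f <- c(rep(0, 100), seq(1e-7, 1e-5, length.out = 100))
  fc <- force_curve(seq(0, 2e-5, length.out = n), f, instrument = "micro")
  ann <- detect_contact(fc, baseline_fraction = 0.3)
  expect_equal(ann$contact_index, 101)
  expect_gt(ann$threshold, ann$baseline_mean)

  flat <- force_curve(seq(0, 1e-5, length.out = 100), rep(0, 100))
  expect_error(detect_contact(flat), class = "cellspring_error_no_contact")

  # baseline window overlapping the rise warns
  early <- force_curve(seq(0, 1e-5, length.out = 100),
                       c(rep(0, 10), seq(1e-5, 9e-4, length.out = 90)))
  expect_warning(detect_contact(early, baseline_fraction = 0.5),
                 class = "cellspring_warning_unstable_baseline")
})

test_that("noisy contact detection lands within 5 samples of truth in >=95% of replicates", {
  nb <- floor(0.4 * 1000) # recipe's pre-contact samples; truth index nb + 1
  hits <- vapply(1:150, function(i) {
    fc <- simulate_micro_curve(curve_recipe(
      true_stiffness = 10, baseline_sd = 1e-7, seed = i, cell_id = paste0("cd", i)
    ))
    ann <- tryCatch(detect_contact(fc, threshold_multiplier = 5),
                    error = function(e) NULL)
    !is.null(ann) && abs(ann$contact_index - (nb + 1)) <= 5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("initial stiffness fits match the exact slope and a normal-equations oracle", {
  fc <- simulate_micro_curve(curve_recipe(true_stiffness = 12, baseline_sd = 0))
  ann <- detect_contact(fc)
  expect_equal(fit_initial_stiffness(fc, ann, list(depth = 1e-6)), 12, tolerance = 1e-9)

  # Hertz-shaped curve, AFM force-fraction window: slope equals the OLS slope
  # computed independently from the normal equations on the same points
  ac <- simulate_afm_curve(curve_recipe(true_modulus = 3e6, baseline_sd = 0,
                                        contact_offset = 5e-8, n_samples = 500,
                                        max_force = 5e-8, hysteresis_factor = 0))
  anna <- detect_contact(ac)
  k <- fit_initial_stiffness(ac, anna, list(force_fraction = 0.10))
  app <- ac[ac$segment == "approach", ]
  i0 <- anna$contact_index
  depth <- app$displacement[i0:nrow(app)] - app$displacement[i0]
  fpost <- app$force[i0:nrow(app)]
  sel <- fpost <= 0.10 * max(fpost)
  X <- cbind(1, depth[sel] * 1e9) # nm scale keeps the normal equations sane
  beta <- solve(t(X) %*% X, t(X) %*% fpost[sel])
  expect_equal(k, beta[2, 1] * 1e9, tolerance = 1e-10)

  expect_error(fit_initial_stiffness(fc, ann, list(depth = 1)),
               class = "cellspring_error_degenerate_window")
})

test_that("Hertz modulus recovery is exact on noise-free curves and linear in force", {
  rec <- curve_recipe(true_modulus = 3e6, baseline_sd = 0, contact_offset = 5e-8,
                      n_samples = 500, max_force = 5e-8, hysteresis_factor = 0)
  ac <- simulate_afm_curve(rec)
  ann <- detect_contact(ac)
  e1 <- fit_hertz_modulus(ac, ann)
  expect_lt(abs(e1 - 3e6) / 3e6, 1e-3)

  # doubling all forces doubles the fitted modulus exactly
  ac2 <- ac
  ac2$force <- 2 * ac$force
  e2 <- fit_hertz_modulus(ac2, detect_contact(ac2))
  expect_equal(e2, 2 * e1, tolerance = 1e-9)

  # force decreasing into adhesion cannot be fit by the contact law
  bad <- force_curve(seq(0, 1e-7, length.out = 50), seq(1e-9, -1e-8, length.out = 50),
                     instrument = "afm", tip_radius = 5e-7)
  bad_ann <- list(contact_index = 5, baseline_mean = 0, baseline_sd = 0, threshold = 1e-12)
  class(bad_ann) <- "contact_annotation"
  expect_error(
    suppressWarnings(fit_hertz_modulus(bad, bad_ann, refine_contact = FALSE)),
    class = "cellspring_error_fit_failure"
  )

  expect_error(fit_hertz_modulus(simulate_micro_curve(curve_recipe()), ann),
               class = "cellspring_error_invalid_parameter")
})

test_that("dissipated energy matches the analytic loop area and handles edge cases", {
  # approach 10x uN (x in um), retract 10x^2 uN: area = 10/6 uN um = 1.667 pJ
  f_app <- function(d) 10 * (d / 1e-6) * 1e-6
  f_ret <- function(d) 10 * (d / 1e-6)^2 * 1e-6
  fc <- loop_curve(f_app, f_ret, span = 1e-6, n = 1000)
  w <- dissipated_energy(fc)
  expect_equal(w, 10 * (1 / 2 - 1 / 3) * 1e-12, tolerance = 5e-3)

  # retract identical to approach: zero
  fc0 <- loop_curve(f_app, f_app)
  expect_equal(dissipated_energy(fc0), 0)

  # below force threshold: excluded with a classed signal
  expect_error(dissipated_energy(fc, force_threshold = 20e-6),
               class = "cellspring_error_below_threshold")

  # missing retract
  expect_error(dissipated_energy(line_curve()), class = "cellspring_error_incomplete_curve")

  # adhesion clip: negative retract forces clipped at zero reduce the area
  f_neg <- function(d) -2e-6 + 0 * d
  w_signed <- dissipated_energy(loop_curve(f_app, f_neg))
  w_clip <- dissipated_energy(loop_curve(f_app, f_neg), clip_negative = TRUE)
  expect_gt(w_signed, w_clip)
})

test_that("stiffness and modulus fits are scale-equivariant in force", {
  fc <- simulate_micro_curve(curve_recipe(true_stiffness = 9, baseline_sd = 0))
  ann <- detect_contact(fc)
  k1 <- fit_initial_stiffness(fc, ann)
  fc$force <- 3 * fc$force
  expect_equal(fit_initial_stiffness(fc, detect_contact(fc)), 3 * k1, tolerance = 1e-9)
})

test_that("loop energy is bounded by the force-depth rectangle for nested loops", {
  for (h in c(0.1, 0.5, 1)) {
    fc <- simulate_micro_curve(curve_recipe(true_stiffness = 10, baseline_sd = 0,
                                            hysteresis_factor = h))
    w <- dissipated_energy(fc)
    tr <- attr(fc, "truth")
    expect_gte(w, 0)
    expect_lte(w, 10 * tr$depth_max * tr$depth_max * 10) # F_max * depth_max
  }
})
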