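# The series-parallel spring network and the exact six-equation inversion.

test_that("series stiffness follows 1/k = 1/k1 + 1/k2", {
  expect_equal(series_stiffness(2, 2), 1)
  expect_equal(series_stiffness(3, 6), 2)
  expect_equal(series_stiffness(7, 1e12), 7, tolerance = 1e-10)
  expect_error(series_stiffness(-1, 2), class = "cellspring_error_invalid_parameter")
})

test_that("series stiffness is symmetric, below both springs, increasing in each", {
  withr::with_seed(1, {
    k1 <- runif(50, 0.1, 50)
    k2 <- runif(50, 0.1, 50)
    s <- series_stiffness(k1, k2)
    expect_equal(s, series_stiffness(k2, k1))
    expect_true(all(s <= pmin(k1, k2)))
    expect_true(all(series_stiffness(k1 * 1.01, k2) > s))
    expect_true(all(series_stiffness(k1, k2 * 1.01) > s))
  })
})

test_that("the parallel branch adds the residual protoplasm and surviving filaments", {
  p <- spring_params(10, 5, 20, 5, 3, 2)
  expect_equal(protoplasm_stiffness("GM", p), 25)
  expect_equal(protoplasm_stiffness("GM-MT", p), 22)
  expect_equal(protoplasm_stiffness("PS-AF", p), 8)
})

test_that("effective stiffness combines the ratio-scaled wall with the branch", {
  p <- spring_params(10, 5, 20, 5, 3, 2)
  expect_equal(effective_stiffness("GM", p), 10 * 25 / 35)
  expect_equal(effective_stiffness("PS-MT", p, ratio_set(r_ps_mt = 0.8)), 28 / 11)
  # rigid wall limit: effective -> branch
  stiff_wall <- spring_params(1e12, 1e12, 20, 5, 3, 2)
  expect_equal(effective_stiffness("GM", stiff_wall), 25, tolerance = 1e-9)
})

test_that("effective stiffness is increasing in every component; removal never stiffens", {
  withr::with_seed(42, {
    for (i in 1:20) {
      k <- exp(runif(6, log(0.5), log(30)))
      p <- do.call(spring_params, as.list(setNames(k, names(kappa_star()))))
      base <- effective_stiffness(treatment_levels(), p)
      for (j in 1:6) {
        k2 <- k
        k2[j] <- k[j] * 1.05
        p2 <- do.call(spring_params, as.list(setNames(k2, names(kappa_star()))))
        expect_true(all(effective_stiffness(treatment_levels(), p2) >= base))
      }
      expect_lte(base[2], base[1]) # GM-MT <= GM at unit ratios
      expect_lte(base[3], base[1])
      expect_lte(base[5], base[4])
      expect_lte(base[6], base[4])
    }
  })
})

test_that("with vanishing filaments the GM-group conditions collapse", {
  p <- spring_params(10, 5, 20, 5, 1e-9, 1e-9)
  eff <- effective_stiffness(c("GM", "GM-MT", "GM-AF"), p)
  expect_equal(eff[1], eff[2], tolerance = 1e-9)
  expect_equal(eff[1], eff[3], tolerance = 1e-9)
})

test_that("AFM ratios divide each drug mean by its osmotic-matched no-drug mean", {
  r <- afm_ratios(c(GM = 10, `GM-MT` = 8, `GM-AF` = 5, PS = 2, `PS-MT` = 1.8, `PS-AF` = 1.2))
  expect_equal(unclass(r), c(r_gm_mt = 0.8, r_gm_af = 0.5, r_ps_mt = 0.9, r_ps_af = 0.6))
  expect_equal(unclass(afm_ratios(setNames(rep(4, 6), treatment_levels()))),
               unclass(ratio_set()))
  expect_error(afm_ratios(c(GM = 10)), class = "cellspring_error_invalid_input")
  expect_error(afm_ratios(setNames(c(1, 1, 1, 1, 1, -2), treatment_levels())),
               class = "cellspring_error_invalid_input")
})

test_that("solve_exact inverts forward-generated means to the generating parameters", {
  p <- kappa_star()
  s <- solve_exact(model_means(p))
  expect_lt(max_rel_err(unclass(s), unclass(p)), 1e-6)
  expect_lt(attr(s, "residual_norm"), 1e-10)

  r <- ratio_set(0.8, 0.5, 0.9, 0.6)
  s2 <- solve_exact(model_means(p, r), ratios = r)
  expect_lt(max_rel_err(unclass(s2), unclass(p)), 1e-6)
})

test_that("solve_exact round-trips on random positive parameter draws", {
  withr::with_seed(99, {
    draws <- replicate(100, exp(runif(6, log(0.5), log(30))))
  })
  ok <- 0
  for (i in seq_len(ncol(draws))) {
    p <- do.call(spring_params, as.list(setNames(draws[, i], names(kappa_star()))))
    s <- tryCatch(solve_exact(model_means(p), seed = i), error = function(e) NULL)
    if (!is.null(s) && max_rel_err(unclass(s), unclass(p)) < 1e-6) ok <- ok + 1
  }
  expect_equal(ok, ncol(draws))
})

test_that("a uniform +1% shift of the target means shifts the solution by exactly +1%", {
  # the mean equations are homogeneous of degree one
  p <- kappa_star()
  s <- solve_exact(model_means(p) * 1.01)
  expect_equal(unclass(s), unclass(p) * 1.01, tolerance = 1e-6, ignore_attr = TRUE)
})
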