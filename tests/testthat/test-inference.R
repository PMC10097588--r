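# Likelihood, priors, the weighted objective, constrained MAP and Laplace
# credible intervals.

test_that("the Gaussian likelihood matches closed-form values on the standard-error model", {
  p <- kappa_star()
  m <- model_means(p)
  ds <- dataset_with_se(m, se = 1) # sample means exactly at the model means
  ll <- log_likelihood(ds, p)
  expect_equal(unname(ll), rep(-0.5 * log(2 * pi), 6), tolerance = 1e-12)

  # one standard error away: previous value minus 1/2
  m2 <- m
  m2["GM"] <- m["GM"] + 1
  ll2 <- log_likelihood(dataset_with_se(m2, se = 1), p)
  expect_equal(unname(ll2["GM"]), -0.5 * log(2 * pi) - 0.5, tolerance = 1e-12)
})

test_that("rescaling data, params and se by c shifts each log-density by -log(c)", {
  p <- kappa_star()
  m <- model_means(p) * 1.02 # off-model means so the quadratic term is active
  c0 <- 3.7
  ll1 <- log_likelihood(dataset_with_se(m, se = 0.5), p)
  p2 <- do.call(spring_params, as.list(unclass(p) * c0))
  ll2 <- log_likelihood(dataset_with_se(m * c0, se = 0.5 * c0), p2)
  expect_equal(unname(ll2 - ll1), rep(-log(c0), 6), tolerance = 1e-10)
})

test_that("priors evaluate their density inside the box and signal outside it", {
  flat <- prior_spec("flat", lower = 0.01, upper = 100)
  p <- kappa_star()
  expect_identical(log_prior(p, flat), 0)
  expect_identical(log_prior(spring_params(1, 1, 1, 1, 1, 1), flat), 0)
  expect_error(log_prior(spring_params(200, 1, 1, 1, 1, 1), flat),
               class = "cellspring_error_out_of_support")

  tn <- prior_spec("truncnorm", location = unclass(p), scale = rep(2, 6),
                   lower = 0.01, upper = 100)
  at_mode <- log_prior(p, tn)
  nudged <- do.call(spring_params, as.list(unclass(p) * 1.1))
  expect_gt(at_mode, log_prior(nudged, tn))
})

test_that("objective F reduces to the common value for equal perfect fits and is symmetric", {
  p <- kappa_star()
  ds <- dataset_with_se(model_means(p), se = 1)
  flat <- prior_spec("flat", lower = 1e-3, upper = 1e3)
  f <- objective_F(p, rep(1 / 6, 6), ds, priors = flat)
  expect_equal(f, -0.5 * log(2 * pi), tolerance = 1e-12)

  # permuting (dataset, weight) pairs leaves F unchanged
  w <- c(0.5, 0.2, 0.1, 0.05, 0.05, 0.1)
  perm <- c(3, 1, 2, 6, 4, 5)
  expect_equal(
    objective_F(p, w, ds, priors = flat),
    objective_F(p, w[perm], ds[perm, ], priors = flat),
    tolerance = 1e-12
  )

  # a larger discrepancy in one dataset strictly decreases F
  m2 <- model_means(p)
  m2["PS"] <- m2["PS"] + 0.5
  f2 <- objective_F(p, rep(1 / 6, 6), dataset_with_se(m2, se = 1), priors = flat)
  expect_lt(f2, f)

  expect_error(objective_F(p, rep(0.2, 6), ds, priors = flat),
               class = "cellspring_error_constraint_violation")
  expect_error(objective_F(p, c(0.6, 0.3, 0.025, 0.025, 0.025, 0.025), ds, priors = flat),
               class = "cellspring_error_constraint_violation")
})

test_that("the inner weight solution is the exact optimum of the linear program", {
  withr::with_seed(11, {
    for (i in 1:50) {
      ll <- rnorm(6, -5, 3)
      w <- optimal_weights(ll, c(0.05, 0.5))
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_true(all(w >= 0.05 - 1e-12 & w <= 0.5 + 1e-12))
      # exchange-argument optimality: whenever ll_i > ll_j, no budget can be
      # moved from j to i (i is at the ceiling or j is at the floor)
      for (a in 1:6) {
        for (b in 1:6) {
          if (ll[a] > ll[b]) {
            expect_true(w[a] >= 0.5 - 1e-12 || w[b] <= 0.05 + 1e-12)
          }
        }
      }
    }
  })
  expect_error(optimal_weights(rnorm(6), c(0.2, 0.5)),
               class = "cellspring_error_constraint_violation")
})

test_that("the MAP recovers forward-generated parameters and respects the simplex", {
  p <- kappa_star()
  fit <- maximize_posterior(dataset_from_summary(model_means(p)),
                            config = infer_config(n_starts = 6))
  expect_lt(max_rel_err(unclass(fit$params), unclass(p)), 0.01)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(fit$converged)
  # no regression against any multi-start initial value
  expect_true(all(fit$objective_value >= fit$starts$initial_value - 1e-8))
})

test_that("the KKT projected gradient at the MAP is below tolerance at realistic noise", {
  sc <- truth_scenario(kappa_star(), noise_cv = 0.1, n_per_treatment = 65, seed = 5)
  fit <- maximize_posterior(treatment_datasets(simulate_treatment_stiffness(sc)))
  expect_lt(fit$gradient_norm, 1e-6)
  expect_true(fit$converged)
})

test_that("MAP inference is deterministic given data and config", {
  sc <- truth_scenario(kappa_star(), noise_cv = 0.1, n_per_treatment = 65, seed = 8)
  ds <- treatment_datasets(simulate_treatment_stiffness(sc))
  f1 <- maximize_posterior(ds, config = infer_config(n_starts = 4))
  f2 <- maximize_posterior(ds, config = infer_config(n_starts = 4))
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$objective_value, f2$objective_value)
})

test_that("Laplace half-widths reproduce quadratic closed forms", {
  # 1-D quadratic with curvature 1/sigma^2: half-width sigma
  sigma <- 2.5
  H <- laplace_hessian(function(x) -(x - 1)^2 / (2 * sigma^2), 1)
  expect_equal(sqrt(1 / -H[1, 1]), sigma, tolerance = 1e-6)

  # isotropic 6-D quadratic
  H6 <- laplace_hessian(function(x) -sum(x^2) / (2 * sigma^2), rep(0.5, 6))
  expect_equal(sqrt(diag(solve(-H6))), rep(sigma, 6), tolerance = 1e-5)
})

test_that("credible_region reports positive half-widths and errors on flat curvature", {
  p <- kappa_star()
  sc <- truth_scenario(p, noise_cv = 0.1, n_per_treatment = 65, seed = 21)
  fit <- maximize_posterior(treatment_datasets(simulate_treatment_stiffness(sc)))
  cr <- credible_region(fit)
  expect_true(all(cr$halfwidths > 0))
  expect_equal(cr$hessian, t(cr$hessian))
  expect_equal(dim(cr$covariance), c(6, 6))

  # a flat (degenerate) objective has no curvature-based interval
  fake <- fit
  fake$objective_kappa <- function(kappa) 0
  expect_error(credible_region(fake), class = "cellspring_error_degenerate_curvature")
})

test_that("combined analysis with all-equal AFM means equals the unit-ratio analysis", {
  sc <- truth_scenario(kappa_star(), noise_cv = 0.1, n_per_treatment = 65, seed = 13)
  ds <- treatment_datasets(simulate_treatment_stiffness(sc))
  eq_means <- setNames(rep(3.5, 6), treatment_levels())
  f_comb <- run_combined_analysis(ds, eq_means)
  f_unit <- maximize_posterior(ds, ratios = ratio_set())
  expect_identical(unclass(f_comb$params), unclass(f_unit$params))
  expect_identical(f_comb$objective_value, f_unit$objective_value)
  expect_error(run_combined_analysis(ds, c(GM = 1)), class = "cellspring_error_invalid_input")
})

test_that("ratio-informed data analysed with the true ratios beats unit-ratio analysis", {
  # paired comparison of summed relative recovery error over seeded replicates
  p <- kappa_star()
  r <- ratio_set(0.8, 0.5, 0.9, 0.6)
  wins <- vapply(1:10, function(i) {
    sc <- truth_scenario(p, ratios = r, noise_cv = 0.1, n_per_treatment = 65, seed = 300 + i)
    ds <- treatment_datasets(simulate_treatment_stiffness(sc))
    cfg <- infer_config(n_starts = 6)
    e_true <- sum(abs(unclass(maximize_posterior(ds, ratios = r, config = cfg)$params) -
                        unclass(p)) / unclass(p))
    e_unit <- sum(abs(unclass(maximize_posterior(ds, ratios = ratio_set(), config = cfg)$params) -
                        unclass(p)) / unclass(p))
    e_true < e_unit
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("tidy, glance and autoplot summarise a spring_map fit", {
  fit <- maximize_posterior(dataset_from_summary(model_means(kappa_star())),
                            config = infer_config(n_starts = 4))
  td <- tidy(fit)
  expect_equal(td$term, names(kappa_star()))
  expect_true(all(td$conf.low < td$conf.high, na.rm = TRUE))
  gl <- glance(fit)
  expect_equal(gl$weight_sum, 1, tolerance = 1e-9)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("pairwise objective projections peak at the MAP", {
  fit <- maximize_posterior(dataset_from_summary(model_means(kappa_star())),
                            config = infer_config(n_starts = 4))
  grid <- map_projection(fit, c("k_cw_gm", "k_gm"), n = 15)
  expect_named(grid, c("k_cw_gm", "k_gm", "objective"))
  expect_equal(nrow(grid), 225)
  # the grid maximum cannot exceed the profiled objective at the MAP
  expect_lte(max(grid$objective), fit$objective_value + 1e-6)
})

test_that("a missing treatment dataset is a hard error naming the treatment", {
  d <- simulate_treatment_stiffness(default_truth())
  d <- d[d$treatment != "PS-MT", ]
  expect_error(treatment_datasets(d), "PS-MT",
               class = "cellspring_error_missing_treatment")
})
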