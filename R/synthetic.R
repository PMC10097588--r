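# Seeded synthetic-data generators: ground-truth spring scenarios,
# per-treatment stiffness samples, and micro/AFM force curves with contact
# points, additive Gaussian force noise and analytically known hysteresis.

#' Ground-truth scenario for synthetic treatment data
#'
#' @param params A [spring_params()] ground truth.
#' @param ratios A [ratio_set()] used in forward generation.
#' @param noise_cv Coefficient of variation of the per-cell stiffness around
#'   each treatment mean. Default 0.1.
#' @param n_per_treatment Cells per treatment. Default 65.
#' @param seed Master seed. Default 101.
#' @return A list of class `truth_scenario`.
#' @export
truth_scenario <- function(params, ratios = ratio_set(), noise_cv = 0.1,
                           n_per_treatment = 65, seed = 101) {
  params <- as_spring_params(params)
  if (noise_cv < 0) cs_abort("noise_cv must be >= 0", "invalid_parameter")
  if (n_per_treatment < 2) cs_abort("n_per_treatment must be >= 2", "invalid_parameter")
  structure(
    list(params = params, ratios = ratios, noise_cv = noise_cv,
         n_per_treatment = as.integer(n_per_treatment), seed = seed),
    class = "truth_scenario"
  )
}

#' The default trend-faithful ground truth
#'
#' Encodes the qualitative orderings the analysis is designed to resolve, on
#' the N/m scale of turgid BY-2 cells: the cell wall about twice as stiff
#' under turgor as after plasmolysis (`k_cw_gm = 2 * k_cw_ps`), residual
#' protoplasm about five times stiffer when turgid (`k_gm = 5 * k_ps`), and
#' the microtubule contribution about twice the actin-filament one
#' (`k_mt = 2 * k_af`). Trend-faithful, not value-faithful: the absolute
#' numbers are plausible scales, not measured values.
#'
#' @return A [truth_scenario()] with fixed defaults (deterministic).
#' @export
#' @examples
#' default_truth()$params
default_truth <- function() {
  truth_scenario(
    params = spring_params(
      k_cw_gm = 10, k_cw_ps = 5, k_gm = 20, k_ps = 4, k_mt = 3, k_af = 1.5
    ),
    ratios = ratio_set(),
    noise_cv = 0.1,
    n_per_treatment = 65,
    seed = 101
  )
}

#' Simulate per-treatment stiffness samples
#'
#' For each treatment, draws `n_per_treatment` per-cell stiffness values from
#' `Normal(mean = effective_stiffness(t), sd = noise_cv * mean)`, truncated
#' at zero by rejection. Each treatment uses its own seeded stream derived
#' from the scenario seed, so datasets are reproducible and order-independent.
#'
#' @param scenario A [truth_scenario()].
#' @return Long tibble with columns `treatment`, `cell_id`, `stiffness`
#'   (N/m); pass to [treatment_datasets()].
#' @export
#' @examples
#' d <- simulate_treatment_stiffness(default_truth())
#' dplyr::count(d, treatment)
simulate_treatment_stiffness <- function(scenario) {
  stopifnot(inherits(scenario, "truth_scenario"))
  means <- effective_means(scenario$params, scenario$ratios)
  purrr::map_dfr(treatment_levels(), function(t) {
    mu <- means[[t]]
    s <- scenario$noise_cv * mu
    if (s > 0 && stats::pnorm(0, mu, s) > 0.01) {
      cs_warn(sprintf(
        "treatment %s: >1%% of the Gaussian mass lies below zero at cv = %.2f; truncation biases the sample",
        t, scenario$noise_cv
      ), "truncation")
    }
    vals <- if (s == 0) {
      rep(mu, scenario$n_per_treatment)
    } else {
      with_stream(derive_seed(scenario$seed, paste0("stiffness/", t)), function() {
        v <- stats::rnorm(scenario$n_per_treatment, mu, s)
        while (any(v <= 0)) {
          v[v <= 0] <- stats::rnorm(sum(v <= 0), mu, s)
        }
        v
      })
    }
    tibble::tibble(
      treatment = t,
      cell_id = sprintf("%s-%03d", t, seq_along(vals)),
      stiffness = vals
    )
  })
}

#' Recipe for one synthetic force curve
#'
#' @param true_stiffness Linear contact stiffness k (N/m) for micro curves.
#' @param true_modulus Young's modulus E (Pa) for AFM (Hertz) curves.
#' @param contact_offset Displacement of the contact point (m).
#' @param baseline_sd Additive Gaussian force-noise sd (N).
#' @param n_samples Samples per segment.
#' @param max_force Peak force (N); `NULL` for an AFM curve draws one
#'   uniformly in 15-70 nN.
#' @param hysteresis_factor Retract force is the approach force scaled by
#'   `1 - hysteresis_factor * g(depth)` with the smooth bump
#'   `g(u) = 4u(1-u)` on normalised depth, so the enclosed loop area has the
#'   closed form `hysteresis_factor * k * depth_max^2 / 3` for micro curves;
#'   0 makes retract identical to approach.
#' @param tip_radius Sphere radius (m) for AFM curves. Default 0.5 um.
#' @param poisson_ratio Poisson's ratio used in forward generation.
#' @param sensor_stiffness When non-NULL, the written displacement is the
#'   measured one (`depth + F/S`), so the compliance correction is exercised.
#' @param pre_contact_fraction Fraction of approach samples spent on the
#'   pre-contact baseline (micro curves). Default 0.4, so the default
#'   baseline window of [detect_contact()] sits safely inside it.
#' @param treatment,cell_id Metadata passed to the curve.
#' @param seed Stream seed for the noise.
#' @return A list of class `curve_recipe`.
#' @export
curve_recipe <- function(true_stiffness = 10, true_modulus = 3e6,
                         contact_offset = 2e-6, baseline_sd = 0,
                         n_samples = 1000, max_force = 900e-6,
                         hysteresis_factor = 0.2, tip_radius = 0.5e-6,
                         poisson_ratio = 0.5, sensor_stiffness = NULL,
                         pre_contact_fraction = 0.4,
                         treatment = NULL, cell_id = "synthetic-1", seed = 1) {
  if (!is.null(max_force) && max_force <= 0) cs_abort("max_force must be > 0", "invalid_parameter")
  if (hysteresis_factor < 0 || hysteresis_factor > 1) {
    cs_abort("hysteresis_factor must lie in [0, 1]", "invalid_parameter")
  }
  structure(
    list(
      true_stiffness = true_stiffness, true_modulus = true_modulus,
      contact_offset = contact_offset, baseline_sd = baseline_sd,
      n_samples = n_samples, max_force = max_force,
      hysteresis_factor = hysteresis_factor, tip_radius = tip_radius,
      poisson_ratio = poisson_ratio, sensor_stiffness = sensor_stiffness,
      pre_contact_fraction = pre_contact_fraction,
      treatment = treatment, cell_id = cell_id, seed = seed
    ),
    class = "curve_recipe"
  )
}

#' Simulate a micro-indentation force curve
#'
#' Approach: baseline (zero force) up to the contact offset, then linear
#' loading `F = k * depth` until `max_force`; retract follows the loading
#' path scaled by `1 - hysteresis_factor * g(depth)`; additive Gaussian
#' noise on every force sample. Ground truth (stiffness, contact offset,
#' enclosed area) is embedded in the curve's `truth` attribute.
#'
#' @param recipe A [curve_recipe()].
#' @return A [force_curve()] with approach and retract segments.
#' @export
#' @examples
#' fc <- simulate_micro_curve(curve_recipe(true_stiffness = 12, baseline_sd = 0))
#' attr(fc, "truth")$stiffness
simulate_micro_curve <- function(recipe) {
  stopifnot(inherits(recipe, "curve_recipe"))
  k <- recipe$true_stiffness
  d_max <- recipe$max_force / k
  # two-segment grid: a baseline stretch before contact (so threshold-based
  # contact detection has a proper noise window), then the indentation ramp
  nb <- max(2L, floor(recipe$pre_contact_fraction * recipe$n_samples))
  delta <- c(
    seq(0, recipe$contact_offset, length.out = nb + 1)[1:nb],
    seq(recipe$contact_offset, recipe$contact_offset + d_max,
        length.out = recipe$n_samples - nb)
  )
  depth <- pmax(delta - recipe$contact_offset, 0)
  f_app <- k * depth
  u <- depth / d_max
  f_ret <- f_app * (1 - recipe$hysteresis_factor * 4 * u * (1 - u))
  noise <- if (recipe$baseline_sd > 0) {
    with_stream(derive_seed(recipe$seed, paste0("micro/", recipe$cell_id)), function() {
      stats::rnorm(2 * length(delta), 0, recipe$baseline_sd)
    })
  } else {
    numeric(2 * length(delta))
  }
  force <- c(f_app, rev(f_ret)) + noise
  disp <- c(delta, rev(delta))
  if (!is.null(recipe$sensor_stiffness)) {
    disp <- disp + force / recipe$sensor_stiffness
  }
  force_curve(
    displacement = disp, force = force,
    segment = rep(c("approach", "retract"), each = length(delta)),
    instrument = "micro",
    treatment = recipe$treatment,
    sensor_stiffness = recipe$sensor_stiffness,
    cell_id = recipe$cell_id,
    truth = list(
      stiffness = k, contact_offset = recipe$contact_offset,
      depth_max = d_max,
      area = recipe$hysteresis_factor * k * d_max^2 / 3
    )
  )
}

#' Simulate an AFM force curve (Hertz loading)
#'
#' Approach follows the spherical-indenter Hertz law
#' `F = (4/3) (E / (1 - nu^2)) sqrt(R) depth^(3/2)` up to the peak force
#' (drawn uniformly in 15-70 nN when the recipe leaves `max_force` NULL),
#' with additive Gaussian noise; the retract mirrors the approach scaled by
#' the hysteresis bump.
#'
#' @param recipe A [curve_recipe()]; `true_modulus` and `tip_radius` are
#'   used.
#' @return A [force_curve()] with instrument `"afm"` and the ground truth
#'   embedded.
#' @export
simulate_afm_curve <- function(recipe) {
  stopifnot(inherits(recipe, "curve_recipe"))
  e <- recipe$true_modulus
  if (is.null(e) || e <= 0) cs_abort("recipe needs a positive true_modulus", "invalid_parameter")
  cc <- (4 / 3) * (e / (1 - recipe$poisson_ratio^2)) * sqrt(recipe$tip_radius)
  fmax <- recipe$max_force %||% with_stream(
    derive_seed(recipe$seed, paste0("afm-fmax/", recipe$cell_id)),
    function() stats::runif(1, 15e-9, 70e-9)
  )
  d_max <- (fmax / cc)^(2 / 3)
  n <- recipe$n_samples
  delta <- seq(0, recipe$contact_offset + d_max, length.out = n)
  depth <- pmax(delta - recipe$contact_offset, 0)
  f_app <- cc * depth^1.5
  u <- depth / d_max
  f_ret <- f_app * (1 - recipe$hysteresis_factor * 4 * u * (1 - u))
  noise <- if (recipe$baseline_sd > 0) {
    with_stream(derive_seed(recipe$seed, paste0("afm/", recipe$cell_id)), function() {
      stats::rnorm(2 * n, 0, recipe$baseline_sd)
    })
  } else {
    numeric(2 * n)
  }
  force_curve(
    displacement = c(delta, rev(delta)),
    force = c(f_app, rev(f_ret)) + noise,
    segment = rep(c("approach", "retract"), each = n),
    instrument = "afm",
    treatment = recipe$treatment,
    tip_radius = recipe$tip_radius,
    cell_id = recipe$cell_id,
    truth = list(
      modulus = e, contact_offset = recipe$contact_offset,
      max_force = fmax, depth_max = d_max
    )
  )
}

#' Write a directory of synthetic curves with a ground-truth manifest
#'
#' Draws per-cell stiffness (micro) or modulus (AFM) values around the
#' scenario's treatment means, simulates one curve per cell, writes each as a
#' curve CSV and collects the embedded ground truth in `manifest.json`.
#'
#' @param dir Output directory (created if needed).
#' @param scenario A [truth_scenario()].
#' @param n_per_treatment Curves per treatment. Default 2.
#' @param instrument `"micro"` or `"afm"`.
#' @param baseline_sd Force-noise sd (N); defaults to 1e-7 (micro) or 5e-11
#'   (AFM).
#' @param hysteresis_factor See [curve_recipe()]. Default 0.2.
#' @return Invisibly, the manifest tibble (`file`, `cell_id`, `treatment`,
#'   plus the true stiffness/modulus).
#' @export
simulate_curve_set <- function(dir, scenario = default_truth(), n_per_treatment = 2,
                               instrument = c("micro", "afm"),
                               baseline_sd = NULL, hysteresis_factor = 0.2) {
  instrument <- match.arg(instrument)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  baseline_sd <- baseline_sd %||% if (instrument == "micro") 1e-7 else 5e-11
  means <- effective_means(scenario$params, scenario$ratios)
  rows <- purrr::map_dfr(treatment_levels(), function(t) {
    purrr::map_dfr(seq_len(n_per_treatment), function(i) {
      cell_id <- sprintf("%s-%s-%02d", instrument, t, i)
      draw <- with_stream(derive_seed(scenario$seed, paste0("curveset/", cell_id)), function() {
        stats::rnorm(1, means[[t]], scenario$noise_cv * means[[t]])
      })
      draw <- max(draw, 0.05 * means[[t]])
      if (instrument == "micro") {
        # force-controlled to 900 uN with a 30 um depth cap: soft plasmolysed
        # cells would otherwise be driven to unphysical depths on a uniform
        # grid too sparse for the 1 um stiffness window
        rec <- curve_recipe(
          true_stiffness = draw, baseline_sd = baseline_sd,
          max_force = min(900e-6, draw * 30e-6),
          hysteresis_factor = hysteresis_factor,
          treatment = t, cell_id = cell_id, seed = scenario$seed
        )
        fc <- simulate_micro_curve(rec)
        truth_val <- c(true_stiffness = draw)
      } else {
        rec <- curve_recipe(
          true_modulus = draw * 1e6, baseline_sd = baseline_sd,
          contact_offset = 5e-8, n_samples = 500, max_force = NULL,
          hysteresis_factor = hysteresis_factor,
          treatment = t, cell_id = cell_id, seed = scenario$seed
        )
        fc <- simulate_afm_curve(rec)
        truth_val <- c(true_modulus = draw * 1e6)
      }
      file <- file.path(dir, paste0(cell_id, ".csv"))
      write_force_curve(fc, file)
      tibble::tibble(
        file = basename(file), cell_id = cell_id, treatment = t,
        truth = unname(truth_val)
      )
    })
  })
  names(rows)[names(rows) == "truth"] <-
    if (instrument == "micro") "true_stiffness" else "true_modulus"
  jsonlite::write_json(
    list(instrument = instrument, seed = scenario$seed, curves = rows),
    file.path(dir, "manifest.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(rows)
}
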