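# Force-curve processing: sensor calibration, compliance correction, contact
# detection, stiffness / Hertz-modulus fits, dissipated energy.

#' Estimate sensor stiffness from a rigid-substrate reference indentation
#'
#' On a rigid substrate all measured displacement is sensor deflection, so the
#' slope of force against displacement over the final part of the approach is
#' the sensor stiffness S. The default window is the last 1 um of approach
#' displacement.
#'
#' @param reference_curve A [force_curve()] recorded on a rigid substrate
#'   (e.g. a coated glass slide).
#' @param window_length Length of the displacement window at the end of the
#'   approach, in metres. Default `1e-6`.
#' @return Sensor stiffness S in N/m.
#' @export
#' @examples
#' d <- seq(0, 3e-6, length.out = 300)
#' ref <- force_curve(d, 1000 * d, instrument = "micro")
#' estimate_sensor_stiffness(ref)
estimate_sensor_stiffness <- function(reference_curve, window_length = 1e-6) {
  app <- approach_segment(reference_curve)
  span <- max(app$displacement) - min(app$displacement)
  if (window_length > span) {
    cs_abort("window_length exceeds the approach displacement span", "degenerate_window")
  }
  sel <- app$displacement >= max(app$displacement) - window_length
  if (sum(sel) < 3) {
    cs_abort("fewer than 3 samples in the calibration window", "degenerate_window")
  }
  s <- ols_slope(app$displacement[sel], app$force[sel])
  if (!is.finite(s) || s <= 0) {
    cs_abort("non-positive slope in reference indentation; not a rigid-substrate record?",
             "invalid_reference")
  }
  s
}

# least-squares slope of y on x (with intercept)
ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) return(NaN)
  sum(xc * (y - mean(y))) / sxx
}

#' Subtract sensor compliance from measured displacement
#'
#' The measured displacement includes the deflection of the force sensor
#' itself; the corrected indentation depth is
#' `delta_corr = delta_measured - F / S` per sample, where S is the sensor
#' stiffness. Force and metadata are unchanged.
#'
#' @param curve A [force_curve()].
#' @param sensor_stiffness Sensor stiffness S (N/m). Defaults to the value
#'   stored on the curve.
#' @return A corrected [force_curve()].
#' @export
correct_compliance <- function(curve, sensor_stiffness = attr(curve, "sensor_stiffness")) {
  if (is.null(sensor_stiffness) || !is.finite(sensor_stiffness) || sensor_stiffness <= 0) {
    cs_abort("sensor_stiffness must be a positive number", "invalid_parameter")
  }
  curve$displacement <- curve$displacement - curve$force / sensor_stiffness
  curve
}

#' Detect the contact point by force thresholding
#'
#' The force baseline (mean and sd) is estimated over the first
#' `baseline_fraction` of the approach samples. Contact is the first approach
#' sample whose force exceeds `baseline_mean + threshold_multiplier * baseline_sd`
#' and stays above it for at least `persistence` consecutive samples (spike
#' rejection). When the baseline is noiseless (sd = 0) a threshold floor of
#' `3 * force_resolution` above the baseline mean applies.
#'
#' @param curve A [force_curve()] (compliance-corrected or raw; contact
#'   detection uses force only).
#' @param baseline_fraction Fraction of approach samples treated as baseline,
#'   in (0, 0.9). Default 0.3.
#' @param threshold_multiplier Threshold in baseline standard deviations.
#'   Default 5.
#' @param persistence Consecutive samples required above threshold. Default 5.
#' @param force_resolution Instrument force resolution (N) used for the
#'   zero-noise threshold floor. Default `1e-12`.
#' @return A list of class `contact_annotation` with fields `contact_index`
#'   (index into the full curve), `baseline_mean`, `baseline_sd`, `threshold`.
#' @export
detect_contact <- function(curve, baseline_fraction = 0.3, threshold_multiplier = 5,
                           persistence = 5, force_resolution = 1e-12) {
  app <- approach_segment(curve)
  n <- nrow(app)
  if (n < 10) cs_abort("approach segment needs at least 10 samples", "invalid_curve")
  if (baseline_fraction <= 0 || baseline_fraction >= 0.9) {
    cs_abort("baseline_fraction must be in (0, 0.9)", "invalid_parameter")
  }
  nb <- max(2L, floor(baseline_fraction * n))
  base <- app$force[seq_len(nb)]
  bmean <- mean(base)
  bsd <- stats::sd(base)
  thr <- bmean + threshold_multiplier * bsd
  if (!is.finite(thr) || thr <= bmean) {
    thr <- bmean + 3 * force_resolution
  }
  above <- app$force > thr
  idx <- first_run(above, persistence)
  if (is.na(idx)) {
    cs_abort("no persistent threshold crossing found: curve appears to be all baseline",
             "no_contact")
  }
  # a drifting or rising baseline window biases the threshold: compare the
  # two halves of the window against the first half's standard error
  h1 <- base[seq_len(nb %/% 2)]
  h2 <- base[(nb %/% 2 + 1):nb]
  drift_tol <- threshold_multiplier * stats::sd(h1) / sqrt(length(h1)) + 3 * force_resolution
  if (idx <= nb || abs(mean(h2) - mean(h1)) > drift_tol) {
    cs_warn("baseline window overlaps the force rise; baseline statistics may be biased",
            "unstable_baseline")
  }
  structure(
    list(contact_index = idx, baseline_mean = bmean, baseline_sd = bsd, threshold = thr),
    class = "contact_annotation"
  )
}

# first index i with x[i..i+len-1] all TRUE; NA if none
first_run <- function(x, len) {
  x[is.na(x)] <- FALSE
  if (!any(x)) return(NA_integer_)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= len
  if (!any(ok)) return(NA_integer_)
  starts[which(ok)[1]]
}

#' @export
print.contact_annotation <- function(x, ...) {
  cat(sprintf(
    "<contact_annotation> index %d | baseline %.3g +/- %.3g N | threshold %.3g N\n",
    x$contact_index, x$baseline_mean, x$baseline_sd, x$threshold
  ))
  invisible(x)
}

# post-contact approach samples as (depth, force), depth = displacement - contact displacement
post_contact <- function(curve, annotation) {
  app <- approach_segment(curve)
  i0 <- annotation$contact_index
  if (i0 < 1 || i0 > nrow(app)) cs_abort("contact_index outside the approach segment", "invalid_annotation")
  tibble::tibble(
    depth = app$displacement[i0:nrow(app)] - app$displacement[i0],
    force = app$force[i0:nrow(app)]
  )
}

#' Fit the initial effective stiffness after contact
#'
#' Least-squares slope of force against corrected indentation depth
#' (`depth = displacement - displacement[contact]`) over a shallow
#' post-contact window. The micro-indentation dialect uses a depth window
#' (default the first 1 um of indentation); the AFM dialect uses the samples
#' up to a fraction of the maximum force (default the first 10%).
#'
#' @param curve A compliance-corrected [force_curve()].
#' @param annotation A `contact_annotation` from [detect_contact()].
#' @param window Either `list(depth = metres)` or
#'   `list(force_fraction = fraction)`.
#' @return Stiffness k in N/m.
#' @export
fit_initial_stiffness <- function(curve, annotation, window = list(depth = 1e-6)) {
  pc <- post_contact(curve, annotation)
  if (!is.null(window$depth)) {
    if (window$depth > max(pc$depth)) {
      cs_abort("requested depth window exceeds the maximum indentation depth", "degenerate_window")
    }
    sel <- pc$depth <= window$depth
  } else if (!is.null(window$force_fraction)) {
    sel <- pc$force <= window$force_fraction * max(pc$force)
  } else {
    cs_abort("window must specify either depth or force_fraction", "invalid_parameter")
  }
  if (sum(sel) < 3) cs_abort("fewer than 3 samples in the fit window", "degenerate_window")
  ols_slope(pc$depth[sel], pc$force[sel])
}

#' Fit the Hertz indentation modulus (spherical tip on elastic half-space)
#'
#' Fits the Hertz contact law for a rigid spherical indenter,
#' `F = (4/3) * (E / (1 - nu^2)) * sqrt(R) * depth^(3/2)`,
#' to the post-contact approach by linear least squares in the transformed
#' predictor `depth^(3/2)` (regression through the origin), and returns the
#' Young's modulus E.
#'
#' @param curve An AFM [force_curve()].
#' @param annotation A `contact_annotation`.
#' @param tip_radius Indenter sphere radius R (m). Defaults to the curve's
#'   stored value.
#' @param poisson_ratio Poisson's ratio nu of the sample. Default 0.5
#'   (incompressible soft matter).
#' @param max_depth_ratio Warn when the maximum depth exceeds this fraction of
#'   the tip radius (half-space validity). Default 0.2.
#' @param refine_contact Refine the contact displacement within one sampling
#'   step of the annotated contact by profiling the Hertz least squares over
#'   the contact point (removes the sampling-grid quantisation bias of the
#'   threshold detector). Default TRUE.
#' @return Young's modulus E in Pa.
#' @export
fit_hertz_modulus <- function(curve, annotation, tip_radius = attr(curve, "tip_radius"),
                              poisson_ratio = 0.5, max_depth_ratio = 0.2,
                              refine_contact = TRUE) {
  if (!identical(attr(curve, "instrument"), "afm")) {
    cs_abort("Hertz modulus fits are defined for the AFM dialect", "invalid_parameter")
  }
  if (is.null(tip_radius) || tip_radius <= 0) {
    cs_abort("tip_radius must be a positive length in metres", "invalid_parameter")
  }
  if (poisson_ratio < 0 || poisson_ratio > 0.5 + 1e-9) {
    cs_abort("poisson_ratio must lie in [0, 0.5]", "invalid_parameter")
  }
  app <- approach_segment(curve)
  i0 <- annotation$contact_index
  if (i0 < 1 || i0 > nrow(app)) cs_abort("contact_index outside the approach segment", "invalid_annotation")
  d0 <- app$displacement[i0]
  hertz_e <- function(contact_disp) {
    depth <- app$displacement - contact_disp
    sel <- depth > 0
    if (sum(sel) < 3) return(NA_real_)
    x <- (4 / 3) * sqrt(tip_radius) * depth[sel]^1.5 / (1 - poisson_ratio^2)
    f <- app$force[sel]
    e <- sum(x * f) / sum(x^2)
    attr(e, "sse") <- sum((f - e * x)^2)
    e
  }
  if (refine_contact && i0 > 1) {
    # the threshold detector fires once the force clears the noise floor,
    # which on a shallow 3/2-power rise can be many samples past true
    # contact; profile the least squares over the contact displacement in a
    # window reaching back from the detected index
    lo <- app$displacement[max(1L, i0 - 25L)]
    hi <- app$displacement[min(i0 + 1L, nrow(app))]
    if (hi > lo) {
      opt <- stats::optimize(
        function(cd) {
          e <- hertz_e(cd)
          if (is.na(e) || e <= 0) Inf else attr(e, "sse")
        },
        interval = c(lo, hi), tol = (hi - lo) * 1e-8
      )
      if (is.finite(opt$objective)) d0 <- opt$minimum
    }
  }
  e <- hertz_e(d0)
  if (is.na(e)) cs_abort("fewer than 3 post-contact samples", "degenerate_window")
  depth_max <- max(app$displacement) - d0
  if (depth_max / tip_radius > max_depth_ratio) {
    cs_warn(sprintf(
      "maximum depth is %.0f%% of the tip radius; half-space Hertz assumptions degrade",
      100 * depth_max / tip_radius
    ), "hertz_validity")
  }
  if (!is.finite(e) || e <= 0) {
    cs_abort("fitted modulus is non-positive; approach force does not increase with depth",
             "fit_failure")
  }
  as.numeric(e)
}

#' Energy dissipated between the approach and retract curves
#'
#' Trapezoidal area enclosed between the approach (loading) and retract
#' (unloading) force-displacement paths over their common displacement range.
#' Both segments are resampled onto a common uniform grid by linear
#' interpolation before subtraction. Tests that never reach `force_threshold`
#' are excluded (a classed error, not a silent NA). Negative (adhesive)
#' retract forces enter the signed area by default; `clip_negative = TRUE`
#' clips them at zero.
#'
#' @param curve A [force_curve()] with both segments.
#' @param force_threshold Minimum peak approach force (N) for a test to be
#'   included. Default 0.
#' @param n_grid Number of resampling grid points. Default 1000.
#' @param clip_negative Clip negative retract forces at zero. Default FALSE.
#' @return Dissipated energy W in joules.
#' @export
dissipated_energy <- function(curve, force_threshold = 0, n_grid = 1000,
                              clip_negative = FALSE) {
  app <- approach_segment(curve)
  ret <- retract_segment(curve)
  if (nrow(ret) < 2) {
    cs_abort("curve has no retract segment; cannot compute a hysteresis loop",
             "incomplete_curve")
  }
  if (max(app$force) < force_threshold) {
    cs_abort(sprintf(
      "peak approach force %.3g N is below the %.3g N threshold; test excluded",
      max(app$force), force_threshold
    ), "below_threshold")
  }
  lo <- max(min(app$displacement), min(ret$displacement))
  hi <- min(max(app$displacement), max(ret$displacement))
  if (hi <= lo) cs_abort("approach and retract displacement ranges do not overlap", "incomplete_curve")
  grid <- seq(lo, hi, length.out = n_grid)
  fa <- stats::approx(app$displacement, app$force, xout = grid, ties = mean)$y
  fr <- stats::approx(ret$displacement, ret$force, xout = grid, ties = mean)$y
  if (clip_negative) fr <- pmax(fr, 0)
  h <- diff(grid)
  dy <- fa - fr
  sum((dy[-1] + dy[-length(dy)]) / 2 * h)
}

#' Process one force curve into a per-cell measurement row
#'
#' Runs the full per-curve pipeline: optional compliance correction, contact
#' detection, initial-stiffness fit (depth window for the micro dialect,
#' force-fraction window for AFM), Hertz modulus (AFM only) and dissipated
#' energy (curves with a retract segment; micro dialect by convention).
#'
#' @param curve A [force_curve()].
#' @param config Dialect parameters, see [pipeline_config()].
#' @return One-row tibble with columns `cell_id`, `treatment`, `instrument`,
#'   `contact_index`, `stiffness` (N/m), `modulus` (Pa, AFM else NA),
#'   `dissipated_energy` (J, NA when excluded or no retract), `max_depth` (m).
#' @export
process_curve <- function(curve, config = pipeline_config()) {
  meta <- curve_meta(curve)
  s <- meta$sensor_stiffness
  if (!is.null(s)) curve <- correct_compliance(curve, s)
  ann <- detect_contact(
    curve,
    baseline_fraction = config$contact$baseline_fraction,
    threshold_multiplier = config$contact$threshold_multiplier,
    persistence = config$contact$persistence,
    force_resolution = config$contact$force_resolution
  )
  window <- if (meta$instrument == "afm") {
    list(force_fraction = config$windows$afm_force_fraction)
  } else {
    list(depth = config$windows$micro_depth)
  }
  k <- fit_initial_stiffness(curve, ann, window)
  modulus <- NA_real_
  if (meta$instrument == "afm" && !is.null(meta$tip_radius)) {
    modulus <- fit_hertz_modulus(
      curve, ann,
      tip_radius = meta$tip_radius,
      poisson_ratio = config$hertz$poisson_ratio,
      max_depth_ratio = config$hertz$max_depth_ratio
    )
  }
  energy <- NA_real_
  energy_excluded <- FALSE
  if (nrow(retract_segment(curve)) >= 2) {
    energy <- tryCatch(
      dissipated_energy(curve,
        force_threshold = config$energy$force_threshold,
        clip_negative = config$energy$clip_negative
      ),
      cellspring_error_below_threshold = function(e) {
        energy_excluded <<- TRUE
        NA_real_
      }
    )
  }
  pc <- post_contact(curve, ann)
  tibble::tibble(
    cell_id = meta$cell_id %||% NA_character_,
    treatment = meta$treatment %||% NA_character_,
    instrument = meta$instrument,
    contact_index = ann$contact_index,
    stiffness = k,
    modulus = modulus,
    dissipated_energy = energy,
    energy_excluded = energy_excluded,
    max_depth = max(pc$depth)
  )
}
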