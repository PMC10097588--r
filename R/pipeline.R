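# End-to-end orchestration: configuration, batch curve processing, inference
# driver with run manifest, and report rendering.

#' Pipeline configuration
#'
#' All dialect parameters and inference settings in one place. Defaults
#' mirror the instruments the package targets: micro-indentation to ~900 uN
#' with a 1 um initial-stiffness depth window, AFM with a 1 um silica bead
#' (radius 0.5 um) and a 10%-of-max-force stiffness window, Poisson's ratio
#' 0.5 for the Hertz fit.
#'
#' @param micro_depth Micro-dialect stiffness fit window (m). Default 1e-6.
#' @param afm_force_fraction AFM-dialect force fraction. Default 0.1.
#' @param poisson_ratio Poisson's ratio for the Hertz fit. Default 0.5.
#' @param tip_radius Default AFM bead radius (m) when a curve carries none.
#' @param max_depth_ratio Hertz validity warning threshold. Default 0.2.
#' @param baseline_fraction,threshold_multiplier,persistence,force_resolution
#'   Contact-detection parameters, see [detect_contact()].
#' @param energy_force_threshold Minimum peak approach force (N) for a test
#'   to enter the dissipated-energy analysis. Default 0 (include all).
#' @param clip_negative Clip adhesive (negative) retract forces at zero in
#'   the energy integral. Default FALSE.
#' @param mode `"unit_ratios"` (micro-only analysis) or `"combined"` (AFM
#'   ratios substituted into the spring equations).
#' @param infer An [infer_config()].
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(micro_depth = 1e-6, afm_force_fraction = 0.1,
                            poisson_ratio = 0.5, tip_radius = 0.5e-6,
                            max_depth_ratio = 0.2,
                            baseline_fraction = 0.3, threshold_multiplier = 5,
                            persistence = 5, force_resolution = 1e-12,
                            energy_force_threshold = 0, clip_negative = FALSE,
                            mode = c("unit_ratios", "combined"),
                            infer = infer_config()) {
  mode <- match.arg(mode)
  structure(
    list(
      windows = list(micro_depth = micro_depth, afm_force_fraction = afm_force_fraction),
      hertz = list(poisson_ratio = poisson_ratio, tip_radius = tip_radius,
                   max_depth_ratio = max_depth_ratio),
      contact = list(baseline_fraction = baseline_fraction,
                     threshold_multiplier = threshold_multiplier,
                     persistence = persistence, force_resolution = force_resolution),
      energy = list(force_threshold = energy_force_threshold, clip_negative = clip_negative),
      mode = mode,
      infer = infer
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [pipeline_config()] and [infer_config()]
#' (under an `infer:` block); missing keys keep their defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  infer_args <- raw$infer %||% list()
  raw$infer <- NULL
  args <- raw[names(raw) %in% names(formals(pipeline_config))]
  args$infer <- do.call(infer_config, infer_args)
  do.call(pipeline_config, args)
}

#' Process a batch of force-curve files into a measurement table
#'
#' Reads every file, runs [process_curve()] on each, and collects one row per
#' successful curve. Unreadable or invalid files are recorded in the error
#' log and skipped (the run continues); an empty input set is a hard error.
#'
#' @param paths Character vector of curve-file paths, or a single directory
#'   (all `*.csv` inside are taken).
#' @param config A [pipeline_config()].
#' @return Tibble of per-cell measurements (see [process_curve()]) with
#'   attributes `log` (per-file tibble: file, status, message) and
#'   `config_hash`.
#' @export
process_curves <- function(paths, config = pipeline_config()) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.csv$", full.names = TRUE)
  }
  if (length(paths) == 0) cs_abort("no input curve files", "empty_input")
  results <- purrr::map(paths, function(p) {
    tryCatch(
      {
        row <- process_curve(read_force_curve(p), config)
        list(row = row, log = tibble::tibble(
          file = basename(p), status = "ok",
          message = if (row$energy_excluded) "energy excluded: below force threshold" else ""
        ))
      },
      error = function(e) {
        list(row = NULL, log = tibble::tibble(
          file = basename(p), status = "error", message = conditionMessage(e)
        ))
      }
    )
  })
  rows <- purrr::map_dfr(results, "row")
  log <- purrr::map_dfr(results, "log")
  if (nrow(rows) == 0) cs_abort("no curve file could be processed", "empty_input")
  structure(rows, log = log, config_hash = config_hash(unclass(config)))
}

#' Run the spring-model inference on a measurement table
#'
#' Groups the per-cell micro-indentation stiffness by treatment, builds the
#' six treatment datasets, and maximises the combined posterior — with unit
#' ratios (`mode = "unit_ratios"`) or with AFM-derived cell-wall ratios
#' (`mode = "combined"`, which requires the six AFM means).
#'
#' @param measurements Data frame with `treatment` and `stiffness` columns
#'   (e.g. from [process_curves()]), micro-indentation rows.
#' @param config A [pipeline_config()]; `config$mode` selects the analysis.
#' @param afm_means Named vector of six AFM mean cell-wall stiffnesses
#'   (N/m); required when `mode = "combined"`.
#' @param priors Optional [prior_spec()].
#' @return A list of class `spring_bundle`: `fit` (the `spring_map`),
#'   `summary` ([summarize_treatments()] output when raw values are
#'   available), `ratios`, `mode` and `manifest` (config hash, seed,
#'   package version, timestamp-free provenance).
#' @export
infer_stiffness <- function(measurements, config = pipeline_config(),
                            afm_means = NULL, priors = NULL) {
  datasets <- treatment_datasets(measurements)
  if (config$mode == "combined") {
    if (is.null(afm_means)) {
      cs_abort("mode 'combined' needs the six AFM treatment means", "invalid_input")
    }
    ratios <- afm_ratios(afm_means)
  } else {
    ratios <- ratio_set()
  }
  fit <- maximize_posterior(datasets, ratios = ratios, priors = priors,
                            config = config$infer)
  summary <- tryCatch(summarize_treatments(datasets), cellspring_error = function(e) NULL)
  structure(
    list(
      fit = fit,
      summary = summary,
      ratios = ratios,
      mode = config$mode,
      manifest = list(
        config_hash = config_hash(list(config = unclass(config),
                                       afm_means = afm_means)),
        seed = config$infer$seed,
        mode = config$mode,
        package_version = as.character(utils::packageVersion("cellspring"))
      )
    ),
    class = "spring_bundle"
  )
}

#' Write a result bundle to disk
#'
#' Writes `map_result.json` (MAP estimates, half-widths, weights,
#' diagnostics, manifest), `stiffness_components.csv` (bar-chart-ready
#' table: component, estimate, half-width), and when available
#' `treatment_summary.csv` and `ks_matrix.csv`.
#'
#' @param bundle A `spring_bundle` from [infer_stiffness()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fit <- bundle$fit
  paths <- character(0)
  js <- list(
    map = as.list(unclass(fit$params)),
    credible_halfwidths = as.list(fit$credible_halfwidths),
    weights = as.list(fit$weights),
    objective_value = fit$objective_value,
    converged = fit$converged,
    gradient_norm = fit$gradient_norm,
    n_starts = fit$n_starts,
    ratios = as.list(unclass(bundle$ratios)),
    manifest = bundle$manifest
  )
  p <- file.path(dir, "map_result.json")
  jsonlite::write_json(js, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  p <- file.path(dir, "stiffness_components.csv")
  utils::write.csv(tidy(fit), p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(bundle$summary)) {
    p <- file.path(dir, "treatment_summary.csv")
    utils::write.csv(bundle$summary$summary, p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(dir, "ks_matrix.csv")
    utils::write.csv(as.data.frame(bundle$summary$ks_matrix), p, row.names = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Render a result bundle as a markdown report
#'
#' Deterministic, idempotent rendering of the treatment summary, the
#' pairwise KS table and the deconvoluted stiffness components with their
#' 68% credible half-widths, stamped with the run's config hash.
#'
#' @param bundle A `spring_bundle`.
#' @param path Optional file to write the report to.
#' @return The report as a character vector of markdown lines (invisibly
#'   when `path` is given).
#' @export
render_report <- function(bundle, path = NULL) {
  fit <- bundle$fit
  td <- tidy(fit)
  lines <- c(
    "# Spring-model deconvolution report",
    "",
    sprintf("- mode: %s", bundle$mode),
    sprintf("- config hash: %s", bundle$manifest$config_hash),
    sprintf("- converged: %s (projected gradient %.2e, %d starts)",
            fit$converged, fit$gradient_norm, fit$n_starts),
    "",
    "## Deconvoluted stiffness components (N/m, MAP +/- 68%)",
    "",
    "| component | estimate | half-width |",
    "|---|---|---|",
    sprintf("| %s | %.4g | %.4g |", td$term, td$estimate, td$std.error),
    "",
    "## Objective weights",
    "",
    paste0("| ", paste(names(fit$weights), collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(fit$weights)), collapse = "|"), "|"),
    paste0("| ", paste(sprintf("%.3f", fit$weights), collapse = " | "), " |")
  )
  if (!is.null(bundle$summary)) {
    s <- bundle$summary$summary
    kp <- bundle$summary$ks_pairs
    lines <- c(
      lines, "",
      "## Treatment summary (N/m)",
      "",
      "| treatment | n | mean | sd | se | median |",
      "|---|---|---|---|---|---|",
      sprintf("| %s | %d | %.4g | %.4g | %.4g | %.4g |",
              s$treatment, s$n, s$mean, s$sd, s$se, s$median),
      "",
      "## Pairwise Kolmogorov-Smirnov tests",
      "",
      "| pair | p-value | |",
      "|---|---|---|",
      sprintf("| %s vs %s | %.3g | %s |",
              kp$treatment_1, kp$treatment_2, kp$p_value, kp$stars)
    )
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
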