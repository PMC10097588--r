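#' Construct a force curve
#'
#' A force curve is the raw record of one indentation test: sampled probe
#' displacement and measured force, split into an approach (loading) and an
#' optional retract (unloading) segment, with instrument metadata attached as
#' attributes. All values are SI internally (metres, newtons); the file reader
#' converts from declared units.
#'
#' @param displacement Numeric vector of probe positions (m).
#' @param force Numeric vector of forces (N), same length as `displacement`.
#' @param segment Character/factor per-sample labels, `"approach"` or
#'   `"retract"`; every approach sample must precede every retract sample and
#'   approach displacement must be non-decreasing.
#' @param instrument `"micro"` (micro-indentation, forces up to ~900 uN,
#'   um-scale depths) or `"afm"` (AFM, 15-70 nN, nm-scale depths).
#' @param treatment Optional treatment label (see [treatment_levels()]).
#' @param sensor_stiffness Optional force-sensor stiffness S (N/m), used by
#'   [correct_compliance()].
#' @param tip_radius Optional spherical indenter radius (m), used by
#'   [fit_hertz_modulus()].
#' @param cell_id Opaque identifier of the tested cell.
#' @param truth Optional named list of ground-truth values carried by
#'   synthetic curves (see [simulate_micro_curve()]).
#' @return A tibble of class `force_curve` with columns `displacement`,
#'   `force`, `segment`, and the metadata stored as attributes.
#' @export
#' @examples
#' fc <- force_curve(
#'   displacement = seq(0, 2e-6, length.out = 50),
#'   force = pmax(seq(0, 2e-6, length.out = 50) - 1e-6, 0) * 10,
#'   instrument = "micro"
#' )
#' fc
force_curve <- function(displacement, force,
                        segment = rep("approach", length(displacement)),
                        instrument = c("micro", "afm"),
                        treatment = NULL,
                        sensor_stiffness = NULL,
                        tip_radius = NULL,
                        cell_id = "cell-1",
                        truth = NULL) {
  instrument <- match.arg(instrument)
  if (length(displacement) != length(force)) {
    cs_abort("displacement and force must have the same length", "invalid_curve")
  }
  if (length(displacement) < 2) {
    cs_abort("a force curve needs at least 2 samples", "invalid_curve")
  }
  segment <- as.character(segment)
  if (!all(segment %in% c("approach", "retract"))) {
    cs_abort("segment labels must be 'approach' or 'retract'", "invalid_curve")
  }
  if (is.unsorted(match(segment, c("approach", "retract")))) {
    cs_abort("approach samples must precede retract samples", "invalid_curve")
  }
  app <- displacement[segment == "approach"]
  if (length(app) >= 2 && any(diff(app) < 0)) {
    cs_abort("approach displacement must be non-decreasing", "invalid_curve")
  }
  out <- tibble::tibble(
    displacement = as.numeric(displacement),
    force = as.numeric(force),
    segment = segment
  )
  structure(
    out,
    class = c("force_curve", class(out)),
    instrument = instrument,
    treatment = if (!is.null(treatment)) as.character(as_treatment(treatment)),
    sensor_stiffness = sensor_stiffness,
    tip_radius = tip_radius,
    cell_id = cell_id,
    truth = truth
  )
}

#' @export
print.force_curve <- function(x, ...) {
  meta <- curve_meta(x)
  cat(sprintf(
    "<force_curve> %s | %s%s | %d approach + %d retract samples\n",
    meta$cell_id %||% "?", meta$instrument,
    if (!is.null(meta$treatment)) paste0(" | ", meta$treatment) else "",
    sum(x$segment == "approach"), sum(x$segment == "retract")
  ))
  NextMethod()
  invisible(x)
}

curve_meta <- function(curve) {
  list(
    instrument = attr(curve, "instrument"),
    treatment = attr(curve, "treatment"),
    sensor_stiffness = attr(curve, "sensor_stiffness"),
    tip_radius = attr(curve, "tip_radius"),
    cell_id = attr(curve, "cell_id"),
    truth = attr(curve, "truth")
  )
}

approach_segment <- function(curve) curve[curve$segment == "approach", , drop = FALSE]
retract_segment  <- function(curve) curve[curve$segment == "retract", , drop = FALSE]

#' Read and write force-curve files
#'
#' Force curves are exchanged as delimited text with `# key=value` comment
#' headers carrying the metadata, followed by a CSV body with columns
#' `displacement`, `force`, `segment`. Recognised header keys:
#' `displacement_unit` (m/mm/um/nm), `force_unit` (N/mN/uN/nN/pN),
#' `instrument`, `treatment`, `sensor_stiffness` (N/m), `tip_radius` (m),
#' `cell_id`, and `truth_*` (ground-truth values embedded by the synthetic
#' generator). Values are converted to SI on read; `write_force_curve()`
#' writes SI units at full double precision so a write/read round trip is
#' bit-identical.
#'
#' @param path File path.
#' @return `read_force_curve()` returns a [force_curve()].
#' @export
read_force_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  meta <- parse_header(hdr)
  df <- utils::read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE)
  need <- c("displacement", "force", "segment")
  if (!all(need %in% names(df))) {
    cs_abort(sprintf("curve file %s lacks columns: %s", path,
                     paste(setdiff(need, names(df)), collapse = ", ")),
             "invalid_file")
  }
  dfac <- si_factor(meta$displacement_unit %||% "m", .length_units, "displacement")
  ffac <- si_factor(meta$force_unit %||% "N", .force_units, "force")
  truth_keys <- grep("^truth_", names(meta), value = TRUE)
  truth <- if (length(truth_keys) > 0) {
    stats::setNames(
      lapply(meta[truth_keys], as.numeric),
      sub("^truth_", "", truth_keys)
    )
  }
  force_curve(
    displacement = df$displacement * dfac,
    force = df$force * ffac,
    segment = df$segment,
    instrument = meta$instrument %||% "micro",
    treatment = meta$treatment,
    sensor_stiffness = if (!is.null(meta$sensor_stiffness)) as.numeric(meta$sensor_stiffness),
    tip_radius = if (!is.null(meta$tip_radius)) as.numeric(meta$tip_radius),
    cell_id = meta$cell_id %||% basename(path),
    truth = truth
  )
}

parse_header <- function(hdr) {
  hdr <- sub("^#\\s*", "", hdr)
  hdr <- hdr[grepl("=", hdr)]
  keys <- sub("=.*$", "", hdr)
  vals <- sub("^[^=]*=", "", hdr)
  stats::setNames(as.list(trimws(vals)), trimws(keys))
}

#' @param curve A [force_curve()].
#' @rdname read_force_curve
#' @export
write_force_curve <- function(curve, path) {
  meta <- curve_meta(curve)
  hdr <- c(
    "# displacement_unit=m",
    "# force_unit=N",
    paste0("# instrument=", meta$instrument),
    if (!is.null(meta$treatment)) paste0("# treatment=", meta$treatment),
    if (!is.null(meta$sensor_stiffness)) paste0("# sensor_stiffness=", num17(meta$sensor_stiffness)),
    if (!is.null(meta$tip_radius)) paste0("# tip_radius=", num17(meta$tip_radius)),
    if (!is.null(meta$cell_id)) paste0("# cell_id=", meta$cell_id),
    if (!is.null(meta$truth)) {
      vapply(names(meta$truth), function(k) {
        paste0("# truth_", k, "=", num17(meta$truth[[k]]))
      }, character(1))
    }
  )
  body <- paste(num17(curve$displacement), num17(curve$force), curve$segment, sep = ",")
  writeLines(c(hdr, "displacement,force,segment", body), path)
  invisible(path)
}

# shortest decimal that round-trips a double
num17 <- function(x) {
  vapply(x, function(v) {
    for (d in c(15L, 16L, 17L)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

#' Plot a force curve
#'
#' @param object A [force_curve()].
#' @param ... Unused.
#' @return A ggplot showing force against displacement, coloured by segment.
#' @method autoplot force_curve
#' @export
autoplot.force_curve <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$displacement, y = .data$force, colour = .data$segment)
  ) +
    ggplot2::geom_path() +
    ggplot2::labs(
      x = "displacement (m)", y = "force (N)",
      title = attr(object, "cell_id"),
      subtitle = attr(object, "instrument"), colour = NULL
    )
}
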