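#' The six osmotic/drug treatment conditions
#'
#' Cells are probed in two osmotic conditions — growth medium (`GM`,
#' hypotonic, turgid) and plasmolysing solution (`PS`, hypertonic, turgor
#' removed) — each alone or combined with a cytoskeletal drug: oryzalin
#' depolymerises microtubules (`-MT`) and latrunculin B removes actin
#' filaments (`-AF`). Treatment labels are fixed strings; hyphen, en-dash and
#' underscore spellings are normalised on ingest.
#'
#' @return `treatment_levels()` returns the six canonical labels in display
#'   order. `treatment_info()` returns a tibble with one row per treatment and
#'   columns `treatment`, `osmotic` (`"GM"` or `"PS"`) and `removed`
#'   (`"none"`, `"MT"` or `"AF"`).
#' @export
#' @examples
#' treatment_levels()
#' treatment_info()
treatment_levels <- function() {
  c("GM", "GM-MT", "GM-AF", "PS", "PS-MT", "PS-AF")
}

#' @rdname treatment_levels
#' @export
treatment_info <- function() {
  tibble::tibble(
    treatment = treatment_levels(),
    osmotic = rep(c("GM", "PS"), each = 3),
    removed = rep(c("none", "MT", "AF"), times = 2)
  )
}

#' Normalise treatment labels to their canonical spelling
#'
#' @param x Character vector of treatment labels (any of `GM-MT`, `GM_MT`,
#'   or the en-dash spelling).
#' @return Factor with the six canonical levels in canonical order.
#' @export
#' @examples
#' as_treatment(c("GM_MT", "PS–AF", "gm"))
as_treatment <- function(x) {
  y <- toupper(trimws(as.character(x)))
  y <- gsub("[_–—]", "-", y)
  bad <- setdiff(unique(y[!is.na(y)]), treatment_levels())
  if (length(bad) > 0) {
    cs_abort(
      sprintf(
        "unknown treatment label(s): %s (expected one of %s)",
        paste(bad, collapse = ", "), paste(treatment_levels(), collapse = ", ")
      ),
      "invalid_treatment"
    )
  }
  factor(y, levels = treatment_levels())
}

# osmotic group ("GM"/"PS") and removed element ("none"/"MT"/"AF") per label
treatment_osmotic <- function(treatment) {
  ifelse(startsWith(as.character(treatment), "PS"), "PS", "GM")
}

treatment_removed <- function(treatment) {
  t <- as.character(treatment)
  ifelse(endsWith(t, "-MT"), "MT", ifelse(endsWith(t, "-AF"), "AF", "none"))
}
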