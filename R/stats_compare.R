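# Nonparametric comparison utilities: ECDFs, two-sample Kolmogorov-Smirnov
# tests and treatment summary tables.

#' Empirical cumulative distribution function
#'
#' Standard right-continuous ECDF: `F(x)` is the fraction of the sample at or
#' below `x` (0 below the minimum, 1 at and above the maximum).
#'
#' @param sample Numeric sample, `n >= 1`.
#' @return A function of class `ecdf_fn`, with the sorted sample stored in
#'   attribute `sorted_values`.
#' @export
#' @examples
#' f <- ecdf_fn(c(1, 2, 3))
#' f(2) # 2/3
ecdf_fn <- function(sample) {
  if (length(sample) < 1 || anyNA(sample)) {
    cs_abort("ECDF needs a non-empty sample without NAs", "invalid_input")
  }
  s <- sort(sample)
  n <- length(s)
  f <- function(x) findInterval(x, s) / n
  structure(f, class = c("ecdf_fn", "function"), sorted_values = s)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup_x |ECDF_x(x) - ECDF_y(x)|`, evaluated at the pooled sample
#' points. The p-value comes from the asymptotic Kolmogorov distribution
#' with effective sample size `n1 * n2 / (n1 + n2)`; for small samples
#' (`n1 + n2 <= exact_max`) an exact permutation p-value over all
#' `choose(n1 + n2, n1)` group assignments is computed instead. Fully
#' degenerate input (every value tied across both samples) returns D = 0,
#' p = 1 with a tie warning.
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @param exact_max Largest `n1 + n2` for which the permutation p-value is
#'   enumerated. Default 20; set to 0 to force the asymptotic value.
#' @return A tibble of class `ks_result` with columns `d_statistic`,
#'   `p_value`, `n1`, `n2`, `method`.
#' @export
#' @examples
#' ks_two_sample(c(1, 2), c(1.5, 2.5))
ks_two_sample <- function(x, y, exact_max = 20) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) cs_abort("both samples need at least 2 observations", "invalid_input")
  if (anyNA(x) || anyNA(y)) cs_abort("samples must not contain NAs", "invalid_input")
  d <- ks_d(x, y)
  if (d == 0 && length(unique(c(x, y))) == 1) {
    cs_warn("all values tied across both samples; D = 0, p = 1", "ties")
    return(ks_result(0, 1, n1, n2, "degenerate"))
  }
  if (n1 + n2 <= exact_max) {
    p <- ks_exact_perm(x, y, d)
    method <- "exact-permutation"
  } else {
    n_eff <- n1 * n2 / (n1 + n2)
    p <- kolmogorov_q(sqrt(n_eff) * d)
    method <- "asymptotic"
  }
  ks_result(d, p, n1, n2, method)
}

ks_result <- function(d, p, n1, n2, method) {
  out <- tibble::tibble(
    d_statistic = d, p_value = min(max(p, 0), 1),
    n1 = as.integer(n1), n2 = as.integer(n2), method = method
  )
  class(out) <- c("ks_result", class(out))
  out
}

# sup distance between the two ECDFs at pooled points
ks_d <- function(x, y) {
  pooled <- sort(unique(c(x, y)))
  fx <- findInterval(pooled, sort(x)) / length(x)
  fy <- findInterval(pooled, sort(y)) / length(y)
  max(abs(fx - fy))
}

# Kolmogorov tail function Q(t) = 2 sum_{j>=1} (-1)^{j-1} exp(-2 j^2 t^2)
kolmogorov_q <- function(t) {
  if (t < 1e-8) return(1)
  j <- 1:100
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))))
}

# exact permutation p-value: fraction of group assignments with D >= d_obs
ks_exact_perm <- function(x, y, d_obs) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  hits <- 0L
  for (k in seq_len(ncol(idx))) {
    xi <- pooled[idx[, k]]
    yi <- pooled[-idx[, k]]
    if (ks_d(xi, yi) >= d_obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(idx)
}

#' Summarise the six treatment datasets
#'
#' Per-treatment descriptive statistics (boxplot-style quartiles, mean,
#' standard deviation with the n-1 convention, standard error) plus the
#' pairwise Kolmogorov-Smirnov p-value matrix with significance flags.
#'
#' @param datasets A `treatment_datasets` tibble carrying raw values (as
#'   produced by [treatment_datasets()]).
#' @param star_thresholds Descending significance thresholds for the star
#'   annotation. Default `c(0.05, 0.01, 0.001)`.
#' @param p_adjust `"none"` (raw pairwise p-values, the default) or
#'   `"holm"`.
#' @return List with `summary` (tibble: treatment, n, mean, sd, se, min, q1,
#'   median, q3, max), `ks_matrix` (6x6 symmetric p-value matrix, unit
#'   diagonal), and `ks_pairs` (long tibble with `stars` flags).
#' @export
summarize_treatments <- function(datasets, star_thresholds = c(0.05, 0.01, 0.001),
                                 p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  datasets <- validate_datasets(datasets, require_all = FALSE)
  if (any(vapply(datasets$values, is.null, logical(1)))) {
    cs_abort("summaries need raw per-cell values", "invalid_data")
  }
  summary <- datasets |>
    dplyr::mutate(
      min = purrr::map_dbl(.data$values, min),
      q1 = purrr::map_dbl(.data$values, ~ unname(stats::quantile(.x, 0.25))),
      median = purrr::map_dbl(.data$values, ~ unname(stats::median(.x))),
      q3 = purrr::map_dbl(.data$values, ~ unname(stats::quantile(.x, 0.75))),
      max = purrr::map_dbl(.data$values, max)
    ) |>
    dplyr::select("treatment", "n", "mean", "sd", "se",
                  "min", "q1", "median", "q3", "max")

  labs <- datasets$treatment
  k <- length(labs)
  pm <- matrix(1, k, k, dimnames = list(labs, labs))
  pairs <- tidyr::expand_grid(i = seq_len(k), j = seq_len(k)) |>
    dplyr::filter(.data$i < .data$j)
  pvals <- purrr::map2_dbl(pairs$i, pairs$j, function(i, j) {
    # always the asymptotic variant in the matrix, labelled by ks_two_sample
    ks_two_sample(datasets$values[[i]], datasets$values[[j]], exact_max = 0)$p_value
  })
  if (p_adjust == "holm") pvals <- stats::p.adjust(pvals, method = "holm")
  for (r in seq_len(nrow(pairs))) {
    pm[pairs$i[r], pairs$j[r]] <- pm[pairs$j[r], pairs$i[r]] <- pvals[r]
  }
  ks_pairs <- tibble::tibble(
    treatment_1 = labs[pairs$i],
    treatment_2 = labs[pairs$j],
    p_value = pvals,
    stars = vapply(pvals, function(p) {
      paste(rep("*", sum(p < star_thresholds)), collapse = "")
    }, character(1))
  )
  list(summary = summary, ks_matrix = pm, ks_pairs = ks_pairs)
}
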