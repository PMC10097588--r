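# The series-parallel spring network: a cell-wall spring in series with a
# parallel branch of residual protoplasm, microtubules and actin filaments.
# Drug treatments remove one parallel element and (in the combined analysis)
# rescale the cell-wall spring by an AFM-derived ratio.

.param_names <- c("k_cw_gm", "k_cw_ps", "k_gm", "k_ps", "k_mt", "k_af")

#' Construct the six-spring parameter vector
#'
#' The latent stiffnesses of the spring network: cell wall in growth medium
#' (`k_cw_gm`) and in plasmolysing solution (`k_cw_ps`); residual protoplasm
#' (everything inside the wall except the two cytoskeletal networks) under
#' hypotonic (`k_gm`) and hypertonic (`k_ps`) conditions; microtubule
#' (`k_mt`) and actin-filament (`k_af`) contributions. All in N/m, all
#' strictly positive.
#'
#' @param k_cw_gm,k_cw_ps,k_gm,k_ps,k_mt,k_af Positive stiffnesses (N/m).
#' @return A named numeric vector of class `spring_params`.
#' @export
#' @examples
#' spring_params(10, 5, 20, 5, 3, 2)
spring_params <- function(k_cw_gm, k_cw_ps, k_gm, k_ps, k_mt, k_af) {
  x <- c(
    k_cw_gm = k_cw_gm, k_cw_ps = k_cw_ps, k_gm = k_gm,
    k_ps = k_ps, k_mt = k_mt, k_af = k_af
  )
  if (any(!is.finite(x)) || any(x <= 0)) {
    cs_abort("all six spring constants must be finite and > 0", "invalid_parameter")
  }
  structure(x, class = c("spring_params", "numeric"))
}

as_spring_params <- function(x) {
  if (inherits(x, "spring_params")) return(x)
  x <- unlist(x)
  if (!all(.param_names %in% names(x))) {
    cs_abort(sprintf("spring parameters need components %s",
                     paste(.param_names, collapse = ", ")), "invalid_parameter")
  }
  do.call(spring_params, as.list(x[.param_names]))
}

#' @export
print.spring_params <- function(x, ...) {
  cat("<spring_params> (N/m)\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Cell-wall stiffness ratios between drug and no-drug conditions
#'
#' Dimensionless ratios of mean cell-wall stiffness in each drug treatment to
#' the matching no-drug condition, measured by AFM. The unit ratio set (all 1)
#' encodes the assumption that drug treatments leave the cell wall unchanged
#' (the micro-indentation-only analysis); [afm_ratios()] computes the set used
#' in the combined analysis.
#'
#' @param r_gm_mt,r_gm_af,r_ps_mt,r_ps_af Positive ratios. Default 1.
#' @return A named numeric vector of class `ratio_set`.
#' @export
#' @examples
#' ratio_set()                       # unit ratios
#' ratio_set(0.8, 0.5, 0.9, 0.6)
ratio_set <- function(r_gm_mt = 1, r_gm_af = 1, r_ps_mt = 1, r_ps_af = 1) {
  x <- c(r_gm_mt = r_gm_mt, r_gm_af = r_gm_af, r_ps_mt = r_ps_mt, r_ps_af = r_ps_af)
  if (any(!is.finite(x)) || any(x <= 0)) {
    cs_abort("all ratios must be finite and > 0", "invalid_parameter")
  }
  structure(x, class = c("ratio_set", "numeric"))
}

#' Effective stiffness of two springs in series
#'
#' @param k1,k2 Positive stiffnesses (N/m); vectorised.
#' @return `k1 * k2 / (k1 + k2)` (N/m).
#' @export
#' @examples
#' series_stiffness(3, 6) # 2
series_stiffness <- function(k1, k2) {
  if (any(!is.finite(k1)) || any(!is.finite(k2)) || any(k1 <= 0) || any(k2 <= 0)) {
    cs_abort("series springs must be finite and > 0", "invalid_parameter")
  }
  k1 * k2 / (k1 + k2)
}

#' Parallel protoplasm branch stiffness for a treatment
#'
#' Parallel springs add: the branch is the residual protoplasm term (`k_gm`
#' for the GM group, `k_ps` for the PS group) plus `k_mt` unless the treatment
#' removed microtubules, plus `k_af` unless it removed actin filaments.
#'
#' @param treatment Treatment label(s), see [treatment_levels()]; vectorised.
#' @param params A [spring_params()] vector.
#' @return Branch stiffness in N/m.
#' @export
#' @examples
#' p <- spring_params(10, 5, 20, 5, 3, 2)
#' protoplasm_stiffness("GM", p)    # 25
#' protoplasm_stiffness("GM-MT", p) # 22
protoplasm_stiffness <- function(treatment, params) {
  params <- as_spring_params(params)
  treatment <- as.character(as_treatment(treatment))
  res <- ifelse(treatment_osmotic(treatment) == "GM", params["k_gm"], params["k_ps"])
  removed <- treatment_removed(treatment)
  unname(res +
    ifelse(removed == "MT", 0, params["k_mt"]) +
    ifelse(removed == "AF", 0, params["k_af"]))
}

#' Model effective cell stiffness for a treatment
#'
#' The effective stiffness measured by micro-indentation is the cell-wall
#' spring in series with the parallel protoplasm branch:
#' `series(R_t * k_cw, protoplasm(t))`, where `k_cw` is the osmotic-matched
#' cell-wall stiffness and `R_t` rescales it in drug treatments (unity for
#' the no-drug conditions and for the micro-only analysis).
#'
#' @inheritParams protoplasm_stiffness
#' @param ratios A [ratio_set()].
#' @return Effective stiffness in N/m (vectorised over `treatment`).
#' @export
#' @examples
#' p <- spring_params(10, 5, 20, 5, 3, 2)
#' effective_stiffness("GM", p)  # 10*25/35
effective_stiffness <- function(treatment, params, ratios = ratio_set()) {
  params <- as_spring_params(params)
  treatment <- as.character(as_treatment(treatment))
  k_cw <- ifelse(treatment_osmotic(treatment) == "GM", params["k_cw_gm"], params["k_cw_ps"])
  rmap <- c(
    "GM" = 1, "PS" = 1,
    "GM-MT" = unname(ratios["r_gm_mt"]), "GM-AF" = unname(ratios["r_gm_af"]),
    "PS-MT" = unname(ratios["r_ps_mt"]), "PS-AF" = unname(ratios["r_ps_af"])
  )
  unname(series_stiffness(rmap[treatment] * k_cw, protoplasm_stiffness(treatment, params)))
}

# all six treatment means as a named vector
effective_means <- function(params, ratios = ratio_set()) {
  stats::setNames(
    effective_stiffness(treatment_levels(), params, ratios),
    treatment_levels()
  )
}

# Precomputed index structure for the hot evaluation path (optimiser and
# solver): per treatment, the wall-parameter index, the CW ratio multiplier
# and the branch-parameter indices (into the canonical parameter order).
spring_core <- function(ratios = ratio_set()) {
  idx <- stats::setNames(seq_along(.param_names), .param_names)
  list(
    cw = c(idx["k_cw_gm"], idx["k_cw_gm"], idx["k_cw_gm"],
           idx["k_cw_ps"], idx["k_cw_ps"], idx["k_cw_ps"]),
    rmult = c(1, unname(ratios["r_gm_mt"]), unname(ratios["r_gm_af"]),
              1, unname(ratios["r_ps_mt"]), unname(ratios["r_ps_af"])),
    branch = list(
      c(idx["k_gm"], idx["k_mt"], idx["k_af"]),
      c(idx["k_gm"], idx["k_af"]),
      c(idx["k_gm"], idx["k_mt"]),
      c(idx["k_ps"], idx["k_mt"], idx["k_af"]),
      c(idx["k_ps"], idx["k_af"]),
      c(idx["k_ps"], idx["k_mt"])
    )
  )
}

# six treatment means from an unnamed length-6 vector in canonical order
eff_fast <- function(x, core) {
  a <- core$rmult * x[core$cw]
  b <- vapply(core$branch, function(ix) sum(x[ix]), numeric(1))
  a * b / (a + b)
}

# 6 x 6 gradient d f_t / d kappa_j of eff_fast
grad_fast <- function(x, core) {
  G <- matrix(0, 6, 6)
  for (t in 1:6) {
    a <- core$rmult[t] * x[core$cw[t]]
    b <- sum(x[core$branch[[t]]])
    G[t, core$cw[t]] <- core$rmult[t] * (b / (a + b))^2
    G[t, core$branch[[t]]] <- (a / (a + b))^2
  }
  G
}

#' Cell-wall stiffness ratios from AFM treatment means
#'
#' Each drug-treatment mean cell-wall stiffness is divided by the matching
#' no-drug osmotic condition: `r_gm_mt = mean(GM-MT)/mean(GM)` and so on.
#'
#' @param afm_means Named numeric vector or list of the six mean AFM cell-wall
#'   stiffnesses (N/m), names being treatment labels.
#' @return A [ratio_set()].
#' @export
#' @examples
#' afm_ratios(c(GM = 10, `GM-MT` = 8, `GM-AF` = 5, PS = 2, `PS-MT` = 1.8, `PS-AF` = 1.2))
afm_ratios <- function(afm_means) {
  m <- unlist(afm_means)
  names(m) <- as.character(as_treatment(names(m)))
  missing <- setdiff(treatment_levels(), names(m))
  if (length(missing) > 0) {
    cs_abort(sprintf("missing AFM mean(s) for: %s", paste(missing, collapse = ", ")),
             "invalid_input")
  }
  m <- m[treatment_levels()]
  if (any(!is.finite(m)) || any(m <= 0)) {
    cs_abort("all AFM means must be finite and > 0", "invalid_input")
  }
  ratio_set(
    r_gm_mt = unname(m["GM-MT"] / m["GM"]),
    r_gm_af = unname(m["GM-AF"] / m["GM"]),
    r_ps_mt = unname(m["PS-MT"] / m["PS"]),
    r_ps_af = unname(m["PS-AF"] / m["PS"])
  )
}

#' Solve the six treatment-mean equations exactly for the spring constants
#'
#' Solves the 6x6 nonlinear system `effective_stiffness(t, kappa, R) = m_t`
#' for the six spring constants. The solver exploits the network structure:
#' given a wall stiffness for each osmotic group, the three parallel-branch
#' sums follow in closed form by inverting the series relation
#' (`B_t = m_t R_t k_cw / (R_t k_cw - m_t)`), and the branch differences
#' yield the filament and residual-protoplasm constants — so only a 2-D
#' root-find over the two wall stiffnesses remains, imposing that both
#' osmotic groups agree on `k_mt` and `k_af`. A damped
#' (Levenberg-Marquardt) Newton iteration on the full 6-D log-parameter
#' system is kept as fallback for starts supplied by the caller.
#'
#' @param target_means Named vector of the six treatment means (N/m).
#' @param ratios A [ratio_set()].
#' @param start Optional [spring_params()] starting point; a moment-matched
#'   heuristic is used when omitted.
#' @param tol Relative residual tolerance (per component, relative to the
#'   target-mean scale). Default 1e-10.
#' @param max_iter Newton iterations per start. Default 100.
#' @param n_starts Additional seeded random starts on failure. Default 8.
#' @param seed Seed for the random starts. Default 1.
#' @return A [spring_params()] vector with attributes `residual_norm`
#'   (relative), `iterations` and `jacobian_condition` (condition number of
#'   the Jacobian at the solution; a large value flags weak identifiability).
#' @export
solve_exact <- function(target_means, ratios = ratio_set(), start = NULL,
                        tol = 1e-10, max_iter = 100, n_starts = 8, seed = 1) {
  m <- unlist(target_means)
  names(m) <- as.character(as_treatment(names(m)))
  if (!all(treatment_levels() %in% names(m))) {
    cs_abort("target_means must contain all six treatments", "invalid_input")
  }
  m <- m[treatment_levels()]
  if (any(!is.finite(m)) || any(m <= 0)) cs_abort("target means must be > 0", "invalid_input")

  core <- spring_core(ratios)
  resid <- function(theta) (eff_fast(exp(theta), core) - m) / m
  # analytic Jacobian in theta = log(kappa): avoids finite-difference noise
  # in weakly identified regimes
  jac_an <- function(theta) {
    x <- exp(theta)
    grad_fast(x, core) * rep(x, each = 6) / m
  }

  best <- NULL
  red <- solve_reduced(m, ratios, tol = tol)
  if (!is.null(red)) {
    theta <- log(red)
    r0 <- resid(theta)
    best <- list(theta = theta, r = r0, norm = sqrt(sum(r0^2)), iter = 0L)
  }
  if (is.null(best) || best$norm >= tol) {
    starts <- list(if (is.null(start)) heuristic_params(m, ratios) else as_spring_params(start))
    if (!is.null(red)) starts <- c(list(red), starts)
    extra <- with_stream(derive_seed(seed, "solve_exact"), function() {
      lapply(seq_len(n_starts), function(i) {
        p <- exp(stats::runif(6, log(min(m) / 10), log(max(m) * 20)))
        do.call(spring_params, as.list(stats::setNames(p, .param_names)))
      })
    })
    for (st in starts) {
      sol <- newton_log(resid, log(unclass(st)), tol = tol, max_iter = max_iter,
                        jac = jac_an)
      if (is.null(best) || sol$norm < best$norm) best <- sol
      if (best$norm < tol) break
    }
  }
  if (best$norm >= tol) {
    cs_abort(
      sprintf("Newton iteration did not converge: best relative residual norm %.3g", best$norm),
      "solver_failure", residuals = best$r
    )
  }
  jac <- num_jacobian(function(th) resid(th), best$theta)
  kappa_cond <- tryCatch(kappa(jac, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kappa_cond) || kappa_cond > 1e10) {
    cs_warn("Jacobian is nearly rank-deficient at the solution; parameters weakly identified",
            "identifiability")
  }
  out <- do.call(spring_params, as.list(stats::setNames(exp(best$theta), .param_names)))
  attr(out, "residual_norm") <- best$norm
  attr(out, "iterations") <- best$iter
  attr(out, "jacobian_condition") <- kappa_cond
  out
}

# Structural reduction of the six mean equations to a single unknown.
#
# For wall stiffness c the series relation inverts in closed form: the
# parallel-branch sum of treatment t is B_t(c) = y_t c / (c - z_t) with
# z_t = y_t / R_t (valid for c > z_t). Within one osmotic group the branch
# differences give the filament constants, e.g.
#   k_mt(c) = B_nodrug(c) - B_MTremoved(c)
#           = c [ (y1 - y2) c - (y1 z2 - y2 z1) ] / ((c - z1)(c - z2)),
# so "k_mt(c) = tau" is a QUADRATIC in c with an explicit admissible root.
# Fixing the PS-group wall stiffness q determines (k_mt, k_af) from the PS
# equations; each target then determines the GM wall stiffness via its
# quadratic, and consistency of the two resulting values is a 1-D root-find
# in q, solved by sign bracketing and uniroot. The remaining constants
# follow in closed form.
solve_reduced <- function(m, ratios, tol) {
  rg <- c(1, unname(ratios["r_gm_mt"]), unname(ratios["r_gm_af"]))
  rp <- c(1, unname(ratios["r_ps_mt"]), unname(ratios["r_ps_af"]))
  yg <- unname(m[1:3])
  yp <- unname(m[4:6])
  zg <- yg / rg
  zp <- yp / rp
  cmin <- max(zg)
  qmin <- max(zp)

  # k_filament as a function of the wall stiffness, for pair (nodrug, drug)
  fil <- function(c, y1, z1, y2, z2) {
    c * ((y1 - y2) * c - (y1 * z2 - y2 * z1)) / ((c - z1) * (c - z2))
  }
  # admissible root of fil(c) = tau, i.e. the wall stiffness that produces a
  # given filament constant; NA when no root exceeds the poles
  wall_of <- function(tau, y1, z1, y2, z2, lo) {
    a <- tau - (y1 - y2)
    b <- (y1 * z2 - y2 * z1) - tau * (z1 + z2)
    cc <- tau * z1 * z2
    if (abs(a) < 1e-300) {
      root <- -cc / b
      return(if (is.finite(root) && root > lo) root else NA_real_)
    }
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NA_real_)
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    roots <- roots[is.finite(roots) & roots > lo]
    if (length(roots) == 0) NA_real_ else min(roots)
  }
  # mismatch between the two GM wall stiffnesses implied by the PS group
  phi <- function(q) {
    tau_mt <- fil(q, yp[1], zp[1], yp[2], zp[2])
    tau_af <- fil(q, yp[1], zp[1], yp[3], zp[3])
    c_mt <- wall_of(tau_mt, yg[1], zg[1], yg[2], zg[2], cmin)
    c_af <- wall_of(tau_af, yg[1], zg[1], yg[3], zg[3], cmin)
    (c_mt - c_af) / cmin
  }
  assemble <- function(q) {
    tau_mt <- fil(q, yp[1], zp[1], yp[2], zp[2])
    c_mt <- wall_of(tau_mt, yg[1], zg[1], yg[2], zg[2], cmin)
    if (is.na(c_mt)) return(NULL)
    Bg <- yg[1] * c_mt / (c_mt - zg[1])
    Bp <- yp[1] * q / (q - zp[1])
    k_mt <- fil(c_mt, yg[1], zg[1], yg[2], zg[2])
    k_af <- fil(c_mt, yg[1], zg[1], yg[3], zg[3])
    kappa <- c(c_mt, q, Bg - k_mt - k_af, Bp - k_mt - k_af, k_mt, k_af)
    if (any(!is.finite(kappa)) || any(kappa <= 0)) NULL else kappa
  }

  vgrid <- seq(-34, 34, length.out = 2001)
  qgrid <- qmin * (1 + exp(vgrid))
  pv <- vapply(qgrid, function(q) tryCatch(phi(q), error = function(e) NA_real_),
               numeric(1))
  core <- spring_core(ratios)
  best <- NULL
  consider <- function(kappa) {
    if (is.null(kappa)) return()
    rnorm_full <- sqrt(sum(((eff_fast(kappa, core) - m) / m)^2))
    if (is.null(best) || rnorm_full < best$norm) {
      best <<- list(kappa = stats::setNames(kappa, .param_names), norm = rnorm_full)
    }
  }
  sign_change <- which(diff(sign(pv)) != 0 & !is.na(pv[-1]) & !is.na(pv[-length(pv)]))
  for (i in sign_change) {
    # phi can be undefined between bracket points (no admissible quadratic
    # root); uniroot handles that internally and the candidate is validated
    # against the full residual, so its NA chatter is muffled
    root <- tryCatch(
      suppressWarnings(
        stats::uniroot(function(v) phi(qmin * (1 + exp(v))),
                       c(vgrid[i], vgrid[i + 1]), tol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (!is.null(root)) consider(assemble(qmin * (1 + exp(root$root))))
    if (!is.null(best) && best$norm < tol) break
  }
  # near-zeros without a sign change (tangency) still make useful starts
  if (is.null(best) || best$norm >= tol) {
    near <- order(abs(pv))[1:5]
    for (i in near[!is.na(pv[near])]) consider(assemble(qgrid[i]))
  }
  best$kappa # near-solution even when above tol: the caller polishes it
}

# Moment-matched heuristic: guess each wall spring as twice the no-drug mean
# (series springs halve when equal), invert the series relation to get the
# parallel-branch stiffness B_t = y_t * k_cw / (k_cw - y_t) per treatment,
# then read the filament constants off the branch differences and the
# residual protoplasm off what remains (floored at small positive values).
heuristic_params <- function(m, ratios = ratio_set()) {
  branch_of <- function(y, cw) {
    y <- min(y, 0.95 * cw) # series output can never exceed the wall spring
    y * cw / (cw - y)
  }
  cw_gm <- 2 * m[["GM"]]
  cw_ps <- 2 * m[["PS"]]
  b <- c(
    gm = branch_of(m[["GM"]], cw_gm),
    gm_mt = branch_of(m[["GM-MT"]], ratios[["r_gm_mt"]] * cw_gm),
    gm_af = branch_of(m[["GM-AF"]], ratios[["r_gm_af"]] * cw_gm),
    ps = branch_of(m[["PS"]], cw_ps),
    ps_mt = branch_of(m[["PS-MT"]], ratios[["r_ps_mt"]] * cw_ps),
    ps_af = branch_of(m[["PS-AF"]], ratios[["r_ps_af"]] * cw_ps)
  )
  floor_k <- 0.02 * m[["GM"]]
  k_mt <- max(0.5 * (b[["gm"]] - b[["gm_mt"]] + b[["ps"]] - b[["ps_mt"]]), floor_k)
  k_af <- max(0.5 * (b[["gm"]] - b[["gm_af"]] + b[["ps"]] - b[["ps_af"]]), floor_k)
  spring_params(
    k_cw_gm = cw_gm, k_cw_ps = cw_ps,
    k_gm = max(b[["gm"]] - k_mt - k_af, floor_k),
    k_ps = max(b[["ps"]] - k_mt - k_af, floor_k),
    k_mt = k_mt, k_af = k_af
  )
}

# Damped (Levenberg-Marquardt regularised) Newton in theta = log(kappa):
# solves (J'J + mu * diag(J'J)) step = -J'r, shrinking mu on success and
# inflating it on rejection, so near-singular Jacobians (weakly identified
# filament constants) still make progress. Iterates stay strictly positive
# by construction.
newton_log <- function(resid, theta, tol, max_iter, jac = NULL) {
  safe_resid <- function(th) tryCatch(resid(th), error = function(e) NULL)
  r <- safe_resid(theta)
  if (is.null(r) || any(!is.finite(r))) {
    return(list(theta = theta, r = r, norm = Inf, iter = 0L))
  }
  nrm <- sqrt(sum(r^2))
  mu <- 1e-3
  it <- 0L
  while (it < max_iter && nrm >= tol) {
    it <- it + 1L
    J <- if (is.null(jac)) num_jacobian(resid, theta) else jac(theta)
    d <- sqrt(pmax(colSums(J^2), 1e-12))
    accepted <- FALSE
    for (bt in 1:40) {
      # augmented least-squares form of the LM step (QR, not normal
      # equations: keeps the effective condition number at cond(J))
      step <- tryCatch(
        -qr.solve(rbind(J, sqrt(mu) * diag(d, length(d))),
                  c(r, numeric(length(d)))),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        th2 <- pmin(pmax(theta + as.numeric(step), -300), 300)
        r2 <- safe_resid(th2)
        n2 <- if (is.null(r2)) Inf else sqrt(sum(r2^2))
        if (is.finite(n2) && n2 < nrm) {
          theta <- th2; r <- r2; nrm <- n2
          mu <- max(mu / 3, 1e-12)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
      if (mu > 1e12) break
    }
    if (!accepted) break
  }
  list(theta = theta, r = r, norm = nrm, iter = it)
}

# central-difference Jacobian
num_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    hp <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + hp
    xm <- x; xm[j] <- x[j] - hp
    J[, j] <- (f(xp) - f(xm)) / (2 * hp)
  }
  J
}
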