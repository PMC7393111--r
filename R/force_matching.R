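#' Equivalent constant force from lifetime matching
#'
#' The translocation assay yields an unfolding rate k_unfold (1/min) for
#' the roadblock at the translocon; force spectroscopy yields the
#' force-dependent folded-state lifetime tau(F). The equivalent constant
#' force generated by the motor is the unique F with
#' tau(F) = 60 / k_unfold (the 60 bridges minutes to seconds), found by
#' bracketed root-finding on the strictly decreasing branch of tau to an
#' absolute tolerance of 1e-4 pN.
#'
#' @param k_unfold Unfolding rate during translocation, 1/min (> 0).
#' @param params A [barrier_params()] object from the force-spectroscopy
#'   fit.
#' @return Force in pN. If the target lifetime is at or above the
#'   intrinsic lifetime tau0 there is no positive-force solution and 0 is
#'   returned with attribute `"no_solution" = TRUE`.
#' @examples
#' mtx <- barrier_params(5.46, 1.67, 15.3)
#' solve_translocon_force(0.0115, mtx) # ~10.6 pN
#' @export
solve_translocon_force <- function(k_unfold, params) {
  if (k_unfold <= 0) stop("k_unfold must be positive")
  target <- 60 / k_unfold              # folded lifetime in seconds
  if (target >= params$tau0) {
    out <- 0
    attr(out, "no_solution") <- TRUE
    return(out)
  }
  # tau is strictly decreasing up to the rate peak, constant beyond
  hi <- min(params$peak_force, params$critical_force) * (1 - 1e-9)
  if (folded_lifetime(hi, params) > target) {
    out <- hi
    attr(out, "no_solution") <- TRUE
    return(out)
  }
  stats::uniroot(function(f) log(folded_lifetime(f, params)) - log(target),
                 c(0, hi), tol = 1e-4)$root
}

#' Monte-Carlo uncertainty propagation for the translocon force
#'
#' Draws barrier parameters from the fit's uncertainty (bootstrap
#' replicates when available, otherwise multivariate-normal draws from
#' the covariance) and k_unfold from Normal(mean, sd) truncated at zero,
#' solves for the matching force per draw, and reports the mean and SD.
#' Draws with no positive-force solution are counted and excluded from
#' the moments; if they exceed 20% of draws the estimate is flagged.
#'
#' @param k_unfold Unfolding rate in 1/min.
#' @param sd_k_unfold Its standard deviation (1/min).
#' @param fit A `barrier_fit` from [fit_global()].
#' @param n_mc Number of Monte-Carlo draws (>= 100, default 1000).
#' @param seed Integer seed.
#' @return An object of class `translocon_force_estimate`: `force` (pN,
#'   mean over solvable draws), `sd_force` (pN), `point` (force at the
#'   point estimates), `k_unfold`, `sd_k_unfold`, `n_mc`,
#'   `n_unsolvable`, `flagged`, `seed`.
#' @export
propagate_force_uncertainty <- function(k_unfold, sd_k_unfold, fit,
                                        n_mc = 1000, seed = 1L) {
  stopifnot(n_mc >= 100, k_unfold > 0, sd_k_unfold >= 0)
  point <- solve_translocon_force(k_unfold, fit$params)
  if (sd_k_unfold == 0 && all(fit$sd == 0, na.rm = TRUE)) {
    return(structure(list(force = as.numeric(point), sd_force = 0,
                          point = as.numeric(point), k_unfold = k_unfold,
                          sd_k_unfold = sd_k_unfold, n_mc = 0L,
                          n_unsolvable = 0L, flagged = FALSE, seed = seed),
                     class = "translocon_force_estimate"))
  }
  draws <- .draw_params(fit, n_mc, seed)
  bnd <- .mle_bounds()
  for (j in 1:3) {
    draws[, j] <- pmin(pmax(draws[, j], bnd$lower[j]), bnd$upper[j])
  }
  ku <- stats::rnorm(n_mc, k_unfold, sd_k_unfold)
  forces <- rep(NA_real_, n_mc)
  for (i in seq_len(n_mc)) {
    if (ku[i] <= 0) next
    th <- draws[i, ]
    p <- barrier_params(th[1], th[2], th[3], nu = fit$params$nu,
                        thermal_energy = fit$params$thermal_energy)
    f <- solve_translocon_force(ku[i], p)
    if (isTRUE(attr(f, "no_solution"))) next
    forces[i] <- f
  }
  bad <- sum(is.na(forces))
  flagged <- bad > 0.2 * n_mc
  if (flagged) warning("more than 20% of draws had no solution")
  structure(list(force = mean(forces, na.rm = TRUE),
                 sd_force = stats::sd(forces, na.rm = TRUE),
                 point = as.numeric(point),
                 k_unfold = k_unfold, sd_k_unfold = sd_k_unfold,
                 n_mc = n_mc, n_unsolvable = bad, flagged = flagged,
                 seed = seed),
            class = "translocon_force_estimate")
}

#' @export
print.translocon_force_estimate <- function(x, ...) {
  cat(sprintf("Translocon force: %.2f +/- %.2f pN (point %.2f pN)\n",
              x$force, x$sd_force, x$point))
  cat(sprintf("  from k_unfold = %.4g +/- %.2g 1/min, %d MC draws",
              x$k_unfold, x$sd_k_unfold, x$n_mc))
  if (x$n_unsolvable > 0) cat(sprintf(", %d unsolvable", x$n_unsolvable))
  cat("\n")
  if (x$flagged) cat("  WARNING: >20% of draws unsolvable\n")
  invisible(x)
}

#' Plot-ready lifetime/force overlay table
#'
#' Emits the folded-state lifetime curve with its Monte-Carlo band, the
#' horizontal lifetime levels 60/k_unfold implied by translocation rates,
#' and the intersection (matching) forces, for reproducing the standard
#' lifetime-vs-force figure.
#'
#' @param fit A `barrier_fit`.
#' @param k_unfold_points Numeric vector of unfolding rates (1/min); may
#'   be empty for a curve-only table.
#' @param force_grid Forces (pN) at which to tabulate the curve.
#' @param n_draws,seed Passed to [lifetime_band()].
#' @return List with `curve` (data frame from [lifetime_band()]) and
#'   `levels` (data frame with `k_unfold`, `lifetime`, `force`).
#' @export
lifetime_overlay_table <- function(fit, k_unfold_points, force_grid,
                                   n_draws = 1000, seed = 1L) {
  curve <- lifetime_band(fit, force_grid, n_draws = n_draws, seed = seed)
  levels <- if (length(k_unfold_points)) {
    data.frame(k_unfold = k_unfold_points,
               lifetime = 60 / k_unfold_points,
               force = vapply(k_unfold_points, solve_translocon_force,
                              numeric(1), params = fit$params))
  } else {
    data.frame(k_unfold = numeric(0), lifetime = numeric(0),
               force = numeric(0))
  }
  list(curve = curve, levels = levels)
}
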