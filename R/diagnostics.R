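# Distribution-shape diagnostics: does a rupture-force dataset look like
# escape over one barrier, or a mixture of two (distinct native states or
# alternative unfolding pathways)?

.mix_nll <- function(th, events, nu, thermal_energy) {
  # th = (qlogis(w), log10_tau0_1, dx1, dG1, log10_tau0_2, dx2, dG2)
  w <- stats::plogis(th[1])
  p1 <- try(barrier_params(th[2], th[3], th[4], nu = nu,
                           thermal_energy = thermal_energy), silent = TRUE)
  p2 <- try(barrier_params(th[5], th[6], th[7], nu = nu,
                           thermal_energy = thermal_energy), silent = TRUE)
  if (inherits(p1, "try-error") || inherits(p2, "try-error")) return(1e10)
  cen <- events$censored
  ll <- numeric(nrow(events))
  if (any(!cen)) {
    f <- events$rip_force[!cen]; r <- events$loading_rate[!cen]
    ll[!cen] <- log(w * rip_force_pdf(f, r, p1) +
                      (1 - w) * rip_force_pdf(f, r, p2))
  }
  if (any(cen)) {
    f <- events$rip_force[cen]; r <- events$loading_rate[cen]
    ll[cen] <- log(w * ramp_survival(f, r, p1) +
                     (1 - w) * ramp_survival(f, r, p2))
  }
  nll <- -sum(ll)
  if (!is.finite(nll)) 1e10 else nll
}

#' Single-barrier versus two-barrier mixture diagnostic
#'
#' Fits the rupture-force data twice: with a single Kramers-like barrier
#' and with a two-component mixture (a weight plus two parameter triplets
#' sharing nu and kBT), both by maximum likelihood. Reports
#' log-likelihoods, AIC and BIC, and the model preferred by BIC. A
#' heavy-shouldered or multi-modal force distribution that a single
#' skewed rupture distribution cannot produce is the signature of
#' unfolding from several states.
#'
#' @param events A [rip_events()] table with at least 20 events.
#' @param single_fit Optional precomputed `barrier_fit` for the
#'   single-barrier model (skips refitting).
#' @param nu Shape exponent shared by all components.
#' @param thermal_energy kBT in pN nm.
#' @return A list of class `shape_diagnostic`: `loglik_single`,
#'   `loglik_mixture`, `aic`, `bic` (named vectors), `preferred`
#'   (`"single"` or `"mixture"` by BIC), `weight`, `mixture_estimate`,
#'   `converged` (both models).
#' @export
barrier_shape_diagnostic <- function(events, single_fit = NULL,
                                     nu = 2 / 3,
                                     thermal_energy = KBT_ROOM) {
  events <- rip_events(as.data.frame(events))
  if (nrow(events) < 20) stop("need at least 20 events")
  if (is.null(single_fit)) {
    single_fit <- fit_global(events, nu = nu,
                             thermal_energy = thermal_energy,
                             uncertainty = "hessian")
  }
  th0 <- single_fit$estimate
  # deterministic starts: split the single-barrier solution into a softer
  # and a stiffer component on either side
  starts <- list(
    c(0, th0[1] - 1, th0[2] * 1.4, th0[3], th0[1] + 1, th0[2] * 0.7, th0[3]),
    c(0, th0[1], th0[2] * 1.8, th0[3] - 3, th0[1], th0[2] * 0.6, th0[3] + 3),
    c(1, th0[1] - 2, th0[2], th0[3] + 4, th0[1] + 2, th0[2], th0[3] - 4)
  )
  bnd <- .mle_bounds()
  lower <- c(-8, bnd$lower, bnd$lower)
  upper <- c(8, bnd$upper, bnd$upper)
  fits <- lapply(starts, function(s) {
    stats::optim(s, .mix_nll, events = events, nu = nu,
                 thermal_energy = thermal_energy, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 1000))
  })
  vals <- vapply(fits, function(f) f$value, numeric(1))
  mix <- fits[[which.min(vals)]]
  conv <- c(single = single_fit$convergence == 0,
            mixture = any(vapply(fits, function(f) f$convergence == 0,
                                 logical(1))))
  if (!all(conv)) warning("non-convergence; diagnostic flagged")
  n <- nrow(events)
  ll <- c(single = single_fit$loglik, mixture = -mix$value)
  k <- c(single = 3, mixture = 7)
  aic <- -2 * ll + 2 * k
  bic <- -2 * ll + k * log(n)
  th <- mix$par
  structure(list(loglik_single = ll[["single"]],
                 loglik_mixture = ll[["mixture"]],
                 aic = aic, bic = bic,
                 preferred = names(bic)[which.min(bic)],
                 weight = stats::plogis(th[1]),
                 mixture_estimate = list(
                   component1 = c(log10_tau0 = th[2], dx_ddagger = th[3],
                                  dG_ddagger = th[4]),
                   component2 = c(log10_tau0 = th[5], dx_ddagger = th[6],
                                  dG_ddagger = th[7])),
                 converged = conv),
            class = "shape_diagnostic")
}

#' @export
print.shape_diagnostic <- function(x, ...) {
  cat("Rupture-force distribution shape diagnostic\n")
  cat(sprintf("  logLik: single %.2f, mixture %.2f\n",
              x$loglik_single, x$loglik_mixture))
  cat(sprintf("  BIC   : single %.2f, mixture %.2f -> prefer %s\n",
              x$bic[["single"]], x$bic[["mixture"]], x$preferred))
  cat(sprintf("  mixture weight: %.2f\n", x$weight))
  if (!all(x$converged)) cat("  WARNING: non-convergence\n")
  invisible(x)
}
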