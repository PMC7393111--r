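#' Negative log-likelihood of rupture events under the Kramers-like law
#'
#' Binless likelihood: each uncensored event contributes
#' -ln p(F_i | r_i, theta) with the event's own loading rate; censored
#' events (molecules that survived the ramp to their recorded force)
#' contribute -ln S(F_i | r_i). Events yielding zero density return a
#' large finite penalty rather than an error, so optimisers can traverse
#' bad parameter regions.
#'
#' @param params A [barrier_params()] object.
#' @param events A [rip_events()] table.
#' @return The negative log-likelihood (dimensionless).
#' @export
negative_loglik <- function(params, events) {
  events <- rip_events(as.data.frame(events))
  cen <- events$censored
  ll <- numeric(nrow(events))
  if (any(!cen)) {
    p <- rip_force_pdf(events$rip_force[!cen], events$loading_rate[!cen],
                       params)
    ll[!cen] <- log(p)
  }
  if (any(cen)) {
    lam <- cumulative_hazard(events$rip_force[cen],
                             events$loading_rate[cen], params)
    ll[cen] <- -lam
  }
  nll <- -sum(ll)
  if (!is.finite(nll)) nll <- 1e10
  nll
}

# default deterministic multi-start grid and box bounds
.mle_start_grid <- function() {
  expand.grid(log10_tau0 = c(3, 5, 7, 9),
              dx_ddagger = c(0.5, 1.5, 2.5),
              dG_ddagger = c(10, 15, 20, 25))
}

.mle_bounds <- function() {
  list(lower = c(log10_tau0 = 0, dx_ddagger = 0.05, dG_ddagger = 1),
       upper = c(log10_tau0 = 12, dx_ddagger = 10, dG_ddagger = 50))
}

.fit_one <- function(events, nu, thermal_energy, start, bounds) {
  obj <- function(th) {
    negative_loglik(barrier_params(th[1], th[2], th[3], nu = nu,
                                   thermal_energy = thermal_energy),
                    events)
  }
  stats::optim(start, obj, method = "L-BFGS-B",
               lower = bounds$lower, upper = bounds$upper,
               control = list(maxit = 500))
}

#' Global binless maximum-likelihood fit of barrier parameters
#'
#' Fits (log10 tau0, dx-dagger, dG-dagger) by minimising
#' [negative_loglik()] over all events pooled across pulling speeds, each
#' at its own loading rate. The shape exponent nu is held fixed.
#' Optimisation is L-BFGS-B within a box, multi-started from a
#' deterministic grid; ties are broken toward the lowest log10 tau0.
#' Parameter uncertainty comes from a parametric bootstrap by default
#' (resample rupture forces from the fitted model at the observed loading
#' rates, refit, take the SD over replicates) or from the observed-
#' information Hessian (`uncertainty = "hessian"`).
#'
#' @param events A [rip_events()] table.
#' @param nu Shape exponent, fixed during fitting. Default 2/3.
#' @param thermal_energy kBT in pN nm.
#' @param init Optional named numeric start
#'   `c(log10_tau0=, dx_ddagger=, dG_ddagger=)`; by default a grid of
#'   starts is used.
#' @param bounds List with `lower` and `upper` named vectors.
#' @param uncertainty `"bootstrap"` (default) or `"hessian"`.
#' @param n_bootstrap Bootstrap replicates (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `barrier_fit`: list with `params`
#'   ([barrier_params()]), `estimate` (named vector), `sd`, `covariance`,
#'   `loglik`, `n_events`, `method`, `n_bootstrap`, `seed`,
#'   `convergence`, `at_bound`, and `bootstrap_replicates` (matrix, when
#'   bootstrapped).
#' @export
fit_global <- function(events, nu = 2 / 3, thermal_energy = KBT_ROOM,
                       init = NULL, bounds = .mle_bounds(),
                       uncertainty = c("bootstrap", "hessian"),
                       n_bootstrap = 200, seed = 1L) {
  uncertainty <- match.arg(uncertainty)
  events <- rip_events(as.data.frame(events))
  n <- nrow(events)
  if (n < 10) warning("fewer than 10 events; estimates will be unstable")
  r_span <- diff(range(log10(events$loading_rate)))
  if (n >= 10 && r_span < 1) {
    warning("loading rates span less than one decade; ",
            "tau0 will be poorly constrained")
  }
  starts <- if (is.null(init)) .mle_start_grid() else
    as.data.frame(as.list(init))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    .fit_one(events, nu, thermal_energy, unlist(starts[i, ]), bounds)
  })
  vals <- vapply(fits, function(f) f$value, numeric(1))
  # best-of-grid; ties broken by lowest log10_tau0
  best_val <- min(vals)
  tied <- which(vals <= best_val + 1e-6)
  best <- tied[which.min(vapply(fits[tied], function(f) f$par[1],
                                numeric(1)))]
  fit <- fits[[best]]
  if (all(vapply(fits, function(f) f$convergence != 0, logical(1)))) {
    stop("optimizer failed to converge from every start")
  }
  est <- fit$par
  names(est) <- c("log10_tau0", "dx_ddagger", "dG_ddagger")
  at_bound <- any(abs(est - bounds$lower) < 1e-6 |
                    abs(est - bounds$upper) < 1e-6)
  pars <- barrier_params(est[1], est[2], est[3], nu = nu,
                         thermal_energy = thermal_energy)
  reps <- NULL
  if (uncertainty == "bootstrap") {
    set.seed(seed)
    reps <- matrix(NA_real_, n_bootstrap, 3,
                   dimnames = list(NULL, names(est)))
    for (b in seq_len(n_bootstrap)) {
      f_b <- sample_rip_forces(n, events$loading_rate, pars)
      ev_b <- rip_events(data.frame(rip_force = as.numeric(f_b),
                                    loading_rate = events$loading_rate,
                                    censored = attr(f_b, "censored")))
      fb <- .fit_one(ev_b, nu, thermal_energy, est, bounds)
      reps[b, ] <- fb$par
    }
    covm <- stats::cov(reps)
    sds <- apply(reps, 2, stats::sd)
  } else {
    h <- stats::optimHess(est, function(th) {
      negative_loglik(barrier_params(th[1], th[2], th[3], nu = nu,
                                     thermal_energy = thermal_energy),
                      events)
    })
    covm <- tryCatch(solve(h), error = function(e) {
      warning("singular Hessian; covariance unavailable")
      matrix(NA_real_, 3, 3)
    })
    sds <- sqrt(pmax(diag(covm), 0))
    dimnames(covm) <- list(names(est), names(est))
    names(sds) <- names(est)
  }
  structure(list(params = pars, estimate = est, sd = sds,
                 covariance = covm, loglik = -fit$value, n_events = n,
                 method = uncertainty, n_bootstrap = if (uncertainty ==
                   "bootstrap") n_bootstrap else 0L,
                 seed = seed, convergence = fit$convergence,
                 at_bound = at_bound, bootstrap_replicates = reps),
            class = "barrier_fit")
}

#' @export
print.barrier_fit <- function(x, ...) {
  cat(sprintf("Binless ML barrier fit (%d events, logLik = %.2f)\n",
              x$n_events, x$loglik))
  est <- cbind(estimate = x$estimate, sd = x$sd)
  print(round(est, 3))
  cat(sprintf("  nu = %.3g (fixed), kBT = %.3g pN nm, uncertainty: %s\n",
              x$params$nu, x$params$thermal_energy, x$method))
  if (x$at_bound) cat("  WARNING: estimate at a parameter bound\n")
  invisible(x)
}

#' Reconstructed rupture-force density averaged over observed loading rates
#'
#' pbar(F) = (1/n) sum_i p(F | r_i, theta-hat): the model density to
#' overlay on a rupture-force histogram of the fitted events.
#'
#' @param fit A `barrier_fit`.
#' @param events The [rip_events()] table the fit used (its loading rates
#'   are averaged over).
#' @param force_grid Forces (pN) at which to evaluate.
#' @return Data frame with columns `force` and `density`.
#' @export
reconstructed_density <- function(fit, events, force_grid) {
  events <- rip_events(as.data.frame(events))
  dens <- vapply(force_grid, function(f) {
    mean(rip_force_pdf(f, events$loading_rate, fit$params))
  }, numeric(1))
  data.frame(force = force_grid, density = dens)
}

# draw parameter vectors consistent with a fit's uncertainty
.draw_params <- function(fit, n_draws, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(fit$bootstrap_replicates)) {
    reps <- fit$bootstrap_replicates
    reps[sample.int(nrow(reps), n_draws, replace = TRUE), , drop = FALSE]
  } else {
    MASS::mvrnorm(n_draws, fit$estimate, fit$covariance)
  }
}

#' Folded-state lifetime curve with a Monte-Carlo uncertainty band
#'
#' Evaluates tau(F) at the point estimate and attaches a standard
#' deviation obtained by propagating the fit's parameter uncertainty
#' through the lifetime law (bootstrap replicates when available,
#' otherwise multivariate-normal draws from the covariance). Lifetimes
#' are summarised on the log scale (geometric mean factor) and as linear
#' SDs of tau.
#'
#' @param fit A `barrier_fit`.
#' @param force_grid Forces in pN.
#' @param n_draws Monte-Carlo draws (default 1000).
#' @param seed Integer seed.
#' @return Data frame with columns `force`, `lifetime` (point estimate,
#'   s), `sd` (linear SD of tau across draws, s), `lo`, `hi` (16/84%
#'   quantiles), and `flagged` (TRUE where the force exceeds the
#'   admissible range of the raw rate law).
#' @export
lifetime_band <- function(fit, force_grid, n_draws = 1000, seed = 1L) {
  draws <- .draw_params(fit, n_draws, seed)
  bnd <- .mle_bounds()
  draws[, 1] <- pmin(pmax(draws[, 1], bnd$lower[1]), bnd$upper[1])
  draws[, 2] <- pmin(pmax(draws[, 2], bnd$lower[2]), bnd$upper[2])
  draws[, 3] <- pmin(pmax(draws[, 3], bnd$lower[3]), bnd$upper[3])
  tau_pt <- folded_lifetime(force_grid, fit$params)
  taus <- apply(draws, 1, function(th) {
    folded_lifetime(force_grid,
                    barrier_params(th[1], th[2], th[3], nu = fit$params$nu,
                                   thermal_energy =
                                     fit$params$thermal_energy))
  })
  taus <- matrix(taus, nrow = length(force_grid))
  data.frame(force = force_grid,
             lifetime = tau_pt,
             sd = apply(taus, 1, stats::sd),
             lo = apply(taus, 1, stats::quantile, probs = 0.16),
             hi = apply(taus, 1, stats::quantile, probs = 0.84),
             flagged = force_grid >= fit$params$peak_force)
}
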