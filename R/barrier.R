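#' Kramers-like (Dudko-Hummer-Szabo) barrier parameters
#'
#' Parameters of the one-barrier force-dependent escape-rate law
#' k(F) = (1/tau0) u^(1/nu - 1) exp(dG (1 - u^(1/nu))),
#' u = 1 - nu F dx / (dG kBT),
#' where tau0 is the intrinsic (zero-force) folded-state lifetime, dx the
#' distance to the transition state, dG the barrier height and nu the
#' shape exponent of the free-energy profile. nu = 2/3 corresponds to a
#' linear-cubic profile, nu = 1/2 to a cusp, and nu = 1 recovers the Bell
#' limit k0 exp(F dx / kBT) in which dG drops out.
#'
#' @param log10_tau0 log10 of the intrinsic lifetime in seconds.
#' @param dx_ddagger Transition-state distance in nm (> 0).
#' @param dG_ddagger Barrier height in units of kBT (> 0).
#' @param nu Shape exponent; one of 1/2, 2/3 or 1. Default 2/3.
#' @param thermal_energy kBT in pN nm. Default [KBT_ROOM].
#'
#' @return An object of class `barrier_params` with derived fields
#'   `tau0` (s), `critical_force` (pN, where the barrier vanishes) and
#'   `peak_force` (pN, where the raw rate is maximal; `Inf` for nu = 1).
#' @examples
#' bp <- barrier_params(log10_tau0 = 5.46, dx_ddagger = 1.67,
#'                      dG_ddagger = 15.3)
#' unfolding_rate(0, bp)   # intrinsic rate 10^-5.46 s^-1
#' folded_lifetime(10.6, bp)
#' @export
barrier_params <- function(log10_tau0, dx_ddagger, dG_ddagger,
                           nu = 2 / 3, thermal_energy = KBT_ROOM) {
  log10_tau0 <- unname(log10_tau0)
  dx_ddagger <- unname(dx_ddagger)
  dG_ddagger <- unname(dG_ddagger)
  stopifnot(is.finite(log10_tau0), dx_ddagger > 0, dG_ddagger > 0,
            thermal_energy > 0)
  if (!isTRUE(all.equal(nu, 1 / 2)) && !isTRUE(all.equal(nu, 2 / 3)) &&
      !isTRUE(all.equal(nu, 1))) {
    stop("nu must be one of 1/2, 2/3, 1")
  }
  fc <- dG_ddagger * thermal_energy / (nu * dx_ddagger)
  # raw rate is maximal at u* = ((1 - nu)/dG)^nu; beyond it the capped-
  # hazard policy holds the rate constant
  if (nu < 1) {
    u_star <- ((1 - nu) / dG_ddagger)^nu
    f_peak <- fc * (1 - u_star)
  } else {
    f_peak <- Inf
  }
  structure(list(log10_tau0 = log10_tau0,
                 dx_ddagger = dx_ddagger,
                 dG_ddagger = dG_ddagger,
                 nu = nu,
                 thermal_energy = thermal_energy,
                 tau0 = 10^log10_tau0,
                 critical_force = fc,
                 peak_force = f_peak),
            class = "barrier_params")
}

#' @export
print.barrier_params <- function(x, ...) {
  cat("Kramers-like barrier parameters\n")
  cat(sprintf("  log10(tau0/s) : %.4g  (tau0 = %.3g s)\n",
              x$log10_tau0, x$tau0))
  cat(sprintf("  dx-dagger     : %.4g nm\n", x$dx_ddagger))
  cat(sprintf("  dG-dagger     : %.4g kBT\n", x$dG_ddagger))
  cat(sprintf("  nu            : %.4g\n", x$nu))
  cat(sprintf("  kBT           : %.4g pN nm\n", x$thermal_energy))
  cat(sprintf("  critical force: %.4g pN\n", x$critical_force))
  invisible(x)
}

# barrier exponent E(F) = dG (1 - u^(1/nu)); defined for u >= 0
.barrier_exponent <- function(force, params) {
  u <- 1 - params$nu * force * params$dx_ddagger /
    (params$dG_ddagger * params$thermal_energy)
  params$dG_ddagger * (1 - u^(1 / params$nu))
}

#' Force-dependent unfolding rate
#'
#' Evaluates the Kramers-like rate law. Above the force at which the raw
#' rate peaks (`params$peak_force`) the rate is held constant at its peak
#' value ("capped hazard", `policy = "cap"`, the default); this keeps
#' likelihoods finite for rupture events recorded at or beyond the model's
#' critical force. `policy = "raw"` refuses forces at or beyond the
#' critical force instead.
#'
#' @param force Force in pN (>= 0). Vectorised.
#' @param params A [barrier_params()] object.
#' @param policy `"cap"` (default) or `"raw"`.
#' @return Rate in 1/s.
#' @export
unfolding_rate <- function(force, params, policy = c("cap", "raw")) {
  policy <- match.arg(policy)
  if (any(force < 0)) stop("force must be non-negative")
  if (policy == "raw" && any(force >= params$critical_force)) {
    stop("force at or beyond the critical force; use policy = \"cap\"")
  }
  f_eff <- pmin(force, params$peak_force)
  u <- 1 - params$nu * f_eff * params$dx_ddagger /
    (params$dG_ddagger * params$thermal_energy)
  (1 / params$tau0) * u^(1 / params$nu - 1) *
    exp(params$dG_ddagger * (1 - u^(1 / params$nu)))
}

#' Force-dependent folded-state lifetime
#'
#' tau(F) = 1 / k(F); tau(0) equals the intrinsic lifetime tau0.
#'
#' @inheritParams unfolding_rate
#' @return Lifetime in s.
#' @export
folded_lifetime <- function(force, params, policy = c("cap", "raw")) {
  1 / unfolding_rate(force, params, policy = match.arg(policy))
}

#' Cumulative hazard along a constant-loading-rate ramp
#'
#' For a force ramp F(t) = r t the cumulative hazard up to force F is
#' Lambda(F) = (1/r) int_0^F k(F') dF', which for the Kramers-like law has
#' the closed form (kBT / (tau0 dx r)) \[exp(E(F)) - 1\] with
#' E(F) = dG (1 - u^(1/nu)). Beyond the rate peak the capped policy
#' continues the integral with the constant peak rate.
#'
#' @param force Force in pN. Vectorised.
#' @param loading_rate Loading rate r in pN/s (> 0).
#' @inheritParams unfolding_rate
#' @return Dimensionless cumulative hazard.
#' @export
cumulative_hazard <- function(force, loading_rate, params,
                              policy = c("cap", "raw")) {
  policy <- match.arg(policy)
  if (any(loading_rate <= 0)) stop("loading_rate must be positive")
  if (any(force < 0)) stop("force must be non-negative")
  if (policy == "raw" && any(force >= params$critical_force)) {
    stop("force at or beyond the critical force; use policy = \"cap\"")
  }
  m <- max(length(force), length(loading_rate))
  force <- rep_len(force, m)
  loading_rate <- rep_len(loading_rate, m)
  pref <- params$thermal_energy /
    (params$tau0 * params$dx_ddagger * loading_rate)
  f_eff <- pmin(force, params$peak_force)
  lam <- pref * (exp(.barrier_exponent(f_eff, params)) - 1)
  over <- force > params$peak_force
  if (any(over)) {
    k_peak <- unfolding_rate(params$peak_force, params)
    lam[over] <- lam[over] +
      k_peak * (force[over] - params$peak_force) / loading_rate[over]
  }
  lam
}

#' Survival probability of the folded state along a force ramp
#'
#' S(F) = exp(-Lambda(F)).
#' @inheritParams cumulative_hazard
#' @return Survival probability in (0, 1].
#' @export
ramp_survival <- function(force, loading_rate, params,
                          policy = c("cap", "raw")) {
  exp(-cumulative_hazard(force, loading_rate, params,
                         policy = match.arg(policy)))
}

#' Rupture-force probability density under constant loading
#'
#' p(F | r) = (k(F)/r) exp(-Lambda(F)). Under the capped-hazard policy the
#' density integrates to one over \[0, Inf); under the raw policy a residual
#' survival mass S(F_c) remains at the critical force.
#'
#' @inheritParams cumulative_hazard
#' @return Probability density per pN.
#' @export
rip_force_pdf <- function(force, loading_rate, params,
                          policy = c("cap", "raw")) {
  policy <- match.arg(policy)
  unfolding_rate(force, params, policy) / loading_rate *
    exp(-cumulative_hazard(force, loading_rate, params, policy))
}

#' Rupture-force cumulative distribution under constant loading
#'
#' P(F_rip <= F) = 1 - S(F).
#' @inheritParams cumulative_hazard
#' @return Cumulative probability.
#' @export
rip_force_cdf <- function(force, loading_rate, params,
                          policy = c("cap", "raw")) {
  1 - ramp_survival(force, loading_rate, params, match.arg(policy))
}

#' Sample rupture forces by exact inverse-transform sampling
#'
#' Inverts the closed-form survival: with U ~ Uniform(0,1),
#' E* = ln(1 + (r tau0 dx / kBT) (-ln U)); if E* <= dG the rupture force is
#' F = (dG kBT / (nu dx)) \[1 - (1 - E*/dG)^nu\], otherwise the molecule
#' survives the ramp past the critical force and the draw is recorded as
#' censored at F_c.
#'
#' @param n Number of draws.
#' @param loading_rate Loading rate in pN/s; scalar or length-n vector.
#' @param params A [barrier_params()] object.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of forces in pN with a logical attribute
#'   `"censored"` marking draws capped at the critical force.
#' @export
sample_rip_forces <- function(n, loading_rate, params, seed = NULL) {
  stopifnot(n >= 1, all(loading_rate > 0))
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  e_star <- log(1 + (loading_rate * params$tau0 * params$dx_ddagger /
                       params$thermal_energy) * (-log(u)))
  censored <- e_star > params$dG_ddagger
  f <- (params$dG_ddagger * params$thermal_energy /
          (params$nu * params$dx_ddagger)) *
    (1 - pmax(1 - e_star / params$dG_ddagger, 0)^params$nu)
  f[censored] <- params$critical_force
  attr(f, "censored") <- censored
  f
}

#' Validate a table of rupture events
#'
#' Checks and classes a data frame of force-ramp rupture observations.
#' Required columns: `rip_force` (pN, > 0) and `loading_rate` (pN/s, > 0).
#' Optional: `molecule_id`, `condition`, `delta_extension` (nm),
#' `trap_velocity` (nm/s), `censored` (logical; defaults to FALSE).
#'
#' @param df A data frame of rupture events.
#' @return The data frame with class `rip_events` and a `censored` column.
#' @export
rip_events <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("rip_force", "loading_rate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$censored)) df$censored <- FALSE
  df$censored <- as.logical(df$censored)
  if (!all(df$rip_force > 0)) stop("rip_force must be positive")
  if (!all(df$loading_rate > 0)) stop("loading_rate must be positive")
  class(df) <- unique(c("rip_events", class(df)))
  df
}

#' Binned lifetime transform of a rupture-force histogram
#'
#' The classical histogram-based transform of rupture forces into
#' force-dependent folded-state lifetimes. For bin i with midpoint F_i,
#' height h_i and N events in total,
#' tau(F_i) = S(F_i) / (p(F_i) <r>_i), with S(F_i) = (h_i/2 +
#' sum over higher bins)/N, p(F_i) = h_i/(N dF), and <r>_i the mean
#' loading rate of the events in the bin. Empty bins are skipped. Provided
#' as the binning-based counterpart to the binless likelihood fit.
#'
#' @param events A [rip_events()] table (censored events are excluded).
#' @param bin_width Bin width dF in pN.
#' @return A data frame with columns `force` (bin midpoint, pN),
#'   `lifetime` (s), `count`, and attribute `"single_bin"` when all events
#'   fell into one bin.
#' @export
binned_lifetime_transform <- function(events, bin_width) {
  events <- rip_events(as.data.frame(events))
  events <- events[!events$censored, , drop = FALSE]
  stopifnot(nrow(events) >= 1, bin_width > 0)
  f <- events$rip_force
  lo <- floor(min(f) / bin_width) * bin_width
  breaks <- seq(lo, max(f) + bin_width, by = bin_width)
  idx <- findInterval(f, breaks, rightmost.closed = TRUE)
  n <- length(f)
  nb <- length(breaks) - 1
  h <- tabulate(idx, nbins = nb)
  single <- sum(h > 0) == 1
  if (single) warning("all events fall in a single bin")
  out <- lapply(which(h > 0), function(i) {
    surv <- (h[i] / 2 + sum(h[seq_len(nb) > i])) / n
    dens <- h[i] / (n * bin_width)
    rbar <- mean(events$loading_rate[idx == i])
    data.frame(force = (breaks[i] + breaks[i + 1]) / 2,
               lifetime = surv / (dens * rbar),
               count = h[i])
  })
  out <- do.call(rbind, out)
  attr(out, "single_bin") <- single
  out
}
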