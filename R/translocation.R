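#' Kinetic rates of the translocation scheme
#'
#' First-order rates, in 1/min, of the three processes that shape the
#' post-reduction translocation signal: unfolding of the folded roadblock
#' at the translocon (`k_unfold`), completion of translocation of the
#' unfolded chain (`k_transloc`), and irreversible incapacitation of the
#' stalled complex (`k_incap`), which competes with unfolding and caps the
#' final signal amplitude at k_unfold / (k_unfold + k_incap).
#'
#' @param k_unfold,k_transloc,k_incap Non-negative rates in 1/min.
#' @return An object of class `translocation_rates`.
#' @export
translocation_rates <- function(k_unfold, k_transloc, k_incap) {
  stopifnot(k_unfold >= 0, k_transloc >= 0, k_incap >= 0)
  structure(list(k_unfold = k_unfold, k_transloc = k_transloc,
                 k_incap = k_incap), class = "translocation_rates")
}

#' Nuisance parameters of the luminescence signal
#'
#' Signal parameters that are not kinetic rates of the translocation
#' scheme: the luminescence amplitude per unit translocated fraction
#' (`amplitude`, RLU), first-order luciferase-substrate depletion
#' (`k_deplete`, 1/min, a multiplicative exp(-k_deplete t) roll-off on
#' the signal), a constant `baseline` (RLU), and the fraction of
#' signal-competent substrate already imported at the moment of reduction
#' (`pre_translocated`, from molecules lacking the disulfide loop).
#' The initial stalled fraction is fixed at 1 by convention.
#'
#' @param amplitude RLU per unit translocated fraction (> 0).
#' @param k_deplete Substrate depletion rate, 1/min (>= 0).
#' @param baseline Constant background, RLU.
#' @param pre_translocated Loop-free fraction already imported (>= 0).
#' @return An object of class `trace_nuisance`.
#' @export
trace_nuisance <- function(amplitude = 1000, k_deplete = 0.01,
                           baseline = 100, pre_translocated = 0.01) {
  stopifnot(amplitude > 0, k_deplete >= 0, pre_translocated >= 0)
  structure(list(amplitude = amplitude, k_deplete = k_deplete,
                 baseline = baseline, pre_translocated = pre_translocated),
            class = "trace_nuisance")
}

#' State occupancies of the translocation scheme
#'
#' Closed-form solution of the scheme
#' stalled (S) --k_unfold--> unfolded (U) --k_transloc--> translocated (T),
#' with incapacitation draining S at rate k_incap into a dead state X.
#' With a = k_unfold + k_incap and S(0) = 1:
#' S(t) = exp(-a t),
#' U(t) = k_unfold (exp(-a t) - exp(-k_transloc t)) / (k_transloc - a),
#' T(t) = (k_unfold/a) \[1 - (k_transloc exp(-a t) - a exp(-k_transloc t))
#'        / (k_transloc - a)\],
#' X(t) = 1 - S - U - T. The degenerate case k_transloc = a uses the
#' analytic limit U = k_unfold t exp(-a t).
#'
#' @param t Time since reduction, in seconds (>= 0). Vectorised.
#' @param rates A [translocation_rates()] object (1/min).
#' @return Data frame with columns `t`, `stalled`, `unfolded`,
#'   `translocated`, `incapacitated`.
#' @export
translocation_states <- function(t, rates) {
  if (any(t < 0)) stop("t must be non-negative (time since reduction)")
  tm <- t / 60                       # rates are per minute
  ku <- rates$k_unfold; kt <- rates$k_transloc; ki <- rates$k_incap
  a <- ku + ki
  s <- exp(-a * tm)
  if (abs(kt - a) < 1e-9) {
    u <- ku * tm * exp(-a * tm)
    tr <- if (a == 0) rep(0, length(tm)) else
      (ku / a) * (1 - exp(-a * tm) * (1 + a * tm))
  } else {
    u <- ku * (exp(-a * tm) - exp(-kt * tm)) / (kt - a)
    tr <- if (a == 0) rep(0, length(tm)) else
      (ku / a) * (1 - (kt * exp(-a * tm) - a * exp(-kt * tm)) / (kt - a))
  }
  data.frame(t = t, stalled = s, unfolded = u, translocated = tr,
             incapacitated = 1 - s - u - tr)
}

#' Model luminescence signal
#'
#' RLU(t) = exp(-k_deplete t) A (T(t) + T0) + baseline, where T(t) is the
#' translocated fraction from [translocation_states()] and T0 the
#' pre-translocated (loop-free) fraction.
#'
#' @param t Time since reduction, seconds. Vectorised.
#' @param rates A [translocation_rates()] object.
#' @param nuisance A [trace_nuisance()] object.
#' @return RLU values.
#' @export
model_signal <- function(t, rates, nuisance) {
  st <- translocation_states(t, rates)
  exp(-nuisance$k_deplete * t / 60) * nuisance$amplitude *
    (st$translocated + nuisance$pre_translocated) + nuisance$baseline
}

#' A time-stamped luminescence trace
#'
#' @param time Time stamps in seconds, strictly increasing.
#' @param rlu Relative light units, finite, same length as `time`.
#' @param t_dtt Time of reducing-agent addition (s); defines t = 0 for
#'   the kinetic model. Must lie within the recorded window.
#' @param condition,replicate_id Labels.
#' @return An object of class `luminescence_trace`.
#' @export
luminescence_trace <- function(time, rlu, t_dtt = 0,
                               condition = "unknown",
                               replicate_id = "r1") {
  stopifnot(length(time) == length(rlu), all(diff(time) > 0),
            all(is.finite(rlu)))
  if (t_dtt < min(time) - 1e-9 || t_dtt > max(time) + 1e-9) {
    stop("t_dtt outside the recorded window")
  }
  structure(list(time = time, rlu = rlu, t_dtt = t_dtt,
                 condition = condition, replicate_id = replicate_id),
            class = "luminescence_trace")
}

# internal: parameter vector <-> model pieces
.trace_par_names <- c("k_unfold", "k_transloc", "k_incap",
                      "amplitude", "k_deplete", "baseline",
                      "pre_translocated")

.trace_model <- function(par, t) {
  model_signal(t,
               translocation_rates(par[["k_unfold"]], par[["k_transloc"]],
                                   par[["k_incap"]]),
               trace_nuisance(par[["amplitude"]], par[["k_deplete"]],
                              par[["baseline"]], par[["pre_translocated"]]))
}

# The translocated fraction is exactly symmetric under exchanging
# a = k_unfold + k_incap with k_transloc (with k_unfold rescaled by
# k_transloc/a to preserve the amplitude), so every trace has two
# equivalent least-squares optima. Canonical branch: k_transloc >= a,
# i.e. completion of translocation is faster than the decay of the
# stalled pool, consistent with independent measurements of unfolded-
# substrate translocation rates.
.canonical_rates <- function(ku, kt, ki) {
  a <- ku + ki
  if (kt >= a || a == 0) return(c(k_unfold = ku, k_transloc = kt,
                                  k_incap = ki))
  ku2 <- kt * ku / a
  c(k_unfold = ku2, k_transloc = a, k_incap = kt - ku2)
}

# numeric Jacobian of the model at par (free parameters only)
.trace_jacobian <- function(par, t, free) {
  J <- matrix(0, length(t), length(free))
  for (j in seq_along(free)) {
    h <- max(1e-7, 1e-6 * abs(par[[free[j]]]))
    p1 <- par; p1[[free[j]]] <- p1[[free[j]]] + h
    p2 <- par; p2[[free[j]]] <- max(p2[[free[j]]] - h, 0)
    J[, j] <- (.trace_model(p1, t) - .trace_model(p2, t)) /
      (p1[[free[j]]] - p2[[free[j]]])
  }
  J
}

#' Fit the kinetic signal model to a luminescence trace
#'
#' Least-squares fit of [model_signal()] to the post-reduction portion of
#' a trace (t >= t_dtt). The four rates are found by variable projection
#' (the amplitude terms and baseline enter the model linearly and are
#' profiled out) multi-started from a deterministic grid, then polished
#' by Levenberg-Marquardt with box constraints (minpack.lm). Parameter
#' standard deviations come from the Gauss-Newton covariance at the
#' optimum. Flat traces (no resolvable signal above the noise) are
#' flagged degenerate and no rates are reported.
#'
#' The luminescence amplitude per unit translocated fraction is a
#' calibration constant of the assay and is held fixed by default:
#' with it free, the model is structurally unidentifiable -- rescaling
#' (k_unfold, k_incap, amplitude, pre_translocated) along
#' (c k_unfold, a - c k_unfold, A/c, c T0) with a = k_unfold + k_incap
#' fixed leaves the curve exactly unchanged, so only the total decay rate
#' a, k_transloc and amplitude products are determined by a single trace.
#' Pass `amplitude = NULL` to fit it anyway (the returned split between
#' k_unfold and k_incap is then arbitrary along that ridge).
#'
#' @param trace A [luminescence_trace()].
#' @param amplitude Calibrated amplitude in RLU per unit translocated
#'   fraction, or `NULL` to treat it as free. Default:
#'   `trace_nuisance()$amplitude`.
#' @param init Optional named vector overriding the automatic starts
#'   (names among k_unfold, k_transloc, k_incap, amplitude, k_deplete,
#'   baseline, pre_translocated).
#' @param fixed Optional named vector of parameters to hold fixed.
#' @param weights Optional per-point weights (default homoscedastic).
#' @return An object of class `translocation_fit`: `rates`
#'   ([translocation_rates()]), `nuisance` ([trace_nuisance()]), `sd`
#'   (named vector), `rss`, `n_points`, `residuals`, `fitted`,
#'   `degenerate`, `convergence`.
#' @export
fit_trace <- function(trace, amplitude = trace_nuisance()$amplitude,
                      init = NULL, fixed = NULL, weights = NULL) {
  stopifnot(inherits(trace, "luminescence_trace"))
  if (!is.null(amplitude) && !"amplitude" %in% names(fixed)) {
    fixed <- c(fixed, amplitude = amplitude)
  }
  sel <- trace$time >= trace$t_dtt
  t <- trace$time[sel] - trace$t_dtt
  y <- trace$rlu[sel]
  if (length(t) < 50) stop("need at least 50 post-reduction samples")
  if (is.null(weights)) weights <- rep(1, length(y))
  # degeneracy screen: compare the range of a smoothed trace to the
  # point-to-point noise
  noise <- stats::mad(diff(y)) / sqrt(2)
  sm <- stats::filter(y, rep(1 / 9, 9), sides = 2)
  sm <- sm[!is.na(sm)]
  if (noise == 0) noise <- stats::sd(y) / 10 + 1e-12
  if (diff(range(sm)) < 3 * noise) {
    return(structure(list(rates = NULL, nuisance = NULL, sd = NULL,
                          rss = sum((y - mean(y))^2), n_points = length(y),
                          residuals = y - mean(y), fitted = rep(mean(y),
                            length(y)),
                          degenerate = TRUE, convergence = NA_integer_),
                     class = "translocation_fit"))
  }
  lower <- c(k_unfold = 0, k_transloc = 0, k_incap = 0,
             amplitude = 1e-6, k_deplete = 0, baseline = 0,
             pre_translocated = 0)
  upper <- c(k_unfold = 10, k_transloc = 10, k_incap = 10,
             amplitude = Inf, k_deplete = 1, baseline = Inf,
             pre_translocated = 1)
  free <- setdiff(.trace_par_names, names(fixed))
  nl_names <- c("k_unfold", "k_transloc", "k_incap", "k_deplete")
  amp_fixed <- if ("amplitude" %in% names(fixed))
    fixed[["amplitude"]] else NULL
  # stage 1: variable projection over the four rates; the linear
  # coefficients (amplitude x translocated fraction, amplitude x T0,
  # baseline) are solved per rate vector by weighted least squares
  varpro_ok <- !any(c("baseline", "pre_translocated") %in% names(fixed))
  rate_starts <- expand.grid(k_unfold = c(0.002, 0.02, 0.1),
                             k_transloc = c(0.1, 0.3),
                             k_incap = 0.05,
                             k_deplete = 0.01)
  if (!is.null(init)) {
    s0 <- c(k_unfold = 0.02, k_transloc = 0.25, k_incap = 0.05,
            k_deplete = 0.01)
    s0[intersect(names(init), nl_names)] <-
      init[intersect(names(init), nl_names)]
    rate_starts <- rbind(s0, rate_starts)
  }
  start_full <- NULL
  if (varpro_ok) {
    varpro <- function(th) {
      th <- stats::setNames(pmax(th, 0), nl_names)
      if (!is.null(fixed)) {
        fx <- intersect(names(fixed), nl_names)
        th[fx] <- fixed[fx]
      }
      tfrac <- translocation_states(
        t, translocation_rates(th[1], th[2], th[3]))$translocated
      dep <- exp(-th[4] * t / 60)
      if (is.null(amp_fixed)) {
        X <- cbind(dep * tfrac, dep, 1)
        off <- 0
      } else {
        X <- cbind(dep, 1)
        off <- amp_fixed * dep * tfrac
      }
      # all linear coefficients are sign-constrained (amplitude > 0,
      # T0 >= 0, baseline >= 0): iteratively drop violating columns
      keep <- seq_len(ncol(X))
      cf <- rep(0, ncol(X))
      repeat {
        sol <- tryCatch(stats::lm.wfit(X[, keep, drop = FALSE], y - off,
                                       weights)$coefficients,
                        error = function(e) NULL)
        if (is.null(sol) || any(!is.finite(sol))) return(1e12)
        neg <- which(sol < 0)
        if (!length(neg)) {
          cf[] <- 0
          cf[keep] <- sol
          break
        }
        keep <- keep[-neg]
        if (!length(keep)) return(1e12)
      }
      if (is.null(amp_fixed) && cf[1] <= 0) return(1e12)
      rss <- sum(weights * (y - off - X %*% cf)^2)
      attr(rss, "coef") <- cf
      rss
    }
    best_v <- NULL
    for (i in seq_len(nrow(rate_starts))) {
      op <- stats::optim(unlist(rate_starts[i, ]), function(th) varpro(th),
                         method = "L-BFGS-B",
                         lower = rep(0, 4),
                         upper = c(10, 10, 10, 1),
                         control = list(maxit = 300))
      if (is.null(best_v) || op$value < best_v$value) best_v <- op
    }
    thv <- stats::setNames(pmax(best_v$par, 0), nl_names)
    cf <- attr(varpro(thv), "coef")
    if (is.null(amp_fixed)) {
      a_hat <- cf[1]; t0_hat <- max(cf[2] / cf[1], 0); b_hat <- cf[3]
    } else {
      a_hat <- amp_fixed; t0_hat <- max(cf[1] / amp_fixed, 0)
      b_hat <- cf[2]
    }
    can <- .canonical_rates(thv[["k_unfold"]], thv[["k_transloc"]],
                            thv[["k_incap"]])
    thv[c("k_unfold", "k_transloc", "k_incap")] <- can
    start_full <- c(thv["k_unfold"], thv["k_transloc"], thv["k_incap"],
                    amplitude = unname(a_hat),
                    k_deplete = unname(thv["k_deplete"]),
                    baseline = unname(b_hat),
                    pre_translocated = unname(t0_hat))
    start_full <- start_full[.trace_par_names]
  }
  # stage 2: full Levenberg-Marquardt polish of the free parameters
  b0 <- stats::quantile(y, 0.02)
  amp0 <- if (is.null(amp_fixed))
    max(diff(range(y)) / 0.3, 10 * noise) else amp_fixed
  fallback_starts <- lapply(seq_len(nrow(rate_starts)), function(i) {
    s <- c(unlist(rate_starts[i, c("k_unfold", "k_transloc", "k_incap")]),
           amplitude = unname(amp0), k_deplete = 0.01,
           baseline = unname(b0), pre_translocated = 0.02)
    s[.trace_par_names]
  })
  starts <- if (!is.null(start_full)) list(start_full) else fallback_starts
  if (!is.null(init)) {
    s <- starts[[1]]
    s[names(init)] <- init
    starts <- c(starts, list(s))
  }
  resid_fn <- function(th) {
    par <- stats::setNames(numeric(length(.trace_par_names)),
                           .trace_par_names)
    par[free] <- th
    if (!is.null(fixed)) par[names(fixed)] <- fixed
    sqrt(weights) * (y - .trace_model(as.list(par), t))
  }
  best <- NULL
  for (s in starts) {
    th0 <- pmin(pmax(s[free], lower[free]), pmin(upper[free], 1e6))
    fit <- try(minpack.lm::nls.lm(
      par = th0, fn = resid_fn, lower = lower[free], upper = upper[free],
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("trace fit failed from every start")
  par <- stats::setNames(numeric(length(.trace_par_names)),
                         .trace_par_names)
  par[free] <- best$par
  if (!is.null(fixed)) par[names(fixed)] <- fixed
  par <- as.list(par)
  rate_names <- c("k_unfold", "k_transloc", "k_incap")
  if (!any(rate_names %in% names(fixed))) {
    can <- .canonical_rates(par$k_unfold, par$k_transloc, par$k_incap)
    par[rate_names] <- as.list(unname(can))
  }
  fitted <- .trace_model(par, t)
  rss <- sum(weights * (y - fitted)^2)
  dof <- max(length(y) - length(free), 1)
  sigma2 <- rss / dof
  J <- .trace_jacobian(par, t, free)
  # at boundaries (e.g. k_deplete = 0) some columns become collinear;
  # fall back to the pseudo-inverse for the identified directions
  covm <- tryCatch(sigma2 * solve(crossprod(J * sqrt(weights))),
                   error = function(e)
                     sigma2 * MASS::ginv(crossprod(J * sqrt(weights))))
  sds <- stats::setNames(sqrt(pmax(diag(covm), 0)), free)
  structure(list(
    rates = translocation_rates(par$k_unfold, par$k_transloc, par$k_incap),
    nuisance = trace_nuisance(par$amplitude, par$k_deplete, par$baseline,
                              par$pre_translocated),
    sd = sds, rss = rss, n_points = length(y),
    residuals = y - fitted, fitted = fitted,
    degenerate = FALSE, convergence = best$info),
    class = "translocation_fit")
}

#' @export
print.translocation_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate trace fit: no signal resolvable above noise\n")
    return(invisible(x))
  }
  cat(sprintf("Translocation trace fit (%d points, RSS = %.3g)\n",
              x$n_points, x$rss))
  r <- x$rates
  cat(sprintf("  k_unfold   = %.4g 1/min (sd %.2g)\n", r$k_unfold,
              x$sd[["k_unfold"]]))
  cat(sprintf("  k_transloc = %.4g 1/min (sd %.2g)\n", r$k_transloc,
              x$sd[["k_transloc"]]))
  cat(sprintf("  k_incap    = %.4g 1/min (sd %.2g)\n", r$k_incap,
              x$sd[["k_incap"]]))
  invisible(x)
}

#' Aggregate replicate trace fits
#'
#' Arithmetic mean and sample SD of each kinetic rate across independent
#' replicate fits.
#'
#' @param fits List of `translocation_fit` objects (degenerate fits are
#'   dropped with a warning).
#' @return Data frame with rows `k_unfold`, `k_transloc`, `k_incap` and
#'   columns `mean`, `sd`, `n`; `sd` is `NA` with attribute
#'   `"single_fit" = TRUE` when only one fit is supplied.
#' @export
aggregate_replicates <- function(fits) {
  deg <- vapply(fits, function(f) isTRUE(f$degenerate), logical(1))
  if (any(deg)) {
    warning(sum(deg), " degenerate fit(s) dropped")
    fits <- fits[!deg]
  }
  stopifnot(length(fits) >= 1)
  m <- t(vapply(fits, function(f) c(f$rates$k_unfold, f$rates$k_transloc,
                                    f$rates$k_incap), numeric(3)))
  colnames(m) <- c("k_unfold", "k_transloc", "k_incap")
  out <- data.frame(mean = colMeans(m),
                    sd = if (nrow(m) >= 2) apply(m, 2, stats::sd) else
                      NA_real_,
                    n = nrow(m))
  attr(out, "single_fit") <- nrow(m) < 2
  out
}

#' Derived rate-ratio comparisons across conditions
#'
#' Reports, per condition, how much slower unfolding is than
#' translocation (k_transloc / k_unfold), and all pairwise cross-condition
#' unfolding-rate ratios, unrounded and rounded to one significant figure.
#'
#' @param table Data frame with columns `condition`, `k_unfold`,
#'   `k_transloc`.
#' @param conditions Conditions that must be present (default: all in the
#'   table).
#' @return List with `within` (per-condition k_transloc/k_unfold) and
#'   `between` (pairwise k_unfold ratios), each with a `rounded` column
#'   (one significant figure).
#' @export
rate_ratio_report <- function(table, conditions = table$condition) {
  missing_cond <- setdiff(conditions, table$condition)
  if (length(missing_cond)) {
    stop("missing condition(s): ", paste(missing_cond, collapse = ", "))
  }
  tab <- table[match(conditions, table$condition), ]
  within <- data.frame(condition = tab$condition,
                       transloc_over_unfold = tab$k_transloc / tab$k_unfold)
  within$rounded <- signif(within$transloc_over_unfold, 1)
  pairs <- expand.grid(num = tab$condition, den = tab$condition,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$num != pairs$den, ]
  pairs$unfold_ratio <- tab$k_unfold[match(pairs$num, tab$condition)] /
    tab$k_unfold[match(pairs$den, tab$condition)]
  pairs$rounded <- signif(pairs$unfold_ratio, 1)
  list(within = within, between = pairs)
}
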