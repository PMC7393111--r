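#' Full synthetic round trip: simulate, fit, match
#'
#' Exercises the whole pipeline against a known ground truth. A rupture
#' dataset is simulated from `truth` at two pulling speeds and fit with
#' the binless likelihood; a luminescence trace is simulated with an
#' unfolding rate equal to the inverse folded-state lifetime at the true
#' motor force `f_true` and fit with the kinetic model; the two fits are
#' then matched to recover the motor force with a propagated SD.
#'
#' @param seed Integer seed driving every random stage.
#' @param f_true True constant force in pN. Default 10.6.
#' @param truth Ground-truth [barrier_params()]. Default: the MTX
#'   reference landscape.
#' @param rates Reference translocation/incapacitation rates supplying
#'   k_transloc and k_incap for the trace.
#' @param n_per_speed Rupture events per pulling speed. Default 150.
#' @param n_bootstrap Bootstrap replicates for the barrier fit.
#'   Default 100.
#' @return List of class `secforce_demo`: `f_true`, `estimate`
#'   (a `translocon_force_estimate`), `barrier_fit`, `trace_fit`,
#'   `k_unfold_true` (1/min), `recovered_within_sd`.
#' @export
run_demo <- function(seed = 1L, f_true = 10.6,
                     truth = mdhfr_barrier_params("MTX"),
                     rates = mdhfr_translocation_rates()[2, ],
                     n_per_speed = 150, n_bootstrap = 100) {
  # stage 1: force spectroscopy
  cfg <- rip_sim_config(truth, n_per_speed = n_per_speed,
                        condition = "demo", seed = seed)
  events <- simulate_rip_dataset(cfg)
  bfit <- fit_global(events, nu = truth$nu,
                     thermal_energy = truth$thermal_energy,
                     n_bootstrap = n_bootstrap, seed = seed + 1L)
  # stage 2: translocation kinetics at the true force
  k_unfold_true <- 60 * unfolding_rate(f_true, truth)   # 1/s -> 1/min
  tr_rates <- translocation_rates(k_unfold_true, rates$k_transloc,
                                  rates$k_incap)
  trace <- simulate_trace(trace_sim_config(tr_rates, condition = "demo",
                                           seed = seed + 2L))
  tfit <- fit_trace(trace)
  # stage 3: matching
  est <- propagate_force_uncertainty(tfit$rates$k_unfold,
                                     tfit$sd[["k_unfold"]], bfit,
                                     seed = seed + 3L)
  structure(list(f_true = f_true, estimate = est, barrier_fit = bfit,
                 trace_fit = tfit, k_unfold_true = k_unfold_true,
                 recovered_within_sd =
                   abs(est$force - f_true) <= pmax(est$sd_force, 1e-6)),
            class = "secforce_demo")
}

#' @export
print.secforce_demo <- function(x, ...) {
  cat("Synthetic round trip: simulate -> fit -> match\n")
  cat(sprintf("  true force          : %.2f pN\n", x$f_true))
  cat(sprintf("  true k_unfold       : %.4g 1/min\n", x$k_unfold_true))
  cat(sprintf("  recovered k_unfold  : %.4g 1/min\n",
              x$trace_fit$rates$k_unfold))
  cat(sprintf("  recovered force     : %.2f +/- %.2f pN\n",
              x$estimate$force, x$estimate$sd_force))
  cat(sprintf("  within propagated SD: %s\n", x$recovered_within_sd))
  invisible(x)
}
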