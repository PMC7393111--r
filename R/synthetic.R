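# Synthetic-data generators. The defaults are the study conditions the
# analyses assume: force ramps at 20 and 150 nm/s with ~0.1 pN/nm trap
# stiffness and log-normal per-molecule loading-rate scatter; 30-min
# luminescence traces sampled at 0.2 Hz with signal-dependent Gaussian
# noise.

#' Configuration for simulating a rupture-event dataset
#'
#' @param params A [barrier_params()] object (ground truth).
#' @param trap_velocities Pulling velocities in nm/s. Default c(20, 150).
#' @param stiffness Trap stiffness in pN/nm. Default 0.1.
#' @param n_per_speed Events per velocity (recycled to match
#'   `trap_velocities`).
#' @param loading_rate_cv Coefficient of variation of the log-normal
#'   per-molecule loading-rate scatter (median 1). Default 0.3.
#' @param censor_at Optional force (pN) above which events are censored
#'   (e.g. the DNA overstretching plateau), or `NULL`.
#' @param target_contour_change Contour-length change (nm) used to
#'   back-compute the extension change at each rupture force. Default:
#'   complete mDHFR unfolding.
#' @param condition Label stored on each event.
#' @param seed Integer seed.
#' @return An object of class `rip_sim_config`.
#' @export
rip_sim_config <- function(params,
                           trap_velocities = c(20, 150),
                           stiffness = 0.1,
                           n_per_speed = 100,
                           loading_rate_cv = 0.3,
                           censor_at = NULL,
                           target_contour_change =
                             expected_contour_change(MDHFR_N_RESIDUES),
                           condition = "sim",
                           seed = 1L) {
  stopifnot(inherits(params, "barrier_params"), all(trap_velocities > 0),
            stiffness > 0, all(n_per_speed >= 0), loading_rate_cv >= 0)
  structure(list(params = params, trap_velocities = trap_velocities,
                 stiffness = stiffness,
                 n_per_speed = rep_len(n_per_speed,
                                       length(trap_velocities)),
                 loading_rate_cv = loading_rate_cv, censor_at = censor_at,
                 target_contour_change = target_contour_change,
                 condition = condition, seed = seed),
            class = "rip_sim_config")
}

#' Simulate a force-ramp rupture-event dataset
#'
#' Per event: the loading rate is r = stiffness x velocity x L with L
#' log-normal (median 1, CV as configured), the rupture force is drawn by
#' exact inverse-transform sampling from the Kramers-like rupture
#' distribution at that r, and the extension change is back-computed
#' through the worm-like chain from the configured contour-length change,
#' dx = dL x z(F). Events at the model's critical force, or above
#' `censor_at`, are marked censored.
#'
#' @param config A [rip_sim_config()].
#' @param model A [polymer_model()] for the extension back-computation.
#' @return A [rip_events()] data frame with columns `molecule_id`,
#'   `condition`, `rip_force`, `loading_rate`, `delta_extension`,
#'   `trap_velocity`, `censored`.
#' @export
simulate_rip_dataset <- function(config, model = polymer_model()) {
  stopifnot(inherits(config, "rip_sim_config"))
  set.seed(config$seed)
  sdlog <- sqrt(log(1 + config$loading_rate_cv^2))
  pieces <- list()
  for (i in seq_along(config$trap_velocities)) {
    n <- config$n_per_speed[i]
    if (n == 0) next
    v <- config$trap_velocities[i]
    L <- stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
    r <- config$stiffness * v * L
    f <- sample_rip_forces(n, r, config$params)
    cen <- attr(f, "censored")
    f <- as.numeric(f)
    if (!is.null(config$censor_at)) {
      over <- f > config$censor_at
      f[over] <- config$censor_at
      cen <- cen | over
    }
    z <- wlc_relative_extension(f, model, config$params$thermal_energy)
    pieces[[length(pieces) + 1]] <- data.frame(
      molecule_id = sprintf("v%g_m%04d", v, seq_len(n)),
      condition = config$condition,
      rip_force = f,
      loading_rate = r,
      delta_extension = config$target_contour_change * z,
      trap_velocity = v,
      censored = cen)
  }
  rip_events(do.call(rbind, pieces))
}

#' Configuration for simulating a luminescence trace
#'
#' @param rates A [translocation_rates()] object (ground truth, 1/min).
#' @param nuisance A [trace_nuisance()] object.
#' @param duration Post-reduction recording length in minutes. Default 30.
#' @param sampling_rate Sampling rate in Hz. Default 0.2.
#' @param pre_dtt Pre-reduction recording length in minutes (flat stalled
#'   phase). Default 0.
#' @param noise_floor Additive noise SD in RLU. Default 0.05.
#' @param noise_scale Signal-dependent noise coefficient
#'   (SD = noise_floor + noise_scale * sqrt(signal)). Default 0.02.
#' @param condition,replicate_id Labels.
#' @param seed Integer seed.
#' @return An object of class `trace_sim_config`.
#' @export
trace_sim_config <- function(rates, nuisance = trace_nuisance(),
                             duration = 30, sampling_rate = 0.2,
                             pre_dtt = 0, noise_floor = 0.05,
                             noise_scale = 0.02, condition = "sim",
                             replicate_id = "r1", seed = 1L) {
  stopifnot(inherits(rates, "translocation_rates"),
            inherits(nuisance, "trace_nuisance"),
            duration > 0, sampling_rate > 0, pre_dtt >= 0,
            noise_floor >= 0, noise_scale >= 0)
  structure(list(rates = rates, nuisance = nuisance, duration = duration,
                 sampling_rate = sampling_rate, pre_dtt = pre_dtt,
                 noise_floor = noise_floor, noise_scale = noise_scale,
                 condition = condition, replicate_id = replicate_id,
                 seed = seed),
            class = "trace_sim_config")
}

#' Simulate a real-time translocation trace
#'
#' Evaluates [model_signal()] on the configured time grid and adds
#' heteroscedastic Gaussian noise, epsilon ~ Normal(0, noise_floor +
#' noise_scale * sqrt(signal)), mimicking the shot-noise-like behaviour
#' of photon counting. An optional pre-reduction segment is held at the
#' t = 0 signal level.
#'
#' @param config A [trace_sim_config()].
#' @return A [luminescence_trace()] whose `t_dtt` marks the reduction
#'   time.
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  set.seed(config$seed)
  dt <- 1 / config$sampling_rate
  t_post <- seq(0, config$duration * 60, by = dt)
  sig_post <- model_signal(t_post, config$rates, config$nuisance)
  if (config$pre_dtt > 0) {
    t_pre <- seq(-config$pre_dtt * 60, -dt, by = dt)
    sig <- c(rep(sig_post[1], length(t_pre)), sig_post)
    t_all <- c(t_pre, t_post)
  } else {
    sig <- sig_post
    t_all <- t_post
  }
  sd_pt <- config$noise_floor + config$noise_scale * sqrt(pmax(sig, 0))
  rlu <- sig + stats::rnorm(length(sig), 0, sd_pt)
  luminescence_trace(time = t_all - min(t_all), rlu = rlu,
                     t_dtt = -min(t_all), condition = config$condition,
                     replicate_id = config$replicate_id)
}

# two-component apo stand-in: the apo protein populates (at least) two
# native states of distinct mechanical stability; synthetic mixture with
# a mechanically soft and a stiff component, 60/40
.apo_mixture_components <- function(thermal_energy = KBT_ROOM) {
  list(weight_soft = 0.6,
       soft = barrier_params(3.0, 2.0, 12.0,
                             thermal_energy = thermal_energy),
       stiff = barrier_params(5.46, 1.67, 15.3,
                              thermal_energy = thermal_energy))
}

#' Write a demonstration suite of synthetic datasets
#'
#' Generates, under `out_dir`, one rupture-event CSV per condition (MTX
#' and M+N at the reference barrier parameters; a synthetic two-component
#' "apo mixture" for the shape diagnostic), one luminescence-trace CSV
#' (plus YAML sidecar) per condition at the reference translocation
#' rates, and a `manifest.json` recording every ground-truth parameter
#' and seed so closed-loop recovery tests can be run against the files.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed; per-file seeds are derived from it.
#' @param n_per_speed Rupture events per pulling speed. Default 150.
#' @return The manifest, invisibly; files are written under `out_dir`.
#' @export
make_demo_suite <- function(out_dir, seed = 1L, n_per_speed = 150) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  rates_tab <- mdhfr_translocation_rates()
  manifest <- list(seed = seed, files = list(), ground_truth = list())
  slug <- c("apo" = "apo", "MTX" = "mtx", "M+N" = "mn")
  # rupture datasets: single-barrier for the liganded conditions
  for (cond in c("MTX", "M+N")) {
    bp <- mdhfr_barrier_params(cond)
    cfg <- rip_sim_config(bp, n_per_speed = n_per_speed, condition = cond,
                          seed = seed + match(cond, c("MTX", "M+N")))
    ev <- simulate_rip_dataset(cfg)
    path <- file.path(out_dir, paste0("rips_", slug[[cond]], ".csv"))
    write_rip_events(ev, path)
    manifest$files[[paste0("rips_", slug[[cond]])]] <- basename(path)
    manifest$ground_truth[[paste0("rips_", slug[[cond]])]] <- list(
      log10_tau0 = bp$log10_tau0, dx_ddagger = bp$dx_ddagger,
      dG_ddagger = bp$dG_ddagger, nu = bp$nu,
      thermal_energy = bp$thermal_energy, n_per_speed = n_per_speed,
      seed = cfg$seed)
  }
  # apo: 60/40 mixture of a soft and a stiff component
  mix <- .apo_mixture_components()
  n_soft <- round(0.6 * n_per_speed)
  cfg_s <- rip_sim_config(mix$soft, n_per_speed = n_soft,
                          condition = "apo", seed = seed + 11L)
  cfg_h <- rip_sim_config(mix$stiff, n_per_speed = n_per_speed - n_soft,
                          condition = "apo", seed = seed + 12L)
  ev_apo <- rbind(simulate_rip_dataset(cfg_s), simulate_rip_dataset(cfg_h))
  path <- file.path(out_dir, "rips_apo_mixture.csv")
  write_rip_events(ev_apo, path)
  manifest$files$rips_apo_mixture <- basename(path)
  manifest$ground_truth$rips_apo_mixture <- list(
    weight_soft = mix$weight_soft,
    soft = list(log10_tau0 = mix$soft$log10_tau0,
                dx_ddagger = mix$soft$dx_ddagger,
                dG_ddagger = mix$soft$dG_ddagger),
    stiff = list(log10_tau0 = mix$stiff$log10_tau0,
                 dx_ddagger = mix$stiff$dx_ddagger,
                 dG_ddagger = mix$stiff$dG_ddagger),
    seeds = c(cfg_s$seed, cfg_h$seed))
  # one trace per condition at the reference rates
  for (i in seq_len(nrow(rates_tab))) {
    cond <- rates_tab$condition[i]
    rr <- translocation_rates(rates_tab$k_unfold[i],
                              rates_tab$k_transloc[i],
                              rates_tab$k_incap[i])
    cfg <- trace_sim_config(rr, condition = cond, replicate_id = "demo",
                            seed = seed + 20L + i)
    tr <- simulate_trace(cfg)
    path <- file.path(out_dir, paste0("trace_", slug[[cond]], ".csv"))
    write_trace(tr, path)
    manifest$files[[paste0("trace_", slug[[cond]])]] <- basename(path)
    manifest$ground_truth[[paste0("trace_", slug[[cond]])]] <- list(
      k_unfold = rr$k_unfold, k_transloc = rr$k_transloc,
      k_incap = rr$k_incap, seed = cfg$seed)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
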