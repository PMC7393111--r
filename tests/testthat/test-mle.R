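test_that("negative log-likelihood matches an independent quadrature density", {
  mtx <- mtx_params()
  ev <- rip_events(data.frame(rip_force = 44, loading_rate = 12))
  # independent density: hazard by quadrature instead of the closed form
  lam_q <- stats::integrate(function(x) unfolding_rate(x, mtx) / 12,
                            0, 44, rel.tol = 1e-10)$value
  p_q <- unfolding_rate(44, mtx) / 12 * exp(-lam_q)
  expect_equal(negative_loglik(mtx, ev), -log(p_q), tolerance = 1e-6)
})

test_that("log-likelihood is additive and order-invariant", {
  mtx <- mtx_params()
  ev <- simulate_rip_dataset(rip_sim_config(mtx, n_per_speed = 30,
                                            seed = 3))
  nll <- negative_loglik(mtx, ev)
  expect_equal(negative_loglik(mtx, rbind(ev, ev)), 2 * nll,
               tolerance = 1e-10)
  expect_equal(negative_loglik(mtx, ev[sample(nrow(ev)), ]), nll,
               tolerance = 1e-10)
  # censored events enter through the survival
  evc <- rip_events(data.frame(rip_force = mtx$critical_force,
                               loading_rate = 12, censored = TRUE))
  expect_equal(negative_loglik(mtx, evc),
               cumulative_hazard(mtx$critical_force, 12, mtx),
               tolerance = 1e-10)
})

test_that("global binless fit recovers generating parameters", {
  fit <- mtx_sim_fit()
  truth <- c(5.46, 1.67, 15.3)
  expect_true(all(abs(fit$estimate - truth) / fit$sd < 3))
  expect_equal(fit$convergence, 0)
  expect_false(fit$at_bound)
  # reconstructed density is a proper density over the observed range
  dens <- reconstructed_density(fit, mtx_sim_events(),
                                seq(0, 120, by = 0.25))
  expect_true(all(dens$density >= 0))
  expect_equal(sum(dens$density) * 0.25, 1, tolerance = 0.01)
})

test_that("likelihood at the truth beats perturbed parameters at large n", {
  mtx <- mtx_params()
  f <- sample_rip_forces(5000, 8, mtx, seed = 17)
  ev <- rip_events(data.frame(rip_force = as.numeric(f), loading_rate = 8,
                              censored = attr(f, "censored")))
  nll0 <- negative_loglik(mtx, ev)
  set.seed(18)
  for (i in 1:20) {
    pert <- barrier_params(5.46 + rnorm(1, 0, 0.4),
                           max(1.67 + rnorm(1, 0, 0.2), 0.1),
                           max(15.3 + rnorm(1, 0, 1.5), 2))
    expect_gt(negative_loglik(pert, ev), nll0 - 1e-6)
  }
})

test_that("pooling two pulling speeds tightens the intrinsic-lifetime estimate", {
  mtx <- mtx_params()
  one <- simulate_rip_dataset(rip_sim_config(mtx, trap_velocities = 150,
                                             n_per_speed = 120, seed = 5))
  two <- simulate_rip_dataset(rip_sim_config(mtx, n_per_speed = 60,
                                             seed = 5))
  f1 <- suppressWarnings(fit_global(one, n_bootstrap = 40, seed = 6))
  f2 <- suppressWarnings(fit_global(two, n_bootstrap = 40, seed = 6))
  expect_lt(f2$sd[["log10_tau0"]], f1$sd[["log10_tau0"]])
})

test_that("a single-rate dataset triggers the loading-rate span warning", {
  mtx <- mtx_params()
  ev <- simulate_rip_dataset(rip_sim_config(mtx, trap_velocities = 150,
                                            loading_rate_cv = 0.05,
                                            n_per_speed = 30, seed = 2))
  expect_warning(fit_global(ev, uncertainty = "hessian"), "decade")
})

test_that("lifetime band is centred on tau and widens when extrapolating", {
  fit <- mtx_sim_fit()
  # observed rupture forces span roughly 16-56 pN; 5 pN is extrapolation
  band <- lifetime_band(fit, c(0, 5, 35, 52), n_draws = 400, seed = 2)
  expect_equal(band$lifetime[1], fit$params$tau0, tolerance = 1e-9)
  relw <- band$sd / band$lifetime
  expect_gt(relw[2], relw[3])   # below the data range
  expect_gt(relw[4], relw[3])   # above it
  # zero parameter uncertainty collapses the band
  fit0 <- fit
  fit0$bootstrap_replicates <- NULL
  fit0$covariance <- matrix(0, 3, 3)
  band0 <- lifetime_band(fit0, c(5, 15), n_draws = 100, seed = 1)
  expect_equal(band0$sd, c(0, 0))
})

test_that("binned transform falls inside the binless lifetime band", {
  mtx <- mtx_params()
  ev <- simulate_rip_dataset(rip_sim_config(mtx, n_per_speed = 60,
                                            seed = 77))
  fit <- suppressWarnings(fit_global(ev, uncertainty = "hessian"))
  # per pulling speed; the highest-force bin of each subset carries the
  # known edge bias of the histogram estimator and is excluded
  for (v in c(20, 150)) {
    sub <- ev[ev$trap_velocity == v & !ev$censored, ]
    tab <- binned_lifetime_transform(sub, 4)
    tab <- tab[tab$count >= 8, ]
    tab <- tab[-nrow(tab), ]
    band <- lifetime_band(fit, tab$force, n_draws = 500, seed = 3)
    expect_true(all(tab$lifetime >= band$lifetime - 2 * band$sd &
                      tab$lifetime <= band$lifetime + 2 * band$sd))
  }
})

test_that("estimator error shrinks with sample size", {
  mtx <- mtx_params()
  err <- function(n, seed) {
    ev <- simulate_rip_dataset(rip_sim_config(mtx, n_per_speed = n,
                                              seed = seed))
    ft <- suppressWarnings(fit_global(ev, uncertainty = "hessian"))
    abs(ft$estimate - c(5.46, 1.67, 15.3)) / c(5.46, 1.67, 15.3)
  }
  e_small <- rowMeans(vapply(1:3, function(s) err(50, s), numeric(3)))
  e_big <- rowMeans(vapply(1:3, function(s) err(500, s), numeric(3)))
  expect_lt(mean(e_big), mean(e_small))
})
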