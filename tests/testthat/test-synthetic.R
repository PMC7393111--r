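test_that("generators are pure functions of configuration and seed", {
  mtx <- mtx_params()
  cfg <- rip_sim_config(mtx, n_per_speed = 50, seed = 4)
  expect_identical(simulate_rip_dataset(cfg), simulate_rip_dataset(cfg))
  cfg2 <- rip_sim_config(mtx, n_per_speed = 50, seed = 5)
  expect_false(identical(simulate_rip_dataset(cfg)$rip_force,
                         simulate_rip_dataset(cfg2)$rip_force))
  tcfg <- trace_sim_config(ref_rates("apo"), seed = 4)
  expect_identical(simulate_trace(tcfg)$rlu, simulate_trace(tcfg)$rlu)
  # zero noise reproduces the model exactly
  t0 <- trace_sim_config(ref_rates("apo"), noise_floor = 0,
                         noise_scale = 0, seed = 1)
  tr <- simulate_trace(t0)
  expect_equal(tr$rlu,
               model_signal(tr$time, ref_rates("apo"), trace_nuisance()),
               tolerance = 1e-12)
})

test_that("simulated rip datasets reflect the pulling-speed conditions", {
  mtx <- mtx_params()
  ev <- simulate_rip_dataset(rip_sim_config(mtx, n_per_speed = 5000,
                                            seed = 9))
  m20 <- mean(ev$rip_force[ev$trap_velocity == 20 & !ev$censored])
  m150 <- mean(ev$rip_force[ev$trap_velocity == 150 & !ev$censored])
  expect_lt(m20, m150)
  # fast pulls of the liganded protein rupture mostly above 40 pN
  expect_gt(mean(ev$rip_force[ev$trap_velocity == 150] > 40), 0.5)
  # one-sided configuration
  ev1 <- simulate_rip_dataset(rip_sim_config(mtx, n_per_speed = c(0, 20),
                                             seed = 1))
  expect_true(all(ev1$trap_velocity == 150))
  # explicit censoring at an overstretching plateau
  evc <- simulate_rip_dataset(rip_sim_config(mtx, n_per_speed = 2000,
                                             censor_at = 45, seed = 2))
  expect_true(all(evc$rip_force <= 45 + 1e-9))
  expect_true(any(evc$censored))
})

test_that("extension changes are consistent with the worm-like chain", {
  mtx <- mtx_params()
  ev <- simulate_rip_dataset(rip_sim_config(mtx, n_per_speed = 50,
                                            seed = 3))
  dl <- extension_to_contour_change(ev$delta_extension, ev$rip_force)
  expect_equal(dl, rep(expected_contour_change(186), nrow(ev)),
               tolerance = 1e-6)
})

test_that("sampled rupture forces pass a KS test against the model CDF", {
  mtx <- mtx_params()
  cdf <- function(q) rip_force_cdf(q, 3, mtx, policy = "raw")
  pass <- vapply(1:30, function(s) {
    f <- as.numeric(sample_rip_forces(300, 3, mtx, seed = s))
    suppressWarnings(stats::ks.test(f, cdf)$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("apo traces plateau within the recording window", {
  tr <- simulate_trace(trace_sim_config(ref_rates("apo"), seed = 2))
  sig <- model_signal(tr$time, ref_rates("apo"), trace_nuisance())
  n <- length(sig)
  i90 <- floor(0.9 * n)
  late <- abs(sig[n] - sig[i90]) / (tr$time[n] - tr$time[i90])
  peak <- max(abs(diff(sig) / diff(tr$time)))
  expect_lt(late, 0.05 * peak)
})

test_that("the demo suite writes reproducible files with usable truth", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- make_demo_suite(d1, seed = 3, n_per_speed = 60)
  m2 <- make_demo_suite(d2, seed = 3, n_per_speed = 60)
  expect_identical(m1$ground_truth, m2$ground_truth)
  for (f in unlist(m1$files)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # closed loop: refit the demo MTX rupture file against its own truth
  ev <- read_rip_events(file.path(d1, m1$files$rips_mtx))
  gt <- m1$ground_truth$rips_mtx
  ft <- fit_global(ev, nu = gt$nu, uncertainty = "hessian")
  truth <- c(gt$log10_tau0, gt$dx_ddagger, gt$dG_ddagger)
  expect_true(all(abs(ft$estimate - truth) / ft$sd < 3))
})
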