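test_that("rate law hits its zero-force limit and reference magnitudes", {
  mtx <- mtx_params()
  expect_equal(unfolding_rate(0, mtx), 10^(-5.46), tolerance = 1e-12)
  expect_equal(folded_lifetime(0, mtx), 10^5.46, tolerance = 1e-12)
  # liganded mDHFR unfolds spontaneously on the 1e-6/s scale
  expect_gt(unfolding_rate(0, mtx), 1e-6)
  expect_lt(unfolding_rate(0, mtx), 1e-5)
  # lifetime at the matching force is ~5.2e3 s (~1/0.0115 per minute)
  expect_equal(folded_lifetime(10.6, mtx), 5312.8, tolerance = 1e-4)
  # lifetimes fall monotonically with force for both parameter sets
  for (p in list(mtx, mn_params())) {
    taus <- folded_lifetime(seq(0, 30, by = 0.5), p)
    expect_true(all(diff(taus) < 0))
    expect_equal(unfolding_rate(seq(0, 30, 0.5), p) *
                   folded_lifetime(seq(0, 30, 0.5), p),
                 rep(1, 61), tolerance = 1e-12)
  }
})

test_that("nu = 1 collapses to the Bell rate law", {
  set.seed(7)
  bp <- barrier_params(3.2, 1.4, 17, nu = 1)
  f <- runif(20, 0, 30)
  bell <- 10^(-3.2) * exp(f * 1.4 / bp$thermal_energy)
  expect_equal(unfolding_rate(f, bp), bell, tolerance = 1e-12)
})

test_that("closed-form cumulative hazard agrees with quadrature", {
  set.seed(11)
  for (nu in c(1 / 2, 2 / 3, 1)) {
    for (i in 1:8) {
      bp <- barrier_params(runif(1, 2, 8), runif(1, 0.5, 3),
                           runif(1, 8, 25), nu = nu)
      fmax <- min(bp$peak_force, bp$critical_force) * 0.9
      f <- runif(1, 1, fmax)
      r <- runif(1, 0.5, 20)
      q <- stats::integrate(function(x) unfolding_rate(x, bp) / r, 0, f,
                            rel.tol = 1e-10)$value
      expect_lt(abs(cumulative_hazard(f, r, bp) - q) / q, 1e-6)
    }
  }
  mtx <- mtx_params()
  expect_identical(cumulative_hazard(0, 10, mtx), 0)
  expect_equal(cumulative_hazard(20, 5, mtx),
               2 * cumulative_hazard(20, 10, mtx), tolerance = 1e-12)
  expect_error(cumulative_hazard(10, -1, mtx), "positive")
})

test_that("ramp survival and rupture density account for all mass", {
  mtx <- mtx_params()
  f <- seq(0, 70, by = 0.5)
  s <- ramp_survival(f, 8, mtx)
  expect_equal(s[1], 1)
  expect_true(all(s > 0 & s <= 1))
  expect_true(all(diff(s) < 0))
  # capped policy: the density integrates to one over [0, Inf)
  total <- stats::integrate(function(x) rip_force_pdf(x, 8, mtx), 0, 200,
                            rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
  # raw policy: mass below the critical force plus residual survival is one
  fc <- mtx$critical_force
  m <- stats::integrate(function(x) rip_force_pdf(x, 8, mtx, "raw"),
                        0, fc * (1 - 1e-9), rel.tol = 1e-9)$value
  expect_equal(m + ramp_survival(fc * (1 - 1e-9), 8, mtx, "raw"), 1,
               tolerance = 1e-7)
  # raw policy refuses the super-critical region
  expect_error(unfolding_rate(fc + 1, mtx, policy = "raw"), "critical")
})

test_that("rupture-force distribution shifts as expected with loading rate", {
  mtx <- mtx_params()
  g <- seq(0.5, mtx$critical_force - 0.5, by = 0.05)
  mode10 <- g[which.max(rip_force_pdf(g, 10, mtx))]
  expect_gt(mode10, 40)
  expect_lt(mode10, 50)
  mean_f <- function(r) {
    stats::integrate(function(x) x * rip_force_pdf(x, r, mtx), 0, 200,
                     rel.tol = 1e-8)$value
  }
  expect_lt(mean_f(1), mean_f(10))
})

test_that("inverse-transform sampler reproduces the closed-form CDF", {
  mtx <- mtx_params()
  # low loading rate: censoring mass is negligible
  f1 <- sample_rip_forces(1e5, 2, mtx, seed = 5)
  expect_lt(sum(attr(f1, "censored")), 5)
  x <- sort(as.numeric(f1))
  ks <- max(abs(seq_along(x) / length(x) -
                  rip_force_cdf(x, 2, mtx, policy = "raw")))
  expect_lt(ks, 0.01)
  expect_gt(min(x), 0)
  # determinism
  f2 <- sample_rip_forces(100, 2, mtx, seed = 9)
  f3 <- sample_rip_forces(100, 2, mtx, seed = 9)
  f4 <- sample_rip_forces(100, 2, mtx, seed = 10)
  expect_identical(as.numeric(f2), as.numeric(f3))
  expect_false(identical(as.numeric(f2), as.numeric(f4)))
  # high loading rate: draws past the barrier are censored at F_c
  f5 <- sample_rip_forces(2e4, 15, mtx, seed = 6)
  expect_gt(sum(attr(f5, "censored")), 0)
  expect_true(all(as.numeric(f5)[attr(f5, "censored")] ==
                    mtx$critical_force))
})

test_that("binned lifetime transform recovers the lifetime curve", {
  mtx <- mtx_params()
  f <- sample_rip_forces(20000, 10, mtx, seed = 21)
  ev <- rip_events(data.frame(rip_force = as.numeric(f),
                              loading_rate = 10,
                              censored = attr(f, "censored")))
  tab <- binned_lifetime_transform(ev, bin_width = 2)
  # compare over the central 80% of probability mass
  qs <- as.numeric(f)[!attr(f, "censored")]
  lo <- stats::quantile(qs, 0.1); hi <- stats::quantile(qs, 0.9)
  mid <- tab$force >= lo & tab$force <= hi
  rel <- abs(tab$lifetime[mid] - folded_lifetime(tab$force[mid], mtx)) /
    folded_lifetime(tab$force[mid], mtx)
  expect_true(all(rel < 0.15))
})

test_that("binned transform estimator arithmetic on degenerate inputs", {
  ev1 <- rip_events(data.frame(rip_force = 20, loading_rate = 4))
  expect_warning(tab <- binned_lifetime_transform(ev1, bin_width = 2),
                 "single bin")
  # one event: S = 1/2, p = 1/dF, tau = dF/(2 r)
  expect_equal(tab$lifetime, 2 / (2 * 4))
  expect_equal(tab$count, 1L)
})

test_that("binned transform is stable under splitting the dataset", {
  mtx <- mtx_params()
  f <- sample_rip_forces(4000, 10, mtx, seed = 33)
  ev <- rip_events(data.frame(rip_force = as.numeric(f), loading_rate = 10,
                              censored = attr(f, "censored")))
  full <- binned_lifetime_transform(ev, 2)
  h1 <- binned_lifetime_transform(ev[seq(1, nrow(ev), 2), ], 2)
  h2 <- binned_lifetime_transform(ev[seq(2, nrow(ev), 2), ], 2)
  shared <- Reduce(intersect, list(full$force, h1$force, h2$force))
  shared <- shared[full$count[match(shared, full$force)] >= 100]
  avg <- (h1$lifetime[match(shared, h1$force)] +
            h2$lifetime[match(shared, h2$force)]) / 2
  rel <- abs(avg - full$lifetime[match(shared, full$force)]) /
    full$lifetime[match(shared, full$force)]
  expect_true(all(rel < 0.25))
})
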