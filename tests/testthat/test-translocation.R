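test_that("signal model limits and amplitudes are the closed-form ones", {
  nu <- trace_nuisance(amplitude = 1000, k_deplete = 0.02,
                       baseline = 50, pre_translocated = 0.1)
  t <- seq(0, 1800, by = 5)
  # no kinetics: only the decaying pre-translocated term plus baseline
  r0 <- translocation_rates(0, 0, 0)
  expect_equal(model_signal(t, r0, nu),
               1000 * 0.1 * exp(-0.02 * t / 60) + 50, tolerance = 1e-12)
  # no incapacitation, no depletion: everything is eventually imported
  nu2 <- trace_nuisance(1000, 0, 50, 0.1)
  r2 <- translocation_rates(0.05, 0.3, 0)
  expect_equal(model_signal(36000 * 60, r2, nu2), 1000 * 1.1 + 50,
               tolerance = 1e-3)
  # asymptotic translocated fractions for the reference conditions
  st_apo <- translocation_states(1e7, ref_rates("apo"))
  expect_equal(st_apo$translocated, 0.0251 / (0.0251 + 0.0658),
               tolerance = 1e-6)
  st_mn <- translocation_states(1e7, ref_rates("M+N"))
  expect_equal(st_mn$translocated, 0.00130 / (0.00130 + 0.0547),
               tolerance = 1e-6)
  expect_gt(st_apo$translocated, st_mn$translocated)
  expect_error(translocation_rates(-0.1, 0.2, 0.05))
})

test_that("state occupancies conserve mass and match an ODE solver", {
  skip_if_not_installed("deSolve")
  t <- seq(0, 3600, by = 30)
  set.seed(4)
  for (i in 1:5) {
    rr <- translocation_rates(runif(1, 0.001, 0.3), runif(1, 0.01, 0.5),
                              runif(1, 0, 0.2))
    st <- translocation_states(t, rr)
    expect_lt(max(abs(rowSums(st[, -1]) - 1)), 1e-10)
    ode <- deSolve::ode(
      c(S = 1, U = 0, T = 0), t / 60,
      function(tt, y, p) list(c(-(p[1] + p[3]) * y[1],
                                p[1] * y[1] - p[2] * y[2],
                                p[2] * y[2])),
      c(rr$k_unfold, rr$k_transloc, rr$k_incap),
      rtol = 1e-10, atol = 1e-12)
    expect_equal(st$stalled, unname(ode[, "S"]), tolerance = 1e-7)
    expect_equal(st$unfolded, unname(ode[, "U"]), tolerance = 1e-7)
    expect_equal(st$translocated, unname(ode[, "T"]), tolerance = 1e-7)
  }
  # degenerate k_transloc ~ a limit is continuous
  ra <- translocation_rates(0.05, 0.12, 0.07)          # kt == a exactly
  rb <- translocation_rates(0.05, 0.12 + 1e-7, 0.07)
  expect_equal(translocation_states(t, ra)$translocated,
               translocation_states(t, rb)$translocated, tolerance = 1e-5)
})

test_that("noiseless traces are recovered to numerical precision", {
  t <- seq(0, 1800, by = 5)
  nu <- trace_nuisance()
  for (cond in c("apo", "M+N")) {
    rr <- ref_rates(cond)
    tr <- luminescence_trace(t, model_signal(t, rr, nu), 0)
    ft <- fit_trace(tr)
    expect_false(ft$degenerate)
    expect_equal(ft$rates$k_unfold, rr$k_unfold, tolerance = 1e-6)
    expect_equal(ft$rates$k_transloc, rr$k_transloc, tolerance = 1e-6)
    expect_equal(ft$rates$k_incap, rr$k_incap, tolerance = 1e-6)
  }
})

test_that("noisy traces are recovered near the generating rates", {
  rr <- ref_rates("apo")
  errs <- vapply(1:5, function(s) {
    tr <- simulate_trace(trace_sim_config(rr, condition = "apo", seed = s))
    ft <- fit_trace(tr)
    abs(ft$rates$k_unfold - rr$k_unfold) / rr$k_unfold
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("swap-initialised fits land on the canonical assignment", {
  # the two-exponential swap twin is an exact symmetry; the canonical
  # branch keeps translocation faster than the stalled-pool decay
  rr <- ref_rates("apo")
  tr <- simulate_trace(trace_sim_config(rr, seed = 12))
  ft <- fit_trace(tr, init = c(k_unfold = rr$k_transloc,
                               k_transloc = rr$k_unfold))
  expect_equal(ft$rates$k_transloc, rr$k_transloc, tolerance = 0.15)
  expect_equal(ft$rates$k_unfold, rr$k_unfold, tolerance = 0.15)
  expect_gt(ft$rates$k_transloc,
            ft$rates$k_unfold + ft$rates$k_incap)
})

test_that("pure-noise traces are flagged degenerate", {
  set.seed(6)
  t <- seq(0, 1800, by = 5)
  tr <- luminescence_trace(t, rnorm(length(t), 100, 2), 0)
  ft <- fit_trace(tr)
  expect_true(ft$degenerate)
  expect_null(ft$rates)
  expect_error(fit_trace(luminescence_trace(1:20, rnorm(20), 1)),
               "at least 50")
})

test_that("replicate aggregation is exact arithmetic", {
  mk <- function(ku, kt = 0.24, ki = 0.06) {
    structure(list(rates = translocation_rates(ku, kt, ki),
                   degenerate = FALSE), class = "translocation_fit")
  }
  fits <- list(mk(0.02), mk(0.03))
  agg <- aggregate_replicates(fits)
  expect_equal(agg["k_unfold", "mean"], 0.025)
  expect_equal(agg["k_unfold", "sd"], sd(c(0.02, 0.03)))
  expect_equal(agg["k_unfold", "n"], 2)
  # permutation invariance
  expect_equal(aggregate_replicates(rev(fits)), agg)
  # identical fits have zero spread
  expect_equal(aggregate_replicates(list(mk(0.02), mk(0.02)))[1, "sd"], 0)
  # single fit: mean only, flagged
  one <- aggregate_replicates(list(mk(0.02)))
  expect_true(is.na(one[1, "sd"]))
  expect_true(attr(one, "single_fit"))
})

test_that("rate-ratio report reproduces the headline comparisons", {
  tab <- mdhfr_translocation_rates()
  rep <- rate_ratio_report(tab)
  apo <- rep$within[rep$within$condition == "apo", ]
  expect_equal(apo$transloc_over_unfold, 0.245 / 0.0251, tolerance = 1e-9)
  expect_equal(apo$rounded, 10)
  cross <- rep$between
  r <- cross[cross$num == "apo" & cross$den == "M+N", "unfold_ratio"]
  expect_equal(r, 0.0251 / 0.00130, tolerance = 1e-9)
  expect_lt(r, 20)
  expect_gt(r, 19)
  same <- rate_ratio_report(data.frame(condition = c("a", "b"),
                                       k_unfold = c(0.1, 0.1),
                                       k_transloc = c(0.1, 0.1)))
  expect_true(all(same$between$unfold_ratio == 1))
  expect_error(rate_ratio_report(tab, conditions = c("apo", "nope")),
               "missing condition")
})
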