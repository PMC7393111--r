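# Shared fixtures, computed lazily and cached for the whole test session.
.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

mtx_params <- function() mdhfr_barrier_params("MTX")
mn_params <- function() mdhfr_barrier_params("M+N")

# a moderately sized simulated MTX rupture dataset plus its hessian fit,
# reused across MLE, band and matching tests
mtx_sim_events <- function() with_cache("mtx_events", {
  simulate_rip_dataset(rip_sim_config(mtx_params(), n_per_speed = 200,
                                      seed = 101))
})

mtx_sim_fit <- function() with_cache("mtx_fit", {
  fit_global(mtx_sim_events(), uncertainty = "hessian")
})

# reference rates as translocation_rates objects, by condition label
ref_rates <- function(cond) {
  tab <- mdhfr_translocation_rates()
  i <- match(cond, tab$condition)
  translocation_rates(tab$k_unfold[i], tab$k_transloc[i], tab$k_incap[i])
}
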