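# Shared fixtures: small deterministic matrices and a reduced simulated
# scenario reused across test files.

tiny_counts <- function() {
  m <- matrix(c(1L, 2L, 0L, 5L, 10L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("taxA", "taxB", "taxC"), c("s1", "s2")))
  m
}

# reduced-scale scenario for fit-dependent tests (fast: N=24, T=150)
small_scenario <- function(seed = 5L, ...) {
  simulate_experiment(n_groups = 2, reps_per_group = 12, n_taxa = 150,
                      k = 3, n_controls = 50, n_spikes = 6, seed = seed, ...)
}

scenario_controls <- function(sim) {
  control_set(names(which(sim$truth$control_flags)), "empirical")
}

scenario_M <- function(sim) {
  build_replicate_matrix(sim$metadata, colnames(sim$counts))
}

# cached small fit shared by tests that only need *a* valid fit
.cache <- new.env()
small_fit <- function() {
  if (is.null(.cache$fit)) {
    sim <- small_scenario()
    .cache$sim <- sim
    .cache$fit <- suppressWarnings(
      fit_ruv3nb(sim$counts, scenario_M(sim), scenario_controls(sim),
                 k = 3, seed = 5L, max_iter = 30))
  }
  list(sim = .cache$sim, fit = .cache$fit)
}
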