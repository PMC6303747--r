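# Shared fixtures, built in code at test time.

# fertility table pooled from the shipped example assay counts
example_factors <- function() {
  estimate_correction_factors(example_data("assays"))
}

# the printed per-stratum proportions the example assay counts imply
printed_table1 <- function() {
  data.frame(
    sterilization_order = rep(c("NR", "RN"), each = 3),
    interval_h = rep(c(0L, 24L, 48L), 2),
    p = c(0.988, 0.979, 0.976, 0.988, 0.988, 0.988),
    z = c(0.068, 0.064, 0.089, 0.068, 0.050, 0.031),
    brown = c(0.046, 0.042, 0.049, 0.046, 0.035, 0.028)
  )
}

# small deterministic simulated experiment + matching factors
small_sim <- function(seed = 42, n = 64, ...) {
  cfg <- sim_config(n_females = n, seed = seed, ...)
  sim <- simulate_experiment(cfg)
  ft <- estimate_correction_factors(simulate_fertility_assays(cfg))
  list(cfg = cfg, trials = sim$trials, truth = sim$truth, factors = ft)
}

# Yates-corrected chi-squared, written out from the textbook formula, as an
# oracle independent of chisq.test
yates_formula <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum(pmax(abs(tab - E) - 0.5, 0)^2 / E)
}
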