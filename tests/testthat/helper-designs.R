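# Shared small designs and a cached corrected experiment for tests.

# one strain, no planted regulation; good for coefficient recovery
recovery_design <- function(seed, a_true = 0.3, b_true = 0.5, n_peaks = 100) {
  simulation_design(n_species = 1, strains_per_species = 1,
                    n_peaks = n_peaks, n_regulated = 0,
                    a_true = a_true, b_true = b_true, seed = seed)
}

# exact, noise-free world: additivity holds to machine precision
exact_design <- function(seed = 1, a_true = 1, b_true = 1, n_peaks = 40) {
  simulation_design(n_species = 1, strains_per_species = 1,
                    n_peaks = n_peaks, n_regulated = 0,
                    a_true = a_true, b_true = b_true,
                    bio_sigma = 0, noise_sigma = 0, noise_floor = 0,
                    trend_fraction = 0, frac_isotopologue = 0, seed = seed)
}

simulate_corrected <- function(design) {
  ex <- simulate_experiment(design)
  nulls <- build_pda_null(ex$concentrations, seed = design$seed)
  ex$corrected <- suppressWarnings(correct_matrix(ex$concentrations, nulls))
  ex$nulls <- nulls
  ex
}

# cached mid-sized experiment shared across test files
shared_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- simulation_design(n_species = 3, strains_per_species = 3,
                             n_peaks = 80, seed = 42)
      cache <<- simulate_corrected(d)
    }
    cache
  }
})

# independent normal-equations least squares (the fitting oracle)
ols_oracle <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))[, 1]
}
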