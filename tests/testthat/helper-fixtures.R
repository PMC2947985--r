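# Shared fixtures, built lazily once per test run. Everything is generated
# in code; no stored data.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small-protein-scale rate set used throughout for oracle comparisons
fix_rates_small <- function() {
  rate_constants(kappa_a = 0.5, kappa_r = 10, kappa_t_plus = 100,
                 kappa_p_plus = 1, kappa_p_minus = 0.25)
}

fix_oracle_small <- function() {
  fixture("oracle_small",
          brute_force_oracle(fix_rates_small(), max_transcripts = 90,
                             max_proteins = 250))
}

fix_af <- function() {
  fixture("af",
          autofluorescence_profile(generate_autofluorescence(seed = 11)))
}

# one mid-bright study-scale clone (b = 15, kappa_a = 0.8, tau = 0.02)
fix_clone_mid <- function() {
  fixture("clone_mid",
          simulate_clone(from_burst_coordinates(15, 0.8, 0.02),
                         calibration(), n_events = 10000, seed = 3))
}

# its steady-state protein marginal on the unit grid
fix_pmf_mid <- function() {
  fixture("pmf_mid",
          marginal(steady_state(from_burst_coordinates(15, 0.8, 0.02),
                                options = list(method = "direct")),
                   "protein", interpolate = TRUE))
}

# total variation between two unit-grid PMFs of possibly different length
tv_unit <- function(a, b) {
  n <- min(length(a), length(b))
  0.5 * sum(abs(a[seq_len(n)] - b[seq_len(n)])) +
    0.5 * sum(a[-seq_len(n)]) + 0.5 * sum(b[-seq_len(n)])
}
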