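# shared fixtures: all built in code, no data files

# the reference n = 3 symmetric ring (alpha = beta = 1, K = 0.5, rho = 0.5)
sym_ring <- function(n = 3L, rho = 0.5) {
  osc_params(rep(1, n), rep(1, n), rep(rho, n))
}

# deterministic random oscillatory draws for property-style loops
draw_rings <- function(n, n_sets, seed) {
  lapply(seq_len(n_sets), function(k) random_params(n, seed = seed + k))
}
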