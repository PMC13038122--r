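# Shared in-code fixtures: tiny morphologies and hand-built states.

# soma at origin + one straight cable of given kind along `dir`
straight_cable <- function(length = 1000, kind = "axon", npts = 11,
                           diameter = 1, dir = c(0, 0, -1),
                           axis = c(0, 0, 1), soma_d = 15) {
  pts <- outer(seq(0, length, length.out = npts), dir)
  secs <- list(
    section(1L, NA_integer_, "soma", matrix(0, 1, 3), soma_d),
    section(2L, 1L, kind, pts, rep(diameter, npts)))
  morphology(secs, soma_center = c(0, 0, 0), axis = axis)
}

# minimal hand-built cable_state for arrival-detection tests
fake_state <- function(v, t_grid, record) {
  structure(list(v = v, t_grid = t_grid, record = record),
            class = "cable_state")
}

# small uniform kernel helper
const_kernel <- function(value, z_edges = seq(-300, 0, by = 100),
                         t_edges = seq(0, 1, by = 0.1),
                         domain = "cortical_z") {
  delay_kernel(matrix(value, length(z_edges) - 1, length(t_edges) - 1),
               z_edges, t_edges, domain = domain)
}

default_test_spec <- function(seed = 1L, n_terminals = 10L)
  synthetic_morph_spec(n_axon_terminals = n_terminals, rng_seed = seed)
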