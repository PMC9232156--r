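# Shared fixtures: small, fast systems used across the test files.

# a reduced nucleus: 4 chains x 30 nodes in a radius-8 sphere, no RTM
small_config <- function(...) {
  meio_config(nodes_per_chain = 30, nuclear_radius = 8,
              rtm = list(enabled = FALSE),
              equil = list(phase1_steps = 2e3, phase2_steps = 1e4), ...)
}

# a single free particle (one 1-node chain), untethered, large sphere
free_particle_config <- function(n = 1, ...) {
  meio_config(n_chains = n, nodes_per_chain = 1, nuclear_radius = 60,
              tether_mode = "none", rtm = list(enabled = FALSE), ...)
}

free_particles <- function(n, seed = 1, config = free_particle_config(n)) {
  st <- initialize_lattice(config, seed = seed)
  st$tether <- integer(0)
  list(state = st, config = config)
}

# a two-node state (one chain) with given positions, zero velocity
two_node_state <- function(pos, config) {
  cfg <- config
  cfg$n_chains <- 1
  cfg$nodes_per_chain <- 2
  st <- structure(list(
    pos = pos, vel = matrix(0, 2, 3),
    chain = c(1L, 1L), label = c(1L, 2L),
    sites = data.frame(hp = integer(), label = integer(),
                       iA = integer(), iB = integer()),
    paired = logical(0), tether = integer(0), step = 0
  ), class = "meio_state")
  list(state = st, config = cfg)
}

# an isolated homologous node pair (two 1-node chains) for bond kinetics
node_pair_state <- function(d, config) {
  st <- structure(list(
    pos = rbind(c(0, 0, 0), c(d, 0, 0)), vel = matrix(0, 2, 3),
    chain = c(1L, 2L), label = c(1L, 1L),
    sites = data.frame(hp = 1L, label = 1L, iA = 1L, iB = 2L),
    paired = FALSE, tether = integer(0), step = 0
  ), class = "meio_state")
  st
}
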