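#' @useDynLib meiosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Draw a pair of 31-bit integers from the R RNG stream; every call into the
# compiled core is seeded this way, so set.seed() at the R level makes whole
# workflows reproducible.
.seed_pair <- function() {
  sample.int(.Machine$integer.max, 2, replace = TRUE)
}

.node_chain <- function(config) {
  rep(seq_len(config$n_chains), each = config$nodes_per_chain)
}

.node_label <- function(config) {
  rep(seq_len(config$nodes_per_chain), times = config$n_chains)
}

# global node index for (chain, label), 1-based
.node_id <- function(config, chain, label) {
  (chain - 1L) * config$nodes_per_chain + label
}

# Eligible pairing-site table: one row per (homolog pair, site label).
.site_table <- function(config, layout = NULL) {
  if (is.null(layout)) {
    layout <- pairing_sites(config$pairing_layout$mode,
                            config$pairing_layout$n_sites,
                            config$nodes_per_chain)
  }
  n_hp <- config$n_chains %/% 2L
  if (n_hp == 0L) {
    return(data.frame(hp = integer(), label = integer(),
                      iA = integer(), iB = integer()))
  }
  hp <- rep(seq_len(n_hp), each = length(layout$site_indices))
  label <- rep(layout$site_indices, times = n_hp)
  data.frame(
    hp = hp, label = label,
    iA = .node_id(config, 2L * hp - 1L, label),
    iB = .node_id(config, 2L * hp, label)
  )
}

.tether_nodes <- function(config, mode = config$tether_mode) {
  N <- config$nodes_per_chain
  firsts <- .node_id(config, seq_len(config$n_chains), 1L)
  lasts <- .node_id(config, seq_len(config$n_chains), N)
  switch(mode,
    both = if (N > 1) sort(c(firsts, lasts)) else firsts,
    single = firsts,
    none = integer(0)
  )
}

.new_state <- function(pos, vel, config, layout = NULL, paired = NULL,
                       step = 0) {
  sites <- .site_table(config, layout)
  if (is.null(paired)) paired <- rep(FALSE, nrow(sites))
  structure(list(
    pos = pos, vel = vel,
    chain = .node_chain(config), label = .node_label(config),
    sites = sites, paired = paired,
    tether = .tether_nodes(config),
    step = step
  ), class = "meio_state")
}

#' @export
print.meio_state <- function(x, ...) {
  cat(sprintf("System state: %d nodes on %d chain(s), step %g\n",
              nrow(x$pos), length(unique(x$chain)), x$step))
  cat(sprintf("  pairing bonds: %d of %d eligible sites\n",
              sum(x$paired), length(x$paired)))
  cat(sprintf("  tethered telomere nodes: %d\n", length(x$tether)))
  invisible(x)
}

# 24 proper rotations of the cube, returned as 3x3 integer matrices.
.cube_rotations <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    for (sx in c(-1, 1)) for (sy in c(-1, 1)) for (sz in c(-1, 1)) {
      M <- matrix(0, 3, 3)
      M[1, p[1]] <- sx; M[2, p[2]] <- sy; M[3, p[3]] <- sz
      if (abs(det(M) - 1) < 1e-9) out[[length(out) + 1]] <- M
    }
  }
  out
})

.serpentine <- function(n, dims) {
  # boustrophedon walk through an nx x ny x nz grid, returns n x 3 matrix of
  # 0-based lattice coordinates with unit spacing
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  out <- matrix(0, n, 3)
  k <- 1L
  for (z in 0:(nz - 1)) {
    ys <- if (z %% 2 == 0) 0:(ny - 1) else (ny - 1):0
    for (y in ys) {
      xs <- if ((y + z) %% 2 == 0) 0:(nx - 1) else (nx - 1):0
      for (x in xs) {
        if (k > n) return(out)
        out[k, ] <- c(x, y, z)
        k <- k + 1L
      }
    }
  }
  out
}

#' Initialize chains on a cubic lattice inside the nuclear sphere
#'
#' All chains are laid out as consecutive segments of a single space-filling
#' serpentine path on a sigma-spaced cubic grid centred at the nuclear
#' centre, so no two nodes start closer than one node diameter while the
#' chains interleave as they would in a dense nucleus.  Chromosome ends that
#' are tethered under the configured `tether_mode` start exactly on the
#' nuclear sphere; untethered ends stay on the lattice.  Velocities are drawn
#' from the thermal distribution at the configured temperature.  The random
#' seed only permutes the order of the chains along the path and the lattice
#' orientation.
#'
#' @param config a [meio_config()].
#' @param seed optional integer seed (otherwise the current R RNG stream is used).
#' @return a `meio_state`.
#' @export
initialize_lattice <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- config$nodes_per_chain
  nc <- config$n_chains
  n_tot <- N * nc
  sig <- config$node_diameter
  # near-cubic communal grid holding every node
  nz <- max(1L, floor(n_tot^(1 / 3)))
  ny <- max(1L, ceiling(sqrt(n_tot / nz)))
  nx <- ceiling(n_tot / (ny * nz))
  half_diag <- sqrt(sum((c(nx, ny, nz) * sig / 2)^2))
  need <- half_diag + sig
  if (need > config$nuclear_radius) {
    stop(sprintf(
      "lattice block does not fit in the nuclear sphere: requires radius >= %.2f, have %.2f",
      need, config$nuclear_radius))
  }
  path <- .serpentine(n_tot, c(nx, ny, nz)) * sig
  path <- sweep(path, 2, colMeans(path))
  tether <- .tether_nodes(config)
  perm <- sample.int(nc)
  Mrot <- .cube_rotations[[sample.int(length(.cube_rotations), 1)]]
  path <- path %*% t(Mrot)
  pos <- matrix(0, n_tot, 3)
  for (k in seq_len(nc)) {
    seg <- ((perm[k] - 1) * N + 1):(perm[k] * N)
    pos[((k - 1) * N + 1):(k * N), ] <- path[seg, ]
  }
  # project tethered terminal nodes onto the sphere, radially outward
  for (i in tether) {
    p <- pos[i, ]
    if (sqrt(sum(p^2)) < 1e-9) p <- c(1e-3, 0, 0)
    pos[i, ] <- p / sqrt(sum(p^2)) * config$nuclear_radius
  }
  if (n_tot > 1) {
    dmin <- min(stats::dist(pos))
    if (dmin < sig - 1e-9) {
      # a projected terminal landed near another node: nudge it outward is
      # impossible (it must stay on the sphere), so jitter along the sphere
      for (i in tether) {
        repeat {
          d <- sqrt(colSums((t(pos[-i, , drop = FALSE]) - pos[i, ])^2))
          if (min(d) >= sig - 1e-9) break
          u <- stats::rnorm(3)
          p <- pos[i, ] + 0.5 * sig * u / sqrt(sum(u^2))
          pos[i, ] <- p / sqrt(sum(p^2)) * config$nuclear_radius
        }
      }
    }
  }
  vel <- matrix(
    if (config$temperature > 0)
      stats::rnorm(3 * n_tot, sd = sqrt(config$temperature / config$mass))
    else 0,
    n_tot, 3)
  for (i in tether) {
    p <- pos[i, ]
    vel[i, ] <- vel[i, ] - sum(vel[i, ] * p) / sum(p^2) * p
  }
  .new_state(pos, vel, config)
}

# Low-level wrapper around the compiled integrator.  Everything that modules
# need (caps, frozen bonds, PBC box, external force schedules) is an argument.
.advance <- function(state, config, n_steps, cap = 0, pairing_on = FALSE,
                     bonds_frozen = FALSE, wca_on = TRUE, box = 0,
                     sample_every = 0, rtm_nodes = integer(0),
                     rtm_forces = matrix(0, 0, 0), bouquet_on = FALSE,
                     p_pair = config$p_pair, p_unpair = config$p_unpair,
                     tether = state$tether) {
  if (n_steps <= 0) {
    return(list(state = state, frames = NULL))
  }
  par <- list(
    dt = config$dt, kbt = config$temperature, m = config$mass,
    zeta = config$damping, k_spring = config$k_spring,
    r0 = config$sigma_lj, eps = config$eps_lj, sigma = config$sigma_lj,
    k_nuc = config$k_nuc, R = config$nuclear_radius,
    box = box, cap = cap, skin = config$skin, wca_on = wca_on,
    p_pair = p_pair, p_unpair = p_unpair,
    capture = config$capture_distance,
    pairing_on = pairing_on, bonds_frozen = bonds_frozen,
    chunk_steps = as.integer(config$rtm$chunk_steps),
    bouquet_on = bouquet_on,
    bouquet_accel = config$bouquet$accel_mag,
    bouquet_focus = as.numeric(config$bouquet$focus)
  )
  sp <- .seed_pair()
  res <- cpp_advance(
    state$pos, state$vel, as.integer(state$chain - 1L), par,
    as.integer(state$sites$iA - 1L), as.integer(state$sites$iB - 1L),
    as.integer(state$sites$hp), state$paired,
    as.integer(tether - 1L), as.integer(rtm_nodes - 1L), rtm_forces,
    as.double(n_steps), as.double(sample_every), as.double(state$step),
    sp[1], sp[2])
  new_state <- state
  new_state$pos <- res$pos
  new_state$vel <- res$vel
  new_state$paired <- res$paired
  new_state$step <- res$step
  list(state = new_state,
       frames = if (sample_every > 0)
         list(pos = res$frames_pos, step = res$frames_step,
              paired = res$frames_paired) else NULL,
       diagnostics = list(ke_mean = res$ke_mean,
                          max_step_disp = res$max_step_disp,
                          max_radius = res$max_radius,
                          max_bond = res$max_bond,
                          n_rebuilds = res$n_rebuilds,
                          n_overlap = res$n_overlap))
}

#' Capped first-phase equilibration
#'
#' Advances the dynamics with the per-step displacement of every node clamped
#' to one tenth of the node diameter, letting the tightly packed lattice
#' configuration relax without instabilities.  Pairing is disabled and the
#' topology unchanged.
#'
#' @param state a `meio_state`, freshly initialized.
#' @param config a [meio_config()].
#' @param n_steps number of capped steps (default `config$equil$phase1_steps`).
#' @param seed optional integer seed.
#' @return a list with the advanced `state` and `diagnostics` (including the
#'   recorded maximum per-step displacement).
#' @export
equilibrate_phase1 <- function(state, config,
                               n_steps = config$equil$phase1_steps,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .advance(state, config, n_steps, cap = config$node_diameter / 10)
}

#' Uncapped second-phase equilibration
#'
#' Advances the dynamics without a displacement cap to randomize chain
#' conformations; the returned state marks t = 0 of a production run (the step
#' counter is reset).  Pairing stays disabled.
#'
#' @inheritParams equilibrate_phase1
#' @param n_steps number of steps (default `config$equil$phase2_steps`).
#' @param wca_on logical; excluded volume on (default) or off (ideal-chain
#'   control runs used to compare against random-chain statistics).
#' @export
equilibrate_phase2 <- function(state, config,
                               n_steps = config$equil$phase2_steps,
                               seed = NULL, wca_on = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  out <- .advance(state, config, n_steps, wca_on = wca_on)
  out$state$step <- 0          # end of equilibration marks t = 0
  out
}

#' Initialize and equilibrate a system in one call
#'
#' Lattice initialization followed by the capped and uncapped equilibration
#' phases; returns the t = 0 state.
#'
#' @inheritParams equilibrate_phase1
#' @export
meio_equilibrate <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- initialize_lattice(config)
  st <- equilibrate_phase1(st, config)$state
  equilibrate_phase2(st, config)$state
}

#' Radius of gyration of a chain
#'
#' Root mean squared distance of the nodes from the chain centroid.
#'
#' @param coords an n x 3 matrix of node coordinates (model length units).
#' @return scalar radius of gyration.
#' @examples
#' radius_of_gyration(matrix(0, 1, 3))                     # 0
#' rod <- cbind(0:9, 0, 0)
#' radius_of_gyration(rod)                                 # sqrt((100-1)/12)
#' @export
radius_of_gyration <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("radius_of_gyration: empty chain")
  ctr <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, ctr)^2)))
}
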