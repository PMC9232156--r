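# Base force field and integrator surface.
#
# The per-step integration runs in compiled code (see src/core.cpp); the
# functions here are the documented reference implementations of each force
# term, used directly for analysis and as the cross-check oracle in the test
# suite.  Forces are in model units throughout.

#' Langevin random force draw
#'
#' Zero-mean random forces with the per-component root mean square magnitude
#' \eqn{\sqrt{2 k_B T m / (\zeta \, dt)}} required by fluctuation-dissipation
#' for a drag coefficient \eqn{m/\zeta} (damping-time convention), independent
#' across nodes, components and steps.
#'
#' @param config a [meio_config()].
#' @param n_nodes number of nodes.
#' @return an `n_nodes` x 3 matrix of forces.
#' @export
random_force <- function(config, n_nodes) {
  if (config$temperature <= 0) return(matrix(0, n_nodes, 3))
  sd <- sqrt(2 * config$temperature * config$mass / (config$damping * config$dt))
  matrix(stats::rnorm(3 * n_nodes, sd = sd), n_nodes, 3)
}

#' Frictional force
#'
#' Drag \eqn{-(m/\zeta) v} per node, with \eqn{\zeta} the damping time.
#'
#' @param velocities n x 3 matrix of node velocities.
#' @param config a [meio_config()].
#' @return n x 3 matrix of forces.
#' @examples
#' friction_force(matrix(c(1, 0, 0), 1), meio_config())  # (-10, 0, 0)
#' @export
friction_force <- function(velocities, config) {
  -(config$mass / config$damping) * velocities
}

#' Harmonic spring forces (backbone and pairing bonds)
#'
#' Energy \eqn{k_s (r - r_0)^2} per bond, hence axial force magnitude
#' \eqn{2 k_s |r - r_0|} restoring towards the rest length, applied equal and
#' opposite to both partners.  Coincident bonded nodes get zero force (the
#' direction is undefined) with a warning.
#'
#' @param state a `meio_state`.
#' @param config a [meio_config()].
#' @return n x 3 matrix of forces.
#' @export
spring_forces <- function(state, config) {
  n <- nrow(state$pos)
  f <- matrix(0, n, 3)
  bonds <- .bond_list(state)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    d <- state$pos[j, ] - state$pos[i, ]
    r <- sqrt(sum(d^2))
    if (r < 1e-12) {
      warning("coincident bonded nodes ", i, ",", j, ": zero spring force this step")
      next
    }
    fv <- 2 * config$k_spring * (r - config$sigma_lj) * d / r
    f[i, ] <- f[i, ] + fv
    f[j, ] <- f[j, ] - fv
  }
  f
}

# backbone + active pairing bonds as a two-column matrix of node indices
.bond_list <- function(state) {
  n <- nrow(state$pos)
  same <- which(state$chain[-n] == state$chain[-1])
  bb <- cbind(same, same + 1L)
  pb <- cbind(state$sites$iA[state$paired], state$sites$iB[state$paired])
  rbind(bb, pb)
}

#' WCA excluded-volume forces
#'
#' Repulsive Lennard-Jones interaction truncated at the potential minimum
#' \eqn{r_c = 2^{1/6}\sigma}; zero beyond the cutoff, with directly bonded
#' pairs excluded.  A deep overlap (r < 0.3 sigma) triggers a warning since it
#' suggests the timestep is too large.
#'
#' @inheritParams spring_forces
#' @return n x 3 matrix of forces.
#' @export
wca_forces <- function(state, config) {
  n <- nrow(state$pos)
  f <- matrix(0, n, 3)
  sig <- config$sigma_lj
  rc2 <- (2^(1 / 6) * sig)^2
  bonds <- .bond_list(state)
  bonded <- rep(FALSE, n * n)
  if (nrow(bonds) > 0) {
    bonded[(bonds[, 1] - 1L) * n + bonds[, 2]] <- TRUE
    bonded[(bonds[, 2] - 1L) * n + bonds[, 1]] <- TRUE
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (bonded[(i - 1L) * n + j]) next
      d <- state$pos[j, ] - state$pos[i, ]
      r2 <- sum(d^2)
      if (r2 >= rc2) next
      if (r2 < (0.3 * sig)^2) {
        warning(sprintf("deep overlap between nodes %d and %d (r = %.3f sigma)",
                        i, j, sqrt(r2) / sig))
      }
      sr6 <- (sig^2 / r2)^3
      c <- 24 * config$eps_lj * sr6 * (2 * sr6 - 1) / r2
      f[i, ] <- f[i, ] - c * d
      f[j, ] <- f[j, ] + c * d
    }
  }
  f
}

#' Nuclear confinement force
#'
#' Spherical indenter: a node at distance \eqn{s > R} from the nuclear centre
#' receives an inward radial force of magnitude \eqn{k_{nuc} (s - R)^2};
#' interior nodes feel nothing.
#'
#' @inheritParams spring_forces
#' @return n x 3 matrix of forces.
#' @export
confinement_force <- function(state, config) {
  s <- sqrt(rowSums(state$pos^2))
  out <- which(s > config$nuclear_radius)
  f <- matrix(0, nrow(state$pos), 3)
  for (i in out) {
    f[i, ] <- -config$k_nuc * (s[i] - config$nuclear_radius)^2 * state$pos[i, ] / s[i]
  }
  f
}

#' Project tethered telomeres onto the nuclear sphere
#'
#' Constraint-projection step: each tethered node's position is rescaled onto
#' the sphere (direction preserved) and the radial component of its velocity
#' removed, so the net motion of a tethered telomere is always tangential to
#' the nuclear surface.  Errors if a tethered node has drifted farther than
#' half a node diameter from the sphere (the constraint blew up).
#'
#' @param state a `meio_state`.
#' @param config a [meio_config()].
#' @param telomeres node indices to constrain (default the state's tether set).
#' @return the projected `meio_state`.
#' @export
project_onto_sphere <- function(state, config, telomeres = state$tether) {
  R <- config$nuclear_radius
  for (i in telomeres) {
    p <- state$pos[i, ]
    s <- sqrt(sum(p^2))
    if (abs(s - R) > 0.5 * config$sigma_lj) {
      stop(sprintf("tethered node %d is %.3f length units from the sphere (limit 0.5 sigma)",
                   i, abs(s - R)))
    }
    state$pos[i, ] <- p / s * R
    p <- state$pos[i, ]
    state$vel[i, ] <- state$vel[i, ] - sum(state$vel[i, ] * p) / sum(p^2) * p
  }
  state
}

#' Advance the dynamics
#'
#' Integrates the Langevin equations of motion for `n_steps` timesteps under
#' the full force field (springs, excluded volume, confinement, thermostat)
#' plus any active external forces, with constraint projection for tethered
#' telomeres.  `step_dynamics` is the low-level entry point; most workflows
#' use [run_pairing()] or the experiment drivers instead.
#'
#' @param state a `meio_state`.
#' @param config a [meio_config()].
#' @param n_steps number of timesteps.
#' @param seed optional integer seed.
#' @param pairing_on create/remove pairing bonds each step.
#' @param sample_every frame-sampling interval in steps (0 = no frames).
#' @param ... further arguments to the internal driver (displacement `cap`,
#'   `wca_on`, periodic `box` side, `rtm_nodes`/`rtm_forces`, `bouquet_on`,
#'   `bonds_frozen`, probability overrides).
#' @return list with elements `state`, `frames` (NULL unless sampled) and
#'   `diagnostics` (mean kinetic energy per node, maximum per-step
#'   displacement, maximum radial excursion, maximum bond length, neighbour
#'   list rebuilds, deep-overlap count).
#' @export
step_dynamics <- function(state, config, n_steps = 1, seed = NULL,
                          pairing_on = FALSE, sample_every = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  .advance(state, config, n_steps, pairing_on = pairing_on,
           sample_every = sample_every, ...)
}
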