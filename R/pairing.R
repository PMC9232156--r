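# Reversible homolog pairing: site layouts, the per-step bond kinetics, and
# the production-run driver that assembles trajectories.

#' Pairing-site layouts
#'
#' Either every node along the chain is an eligible pairing site (`"all"`) or
#' `n_sites` sites are spaced uniformly along the chain with both terminal
#' labels included (`"spread"`), mimicking a discrete distribution of pairing
#' initiation sites.
#'
#' @param mode `"all"` or `"spread"`.
#' @param n_sites number of sites in spread mode (>= 2).
#' @param nodes_per_chain chain length N.
#' @return a `meio_layout`: list with `mode` and sorted 1-based `site_indices`.
#' @examples
#' pairing_sites("spread", 20, 100)$site_indices
#' @export
pairing_sites <- function(mode = c("all", "spread"), n_sites = 20,
                          nodes_per_chain = 100) {
  mode <- match.arg(mode)
  N <- nodes_per_chain
  if (mode == "all") {
    idx <- seq_len(N)
  } else {
    if (n_sites < 2) stop("spread layout requires n_sites >= 2")
    if (n_sites > N) stop("n_sites (", n_sites, ") exceeds nodes_per_chain (", N, ")")
    idx <- unique(round(1 + (seq_len(n_sites) - 1) * (N - 1) / (n_sites - 1)))
  }
  structure(list(mode = mode, site_indices = as.integer(idx)),
            class = "meio_layout")
}

#' One step of reversible pairing kinetics
#'
#' For every unpaired eligible site whose homologous nodes lie within the
#' capture distance, a harmonic pairing bond forms with probability `p_pair`;
#' every existing bond dissolves with probability `p_unpair`.  Bonds connect
#' only equal labels on homologous chains.  This is the same rule the
#' compiled integrator applies once per timestep.
#'
#' @param state a `meio_state`.
#' @param config a [meio_config()].
#' @return the updated `meio_state`.
#' @export
update_pairing <- function(state, config) {
  d <- sqrt(rowSums((state$pos[state$sites$iA, , drop = FALSE] -
                     state$pos[state$sites$iB, , drop = FALSE])^2))
  u <- stats::runif(nrow(state$sites))
  unbind <- state$paired & u < config$p_unpair
  bind <- !state$paired & d <= config$capture_distance & u < config$p_pair
  state$paired <- (state$paired | bind) & !unbind
  state
}

#' Fraction of paired eligible sites
#'
#' Number of currently bonded eligible sites divided by the total number of
#' eligible sites across all homolog pairs.
#'
#' @param paired logical vector of per-site bond states, or a `meio_state`.
#' @param by_pair if TRUE, return the per-homolog-pair fractions instead.
#' @param sites the site table (needed for `by_pair` with a bare vector).
#' @return fraction in `[0, 1]` (or a named vector per homolog pair).
#' @export
pairing_fraction <- function(paired, by_pair = FALSE, sites = NULL) {
  if (inherits(paired, "meio_state")) {
    sites <- paired$sites
    paired <- paired$paired
  }
  if (!by_pair) return(if (length(paired)) mean(paired) else 0)
  tapply(paired, sites$hp, mean)
}

#' Generate the rapid-telomere-movement pull schedule
#'
#' The run is divided into chunks of `chunk_steps` timesteps.  In every chunk
#' each telomere independently experiences an active pull with probability
#' `p_pull`; a pulled telomere gets a uniformly random 3D direction that is
#' held fixed for the whole chunk.
#'
#' @param config a [meio_config()].
#' @param telomeres vector of telomere node indices.
#' @param n_steps run length in timesteps.
#' @param seed optional integer seed.
#' @return data frame of events: `telomere_id`, `chunk`, `start_step`,
#'   `duration_steps`, direction components `dx`, `dy`, `dz` (unit norm).
#' @export
rtm_schedule <- function(config, telomeres, n_steps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chunk <- config$rtm$chunk_steps
  n_chunks <- ceiling(n_steps / chunk)
  grid <- expand.grid(telomere_id = telomeres, chunk = seq_len(n_chunks))
  on <- stats::runif(nrow(grid)) < config$rtm$p_pull
  ev <- grid[on, , drop = FALSE]
  if (nrow(ev) == 0) {
    return(data.frame(telomere_id = integer(), chunk = integer(),
                      start_step = numeric(), duration_steps = numeric(),
                      dx = numeric(), dy = numeric(), dz = numeric()))
  }
  dirs <- matrix(stats::rnorm(3 * nrow(ev)), ncol = 3)
  nn <- sqrt(rowSums(dirs^2))
  nn[nn == 0] <- 1
  dirs <- dirs / nn
  out <- data.frame(
    telomere_id = ev$telomere_id,
    chunk = ev$chunk,
    start_step = (ev$chunk - 1) * chunk,
    duration_steps = chunk,
    dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3]
  )
  out[order(out$chunk, out$telomere_id), , drop = FALSE]
}

#' Constant force of an active telomere pull
#'
#' @param event one row of an [rtm_schedule()] data frame.
#' @param magnitude force magnitude (model units).
#' @return force 3-vector; the on-sphere constraint later projects it
#'   tangentially, so a pull aligned with the local radial direction produces
#'   no drag along the surface.
#' @export
rtm_force <- function(event, magnitude) {
  magnitude * c(event$dx, event$dy, event$dz)
}

# dense per-chunk force table consumed by the compiled core:
# n_chunks x (3 * n_telomeres), zero where no pull is active
.rtm_force_matrix <- function(schedule, telomeres, n_chunks, magnitude) {
  M <- matrix(0, n_chunks, 3 * length(telomeres))
  if (is.null(schedule) || nrow(schedule) == 0) return(M)
  k <- match(schedule$telomere_id, telomeres)
  for (r in seq_len(nrow(schedule))) {
    M[schedule$chunk[r], 3 * (k[r] - 1) + 1:3] <-
      magnitude * c(schedule$dx[r], schedule$dy[r], schedule$dz[r])
  }
  M
}

#' Bouquet bias force on tethered telomeres
#'
#' Each tethered telomere receives a constant-magnitude force `m * accel_mag`
#' directed at the bouquet focus point on the nuclear surface; the on-sphere
#' constraint turns this into a tangential drift that clusters telomeres
#' around the focus.
#'
#' @param state a `meio_state`.
#' @param config a [meio_config()] with `bouquet$enabled`.
#' @return n x 3 matrix of forces (zero off the tether set).
#' @export
bouquet_force <- function(state, config) {
  f <- matrix(0, nrow(state$pos), 3)
  focus <- config$bouquet$focus
  nf <- sqrt(sum(focus^2))
  if (abs(nf - config$nuclear_radius) > 1e-6) {
    warning("bouquet focus not on the nuclear sphere; normalizing")
    focus <- focus / nf * config$nuclear_radius
  }
  for (i in state$tether) {
    d <- focus - state$pos[i, ]
    r <- sqrt(sum(d^2))
    if (r < 1e-9) next
    f[i, ] <- config$mass * config$bouquet$accel_mag * d / r
  }
  f
}

#' Run a production pairing simulation
#'
#' Advances an equilibrated state for `n_steps` with reversible pairing
#' active, the strain's telomere behaviour (tether constraint, rapid telomere
#' movements, optional bouquet) applied, and frames sampled on a fixed
#' interval.  The realized RTM schedule is returned so any run is exactly
#' replayable from (config, seed).
#'
#' @param state an equilibrated `meio_state` (t = 0).
#' @param config a [meio_config()].
#' @param n_steps production steps (default `config$n_steps`).
#' @param seed optional integer seed.
#' @param sample_every sampling interval (default `config$sample_every`).
#' @param pairing_on logical; reversible pairing active (default TRUE).
#' @param bonds_frozen logical; freeze the bond set (topology-preserving runs).
#' @return a `meio_run`: list with `trajectory` (a `meio_trajectory`), final
#'   `state`, the `rtm_schedule` used, and integrator `diagnostics`.
#' @export
run_pairing <- function(state, config, n_steps = config$n_steps, seed = NULL,
                        sample_every = config$sample_every,
                        pairing_on = TRUE, bonds_frozen = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  tel <- state$tether
  sched <- NULL
  rtm_forces <- matrix(0, 0, 0)
  rtm_nodes <- integer(0)
  if (config$rtm$enabled && length(tel) > 0) {
    sched <- rtm_schedule(config, tel, n_steps)
    n_chunks <- ceiling(n_steps / config$rtm$chunk_steps)
    rtm_forces <- .rtm_force_matrix(sched, tel, n_chunks, config$rtm$force_mag)
    rtm_nodes <- tel
  }
  out <- .advance(state, config, n_steps,
                  pairing_on = pairing_on, bonds_frozen = bonds_frozen,
                  sample_every = sample_every,
                  rtm_nodes = rtm_nodes, rtm_forces = rtm_forces,
                  bouquet_on = config$bouquet$enabled)
  traj <- .new_trajectory(out$frames, state, config,
                          initial = list(pos = state$pos, step = state$step,
                                         paired = state$paired))
  structure(list(trajectory = traj, state = out$state,
                 rtm_schedule = sched, diagnostics = out$diagnostics),
            class = "meio_run")
}

#' @export
print.meio_run <- function(x, ...) {
  cat(sprintf("Simulation run to step %g; paired fraction %.3f\n",
              x$state$step, pairing_fraction(x$state)))
  print(x$trajectory)
  invisible(x)
}

.new_trajectory <- function(frames, state, config, initial = NULL) {
  if (is.null(frames)) {
    steps <- numeric(0)
    pos <- array(0, c(0, nrow(state$pos), 3))
    paired <- matrix(FALSE, 0, nrow(state$sites))
  } else {
    steps <- frames$step
    pos <- frames$pos
    paired <- frames$paired
  }
  if (!is.null(initial)) {
    nf <- length(steps) + 1L
    pos2 <- array(0, c(nf, dim(pos)[2], 3))
    pos2[1, , ] <- initial$pos
    if (nf > 1) pos2[2:nf, , ] <- pos
    paired <- rbind(matrix(initial$paired, 1), paired)
    steps <- c(initial$step, steps)
    pos <- pos2
  }
  u <- unit_system()
  structure(list(
    steps = steps,
    times = steps * config$dt * u$time_ms * 1e-3,   # physical seconds
    pos = pos, paired = paired,
    sites = state$sites, chain = state$chain, label = state$label,
    tether = state$tether, config = config
  ), class = "meio_trajectory")
}

#' @export
print.meio_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d nodes, t = %.1f..%.1f s (steps %g..%g)\n",
              length(x$steps), dim(x$pos)[2],
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA,
              if (length(x$steps)) min(x$steps) else NA,
              if (length(x$steps)) max(x$steps) else NA))
  invisible(x)
}

#' Per-frame pairing fraction of a trajectory
#'
#' @param trajectory a `meio_trajectory`.
#' @return numeric vector, one fraction per frame.
#' @export
trajectory_fraction <- function(trajectory) {
  if (ncol(trajectory$paired) == 0) return(rep(0, nrow(trajectory$paired)))
  rowMeans(trajectory$paired)
}
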