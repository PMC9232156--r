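# Topological interlocks: planted configurations, the forced-pairing
# detection assay, open/closed classification, localization, and the
# three-step resolution timeline.

# ---- template geometry ------------------------------------------------------
#
# Planted interlocks are built from analytic curves.  Each homolog pair is a
# "ribbon": a centerline C(s) with the two chains offset +-(w(s)/2) in a fixed
# direction (y).  Paired regions have width w = 1 (bond rest length); an
# unpaired "eye" widens smoothly to w = 4, forming a loop (chainA + chainB +
# the flanking bonds) with a hole through which another pair's strand can
# thread.  An open interlock is one eyed pair threaded by a fully paired
# straight pair; a closed interlock is two eyed pairs threaded through each
# other's holes (a Hopf link of the two loops).  Slack (each chain must have
# total arc length (N-1)*sigma) is stored in helical coils along the exit
# strands, placed so the two pairs never come closer than about one node
# diameter.  Chain ends land exactly on the nuclear sphere.

.resample_polyline <- function(P, n) {
  seg <- sqrt(rowSums(diff(P)^2))
  P <- P[c(TRUE, seg > 1e-12), , drop = FALSE]   # drop duplicate joints
  seg <- seg[seg > 1e-12]
  s <- c(0, cumsum(seg))
  tgt <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, P[, 1], xout = tgt)$y,
        stats::approx(s, P[, 2], xout = tgt)$y,
        stats::approx(s, P[, 3], xout = tgt)$y)
}

.polyline_length <- function(P) sum(sqrt(rowSums(diff(P)^2)))

# planar serpentine slack store: a rounded square-wave in the (axial,
# lateral) plane -- straight lateral arms of half-height A joined by
# semicircular caps of radius r_c -- so neighbouring arms stay 2*r_c apart
# and the turning angle per node never exceeds what keeps second-neighbour
# beads out of excluded-volume contact.  Returns (axial, lateral) points.
.serp_path <- function(L_ax, A, r_c = 0.7, ds = 0.02) {
  n_arms <- floor((L_ax - 1 - 2 * r_c) / (2 * r_c))
  if (A <= r_c + 1e-9 || n_arms < 2) {
    ax <- seq(0, L_ax, by = ds)
    return(cbind(ax, 0))
  }
  pts <- list(cbind(seq(0, 0.5, by = ds), 0))
  # quarter turn off the axis into the first arm (heading +lat)
  phi <- seq(0, pi / 2, by = ds / r_c)
  pts[[length(pts) + 1]] <- cbind(0.5 + r_c * sin(phi), r_c * (1 - cos(phi)))
  x <- 0.5 + r_c
  dirn <- +1
  lat <- r_c
  for (j in seq_len(n_arms)) {
    last <- j == n_arms
    target <- if (last) dirn * r_c else dirn * A
    if (abs(target - lat) > ds) {
      pts[[length(pts) + 1]] <- cbind(x, seq(lat, target, by = dirn * ds))
    }
    if (!last) {
      # semicircular cap advancing axially by 2 r_c
      psi <- seq(0, pi, by = ds / r_c)
      pts[[length(pts) + 1]] <- cbind(x + r_c * (1 - cos(psi)),
                                      dirn * (A + r_c * sin(psi)))
      x <- x + 2 * r_c
      lat <- dirn * A
      dirn <- -dirn
    } else {
      lat <- target
    }
  }
  # quarter turn back to axial heading (leaves a 2 r_c lateral offset)
  tt <- seq(0, pi / 2, by = ds / r_c)
  pts[[length(pts) + 1]] <- cbind(x + r_c * (1 - cos(tt)),
                                  dirn * r_c * (1 + sin(tt)))
  x <- x + r_c
  if (x < L_ax) {
    pts[[length(pts) + 1]] <- cbind(seq(x, L_ax, by = ds), dirn * 2 * r_c)
  }
  do.call(rbind, pts)
}

# one chain of an eyed ribbon in canonical frame: the chain lies entirely in
# the plane y = side * w(x)/2 -- an eye profile on x in [-2, 2] widening to
# half-width 2, exits along +-x with serpentine slack in z -- so the two
# chains (side = +1/-1) are parallel-plane translates at distance 1 in the
# exits and mirror images across the eye.  Ends land on the sphere radius R.
.eyed_chain <- function(side, a, R, ds = 0.05) {
  xe <- seq(-2, 2, by = ds / 2)
  eye <- cbind(xe, side * (0.5 + 1.5 * cos(pi * xe / 4)), 0)
  x_end <- sqrt(R^2 - 0.25) - 0.05
  sp <- .serp_path(x_end - 2.3, a)
  exit_plus <- cbind(2.25 + sp[, 1], side * 0.5, sp[, 2])
  exit_minus <- exit_plus[nrow(exit_plus):1, ]
  exit_minus[, 1] <- -exit_minus[, 1]
  P <- rbind(exit_minus, eye, exit_plus)
  for (k in c(1, nrow(P))) P[k, ] <- P[k, ] / sqrt(sum(P[k, ]^2)) * R
  P
}

# straight (fully paired) threading ribbon chain in canonical frame: the
# chain lies in the plane x = side * 0.5, centerline along z through the
# origin, serpentine slack in y beyond |z| > 2.3.
.straight_chain <- function(side, a, R, ds = 0.05) {
  z_end <- sqrt(R^2 - 0.25) - 0.05
  sp <- .serp_path(z_end - 2.35, a)
  up <- cbind(side * 0.5, sp[, 2], 2.3 + sp[, 1])
  down <- up[nrow(up):1, ]
  down[, 3] <- -down[, 3]
  mid <- cbind(side * 0.5, 0, seq(-2.25, 2.25, by = ds))
  P <- rbind(down, mid, up)
  for (k in c(1, nrow(P))) P[k, ] <- P[k, ] / sqrt(sum(P[k, ]^2)) * R
  P
}

# solve the coil radius so that the chain arc length equals the target
.solve_amplitude <- function(builder, target, A_max = 5.5) {
  f <- function(A) .polyline_length(builder(A)) - target
  if (f(0) > 0) stop("interlock template: chain too long even without meanders")
  if (f(A_max) < 0) {
    stop(sprintf(
      "interlock template does not fit: need chain length %.1f but maximum attainable is %.1f at this nuclear radius",
      target, .polyline_length(builder(A_max))))
  }
  stats::uniroot(f, c(0, A_max), tol = 1e-4)$root
}

.rot_y_to_frame <- function(P, origin, ex, ey, ez) {
  # map canonical coords (x,y,z) into frame with axes ex,ey,ez at origin
  sweep(P[, 1, drop = FALSE] %*% t(ex) + P[, 2, drop = FALSE] %*% t(ey) +
          P[, 3, drop = FALSE] %*% t(ez), 2, origin, "+")
}

#' Plant an interlocked configuration
#'
#' Builds a deterministic template geometry in which both homolog pairs are
#' fully paired except for a mid-chain gap ("eye"): for an open interlock one
#' pair's eye is threaded by the other, fully paired, pair; for a closed
#' interlock the two eyed pairs thread each other's loops (a Hopf link).
#' The interlock sits near the middle of the chains, chain ends lie on the
#' nuclear sphere, and bond lengths are near the rest length.
#'
#' @param type `"open"` or `"closed"`.
#' @param config a [meio_config()] with 4 chains.
#' @param seed optional integer seed (orients the template in the nucleus).
#' @return a `meio_state` with the template's pairing bonds set.
#' @export
make_interlocked_config <- function(type = c("open", "closed"), config,
                                    seed = NULL) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  if (config$n_chains != 4) stop("interlock templates require 4 chains")
  N <- config$nodes_per_chain
  R <- config$nuclear_radius
  target <- (N - 1) * config$sigma_lj
  # pair 1: eyed ribbon in canonical frame
  A1 <- .solve_amplitude(function(A) .eyed_chain(+1, A, R), target)
  c1 <- .resample_polyline(.eyed_chain(+1, A1, R), N)
  c2 <- .resample_polyline(.eyed_chain(-1, A1, R), N)
  if (type == "open") {
    A2 <- .solve_amplitude(function(A) .straight_chain(+1, A, R), target)
    c3 <- .resample_polyline(.straight_chain(+1, A2, R), N)
    c4 <- .resample_polyline(.straight_chain(-1, A2, R), N)
  } else {
    # second eyed ribbon: the same template mapped so its centerline runs
    # along z at (x, y) = (1, 1.4) and its eye opens in y -- threaded by
    # pair 1's eye-region strand, while pair 1's exits thread its own eye
    ex <- c(0, 0, 1); ey <- c(0, 1, 0); ez <- c(1, 0, 0)
    off <- c(1, 2.2, 0)
    c3 <- .rot_y_to_frame(c1, off, ex, ey, ez)
    c4 <- .rot_y_to_frame(c2, off, ex, ey, ez)
    # ends pushed off the sphere by the offset: put them back, spreading
    # the correction over the terminal ten bonds so none stretches
    for (cc in c("c3", "c4")) {
      P <- get(cc)
      for (endk in c(1L, N)) {
        tgt <- P[endk, ] / sqrt(sum(P[endk, ]^2)) * R
        delta <- tgt - P[endk, ]
        span <- 10
        for (j in 0:span) {
          k <- if (endk == 1L) 1L + j else N - j
          P[k, ] <- P[k, ] + delta * (1 - j / (span + 1))
        }
      }
      assign(cc, P)
    }
  }
  pos <- rbind(c1, c2, c3, c4)
  # random global rotation (uniform, via QR of a Gaussian matrix)
  M <- matrix(stats::rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  pos <- pos %*% Q
  cfg_all <- config
  cfg_all$pairing_layout <- list(mode = "all", n_sites = N)
  vel <- matrix(stats::rnorm(3 * 4 * N, sd = sqrt(max(config$temperature, 0) /
                                                    config$mass)), 4 * N, 3)
  st <- .new_state(pos, vel, cfg_all)
  # bond every site whose homologs sit within 1.2 capture distances
  d <- sqrt(rowSums((st$pos[st$sites$iA, ] - st$pos[st$sites$iB, ])^2))
  st$paired <- d <= 1.2 * config$capture_distance
  # tethered ends must be on the sphere
  st <- project_onto_sphere(st, config)
  st
}

#' Well-separated control configuration (no interlock)
#'
#' Two homolog pairs placed as adjacent, unentangled ribbons in opposite
#' hemispheres; used as planted-negative fixtures for the detection assay.
#'
#' @inheritParams make_interlocked_config
#' @param paired start with all pairing bonds formed (default FALSE).
#' @export
make_separated_config <- function(config, seed = NULL, paired = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (config$n_chains != 4) stop("requires 4 chains")
  N <- config$nodes_per_chain
  R <- config$nuclear_radius
  target <- (N - 1) * config$sigma_lj
  xoff <- 0.25 * R
  A <- .solve_amplitude(function(a) .straight_chain(+1, a, R), target)
  shift_proj <- function(P, sgn) {
    P[, 1] <- P[, 1] + sgn * xoff
    for (k in c(1, N)) P[k, ] <- P[k, ] / sqrt(sum(P[k, ]^2)) * R
    .resample_polyline(P, N)
  }
  c1 <- shift_proj(.resample_polyline(.straight_chain(+1, A, R), N), +1)
  c2 <- shift_proj(.resample_polyline(.straight_chain(-1, A, R), N), +1)
  c3 <- shift_proj(.resample_polyline(.straight_chain(+1, A, R), N), -1)
  c4 <- shift_proj(.resample_polyline(.straight_chain(-1, A, R), N), -1)
  cfg_all <- config
  cfg_all$pairing_layout <- list(mode = "all", n_sites = N)
  vel <- matrix(stats::rnorm(3 * 4 * N, sd = sqrt(max(config$temperature, 0) /
                                                    config$mass)), 4 * N, 3)
  st <- .new_state(rbind(c1, c2, c3, c4), vel, cfg_all)
  if (paired) {
    d <- sqrt(rowSums((st$pos[st$sites$iA, ] - st$pos[st$sites$iB, ])^2))
    st$paired <- d <= 1.2 * config$capture_distance
  }
  project_onto_sphere(st, config)
}

#' Randomize geometry while preserving bond topology
#'
#' Advances the dynamics with the pairing-bond set frozen (no creation, no
#' deletion), decorrelating the template geometry without letting the
#' interlock resolve; the forced-pairing assay type is unchanged.
#'
#' @param state a `meio_state` (typically from [make_interlocked_config()]).
#' @param config a [meio_config()].
#' @param n_steps randomization steps.
#' @param seed optional integer seed.
#' @param cap_steps initial displacement-capped steps that relax template
#'   bond-length artifacts before free dynamics.
#' @return the randomized `meio_state`.
#' @export
randomize_preserving_topology <- function(state, config, n_steps = 1e5,
                                          seed = NULL, cap_steps = 2e4) {
  if (!is.null(seed)) set.seed(seed)
  step0 <- state$step
  if (cap_steps > 0) {
    state <- .advance(state, config, cap_steps, cap = config$node_diameter / 10,
                      pairing_on = FALSE, bonds_frozen = TRUE)$state
  }
  if (n_steps > 0) {
    state <- .advance(state, config, n_steps, pairing_on = FALSE,
                      bonds_frozen = TRUE)$state
  }
  state$step <- step0
  state
}

#' Forced-pairing completion assay
#'
#' Detects interlocks operationally: dynamics are run with the pairing
#' probability forced to 1, the unpairing probability to 0, and every node an
#' eligible site.  A homolog pair "completes" if its pairing fraction reaches
#' 1; a pair that ends below 1 with no progress over the final quarter of the
#' assay is blocked by a topological obstruction.
#'
#' @param state a `meio_state`.
#' @param config a [meio_config()].
#' @param assay_steps assay length in timesteps.
#' @param check_every interval between completion checks.
#' @param seed optional integer seed.
#' @return list: `complete` (logical per homolog pair), `fractions` (matrix of
#'   per-pair fractions at each check), `plateaued` (logical per pair),
#'   `state` (assay end state), `type` (the [classify_interlock()] call).
#' @export
force_pair_completion <- function(state, config, assay_steps = 2e6,
                                  check_every = 1e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  cfg$pairing_layout <- list(mode = "all", n_sites = config$nodes_per_chain)
  full_sites <- .site_table(cfg)
  # carry existing bonds over to the all-sites table
  paired <- rep(FALSE, nrow(full_sites))
  if (any(state$paired)) {
    key_full <- paste(full_sites$hp, full_sites$label)
    key_st <- paste(state$sites$hp, state$sites$label)[state$paired]
    paired[key_full %in% key_st] <- TRUE
  }
  st <- state
  st$sites <- full_sites
  st$paired <- paired
  n_checks <- max(1, ceiling(assay_steps / check_every))
  n_hp <- config$n_chains %/% 2
  frac <- matrix(NA_real_, n_checks, n_hp)
  for (k in seq_len(n_checks)) {
    st <- .advance(st, cfg, check_every, pairing_on = TRUE,
                   p_pair = 1, p_unpair = 0)$state
    frac[k, ] <- as.numeric(tapply(st$paired, st$sites$hp, mean))
    if (all(frac[k, ] >= 1)) {
      frac <- frac[seq_len(k), , drop = FALSE]
      break
    }
  }
  last <- frac[nrow(frac), ]
  complete <- last >= 1
  tail_from <- max(1, ceiling(nrow(frac) * 0.75))
  plateaued <- apply(frac, 2, function(col) {
    max(col[tail_from:length(col)]) - min(col[tail_from:length(col)]) < 1e-9
  })
  if (any(!complete & !plateaued)) {
    warning("assay ended before blocked pair(s) plateaued; consider a longer assay")
  }
  res <- list(complete = complete, fractions = frac, plateaued = plateaued,
              state = st)
  res$type <- classify_interlock(complete)
  res
}

#' Classify an interlock from completion flags
#'
#' @param complete logical vector of per-homolog-pair completion flags from
#'   the forced-pairing assay.
#' @return `"none"` (all pairs complete), `"open"` (exactly one blocked) or
#'   `"closed"` (both blocked).
#' @export
classify_interlock <- function(complete) {
  n_blocked <- sum(!complete)
  if (n_blocked == 0) "none" else if (n_blocked == 1) "open" else "closed"
}

#' Locate an interlock along the blocked chains
#'
#' Finds, on a blocked homolog pair, the contiguous run of unpaired sites
#' threaded by another chain: a gap is "threaded" when nodes of a chain from
#' the other homolog pair come within `thread_radius` of the gap's midline
#' (the midpoints between the two homologous chains across the gap).  The
#' interlock position is the midpoint label of that gap.
#'
#' @param state a `meio_state` (all-sites pairing bookkeeping, e.g. the frame
#'   of a resolution run).
#' @param config a [meio_config()].
#' @param hp restrict the search to specific homolog pairs (default: all).
#' @param thread_radius threading test radius (model length; default 1.5).
#' @return list: `hp`, `label` (gap midpoint), `distance_to_end`,
#'   `gap_labels`, `migrated` (within 10 nodes of an endpoint).  Errors if no
#'   threaded gap exists.
#' @export
interlock_position <- function(state, config, hp = NULL,
                               thread_radius = 1.5) {
  N <- config$nodes_per_chain
  hps <- if (is.null(hp)) sort(unique(state$sites$hp)) else hp
  best <- NULL
  for (h in hps) {
    rows <- which(state$sites$hp == h)
    rows <- rows[order(state$sites$label[rows])]
    lab <- state$sites$label[rows]
    unp <- !state$paired[rows]
    if (!any(unp)) next
    runs <- rle(unp)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    other_nodes <- which(!(state$chain %in% c(2 * h - 1, 2 * h)))
    if (!length(other_nodes)) next
    for (r in which(runs$values)) {
      gl <- lab[starts[r]:ends[r]]
      mid <- (state$pos[.node_id(config, 2 * h - 1, gl), , drop = FALSE] +
              state$pos[.node_id(config, 2 * h, gl), , drop = FALSE]) / 2
      dmin <- min(apply(mid, 1, function(p) {
        min(sqrt(colSums((t(state$pos[other_nodes, , drop = FALSE]) - p)^2)))
      }))
      if (dmin <= thread_radius) {
        label <- gl[ceiling(length(gl) / 2)]
        cand <- list(hp = h, label = label,
                     distance_to_end = min(label - 1, N - label),
                     gap_labels = gl,
                     migrated = min(label - 1, N - label) <= 10)
        if (is.null(best) || length(cand$gap_labels) > length(best$gap_labels))
          best <- cand
      }
    }
  }
  if (is.null(best)) {
    stop("no threaded unpaired gap found: state is inconsistent with a detected interlock")
  }
  best
}

.state_from_frame <- function(trajectory, k, config) {
  pos <- trajectory$pos[k, , ]
  vel <- matrix(stats::rnorm(length(pos), sd = sqrt(max(config$temperature, 0) /
                                                      config$mass)),
                nrow(pos), 3)
  st <- .new_state(pos, vel, config,
                   layout = list(mode = "given",
                                 site_indices = sort(unique(trajectory$sites$label))))
  st$sites <- trajectory$sites
  st$paired <- as.logical(trajectory$paired[k, ])
  st$step <- trajectory$steps[k]
  st
}

#' Three-step interlock resolution timeline
#'
#' Given a trajectory started from a planted interlock, extracts the times of
#' the three sequential resolution steps: (1) interlock migration, the first
#' time the interlock position comes within `migration_nodes` of a chain
#' endpoint; (2) telomeric unpairing, the subsequent first time the terminal
#' `tail_nodes` labels of the involved chains hold no pairing bond; (3)
#' diffusive unwinding, the subsequent first time the forced-pairing assay
#' (run on a copy of the frame) reports no interlock.  The unwinding check is
#' evaluated every `assay_stride` frames to keep the cost bounded.
#'
#' @param run a `meio_run` (or `meio_trajectory`) from a planted-interlock start.
#' @param config a [meio_config()].
#' @param migration_nodes endpoint distance defining migration (default 10).
#' @param tail_nodes terminal region for the unpairing step (default 10).
#' @param assay_steps,assay_stride unwinding-assay length and stride.
#' @param track_stride evaluate the interlock position every `track_stride`
#'   frames (the migration time is resolved to that granularity).
#' @param unwind_check run the forced-pairing assay for the unwinding step
#'   (set FALSE to extract only the first two steps cheaply).
#' @param seed optional integer seed (assay runs are stochastic).
#' @return a `meio_timeline`: list with `t_migration`, `t_telomere_unpair`,
#'   `t_unwind` (physical seconds, NA if unobserved), `resolved`, and the
#'   per-frame interlock `track` (label and distance to end, NA when no
#'   threaded gap was detectable).
#' @export
resolution_timeline <- function(run, config, migration_nodes = 10,
                                tail_nodes = 10, assay_steps = 2e5,
                                assay_stride = 25, track_stride = 1,
                                unwind_check = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traj <- if (inherits(run, "meio_run")) run$trajectory else run
  nF <- length(traj$steps)
  if (nF < 2) stop("trajectory too short for a resolution timeline")
  if (diff(traj$steps[1:2]) > 2000) {
    stop("trajectory sampling coarser than 2000 steps: resolution events unresolvable")
  }
  N <- config$nodes_per_chain
  frames_eval <- unique(c(seq(1, nF, by = track_stride), nF))
  track <- data.frame(frame = frames_eval, time = traj$times[frames_eval],
                      hp = NA_integer_, label = NA_integer_,
                      distance_to_end = NA_integer_)
  for (ti in seq_along(frames_eval)) {
    k <- frames_eval[ti]
    st <- .state_from_frame(traj, k, config)
    pos_k <- tryCatch(interlock_position(st, config), error = function(e) NULL)
    if (!is.null(pos_k)) {
      track$hp[ti] <- pos_k$hp
      track$label[ti] <- pos_k$label
      track$distance_to_end[ti] <- pos_k$distance_to_end
    }
  }
  hp_host <- track$hp[which(!is.na(track$hp))[1]]
  t_mig <- NA_real_
  k_mig <- NA_integer_
  mig <- which(!is.na(track$distance_to_end) &
                 track$distance_to_end <= migration_nodes)
  if (length(mig)) {
    k_mig <- track$frame[mig[1]]
    t_mig <- traj$times[k_mig]
  }
  t_unp <- NA_real_
  k_unp <- NA_integer_
  if (!is.na(k_mig)) {
    involved <- sort(unique(stats::na.omit(track$hp)))
    tail_rows <- traj$sites$hp %in% involved &
      (traj$sites$label <= tail_nodes | traj$sites$label > N - tail_nodes)
    for (k in k_mig:nF) {
      if (!any(traj$paired[k, tail_rows])) { k_unp <- k; t_unp <- traj$times[k]; break }
    }
  }
  t_unw <- NA_real_
  if (unwind_check && !is.na(k_unp)) {
    for (k in seq(k_unp, nF, by = assay_stride)) {
      st <- .state_from_frame(traj, k, config)
      res <- suppressWarnings(
        force_pair_completion(st, config, assay_steps = assay_steps))
      if (res$type == "none") { t_unw <- traj$times[k]; break }
    }
  }
  structure(list(t_migration = t_mig, t_telomere_unpair = t_unp,
                 t_unwind = t_unw,
                 resolved = !is.na(t_mig) && !is.na(t_unp) && !is.na(t_unw),
                 host_pair = hp_host, track = track),
            class = "meio_timeline")
}

#' @export
print.meio_timeline <- function(x, ...) {
  cat("Interlock resolution timeline (physical seconds):\n")
  cat(sprintf("  migration to within 10 nodes of an end : %s\n",
              format(x$t_migration)))
  cat(sprintf("  telomeric unpairing                    : %s\n",
              format(x$t_telomere_unpair)))
  cat(sprintf("  diffusive unwinding                    : %s\n",
              format(x$t_unwind)))
  cat(sprintf("  resolved: %s\n", x$resolved))
  invisible(x)
}
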