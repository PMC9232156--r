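#' Model-unit / physical-unit mapping
#'
#' The simulation works in reduced model units chosen for budding-yeast
#' meiotic chromatin: one length unit is 100 nm (one Kuhn segment / node
#' diameter), the energy unit is \eqn{k_B T} at simulation temperature
#' (4.17 pN nm), and the damping time of 0.1 model units corresponds to
#' 5 ms, fixing the time unit at 50 ms.  All other units are derived
#' products of these three plus the node mass (1).
#'
#' @return An object of class `meio_units`: a list with `length_nm`,
#'   `time_ms`, `energy_pNnm`, `mass` and the derived `velocity_um_s`
#'   (model velocity unit in micrometres per second) and `diffusivity_nm2_s`.
#' @examples
#' u <- unit_system()
#' u$time_ms                      # 50
#' to_physical(12, "length")      # 1200 nm, the 1.2 um nuclear radius
#' @export
unit_system <- function() {
  structure(list(
    length_nm = 100,
    time_ms = 5 / 0.1,       # damping time 0.1 model units <-> 5 ms
    energy_pNnm = 4.17,
    mass = 1,
    velocity_um_s = 100 / (5 / 0.1) * 1e-3 * 1e3,  # 100 nm / 50 ms = 2 um/s
    diffusivity_nm2_s = 100^2 / ((5 / 0.1) * 1e-3) # 2e5 nm^2/s
  ), class = "meio_units")
}

.unit_factor <- function(dimension, u = unit_system()) {
  switch(dimension,
    length = u$length_nm,                          # nm
    time = u$time_ms * 1e-3,                       # s
    energy = u$energy_pNnm,                        # pN nm
    force = u$energy_pNnm / u$length_nm,           # pN
    velocity = u$velocity_um_s,                    # um/s
    diffusivity = u$diffusivity_nm2_s,             # nm^2/s
    `spring constant` = u$energy_pNnm / u$length_nm^2,  # pN/nm
    acceleration = u$velocity_um_s / (u$time_ms * 1e-3),  # um/s^2
    stop("unknown dimension '", dimension, "'; supported: length, time, ",
         "energy, force, velocity, diffusivity, spring constant, acceleration")
  )
}

#' Convert between model units and physical units
#'
#' Physical units are: length in nm, time in s, energy in pN nm, force in pN,
#' velocity in um/s, diffusivity in nm^2/s, spring constant in pN/nm.
#'
#' @param value numeric quantity in model units (`to_physical`) or physical
#'   units (`to_model`).
#' @param dimension one of `"length"`, `"time"`, `"energy"`, `"force"`,
#'   `"velocity"`, `"diffusivity"`, `"spring constant"`, `"acceleration"`.
#' @return the converted numeric quantity.
#' @examples
#' to_physical(100, "spring constant")  # 0.0417 pN/nm
#' to_model(0.6, "velocity")            # 0.3 model velocity units
#' @export
to_physical <- function(value, dimension) {
  value * .unit_factor(dimension)
}

#' @rdname to_physical
#' @export
to_model <- function(value, dimension) {
  value / .unit_factor(dimension)
}

#' @export
print.meio_units <- function(x, ...) {
  cat("Model unit system (budding-yeast meiotic chromatin scale)\n")
  cat(sprintf("  length unit      : %g nm\n", x$length_nm))
  cat(sprintf("  time unit        : %g ms\n", x$time_ms))
  cat(sprintf("  energy unit (kT) : %g pN nm\n", x$energy_pNnm))
  cat(sprintf("  velocity unit    : %g um/s\n", x$velocity_um_s))
  cat(sprintf("  diffusivity unit : %g nm^2/s\n", x$diffusivity_nm2_s))
  invisible(x)
}

#' Build a simulation configuration
#'
#' Returns the full parameter set of the model with defaults at the values
#' used throughout: 4 chains of 100 nodes in a sphere of radius 12 (1.2 um),
#' backbone/pairing spring constant 100, WCA excluded volume with
#' \eqn{\epsilon = k_B T} and \eqn{\sigma = 1}, temperature 1, damping time
#' 0.1, timestep 0.01, pairing probability 0.85 per step within the capture
#' distance (1 node diameter) and unpairing probability 1.25e-5 per step.
#'
#' @param n_chains number of chains; homologs are consecutive pairs (1,2), (3,4), ...
#' @param nodes_per_chain beads per chain.
#' @param nuclear_radius confinement radius, model length units.
#' @param node_diameter bead diameter sigma (model length).
#' @param k_spring backbone and pairing spring constant (energy/length^2).
#' @param eps_lj,sigma_lj WCA (repulsive Lennard-Jones) parameters.
#' @param temperature thermostat temperature in units of kT.
#' @param damping Langevin damping time (model time units).
#' @param mass node mass.
#' @param dt integration timestep (model time units).
#' @param n_steps default production run length.
#' @param capture_distance centre-to-centre distance below which homologous
#'   nodes may form a pairing bond.
#' @param p_pair,p_unpair per-timestep bond creation / dissociation probabilities.
#' @param k_nuc confinement force constant (force/length^2).
#' @param rtm list: `enabled`, `chunk_steps`, `p_pull`, `force_mag` (model force).
#' @param bouquet list: `enabled`, `focus` (point on the sphere), `accel_mag`.
#' @param tether_mode `"both"`, `"single"` (first chain end only) or `"none"`.
#' @param pairing_layout list: `mode` (`"all"` or `"spread"`), `n_sites`.
#' @param equil list: `phase1_steps`, `phase2_steps`.
#' @param sample_every default trajectory sampling interval in steps.
#' @param skin neighbour-list skin distance (model length).
#' @return validated object of class `meio_config`.
#' @examples
#' cfg <- meio_config()
#' cfg$nuclear_radius
#' @export
meio_config <- function(n_chains = 4, nodes_per_chain = 100,
                        nuclear_radius = 12, node_diameter = 1,
                        k_spring = 100, eps_lj = 1, sigma_lj = 1,
                        temperature = 1, damping = 0.1, mass = 1,
                        dt = 0.01, n_steps = 1e7,
                        capture_distance = 1,
                        p_pair = 0.85, p_unpair = 1.25e-5,
                        k_nuc = 5000,
                        rtm = list(),
                        bouquet = list(),
                        tether_mode = c("both", "single", "none"),
                        pairing_layout = list(),
                        equil = list(),
                        sample_every = 2000, skin = 0.8) {
  tether_mode <- match.arg(tether_mode)
  rtm_def <- list(enabled = TRUE, chunk_steps = 2000, p_pull = 0.25,
                  force_mag = 3)
  bq_def <- list(enabled = FALSE, focus = c(0, 0, 1), accel_mag = 3)
  lay_def <- list(mode = "all", n_sites = 20)
  eq_def <- list(phase1_steps = 5e4, phase2_steps = 5e5)
  cfg <- list(
    n_chains = n_chains, nodes_per_chain = nodes_per_chain,
    nuclear_radius = nuclear_radius, node_diameter = node_diameter,
    k_spring = k_spring, eps_lj = eps_lj, sigma_lj = sigma_lj,
    temperature = temperature, damping = damping, mass = mass,
    dt = dt, n_steps = n_steps, capture_distance = capture_distance,
    p_pair = p_pair, p_unpair = p_unpair, k_nuc = k_nuc,
    rtm = utils::modifyList(rtm_def, rtm),
    bouquet = utils::modifyList(bq_def, bouquet),
    tether_mode = tether_mode,
    pairing_layout = utils::modifyList(lay_def, pairing_layout),
    equil = utils::modifyList(eq_def, equil),
    sample_every = sample_every, skin = skin
  )
  class(cfg) <- "meio_config"
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every invariant of the parameter set (probability bounds, positive
#' lengths, timestep below the damping time, pairing-site count within the
#' chain length, unit focus point, ...) and returns the normalized
#' configuration with derived fields (`r0`, the bouquet focus scaled onto the
#' sphere) populated.  All violations are reported together.
#'
#' @param config a `meio_config` (or plain list with the same fields).
#' @return the validated `meio_config`.
#' @export
validate_config <- function(config) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(config$n_chains >= 1 && config$n_chains %% 2 == 0 || config$n_chains == 1,
      "n_chains: must be a positive even number (homolog pairs) or 1")
  chk(config$nodes_per_chain >= 1, "nodes_per_chain: must be >= 1")
  chk(config$nuclear_radius > 0, "nuclear_radius: must be > 0")
  chk(config$node_diameter > 0, "node_diameter: must be > 0")
  chk(config$k_spring > 0, "k_spring: must be > 0")
  chk(config$temperature >= 0, "temperature: must be >= 0")
  chk(config$damping > 0, "damping: must be > 0")
  chk(config$dt > 0, "dt: must be > 0")
  chk(config$dt < config$damping,
      "dt: must be smaller than the damping time (momentum-timescale resolution)")
  chk(config$p_pair >= 0 && config$p_pair <= 1, "p_pair: probability must lie in [0,1]")
  chk(config$p_unpair >= 0 && config$p_unpair <= 1, "p_unpair: probability must lie in [0,1]")
  chk(config$rtm$p_pull >= 0 && config$rtm$p_pull <= 1, "rtm$p_pull: probability must lie in [0,1]")
  chk(config$capture_distance > 0, "capture_distance: must be > 0")
  chk(config$k_nuc > 0, "k_nuc: must be > 0")
  chk(config$rtm$chunk_steps >= 1, "rtm$chunk_steps: must be >= 1")
  chk(config$pairing_layout$mode %in% c("all", "spread"),
      "pairing_layout$mode: must be 'all' or 'spread'")
  if (identical(config$pairing_layout$mode, "spread")) {
    chk(config$pairing_layout$n_sites <= config$nodes_per_chain,
        sprintf("pairing_layout$n_sites: %d exceeds nodes_per_chain = %d",
                config$pairing_layout$n_sites, config$nodes_per_chain))
    chk(config$pairing_layout$n_sites >= 2,
        "pairing_layout$n_sites: spread layout needs at least 2 sites")
  }
  chk(config$tether_mode %in% c("both", "single", "none"),
      "tether_mode: must be 'both', 'single' or 'none'")
  chk(length(config$bouquet$focus) == 3 && all(is.finite(config$bouquet$focus)),
      "bouquet$focus: must be a finite 3-vector")
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  }
  # derived fields
  config$r0 <- config$sigma_lj      # backbone rest length = sigma
  nf <- sqrt(sum(config$bouquet$focus^2))
  if (nf > 0 && abs(nf - config$nuclear_radius) > 1e-9) {
    config$bouquet$focus <- config$bouquet$focus / nf * config$nuclear_radius
  }
  config
}

#' In-silico strain presets
#'
#' Three telomere-behaviour presets modelled on budding-yeast strains:
#' wild type (`WT`: active rapid telomere movement, both chromosome ends
#' tethered to the nuclear envelope), `csm4` (telomeres tethered but
#' motionless, no active pulls) and `ndj1` (telomeres detached from the
#' envelope, no active pulls).
#'
#' @param name one of `"WT"`, `"csm4"`, `"ndj1"`.
#' @param ... further arguments passed to [meio_config()] to override defaults.
#' @return a `meio_config`.
#' @examples
#' strain_preset("csm4")$rtm$enabled   # FALSE
#' @export
strain_preset <- function(name, ...) {
  valid <- c("WT", "csm4", "ndj1")
  if (!is.character(name) || length(name) != 1 || !(name %in% valid)) {
    stop("unknown strain '", paste(name, collapse = ","),
         "'; valid strains: ", paste(valid, collapse = ", "))
  }
  cfg <- switch(name,
    WT = meio_config(rtm = list(enabled = TRUE), tether_mode = "both", ...),
    csm4 = meio_config(rtm = list(enabled = FALSE), tether_mode = "both", ...),
    ndj1 = meio_config(rtm = list(enabled = FALSE), tether_mode = "none", ...)
  )
  cfg$strain <- name
  cfg
}

#' @export
print.meio_config <- function(x, ...) {
  cat("Meiotic pairing simulation configuration",
      if (!is.null(x$strain)) sprintf("(strain %s)", x$strain), "\n")
  cat(sprintf("  %d chains x %d nodes, nuclear radius %g (%.2g um)\n",
              x$n_chains, x$nodes_per_chain, x$nuclear_radius,
              to_physical(x$nuclear_radius, "length") / 1000))
  cat(sprintf("  k_spring %g, WCA eps %g sigma %g, T %g, damping %g, dt %g\n",
              x$k_spring, x$eps_lj, x$sigma_lj, x$temperature, x$damping, x$dt))
  cat(sprintf("  pairing: p_pair %g, p_unpair %g, capture %g, layout %s\n",
              x$p_pair, x$p_unpair, x$capture_distance,
              if (x$pairing_layout$mode == "all") "all nodes"
              else sprintf("%d spread sites", x$pairing_layout$n_sites)))
  cat(sprintf("  telomeres: %s-end tether, RTM %s (F=%g, p=%g/chunk), bouquet %s\n",
              x$tether_mode, if (x$rtm$enabled) "on" else "off",
              x$rtm$force_mag, x$rtm$p_pull,
              if (x$bouquet$enabled) "on" else "off"))
  invisible(x)
}

#' Read / write plain-text configuration files
#'
#' Flat `key = value` text files, one field per line, `#` comments.  Nested
#' fields use dotted keys (`rtm.p_pull`, `bouquet.enabled`, ...).
#'
#' @param path file path.
#' @param config a `meio_config` (for writing).
#' @return `read_config` returns a validated `meio_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- meio_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parsed <- if (val %in% c("TRUE", "FALSE", "true", "false")) {
      toupper(val) == "TRUE"
    } else if (grepl("^[-+0-9.eE ]+$", val) && nzchar(val)) {
      as.numeric(strsplit(val, "\\s+")[[1]])
    } else {
      val
    }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      cfg[[parts]] <- parsed
    } else if (length(parts) == 2) {
      cfg[[parts[1]]][[parts[2]]] <- parsed
    } else {
      stop("config key too deep: '", key, "'")
    }
  }
  validate_config(cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  out <- character()
  for (k in names(config)) {
    v <- config[[k]]
    if (is.list(v)) {
      for (k2 in names(v)) {
        out <- c(out, sprintf("%s.%s = %s", k, k2, paste(v[[k2]], collapse = " ")))
      }
    } else if (is.atomic(v)) {
      out <- c(out, sprintf("%s = %s", k, paste(v, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}
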