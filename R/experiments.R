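# Experiment drivers for the named simulation protocols: strain comparisons
# with both pairing-site layouts, bouquet on/off, nuclear-radius sweeps,
# interlock censuses, planted-interlock resolution runs, chain-length
# sweeps, and the periodic-box diffusion measurement.

.derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max %/% 2, n)
}

# one production run from a fresh equilibrated system; optionally assay the
# end state for interlocks
.one_run <- function(config, n_steps, seed, assay = FALSE, assay_steps = 5e5,
                     sample_every = config$sample_every) {
  set.seed(seed)
  st <- meio_equilibrate(config)
  run <- run_pairing(st, config, n_steps = n_steps, sample_every = sample_every)
  out <- list(fraction = trajectory_fraction(run$trajectory),
              times = run$trajectory$times,
              final_state = run$state, run = run)
  if (assay) {
    res <- force_pair_completion(run$state, config, assay_steps = assay_steps)
    out$interlock <- res$type
    out$complete <- res$complete
  }
  out
}

#' Run a named experiment protocol
#'
#' Runs one of the packaged experiment protocols:
#' \describe{
#'   \item{fig3a}{three strains, pairing at every node}
#'   \item{fig3b}{three strains, twenty spread pairing sites}
#'   \item{fig4}{bouquet on vs off}
#'   \item{fig5}{nuclear radius sweep 8, 10, 12 (0.8-1.2 um)}
#'   \item{fig6b}{three strains with an end-of-run interlock census}
#'   \item{fig6cd}{planted open/closed interlock resolution probability}
#'   \item{fig7}{double- vs single-end telomere attachment (+ census)}
#'   \item{fig8}{bouquet on/off census and radius-sweep census}
#'   \item{s9}{chain-length sweep N = 80, 100, 120 (+ census)}
#'   \item{msd}{periodic-box diffusion measurement}
#' }
#'
#' @param name experiment name (see Details).
#' @param config base configuration (default [meio_config()]).
#' @param n_runs runs per condition.
#' @param n_steps production steps per run (default `config$n_steps`).
#' @param seed master seed; per-run seeds are derived from it.
#' @param out_dir optional directory: per-condition time courses (TSV),
#'   trajectories (native dialect) and a manifest are written there.
#' @return a `meio_experiment`: list of per-condition results (time-course
#'   ensembles, interlock censuses or timelines as appropriate) plus the
#'   manifest.
#' @export
run_experiment <- function(name, config = meio_config(), n_runs = 3,
                           n_steps = config$n_steps, seed = 1,
                           out_dir = NULL) {
  valid <- c("fig3a", "fig3b", "fig4", "fig5", "fig6b", "fig6cd", "fig7",
             "fig8", "s9", "msd")
  if (!name %in% valid) {
    stop("unknown experiment '", name, "'; valid: ", paste(valid, collapse = ", "))
  }
  mod <- function(base, ...) {
    ch <- list(...)
    for (k in names(ch)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(ch[[k]]))
        utils::modifyList(base[[k]], ch[[k]]) else ch[[k]]
    }
    validate_config(base)
  }
  strain_mod <- function(base, s, layout) {
    cc <- switch(s,
      WT = mod(base, rtm = list(enabled = TRUE), tether_mode = "both"),
      csm4 = mod(base, rtm = list(enabled = FALSE), tether_mode = "both"),
      ndj1 = mod(base, rtm = list(enabled = FALSE), tether_mode = "none"))
    cc$strain <- s
    if (!missing(layout)) cc$pairing_layout <- layout
    cc
  }
  conds <- switch(name,
    fig3a = lapply(c("WT", "csm4", "ndj1"), function(s)
      list(label = s, config = strain_mod(config, s, list(mode = "all")))),
    fig3b = lapply(c("WT", "csm4", "ndj1"), function(s)
      list(label = s,
           config = strain_mod(config, s, list(mode = "spread", n_sites = 20)))),
    fig4 = list(
      list(label = "bouquet", config = mod(config, bouquet = list(enabled = TRUE))),
      list(label = "no_bouquet", config = mod(config, bouquet = list(enabled = FALSE)))),
    fig5 = lapply(c(8, 10, 12), function(R)
      list(label = paste0("R", R), config = mod(config, nuclear_radius = R))),
    fig6b = lapply(c("WT", "csm4", "ndj1"), function(s)
      list(label = s, config = strain_mod(config, s))),
    fig6cd = list(
      list(label = "open", config = config),
      list(label = "closed", config = config)),
    fig7 = list(
      list(label = "both_ends", config = mod(config, tether_mode = "both")),
      list(label = "single_end", config = mod(config, tether_mode = "single"))),
    fig8 = list(
      list(label = "bouquet", config = mod(config, bouquet = list(enabled = TRUE))),
      list(label = "no_bouquet", config = mod(config, bouquet = list(enabled = FALSE))),
      list(label = "R8", config = mod(config, nuclear_radius = 8)),
      list(label = "R10", config = mod(config, nuclear_radius = 10))),
    s9 = lapply(c(80, 100, 120), function(N)
      list(label = paste0("N", N), config = mod(config, nodes_per_chain = N))),
    msd = list(list(label = "msd", config = mod(config, tether_mode = "none")))
  )
  census <- name %in% c("fig6b", "fig7", "fig8", "s9")
  seeds <- .derive_seeds(seed, length(conds) * max(n_runs, 1))
  results <- list()
  si <- 0
  for (cond in conds) {
    cc <- cond$config
    runs <- list()
    for (r in seq_len(n_runs)) {
      si <- si + 1
      if (name == "fig6cd") {
        runs[[r]] <- .planted_resolution_run(cond$label, cc, n_steps, seeds[si])
      } else if (name == "msd") {
        runs[[r]] <- list(run = diffusion_run(cc, n_steps = n_steps,
                                              seed = seeds[si]))
      } else {
        runs[[r]] <- .one_run(cc, n_steps, seeds[si], assay = census)
      }
    }
    res <- list(label = cond$label, config = cc, runs = runs)
    if (!name %in% c("fig6cd", "msd")) {
      res$timecourse <- timecourse_ensemble(lapply(runs, `[[`, "fraction"),
                                            runs[[1]]$times)
    }
    if (census) {
      k <- sum(vapply(runs, function(x) x$interlock != "none", logical(1)))
      res$interlock_fraction <- k / n_runs
      res$interlock_ci <- binomial_proportion_ci(k, n_runs)
    }
    if (name == "fig6cd") {
      k <- sum(vapply(runs, function(x) x$remaining, logical(1)))
      res$interlock_fraction <- k / n_runs
      res$interlock_ci <- binomial_proportion_ci(k, n_runs)
    }
    results[[cond$label]] <- res
  }
  out <- structure(list(name = name, conditions = results, seed = seed,
                        n_runs = n_runs, n_steps = n_steps),
                   class = "meio_experiment")
  if (!is.null(out_dir)) .write_experiment(out, out_dir)
  out
}

.planted_resolution_run <- function(type, config, n_steps, seed) {
  set.seed(seed)
  st <- make_interlocked_config(type, config)
  st <- randomize_preserving_topology(st, config)
  run <- run_pairing(st, config, n_steps = n_steps)
  res <- force_pair_completion(run$state, config, assay_steps = 5e5)
  list(run = run, type0 = type, type_end = res$type,
       remaining = res$type != "none",
       fraction = trajectory_fraction(run$trajectory),
       times = run$trajectory$times)
}

#' Periodic-box diffusion run
#'
#' Simulates the default chains, unconfined and untethered, in a periodic
#' cubic box of volume equal to the nuclear sphere (density matched), the
#' protocol used to measure the chromatin diffusion coefficient without
#' confinement effects.
#'
#' @param config a [meio_config()].
#' @param n_steps production steps.
#' @param seed optional integer seed.
#' @param sample_every frame interval.
#' @param equil_steps equilibration steps in the box before recording.
#' @return a `meio_run` whose trajectory holds unwrapped coordinates.
#' @export
diffusion_run <- function(config, n_steps = 2e6, seed = NULL,
                          sample_every = 500, equil_steps = 2e5) {
  if (!is.null(seed)) set.seed(seed)
  box <- (4 / 3 * pi * config$nuclear_radius^3)^(1 / 3)
  cfg <- config
  cfg$tether_mode <- "none"
  st <- initialize_lattice(cfg)
  st$tether <- integer(0)
  st <- .advance(st, cfg, 5e4, cap = cfg$node_diameter / 10, box = box)$state
  st <- .advance(st, cfg, equil_steps, box = box)$state
  st$step <- 0
  out <- .advance(st, cfg, n_steps, box = box, sample_every = sample_every)
  traj <- .new_trajectory(out$frames, st, cfg,
                          initial = list(pos = st$pos, step = 0,
                                         paired = st$paired))
  structure(list(trajectory = traj, state = out$state, rtm_schedule = NULL,
                 diagnostics = out$diagnostics, box = box),
            class = "meio_run")
}

#' @export
print.meio_experiment <- function(x, ...) {
  cat(sprintf("Experiment '%s': %d condition(s), %d run(s) each, %g steps\n",
              x$name, length(x$conditions), x$n_runs, x$n_steps))
  for (cond in x$conditions) {
    line <- sprintf("  %-12s", cond$label)
    if (!is.null(cond$timecourse)) {
      line <- paste0(line, sprintf(" final paired fraction %.3f",
                                   cond$timecourse$mean[length(cond$timecourse$mean)]))
    }
    if (!is.null(cond$interlock_fraction)) {
      line <- paste0(line, sprintf("  interlocks %.0f%%", 100 * cond$interlock_fraction))
    }
    cat(line, "\n")
  }
  invisible(x)
}

.write_experiment <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in x$conditions) {
    d <- file.path(out_dir, cond$label)
    dir.create(d, showWarnings = FALSE)
    if (!is.null(cond$timecourse)) {
      utils::write.table(
        data.frame(time_s = cond$timecourse$times, mean = cond$timecourse$mean,
                   ci_low = cond$timecourse$ci_low, ci_high = cond$timecourse$ci_high),
        file.path(d, "timecourse.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    }
    for (r in seq_along(cond$runs)) {
      rr <- cond$runs[[r]]
      if (!is.null(rr$run) && inherits(rr$run, "meio_run")) {
        write_trajectory(rr$run$trajectory,
                         file.path(d, sprintf("run%02d.traj", r)))
      }
    }
    write_config(cond$config, file.path(d, "config.txt"))
  }
  manifest <- c(
    sprintf("experiment = %s", x$name),
    sprintf("seed = %d", x$seed),
    sprintf("n_runs = %d", x$n_runs),
    sprintf("n_steps = %g", x$n_steps),
    sprintf("package_version = %s",
            as.character(utils::packageVersion("meiosim"))),
    sprintf("conditions = %s", paste(names(x$conditions), collapse = " "))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
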