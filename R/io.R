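# Trajectory serialization: a self-describing native text dialect plus XYZ
# and LAMMPS-dump exports for external visualizers.

.config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "")
  # small deterministic text hash (djb2 modulo 2^31), hex
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a trajectory to a text file
#'
#' The native dialect is self-describing: a header with unit metadata and the
#' configuration hash, then one block per frame holding node records
#' (chain, label, x, y, z in model units) and the active pairing bonds as
#' (chainA, chainB, label) triples.  The `xyz` and `lammps-dump` dialects are
#' lossy exports for external visualizers, with the chain encoded in the atom
#' type column.
#'
#' @param trajectory a `meio_trajectory`.
#' @param path output file path.
#' @param dialect `"native"`, `"xyz"` or `"lammps-dump"`.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(trajectory, path,
                             dialect = c("native", "xyz", "lammps-dump")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  nF <- length(trajectory$steps)
  n <- length(trajectory$chain)
  u <- unit_system()
  if (dialect == "native") {
    writeLines(c(
      "# meiosim trajectory v1",
      sprintf("# units length_nm=%g time_ms=%g energy_pNnm=%g",
              u$length_nm, u$time_ms, u$energy_pNnm),
      sprintf("# n_nodes=%d n_chains=%d config_hash=%s n_frames=%d",
              n, length(unique(trajectory$chain)), .config_hash(trajectory$config), nF)
    ), con)
    for (k in seq_len(nF)) {
      bonded <- which(as.logical(trajectory$paired[k, ]))
      writeLines(sprintf("FRAME step=%.0f time=%.6g n_nodes=%d n_bonds=%d",
                         trajectory$steps[k], trajectory$times[k], n,
                         length(bonded)), con)
      writeLines(sprintf("%d %d %.10g %.10g %.10g", trajectory$chain,
                         trajectory$label, trajectory$pos[k, , 1],
                         trajectory$pos[k, , 2], trajectory$pos[k, , 3]), con)
      writeLines("BONDS", con)
      if (length(bonded)) {
        s <- trajectory$sites[bonded, ]
        writeLines(sprintf("%d %d %d", 2 * s$hp - 1, 2 * s$hp, s$label), con)
      }
    }
  } else if (dialect == "xyz") {
    for (k in seq_len(nF)) {
      writeLines(sprintf("%d", n), con)
      writeLines(sprintf("step=%.0f time=%.6g", trajectory$steps[k],
                         trajectory$times[k]), con)
      writeLines(sprintf("C%d %.6f %.6f %.6f", trajectory$chain,
                         trajectory$pos[k, , 1], trajectory$pos[k, , 2],
                         trajectory$pos[k, , 3]), con)
    }
  } else {
    R <- trajectory$config$nuclear_radius
    for (k in seq_len(nF)) {
      writeLines(c("ITEM: TIMESTEP",
                   sprintf("%.0f", trajectory$steps[k]),
                   "ITEM: NUMBER OF ATOMS",
                   sprintf("%d", n),
                   "ITEM: BOX BOUNDS ff ff ff",
                   sprintf("%.6f %.6f", -R, R),
                   sprintf("%.6f %.6f", -R, R),
                   sprintf("%.6f %.6f", -R, R),
                   "ITEM: ATOMS id type x y z"), con)
      writeLines(sprintf("%d %d %.6f %.6f %.6f", seq_len(n), trajectory$chain,
                         trajectory$pos[k, , 1], trajectory$pos[k, , 2],
                         trajectory$pos[k, , 3]), con)
    }
  }
  invisible(path)
}

#' Read a trajectory file
#'
#' Reads the native dialect losslessly (inverse of [write_trajectory()]); a
#' LAMMPS dump is imported with positions and ids only (empty bond sets, with
#' a warning).
#'
#' @param path file path.
#' @param config a [meio_config()] used to rebuild unit/time metadata for
#'   dump imports (default [meio_config()]).
#' @return a `meio_trajectory`.
#' @export
read_trajectory <- function(path, config = meio_config()) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty trajectory file")
  if (startsWith(lines[1], "# meiosim trajectory")) {
    return(.read_native(lines, path))
  }
  if (startsWith(lines[1], "ITEM: TIMESTEP")) {
    return(.read_dump(lines, config))
  }
  stop("unrecognized trajectory dialect (line 1: '", lines[1], "')")
}

.read_native <- function(lines, path) {
  hdr <- grep("^# n_nodes=", lines, value = TRUE)
  if (!length(hdr)) stop("malformed header: missing n_nodes line (line 3)")
  get_field <- function(s, key) {
    m <- regmatches(s, regexpr(paste0(key, "=[-0-9a-fx.e]+"), s))
    if (!length(m)) stop("malformed header near '", s, "'")
    sub(paste0(key, "="), "", m)
  }
  n <- as.integer(get_field(hdr, "n_nodes"))
  frame_starts <- grep("^FRAME ", lines)
  if (!length(frame_starts)) {
    # header-only file: empty trajectory
    return(structure(list(steps = numeric(0), times = numeric(0),
                          pos = array(0, c(0, n, 3)),
                          paired = matrix(FALSE, 0, 0),
                          sites = NULL, chain = integer(0), label = integer(0),
                          tether = integer(0), config = NULL),
                     class = "meio_trajectory"))
  }
  nF <- length(frame_starts)
  steps <- numeric(nF); times <- numeric(nF)
  pos <- array(NA_real_, c(nF, n, 3))
  bonds <- vector("list", nF)
  chain <- label <- NULL
  for (k in seq_len(nF)) {
    at <- frame_starts[k]
    steps[k] <- as.numeric(get_field(lines[at], "step"))
    times[k] <- as.numeric(get_field(lines[at], "time"))
    nb <- as.integer(get_field(lines[at], "n_bonds"))
    node_rows <- lines[(at + 1):(at + n)]
    if (length(node_rows) < n || anyNA(node_rows)) {
      stop("truncated frame at line ", at)
    }
    M <- matrix(as.numeric(unlist(strsplit(node_rows, " ", fixed = TRUE))),
                ncol = 5, byrow = TRUE)
    if (anyNA(M)) stop("malformed node record in frame starting at line ", at)
    if (k == 1) { chain <- as.integer(M[, 1]); label <- as.integer(M[, 2]) }
    pos[k, , ] <- M[, 3:5]
    if (!identical(lines[at + n + 1], "BONDS")) {
      stop("malformed frame: expected BONDS at line ", at + n + 1)
    }
    if (nb > 0) {
      brows <- lines[(at + n + 2):(at + n + 1 + nb)]
      if (length(brows) < nb || anyNA(brows)) stop("truncated bond block at line ", at + n + 1)
      B <- matrix(as.integer(unlist(strsplit(brows, " ", fixed = TRUE))),
                  ncol = 3, byrow = TRUE)
      bonds[[k]] <- B
    } else {
      bonds[[k]] <- matrix(integer(0), 0, 3)
    }
  }
  all_b <- unique(do.call(rbind, bonds))
  hp_of <- function(cA) (cA + 1) %/% 2
  if (nrow(all_b)) {
    sites <- data.frame(hp = hp_of(all_b[, 1]), label = all_b[, 3])
    sites <- unique(sites[order(sites$hp, sites$label), ])
  } else {
    sites <- data.frame(hp = integer(0), label = integer(0))
  }
  paired <- matrix(FALSE, nF, nrow(sites))
  if (nrow(sites)) {
    key <- paste(sites$hp, sites$label)
    for (k in seq_len(nF)) {
      if (nrow(bonds[[k]])) {
        paired[k, key %in% paste(hp_of(bonds[[k]][, 1]), bonds[[k]][, 3])] <- TRUE
      }
    }
  }
  structure(list(steps = steps, times = times, pos = pos, paired = paired,
                 sites = sites, chain = chain, label = label,
                 tether = integer(0), config = NULL),
            class = "meio_trajectory")
}

.read_dump <- function(lines, config) {
  warning("LAMMPS dump import: no pairing block, bond sets will be empty")
  starts <- grep("^ITEM: TIMESTEP", lines)
  nF <- length(starts)
  steps <- numeric(nF)
  pos <- NULL
  chain <- NULL
  for (k in seq_len(nF)) {
    at <- starts[k]
    steps[k] <- as.numeric(lines[at + 1])
    n <- as.integer(lines[at + 3])
    rows <- lines[(at + 9):(at + 8 + n)]
    M <- matrix(as.numeric(unlist(strsplit(rows, " ", fixed = TRUE))),
                ncol = 5, byrow = TRUE)
    M <- M[order(M[, 1]), , drop = FALSE]
    if (is.null(pos)) {
      pos <- array(NA_real_, c(nF, n, 3))
      chain <- as.integer(M[, 2])
    }
    pos[k, , ] <- M[, 3:5]
  }
  u <- unit_system()
  structure(list(steps = steps, times = steps * config$dt * u$time_ms * 1e-3,
                 pos = pos, paired = matrix(FALSE, nF, 0),
                 sites = data.frame(hp = integer(0), label = integer(0)),
                 chain = chain,
                 label = stats::ave(chain, chain, FUN = seq_along),
                 tether = integer(0), config = config),
            class = "meio_trajectory")
}
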