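# Primitive path analysis: contract chains to their primitive paths and
# count entanglement kinks.

#' Primitive path of a chain in a multi-chain system
#'
#' Implements the classic contraction protocol: the endpoints of every chain
#' are fixed, intra-chain excluded volume is switched off, inter-chain
#' excluded volume and the backbone springs are retained (with the spring
#' rest length set to zero so the springs provide pure contraction), and the
#' system is quenched to zero temperature by overdamped minimization until
#' the maximum force falls below `ftol`.  Each chain contracts to the
#' shortest path through its entanglements; an isolated chain contracts to
#' the straight endpoint-to-endpoint segment.
#'
#' @param state an equilibrated `meio_state`.
#' @param chain_of_interest chain index whose contracted path is reported.
#' @param config a [meio_config()].
#' @param ftol force tolerance for convergence (model units).
#' @param max_iter maximum minimization iterations.
#' @param kink_args arguments passed on to [count_kinks()].
#' @return a `meio_ppa`: list with `path` (contracted coordinates of the
#'   chain of interest), `all_pos` (contracted coordinates of every chain),
#'   `kink_labels`, `kink_count`, `converged`, `max_force`.
#' @export
primitive_path <- function(state, chain_of_interest = 1, config,
                           ftol = 1e-3, max_iter = 2e5, kink_args = list()) {
  res <- cpp_ppa(state$pos, as.integer(state$chain - 1L),
                 config$k_spring, config$eps_lj, config$sigma_lj,
                 ftol, as.double(max_iter))
  if (!res$converged) {
    stop(sprintf("primitive-path minimization did not converge: residual max force %.3g after %g iterations",
                 res$max_force, res$iterations))
  }
  pos <- res$pos
  sel <- state$chain == chain_of_interest
  if (!any(sel)) stop("chain ", chain_of_interest, " not present")
  path <- pos[sel, , drop = FALSE]
  others <- lapply(setdiff(unique(state$chain), chain_of_interest),
                   function(ch) pos[state$chain == ch, , drop = FALSE])
  kk <- do.call(count_kinks, c(list(path = path, others = others), kink_args))
  structure(list(path = path, all_pos = pos,
                 kink_labels = attr(kk, "labels"), kink_count = as.integer(kk),
                 converged = res$converged, max_force = res$max_force,
                 iterations = res$iterations),
            class = "meio_ppa")
}

#' @export
print.meio_ppa <- function(x, ...) {
  cat(sprintf("Primitive path: %d nodes, %d entanglement kink(s)%s\n",
              nrow(x$path), x$kink_count,
              if (length(x$kink_labels))
                paste0(" at node(s) ", paste(x$kink_labels, collapse = ", "))
              else ""))
  invisible(x)
}

# Douglas-Peucker polyline simplification
.simplify_polyline <- function(P, tol) {
  n <- nrow(P)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2) next
    a <- P[i, ]; b <- P[j, ]
    ab <- b - a
    ab2 <- sum(ab^2)
    seg <- (i + 1):(j - 1)
    d <- vapply(seg, function(k) {
      t <- if (ab2 > 0) sum((P[k, ] - a) * ab) / ab2 else 0
      t <- min(1, max(0, t))
      sqrt(sum((P[k, ] - (a + t * ab))^2))
    }, numeric(1))
    kmax <- seg[which.max(d)]
    if (max(d) > tol) {
      keep[kmax] <- TRUE
      stack <- c(stack, list(c(i, kmax)), list(c(kmax, j)))
    }
  }
  which(keep)
}

#' Count entanglement kinks along a contracted path
#'
#' Automates the visual entanglement count: the contracted path is first
#' simplified (Douglas-Peucker, tolerance `simplify_tol`) so that collinear
#' runs collapse; a retained interior vertex is a kink when its turning angle
#' exceeds `angle_deg` and it lies within `proximity` of another chain (an
#' excluded-volume contact, the signature of an entanglement).  Nearby kink
#' vertices (within `merge_dist` along the path) are merged into one
#' entanglement.
#'
#' @param path n x 3 contracted coordinates of the chain of interest.
#' @param others list of m x 3 coordinate matrices of the other chains
#'   (contracted); may be empty.
#' @param angle_deg turning-angle threshold in degrees (default 45).
#' @param proximity contact distance to another chain in model length
#'   (default 1.5).
#' @param simplify_tol simplification tolerance (default 0.3).
#' @param merge_dist merge radius for adjacent kink vertices (default 2).
#' @return integer kink count with attribute `labels` (node indices on the
#'   original path).
#' @export
count_kinks <- function(path, others = list(), angle_deg = 45,
                        proximity = 1.5, simplify_tol = 0.3, merge_dist = 2) {
  keep <- .simplify_polyline(path, simplify_tol)
  if (length(keep) <= 2) {
    return(structure(0L, labels = integer(0)))
  }
  verts <- keep[-c(1, length(keep))]
  kinks <- integer(0)
  for (m in seq_along(verts)) {
    k <- verts[m]
    prev <- keep[m]; nxt <- keep[m + 2]
    v1 <- path[k, ] - path[prev, ]
    v2 <- path[nxt, ] - path[k, ]
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 < 1e-12 || n2 < 1e-12) next
    ang <- acos(min(1, max(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
    if (ang <= angle_deg) next
    if (length(others)) {
      dmin <- min(vapply(others, function(O) {
        min(sqrt(colSums((t(O) - path[k, ])^2)))
      }, numeric(1)))
      if (dmin > proximity) next
    } else {
      next   # no other chains: a kink cannot be an entanglement
    }
    kinks <- c(kinks, k)
  }
  if (length(kinks) > 1) {
    merged <- kinks[c(TRUE, diff(kinks) > merge_dist)]
  } else {
    merged <- kinks
  }
  structure(length(merged), labels = merged)
}
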