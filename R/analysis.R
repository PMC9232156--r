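# Ensemble kinetics, MSD/diffusion, kymographs, telomere speeds, and the
# statistical procedures used to compare conditions.

#' Ensemble pairing time course with 95% confidence band
#'
#' Pointwise mean of per-run pairing-fraction series on a common time grid
#' with the normal-theory 95% confidence interval on the mean
#' (mean +- 1.96 SE).
#'
#' @param runs list of numeric vectors (one pairing-fraction series per run,
#'   equal lengths) or a runs x timepoints matrix.
#' @param times physical times (seconds) of the grid points.
#' @return a `meio_timecourse`: list with `times`, `per_run`, `mean`,
#'   `ci_low`, `ci_high`, `n_runs`; the CI is NA (flagged) for a single run.
#' @export
timecourse_ensemble <- function(runs, times = NULL) {
  M <- if (is.list(runs)) do.call(rbind, runs) else as.matrix(runs)
  if (is.null(times)) times <- seq_len(ncol(M))
  if (length(times) != ncol(M)) stop("times and series lengths differ")
  mu <- colMeans(M)
  n <- nrow(M)
  if (n >= 2) {
    se <- apply(M, 2, stats::sd) / sqrt(n)
    lo <- mu - 1.96 * se
    hi <- mu + 1.96 * se
  } else {
    lo <- hi <- rep(NA_real_, ncol(M))
  }
  structure(list(times = times, per_run = M, mean = mu,
                 ci_low = lo, ci_high = hi, n_runs = n),
            class = "meio_timecourse")
}

#' @export
print.meio_timecourse <- function(x, ...) {
  cat(sprintf("Pairing time course: %d runs x %d timepoints, final mean %.3f",
              x$n_runs, length(x$times), x$mean[length(x$mean)]))
  if (x$n_runs >= 2) {
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$ci_low[length(x$mean)],
                x$ci_high[length(x$mean)]))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.meio_timecourse <- function(x, col = "steelblue", ...) {
  graphics::plot(x$times, x$mean, type = "l", lwd = 2, col = col,
                 xlab = "time (s)", ylab = "paired fraction", ylim = c(0, 1), ...)
  if (x$n_runs >= 2) {
    graphics::polygon(c(x$times, rev(x$times)), c(x$ci_low, rev(x$ci_high)),
                      col = grDevices::adjustcolor(col, 0.25), border = NA)
  }
  invisible(x)
}

#' Time to half-maximum pairing
#'
#' The plateau is the mean of the final 10% of timepoints; the half-max time
#' is the first crossing of half the plateau, linearly interpolated between
#' samples.  Returns NA (with a flag attribute) if the series never crosses.
#'
#' @param times physical times (seconds).
#' @param series mean pairing-fraction series.
#' @return half-max crossing time in seconds.
#' @export
half_max_time <- function(times, series) {
  stopifnot(length(times) == length(series))
  n <- length(series)
  plateau <- mean(series[max(1, ceiling(0.9 * n)):n])
  thr <- plateau / 2
  if (plateau <= 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  above <- which(series >= thr)
  if (!length(above)) {
    return(structure(NA_real_, undefined = TRUE))
  }
  k <- above[1]
  if (k == 1) return(times[1])
  t0 <- times[k - 1]; t1 <- times[k]
  y0 <- series[k - 1]; y1 <- series[k]
  t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
}

#' Time-averaged mean squared displacement
#'
#' MSD over all time origins at each lag, averaged over a node subset
#' (default: the ten centermost nodes of each chain), in physical units
#' (nm^2 vs seconds).
#'
#' @param trajectory a `meio_trajectory`.
#' @param nodes node indices to average over (default ten centermost per chain).
#' @param max_lag maximum lag in frames (default half the trajectory).
#' @return data frame with `lag_s` and `msd_nm2`.
#' @export
msd_curve <- function(trajectory, nodes = NULL, max_lag = NULL) {
  nF <- length(trajectory$steps)
  if (nF < 2) stop("need at least 2 frames for an MSD")
  if (is.null(nodes)) nodes <- centermost_nodes(trajectory)
  if (is.null(max_lag)) max_lag <- floor(nF / 2)
  if (max_lag >= nF) stop("max_lag exceeds the trajectory length")
  P <- trajectory$pos[, nodes, , drop = FALSE]
  u <- unit_system()
  msd <- numeric(max_lag)
  for (L in seq_len(max_lag)) {
    d <- P[(1 + L):nF, , , drop = FALSE] - P[1:(nF - L), , , drop = FALSE]
    msd[L] <- 3 * mean(d * d)   # mean over origins and nodes of |dr|^2
  }
  dt_frame <- diff(trajectory$times[1:2])
  data.frame(lag_s = seq_len(max_lag) * dt_frame,
             msd_nm2 = msd * u$length_nm^2)
}

#' Ten centermost nodes of each chain
#'
#' @param trajectory a `meio_trajectory` (or `meio_state`).
#' @param k how many central nodes per chain (default 10).
#' @return integer node indices.
#' @export
centermost_nodes <- function(trajectory, k = 10) {
  out <- integer(0)
  for (ch in unique(trajectory$chain)) {
    idx <- which(trajectory$chain == ch)
    N <- length(idx)
    lo <- floor((N - k) / 2) + 1
    out <- c(out, idx[lo:(lo + min(k, N) - 1)])
  }
  out
}

#' Diffusion coefficient from an MSD curve
#'
#' Least-squares slope of the MSD over the fit window, divided by 6.  The fit
#' window should sit in the linear regime; a fit with R^2 < 0.99 triggers a
#' warning but the estimate is still returned.
#'
#' @param msd data frame from [msd_curve()].
#' @param fit_window lag-time window in seconds, `c(lo, hi)`.
#' @return diffusion coefficient in nm^2/s, with attributes `r_squared` and
#'   `slope`.
#' @export
diffusion_coefficient <- function(msd, fit_window = c(10, 50)) {
  sel <- msd$lag_s >= fit_window[1] & msd$lag_s <= fit_window[2]
  if (sum(sel) < 2) stop("fit window contains fewer than 2 MSD points")
  fit <- stats::lm(msd_nm2 ~ lag_s, data = msd[sel, ])
  r2 <- summary(fit)$r.squared
  if (is.finite(r2) && r2 < 0.99) {
    warning(sprintf("MSD fit window not in the linear regime (R^2 = %.3f)", r2))
  }
  D <- unname(stats::coef(fit)[2]) / 6
  attr(D, "r_squared") <- r2
  attr(D, "slope") <- unname(stats::coef(fit)[2])
  D
}

#' Homolog-distance kymograph
#'
#' Matrix of distances between corresponding nodes of a homolog pair: rows
#' are node labels 1..N, columns are frames in time order.  Fast zippering
#' appears as a sudden near-vertical drop of whole label blocks below the
#' capture distance.
#'
#' @param trajectory a `meio_trajectory`.
#' @param hp homolog pair index (1 = chains 1 and 2).
#' @return an N x n_frames matrix (model length units) of class
#'   `meio_kymograph` with a `times` attribute.
#' @export
kymograph <- function(trajectory, hp = 1) {
  chains <- sort(unique(trajectory$chain))
  cA <- chains[2 * hp - 1]; cB <- chains[2 * hp]
  if (is.na(cB)) stop("homolog pair ", hp, " not present")
  iA <- which(trajectory$chain == cA)
  iB <- which(trajectory$chain == cB)
  nF <- length(trajectory$steps)
  M <- matrix(0, length(iA), nF)
  for (k in seq_len(nF)) {
    M[, k] <- sqrt(rowSums((trajectory$pos[k, iA, ] - trajectory$pos[k, iB, ])^2))
  }
  rownames(M) <- trajectory$label[iA]
  structure(M, times = trajectory$times, class = "meio_kymograph")
}

#' @export
plot.meio_kymograph <- function(x, ...) {
  graphics::image(attr(x, "times"), seq_len(nrow(x)), t(unclass(x)),
                  col = grDevices::hcl.colors(64, "Blue-Red 2", rev = TRUE),
                  xlab = "time (s)", ylab = "node label", ...)
  invisible(x)
}

#' Windowed telomere speed profile
#'
#' Speed per window is the telomere displacement over `window_steps`
#' timesteps divided by the window duration, in micrometres per second.  For
#' a telomere tethered to the nuclear envelope the displacement is measured
#' along the sphere surface (great-circle arc); for a detached telomere the
#' straight-line displacement is used.
#'
#' @param trajectory a `meio_trajectory` sampled at least as finely as the window.
#' @param telomere_id node index of the telomere.
#' @param window_steps window length in timesteps (default 2000, one RTM chunk).
#' @return a `meio_velocity_profile`: list with `times`, `speeds` (um/s),
#'   `peak`, `mean`, `telomere_id`, `window_steps`.
#' @export
telomere_velocity_profile <- function(trajectory, telomere_id,
                                      window_steps = 2000) {
  steps <- trajectory$steps
  if (length(steps) < 2) stop("trajectory too short")
  frame_int <- diff(steps[1:2])
  if (frame_int > window_steps) {
    stop("trajectory sampled more coarsely than the requested window")
  }
  stride <- max(1L, round(window_steps / frame_int))
  idx <- seq(1, length(steps), by = stride)
  P <- trajectory$pos[idx, telomere_id, , drop = TRUE]
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  cfg <- trajectory$config
  u <- unit_system()
  tethered <- telomere_id %in% trajectory$tether
  n <- nrow(P) - 1
  if (n < 1) stop("window larger than the trajectory")
  if (tethered) {
    R <- cfg$nuclear_radius
    a <- P[-(n + 1), , drop = FALSE]; b <- P[-1, , drop = FALSE]
    cosang <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
    disp <- R * acos(pmin(1, pmax(-1, cosang)))
  } else {
    disp <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-(n + 1), , drop = FALSE])^2))
  }
  win_s <- stride * frame_int * cfg$dt * u$time_ms * 1e-3
  speeds <- disp * u$length_nm * 1e-3 / win_s   # um/s
  structure(list(times = trajectory$times[idx][-1], speeds = speeds,
                 peak = max(speeds), mean = mean(speeds),
                 telomere_id = telomere_id, window_steps = window_steps),
            class = "meio_velocity_profile")
}

#' @export
print.meio_velocity_profile <- function(x, ...) {
  cat(sprintf("Telomere %d speeds over %d-step windows: mean %.3f um/s, peak %.3f um/s\n",
              x$telomere_id, x$window_steps, x$mean, x$peak))
  invisible(x)
}

#' Calibrate the RTM force against a target peak telomere speed
#'
#' Bisection on the pull-force magnitude: short test runs with every chunk
#' pulling measure the peak windowed telomere speed, and the force is
#' adjusted until the peak matches the target within `tol`.  The analytic
#' starting bracket uses the terminal-velocity relation v = F zeta / m.
#'
#' @param target_peak target peak speed in um/s (> 0).
#' @param config a [meio_config()].
#' @param state optional pre-equilibrated state (else a fresh one is built).
#' @param test_steps length of each test run.
#' @param tol relative tolerance on the peak (default 0.1).
#' @param max_iter bisection iterations (default 20).
#' @param seed optional integer seed.
#' @return calibrated force magnitude in model units.
#' @export
calibrate_rtm_force <- function(target_peak, config, state = NULL,
                                test_steps = 6e4, tol = 0.1, max_iter = 20,
                                seed = NULL) {
  if (target_peak <= 0) stop("target peak speed must be > 0 (thermal floor)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- meio_equilibrate(config)
  u <- unit_system()
  measure <- function(fmag) {
    cfg <- config
    cfg$rtm <- utils::modifyList(config$rtm,
                                 list(enabled = TRUE, p_pull = 1, force_mag = fmag))
    run <- run_pairing(state, cfg, n_steps = test_steps, pairing_on = FALSE,
                       sample_every = cfg$rtm$chunk_steps)
    peaks <- vapply(state$tether, function(tid) {
      telomere_velocity_profile(run$trajectory, tid, cfg$rtm$chunk_steps)$peak
    }, numeric(1))
    max(peaks)
  }
  # analytic guess and bracket
  f_guess <- target_peak / u$velocity_um_s * config$mass / config$damping
  lo <- f_guess / 8; hi <- f_guess * 8
  v_lo <- measure(lo); v_hi <- measure(hi)
  if (v_lo > target_peak || v_hi < target_peak) {
    stop(sprintf("calibration bracket failed: peak(%.3g) = %.3g, peak(%.3g) = %.3g um/s",
                 lo, v_lo, hi, v_hi))
  }
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    v <- measure(mid)
    if (abs(v - target_peak) <= tol * target_peak) return(mid)
    if (v < target_peak) lo <- mid else hi <- mid
  }
  stop(sprintf("calibration did not converge in %d iterations: bracket [%.3g, %.3g]",
               max_iter, lo, hi))
}

#' Wald 95% binomial proportion confidence interval
#'
#' Normal-approximation interval \eqn{\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n}}
#' clipped to `[0, 1]`.  The degenerate k = 0 and k = n cases collapse to a
#' point and are flagged.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @return numeric `c(low, high)` with attributes `estimate` and `degenerate`.
#' @examples
#' binomial_proportion_ci(50, 100)   # (0.402, 0.598)
#' @export
binomial_proportion_ci <- function(k, n) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  p <- k / n
  half <- 1.96 * sqrt(p * (1 - p) / n)
  out <- c(max(0, p - half), min(1, p + half))
  attr(out, "estimate") <- p
  attr(out, "degenerate") <- (k == 0 || k == n)
  out
}

#' Two-proportion z-test
#'
#' Pooled-proportion z statistic with two-sided normal p-value, as used to
#' compare interlock percentages between conditions.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list with `z`, `p_value`, `estimate1`, `estimate2`; `z` is NA
#'   (flagged `undefined`) when the pooled proportion is 0 or 1.
#' @examples
#' two_proportion_ztest(30, 100, 15, 100)$z   # ~2.54
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("both sample sizes must be >= 1")
  p1 <- k1 / n1; p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) {
    return(list(z = NA_real_, p_value = NA_real_, estimate1 = p1,
                estimate2 = p2, undefined = TRUE))
  }
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), estimate1 = p1,
       estimate2 = p2, undefined = FALSE)
}
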