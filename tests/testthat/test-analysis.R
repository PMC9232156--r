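test_that("time course ensembles give pointwise means with normal-theory CIs", {
  runs <- list(c(0.4, 0.5), c(0.6, 0.7))
  tc <- timecourse_ensemble(runs, times = c(1, 2))
  expect_equal(tc$mean, c(0.5, 0.6))
  expect_equal(tc$ci_high - tc$ci_low, rep(2 * 1.96 * 0.1, 2),
               tolerance = 1e-9)   # sd = 0.1*sqrt(2), n = 2
  # identical runs collapse the CI
  tc0 <- timecourse_ensemble(list(c(0.2, 0.8), c(0.2, 0.8)), c(1, 2))
  expect_equal(tc0$ci_low, tc0$mean)
  # single run: mean only, CI flagged NA
  tc1 <- timecourse_ensemble(list(c(0.1, 0.2)), c(1, 2))
  expect_true(all(is.na(tc1$ci_low)))
})

test_that("the 95% CI on the mean has calibrated coverage", {
  set.seed(123)
  n_runs <- 12; n_rep <- 1000
  covered <- replicate(n_rep, {
    M <- matrix(stats::rnorm(n_runs, mean = 0.5, sd = 0.1), ncol = 1)
    tc <- timecourse_ensemble(M, times = 1)
    tc$ci_low <= 0.5 && 0.5 <= tc$ci_high
  })
  # normal-theory interval with estimated sd at n = 12 covers slightly
  # under 95%; binomial error over 1000 replications
  expect_equal(mean(covered), 0.94, tolerance = 0.025)
})

test_that("half-max time handles steps, ramps and logistic curves", {
  tt <- seq(0, 10, by = 0.1)
  step <- as.numeric(tt >= 4)
  expect_equal(half_max_time(tt, step), 4, tolerance = 0.1)
  ramp <- tt / 10
  expect_equal(half_max_time(tt, ramp), 10 / 2, tolerance = 0.3)
  logi <- 1 / (1 + exp(-(tt - 3) / 0.5))
  expect_equal(half_max_time(tt, logi), 3, tolerance = 0.15)
  flat <- rep(0, length(tt))
  expect_true(is.na(half_max_time(tt, flat)) ||
                isTRUE(attr(half_max_time(tt, flat), "undefined")))
})

test_that("MSD closed forms: static and ballistic trajectories", {
  cfg <- meio_config()
  nf <- 21
  mk_traj <- function(posfun) {
    pos <- array(0, c(nf, 2, 3))
    for (k in seq_len(nf)) pos[k, , ] <- posfun(k - 1)
    structure(list(steps = (0:(nf - 1)) * 100,
                   times = (0:(nf - 1)) * 100 * cfg$dt * 0.05,
                   pos = pos, paired = matrix(FALSE, nf, 0),
                   sites = data.frame(), chain = c(1L, 2L), label = c(1L, 1L),
                   tether = integer(0), config = cfg),
              class = "meio_trajectory")
  }
  static <- mk_traj(function(k) matrix(c(1, 2, 3, 4, 5, 6), 2, 3))
  ms <- msd_curve(static, nodes = 1:2, max_lag = 10)
  expect_equal(ms$msd_nm2, rep(0, 10))
  v <- c(2, 0, 0)   # model units per step
  ball <- mk_traj(function(k) rbind(k * v, k * v))
  mb <- msd_curve(ball, nodes = 1:2, max_lag = 10)
  # displacement 2 model lengths (200 nm) per frame: MSD = (200 L)^2 nm^2
  expect_equal(mb$msd_nm2, (200 * seq_len(10))^2, tolerance = 1e-9)
})

test_that("diffusion coefficient recovers a planted D from Brownian traces", {
  cfg <- meio_config()
  set.seed(55)
  D_model <- 0.1                      # model units: kT zeta / m
  n_steps <- 1e5; dt_frame <- 10      # frames every 10 steps
  nf <- n_steps / dt_frame
  n_nodes <- 10
  sd_step <- sqrt(2 * D_model * dt_frame * cfg$dt)
  pos <- array(0, c(nf, n_nodes, 3))
  for (i in seq_len(n_nodes)) {
    pos[, i, ] <- apply(matrix(stats::rnorm(3 * nf, sd = sd_step), ncol = 3),
                        2, cumsum)
  }
  traj <- structure(list(steps = seq_len(nf) * dt_frame,
                         times = seq_len(nf) * dt_frame * cfg$dt * 0.05,
                         pos = pos, paired = matrix(FALSE, nf, 0),
                         sites = data.frame(), chain = seq_len(n_nodes),
                         label = rep(1L, n_nodes),
                         tether = integer(0), config = cfg),
                    class = "meio_trajectory")
  m <- msd_curve(traj, nodes = seq_len(n_nodes), max_lag = 60)
  D <- diffusion_coefficient(m, fit_window = range(m$lag_s))
  expect_equal(as.numeric(D), 2e4, tolerance = 0.03)
  # exact line MSD = 6 D t returns D with R^2 = 1
  exact <- data.frame(lag_s = 1:10, msd_nm2 = 6 * 600 * (1:10))
  expect_equal(as.numeric(suppressWarnings(diffusion_coefficient(exact, c(1, 10)))), 600)
})

test_that("kymograph rows are homolog distances by label through time", {
  cfg <- small_config()
  set.seed(77)
  st <- meio_equilibrate(cfg)
  out <- step_dynamics(st, cfg, n_steps = 4e3, pairing_on = TRUE,
                       sample_every = 1e3)
  traj <- meiosim:::.new_trajectory(out$frames, st, cfg)
  km <- kymograph(traj, hp = 1)
  expect_equal(dim(km), c(cfg$nodes_per_chain, length(traj$steps)))
  iA <- which(traj$chain == 1)
  iB <- which(traj$chain == 2)
  expect_equal(unname(km[5, 2]),
               sqrt(sum((traj$pos[2, iA[5], ] - traj$pos[2, iB[5], ])^2)))
  # identical chains give an all-zero kymograph
  traj0 <- traj
  traj0$pos[, iB, ] <- traj0$pos[, iA, ]
  expect_true(all(kymograph(traj0, 1) == 0))
})

test_that("Wald binomial interval and two-proportion z-test match reference formulas", {
  ci <- binomial_proportion_ci(50, 100)
  expect_equal(as.numeric(ci), c(0.402, 0.598), tolerance = 1e-3)
  expect_true(attr(binomial_proportion_ci(0, 20), "degenerate"))
  expect_equal(as.numeric(binomial_proportion_ci(20, 20)), c(1, 1))
  expect_error(binomial_proportion_ci(5, 0), ">= 1")

  zt <- two_proportion_ztest(30, 100, 15, 100)
  expect_equal(zt$z, 2.5398, tolerance = 1e-4)
  # cross-check against the chi-square equivalence (z^2) in prop.test
  pt <- stats::prop.test(c(30, 15), c(100, 100), correct = FALSE)
  expect_equal(zt$z^2, unname(pt$statistic), tolerance = 1e-9)
  expect_equal(zt$p_value, pt$p.value, tolerance = 1e-9)
  # antisymmetry
  zt2 <- two_proportion_ztest(15, 100, 30, 100)
  expect_equal(zt2$z, -zt$z)
  expect_equal(zt2$p_value, zt$p_value)
  # degenerate pooled proportion flagged
  expect_true(two_proportion_ztest(0, 10, 0, 10)$undefined)
})
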