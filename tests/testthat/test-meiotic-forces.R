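test_that("RTM schedule occupancy follows the per-chunk pull probability", {
  cfg <- meio_config()
  tel <- c(1L, 30L)
  s0 <- rtm_schedule(meio_config(rtm = list(p_pull = 0)), tel, 2e4, seed = 1)
  expect_equal(nrow(s0), 0)
  s1 <- rtm_schedule(meio_config(rtm = list(p_pull = 1)), tel, 2e4, seed = 1)
  expect_equal(nrow(s1), 2 * 10)   # one event per telomere per chunk
  n_chunks <- 1e4
  s <- rtm_schedule(cfg, 1L, n_chunks * 2000, seed = 2)
  expect_equal(nrow(s) / n_chunks, 0.25, tolerance = 0.04)
  # directions are unit vectors held for a whole chunk
  expect_equal(sqrt(s$dx^2 + s$dy^2 + s$dz^2), rep(1, nrow(s)), tolerance = 1e-9)
  expect_true(all(s$duration_steps == 2000))
})

test_that("a radial pull on a tethered telomere produces no surface drag", {
  cfg <- meio_config(temperature = 0, n_chains = 1, nodes_per_chain = 1)
  st <- node_pair_state(1, cfg)
  st$pos <- matrix(c(0, 0, 12), 1, 3)[1, , drop = FALSE]
  st$pos <- rbind(c(0, 0, 12))
  st$vel <- rbind(c(0, 0, 0))
  st$chain <- 1L; st$label <- 1L
  st$sites <- st$sites[0, ]; st$paired <- logical(0)
  st$tether <- 1L
  rtmF <- matrix(c(0, 0, 5), 1, 3)   # outward radial pull
  out <- meiosim:::.advance(st, cfg, 500, rtm_nodes = 1L, rtm_forces = rtmF,
                            wca_on = FALSE)
  expect_equal(out$state$pos[1, ], c(0, 0, 12), tolerance = 1e-6)
})

test_that("a tangential pull reaches the terminal drift speed F zeta / m", {
  cfg <- meio_config(temperature = 0, n_chains = 1, nodes_per_chain = 1)
  st <- structure(list(pos = rbind(c(0, 0, 12)), vel = rbind(c(0, 0, 0)),
                       chain = 1L, label = 1L,
                       sites = data.frame(hp = integer(), label = integer(),
                                          iA = integer(), iB = integer()),
                       paired = logical(0), tether = 1L, step = 0),
                  class = "meio_state")
  rtmF <- matrix(c(3, 0, 0), 1, 3)   # tangential at the north pole
  out <- meiosim:::.advance(st, cfg, 2000, rtm_nodes = 1L, rtm_forces = rtmF,
                            wca_on = FALSE, sample_every = 2000)
  # arc speed: terminal velocity F zeta / m = 0.3 sigma per time unit
  traj <- meiosim:::.new_trajectory(out$frames, st, cfg,
                                    initial = list(pos = st$pos, step = 0,
                                                   paired = st$paired))
  prof <- telomere_velocity_profile(traj, 1, window_steps = 2000)
  expect_equal(prof$peak, to_physical(0.3, "velocity"), tolerance = 0.05)
})

test_that("velocity profile of a static telomere is zero", {
  cfg <- meio_config()
  nf <- 6
  traj <- structure(list(
    steps = (0:(nf - 1)) * 2000,
    times = (0:(nf - 1)) * 2000 * cfg$dt * 0.05,
    pos = array(rep(c(0, 0, 12), each = nf), c(nf, 1, 3)),
    paired = matrix(FALSE, nf, 0),
    sites = data.frame(), chain = 1L, label = 1L, tether = 1L,
    config = cfg), class = "meio_trajectory")
  prof <- telomere_velocity_profile(traj, 1, 2000)
  expect_equal(prof$speeds, rep(0, nf - 1))
  expect_error(telomere_velocity_profile(traj, 1, 500), "coarsely")
})

test_that("RTM force calibration responds linearly to the target speed", {
  cfg <- meio_config(equil = list(phase1_steps = 2e4, phase2_steps = 1e5))
  set.seed(9)
  st <- meio_equilibrate(cfg)
  f1 <- calibrate_rtm_force(0.6, cfg, state = st, test_steps = 2e4, seed = 10)
  f2 <- calibrate_rtm_force(1.2, cfg, state = st, test_steps = 2e4, seed = 10)
  # the bare-drag estimate F = v m / zeta gives 3 for a 0.6 um/s peak;
  # chain recruitment makes the response super-linear beyond that
  expect_gt(f1, 1.5)
  expect_lt(f1, 6)
  expect_gt(f2, f1 * 1.4)
  expect_error(calibrate_rtm_force(0, cfg, state = st), "thermal floor")
})

test_that("the bouquet bias clusters telomeres around the focus", {
  eq <- list(phase1_steps = 2e4, phase2_steps = 1e5)
  cfg_b <- meio_config(bouquet = list(enabled = TRUE),
                       rtm = list(enabled = FALSE), equil = eq)
  cfg_n <- meio_config(bouquet = list(enabled = FALSE),
                       rtm = list(enabled = FALSE), equil = eq)
  angle_spread <- function(cfg, seed) {
    set.seed(seed)
    st <- meio_equilibrate(cfg)
    out <- step_dynamics(st, cfg, n_steps = 1.2e5,
                         bouquet_on = cfg$bouquet$enabled)
    p <- out$state$pos[out$state$tether, ]
    focus <- cfg$bouquet$focus / sqrt(sum(cfg$bouquet$focus^2))
    acos(pmin(1, pmax(-1, (p %*% focus) / sqrt(rowSums(p^2)))))
  }
  a_b <- angle_spread(cfg_b, 31)
  a_n <- angle_spread(cfg_n, 32)
  tst <- stats::wilcox.test(a_b, a_n, alternative = "less")
  expect_lt(tst$p.value, 0.01)
  # bouquet force geometry: telomere at the focus feels no tangential bias
  stf <- structure(list(pos = rbind(cfg_b$bouquet$focus), vel = rbind(c(0, 0, 0)),
                        chain = 1L, label = 1L, sites = data.frame(),
                        paired = logical(0), tether = 1L, step = 0),
                   class = "meio_state")
  expect_equal(bouquet_force(stf, cfg_b), matrix(0, 1, 3))
})
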