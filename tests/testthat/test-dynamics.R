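test_that("friction force is minus (m/zeta) times velocity", {
  cfg <- meio_config()
  expect_equal(friction_force(matrix(c(1, 0, 0), 1), cfg),
               matrix(c(-10, 0, 0), 1))
  expect_equal(friction_force(matrix(0, 4, 3), cfg), matrix(0, 4, 3))
  cfg2 <- meio_config(damping = 0.2)
  v <- matrix(stats::rnorm(12), 4)
  expect_equal(friction_force(v, cfg2), friction_force(v, cfg) / 2)
})

test_that("random force amplitude follows fluctuation-dissipation scaling", {
  cfg0 <- meio_config(temperature = 0)
  expect_equal(random_force(cfg0, 5), matrix(0, 5, 3))
  set.seed(1)
  cfg <- meio_config()
  f1 <- random_force(cfg, 4000)
  cfg_half <- meio_config(dt = cfg$dt / 2)
  f2 <- random_force(cfg_half, 4000)
  expect_equal(mean(f2^2) / mean(f1^2), 2, tolerance = 0.1)  # halving dt doubles variance
  expect_equal(mean(f1), 0, tolerance = 3 * sd(f1) / sqrt(length(f1)))
})

test_that("spring forces have magnitude 2 k |r - r0| and obey Newton's third law", {
  cfg <- meio_config()
  tn <- two_node_state(rbind(c(0, 0, 0), c(1.1, 0, 0)), cfg)
  f <- spring_forces(tn$state, tn$config)
  expect_equal(f[1, ], c(2 * 100 * 0.1, 0, 0), tolerance = 1e-10)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-12)
  # at rest length the force vanishes
  tn0 <- two_node_state(rbind(c(0, 0, 0), c(1, 0, 0)), cfg)
  expect_equal(spring_forces(tn0$state, tn0$config), matrix(0, 2, 3))
  # coincident bonded nodes: zero force with a warning
  tnc <- two_node_state(rbind(c(0, 0, 0), c(0, 0, 0)), cfg)
  expect_warning(fc <- spring_forces(tnc$state, tnc$config), "coincident")
  expect_equal(fc, matrix(0, 2, 3))
})

test_that("WCA force is 24 eps/sigma at contact and zero beyond the cutoff", {
  cfg <- meio_config()
  mk <- function(d) {
    st <- node_pair_state(d, cfg)   # two different chains: no backbone bond
    st
  }
  f_contact <- wca_forces(mk(1), cfg)
  expect_equal(f_contact[1, 1], -24, tolerance = 1e-9)
  expect_equal(f_contact[2, 1], 24, tolerance = 1e-9)
  expect_equal(wca_forces(mk(2^(1 / 6)), cfg), matrix(0, 2, 3))
  expect_equal(wca_forces(mk(2), cfg), matrix(0, 2, 3))
  expect_warning(wca_forces(mk(0.2), cfg), "deep overlap")
})

test_that("confinement is zero inside and k_nuc (s-R)^2 inward outside", {
  cfg <- meio_config()
  st <- node_pair_state(1, cfg)
  st$pos <- rbind(c(6, 0, 0), c(0, 0, 12.1))   # interior; 0.1 beyond R
  f <- confinement_force(st, cfg)
  expect_equal(f[1, ], c(0, 0, 0))
  expect_equal(f[2, 3], -cfg$k_nuc * 0.1^2, tolerance = 1e-9)
  st$pos[2, ] <- c(0, 0, 12)                   # exactly at the boundary
  expect_equal(confinement_force(st, cfg)[2, ], c(0, 0, 0))
})

test_that("sphere projection puts telomeres on the sphere with tangential velocity", {
  cfg <- meio_config()
  st <- node_pair_state(1, cfg)
  st$pos <- rbind(c(0, 0, 12.01), c(12.2, 0, 0))
  st$vel <- rbind(c(1, 2, 3), c(4, 5, 6))
  out <- project_onto_sphere(st, cfg, telomeres = 1:2)
  r <- sqrt(rowSums(out$pos^2))
  expect_equal(r, c(12, 12), tolerance = 1e-9)
  vr <- rowSums(out$vel * out$pos) / r
  expect_lt(max(abs(vr)), 1e-9)
  # direction preserved
  expect_equal(out$pos[1, ] / 12, c(0, 0, 1), tolerance = 1e-12)
  # far-off telomere triggers a hard error
  st$pos[1, ] <- c(0, 0, 13)
  expect_error(project_onto_sphere(st, cfg, telomeres = 1), "0.5 sigma")
})

test_that("kinetic energy equilibrates to (3/2) kT per node within 2%", {
  fp <- free_particles(100, seed = 2)
  set.seed(3)
  out <- step_dynamics(fp$state, fp$config, n_steps = 2e4, wca_on = FALSE)
  expect_equal(out$diagnostics$ke_mean, 1.5, tolerance = 0.02)
})

test_that("free-particle diffusivity equals kT zeta / m within 5%", {
  fp <- free_particles(150, seed = 4)
  set.seed(5)
  out <- step_dynamics(fp$state, fp$config, n_steps = 3e4, wca_on = FALSE,
                       sample_every = 100)
  traj <- meiosim:::.new_trajectory(out$frames, fp$state, fp$config)
  m <- msd_curve(traj, nodes = seq_len(150), max_lag = 60)
  D <- diffusion_coefficient(m, fit_window = range(m$lag_s))
  expect_equal(as.numeric(D), 2e4, tolerance = 0.05)   # kT zeta/m in nm^2/s
})

test_that("a thermalized default system stays contained and keeps finite bonds", {
  cfg <- meio_config()
  set.seed(6)
  st <- meio_equilibrate(cfg)
  out <- step_dynamics(st, cfg, n_steps = 1e4, pairing_on = TRUE)
  expect_true(all(is.finite(out$state$pos)))
  expect_lt(out$diagnostics$max_bond, 1.5 * cfg$sigma_lj)
  expect_lte(out$diagnostics$max_radius,
             cfg$nuclear_radius + 0.2 * cfg$sigma_lj)
})

test_that("T = 0 system at mechanical equilibrium does not move", {
  cfg <- meio_config(temperature = 0, n_chains = 1, nodes_per_chain = 5,
                     nuclear_radius = 30, tether_mode = "none",
                     rtm = list(enabled = FALSE))
  st <- initialize_lattice(cfg, seed = 1)
  # straight line at rest length: all forces balance
  st$pos <- cbind(seq_len(5), 0, 0)
  st$vel[] <- 0
  out <- step_dynamics(st, cfg, n_steps = 100)
  expect_equal(out$state$pos, st$pos, tolerance = 1e-10)
})

test_that("simulation runs are deterministic given (config, seed)", {
  cfg <- small_config()
  run1 <- {
    set.seed(77); st <- meio_equilibrate(cfg)
    run_pairing(st, cfg, n_steps = 5e3, sample_every = 1e3)
  }
  run2 <- {
    set.seed(77); st <- meio_equilibrate(cfg)
    run_pairing(st, cfg, n_steps = 5e3, sample_every = 1e3)
  }
  expect_identical(run1$state$pos, run2$state$pos)
  expect_identical(run1$trajectory$paired, run2$trajectory$paired)
})
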