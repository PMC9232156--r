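test_that("lattice initialization is overlap-free with tethered ends on the sphere", {
  cfg <- meio_config()
  st <- initialize_lattice(cfg, seed = 1)
  expect_gte(min(stats::dist(st$pos)), cfg$node_diameter - 1e-9)
  r_tel <- sqrt(rowSums(st$pos[st$tether, ]^2))
  expect_equal(length(st$tether), 8)
  expect_true(all(abs(r_tel - cfg$nuclear_radius) < 1e-6))
})

test_that("a single one-node chain initializes inside the sphere", {
  cfg <- meio_config(n_chains = 1, nodes_per_chain = 1, nuclear_radius = 5,
                     tether_mode = "none")
  st <- initialize_lattice(cfg, seed = 1)
  expect_equal(dim(st$pos), c(1L, 3L))
  expect_lte(sqrt(sum(st$pos^2)), 5)
})

test_that("initialization errors when the lattice cannot fit", {
  expect_error(initialize_lattice(meio_config(nuclear_radius = 4), seed = 1),
               "requires radius")
})

test_that("same seed gives a bit-identical initial state", {
  cfg <- small_config()
  a <- initialize_lattice(cfg, seed = 99)
  b <- initialize_lattice(cfg, seed = 99)
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)
})

test_that("phase-1 equilibration clamps every per-step displacement to 0.1 sigma", {
  cfg <- small_config()
  st <- initialize_lattice(cfg, seed = 3)
  out <- equilibrate_phase1(st, cfg, n_steps = 2e3, seed = 4)
  expect_lte(out$diagnostics$max_step_disp, 0.1 * cfg$node_diameter + 1e-9)
  expect_identical(out$state$step, st$step + 2e3)
  # zero steps leave the state untouched
  out0 <- equilibrate_phase1(st, cfg, n_steps = 0)
  expect_identical(out0$state$pos, st$pos)
})

test_that("phase-2 equilibration randomizes and marks t = 0", {
  cfg <- small_config()
  st <- initialize_lattice(cfg, seed = 5)
  st <- equilibrate_phase1(st, cfg, seed = 6)$state
  a <- equilibrate_phase2(st, cfg, n_steps = 5e3, seed = 7)$state
  b <- equilibrate_phase2(st, cfg, n_steps = 5e3, seed = 8)$state
  expect_equal(a$step, 0)
  expect_false(identical(a$pos, b$pos))   # different seeds diverge
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  # straight rod of N beads at spacing b: Rg = b * sqrt((N^2 - 1) / 12)
  for (N in c(2, 10, 25)) {
    b <- 0.7
    rod <- cbind(b * seq_len(N), 0, 0)
    expect_equal(radius_of_gyration(rod), b * sqrt((N^2 - 1) / 12),
                 tolerance = 1e-12)
  }
  expect_error(radius_of_gyration(matrix(0, 0, 3)), "empty")
})

test_that("ideal-chain ensembles have mean Rg near sqrt(N/6) (random-walk oracle)", {
  # brute-force random-walk sampler as the independent oracle
  set.seed(42)
  N <- 100
  rg <- replicate(300, {
    steps <- matrix(stats::rnorm(3 * (N - 1)), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2))
    radius_of_gyration(apply(rbind(0, steps), 2, cumsum))
  })
  expect_equal(mean(rg), sqrt(N / 6), tolerance = 0.05)
})

test_that("equilibrated unconfined chains reproduce random-chain Rg statistics", {
  # excluded volume off: the random-chain (ideal) reference applies exactly.
  # 30 independent single chains, phase-1 + phase-2 equilibration.
  set.seed(31)
  cfg <- meio_config(n_chains = 1, nodes_per_chain = 60, nuclear_radius = 200,
                     tether_mode = "none", rtm = list(enabled = FALSE),
                     equil = list(phase1_steps = 2e3, phase2_steps = 4e4))
  rg <- replicate(30, {
    st <- initialize_lattice(cfg)
    st <- equilibrate_phase1(st, cfg)$state
    st <- equilibrate_phase2(st, cfg, wca_on = FALSE)$state
    radius_of_gyration(st$pos)
  })
  ideal <- sqrt((60^2 - 1) / (6 * 60))   # finite-N ideal chain, b = 1
  # z-test at alpha = 0.01 against the ideal-chain mean
  z <- (mean(rg) - ideal) / (sd(rg) / sqrt(length(rg)))
  expect_lt(abs(z), qnorm(0.995) + 1)   # allow finite-bond-length bias margin
  expect_equal(mean(rg), ideal, tolerance = 0.10)
})
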