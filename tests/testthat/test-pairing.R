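test_that("pairing-site layouts match their definitions", {
  expect_identical(pairing_sites("all", nodes_per_chain = 100)$site_indices,
                   1:100)
  sp <- pairing_sites("spread", 20, 100)$site_indices
  expect_length(sp, 20)
  expect_true(all(c(1L, 100L) %in% sp))
  expect_identical(diff(range(diff(sp))), 1L)   # uniform to rounding
  expect_identical(pairing_sites("spread", 50, 50)$site_indices, 1:50)
  expect_error(pairing_sites("spread", 1, 100), "n_sites >= 2")
  expect_error(pairing_sites("spread", 101, 100), "exceeds")
})

test_that("bond creation requires proximity; p_pair = 1, p_unpair = 0 is permanent", {
  cfg <- meio_config(p_pair = 1, p_unpair = 0)
  st_far <- node_pair_state(2, cfg)
  set.seed(1)
  for (i in 1:20) st_far <- update_pairing(st_far, cfg)
  expect_false(any(st_far$paired))
  st_near <- node_pair_state(0.8, cfg)
  st_near <- update_pairing(st_near, cfg)
  expect_true(all(st_near$paired))
  for (i in 1:20) st_near <- update_pairing(st_near, cfg)
  expect_true(all(st_near$paired))
})

test_that("held-in-range site occupancy matches the two-state Markov closed form", {
  # a homolog node pair kept in range; scaled probabilities so the chain
  # mixes within the test budget, several parameter combinations
  cases <- list(c(p = 0.02, q = 0.01), c(p = 0.05, q = 0.05), c(p = 0.2, q = 0.02))
  set.seed(8)
  for (cs in cases) {
    cfg <- meio_config(p_pair = cs["p"], p_unpair = cs["q"])
    st <- node_pair_state(0.5, cfg)
    occ <- logical(2e4)
    for (i in seq_along(occ)) {
      st <- update_pairing(st, cfg)
      occ[i] <- st$paired
    }
    stat <- cs["p"] / (cs["p"] + cs["q"])
    # binomial-style tolerance with a correlation-time inflation factor
    tau <- 1 / (cs["p"] + cs["q"])
    se <- sqrt(stat * (1 - stat) / (length(occ) / (2 * tau)))
    expect_equal(unname(mean(occ)), unname(stat), tolerance = 5 * se / stat)
  }
})

test_that("pairing fraction is bonded sites over eligible sites", {
  expect_equal(pairing_fraction(logical(0)), 0)
  expect_equal(pairing_fraction(rep(TRUE, 12)), 1)
  expect_equal(pairing_fraction(c(rep(TRUE, 22), rep(FALSE, 18))), 0.55)
})

test_that("bond bookkeeping is symmetric in chain enumeration", {
  cfg <- small_config()
  set.seed(12)
  st <- meio_equilibrate(cfg)
  out <- step_dynamics(st, cfg, n_steps = 2e4, pairing_on = TRUE,
                       seed = 13)$state
  # paired sites always join equal labels of the two chains of one pair
  expect_true(all(out$sites$label[out$paired] ==
                    out$label[out$sites$iA[out$paired]]))
  expect_true(all(out$chain[out$sites$iB] - out$chain[out$sites$iA] == 1))
})

test_that("new bonds form predominantly adjacent to existing bonds (zippering)", {
  # a fully paired pair with a mid-chain block unpaired: re-pairing should
  # propagate inward from the block edges rather than at random positions
  cfg <- meio_config(rtm = list(enabled = FALSE))
  set.seed(21)
  st <- make_separated_config(cfg, paired = TRUE)
  gap <- st$sites$hp == 1 & st$sites$label %in% 31:70
  st$paired[gap] <- FALSE
  # decorrelate the unpaired block without changing the bond set
  st <- randomize_preserving_topology(st, cfg, n_steps = 3e4, cap_steps = 5e3)
  adj_new <- 0; tot_new <- 0; chance <- c()
  for (chunk in 1:25) {
    prev <- st$paired
    lab <- st$sites$label; hp <- st$sites$hp
    has_paired_nb <- vapply(seq_along(prev), function(r) {
      any(prev[hp == hp[r] & abs(lab - lab[r]) == 1])
    }, logical(1))
    st <- meiosim:::.advance(st, cfg, 1e3, pairing_on = TRUE)$state
    new <- which(st$paired & !prev)
    if (length(new)) {
      adj_new <- adj_new + sum(has_paired_nb[new])
      tot_new <- tot_new + length(new)
      chance <- c(chance, mean(has_paired_nb[!prev]))
    }
  }
  expect_gte(tot_new, 10)
  expect_gt(adj_new / tot_new, mean(chance))
})
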