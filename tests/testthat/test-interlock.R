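test_that("classification maps completion flags to none/open/closed", {
  expect_identical(classify_interlock(c(TRUE, TRUE)), "none")
  expect_identical(classify_interlock(c(FALSE, TRUE)), "open")
  expect_identical(classify_interlock(c(TRUE, FALSE)), "open")
  expect_identical(classify_interlock(c(FALSE, FALSE)), "closed")
})

test_that("planted templates are geometrically sound", {
  cfg <- meio_config(rtm = list(enabled = FALSE))
  for (type in c("open", "closed")) {
    st <- make_interlocked_config(type, cfg, seed = 5)
    # bonds at the rest length, nodes inside the nucleus, telomeres on it
    bb <- unlist(lapply(split(seq_len(nrow(st$pos)), st$chain), function(ix) {
      sqrt(rowSums(diff(st$pos[ix, ])^2))
    }))
    expect_lt(max(abs(bb - 1)), 0.2)
    expect_lte(max(sqrt(rowSums(st$pos^2))), cfg$nuclear_radius + 1e-6)
    r_tel <- sqrt(rowSums(st$pos[st$tether, ]^2))
    expect_equal(r_tel, rep(cfg$nuclear_radius, 8), tolerance = 1e-6)
    # the unpaired gap sits near mid-chain
    pos <- interlock_position(st, cfg)
    expect_gt(pos$distance_to_end, 40)
  }
})

test_that("the forced-pairing assay types planted configurations correctly", {
  cfg <- meio_config(rtm = list(enabled = FALSE))
  set.seed(61)
  st_o <- make_interlocked_config("open", cfg)
  st_o <- randomize_preserving_topology(st_o, cfg, n_steps = 3e4)
  expect_identical(
    suppressWarnings(force_pair_completion(st_o, cfg, assay_steps = 1e5)$type),
    "open")
  st_c <- make_interlocked_config("closed", cfg)
  st_c <- randomize_preserving_topology(st_c, cfg, n_steps = 3e4)
  expect_identical(
    suppressWarnings(force_pair_completion(st_c, cfg, assay_steps = 1e5)$type),
    "closed")
  st_n <- make_separated_config(cfg, paired = TRUE)
  st_n <- randomize_preserving_topology(st_n, cfg, n_steps = 3e4)
  st_n$paired[] <- FALSE
  expect_identical(
    suppressWarnings(force_pair_completion(st_n, cfg, assay_steps = 1e5)$type),
    "none")
})

test_that("topology-preserving randomization decorrelates geometry, keeps bonds", {
  cfg <- meio_config(rtm = list(enabled = FALSE))
  set.seed(62)
  st <- make_interlocked_config("open", cfg)
  r1 <- randomize_preserving_topology(st, cfg, n_steps = 2e4, seed = 63)
  r2 <- randomize_preserving_topology(st, cfg, n_steps = 2e4, seed = 64)
  expect_identical(r1$paired, st$paired)     # bond set frozen
  expect_identical(r2$paired, st$paired)
  expect_false(identical(r1$pos, r2$pos))    # distinct geometries
  expect_gt(mean(sqrt(rowSums((r1$pos - st$pos)^2))), 0.3)
  # zero steps leave the state unchanged
  r0 <- randomize_preserving_topology(st, cfg, n_steps = 0, cap_steps = 0)
  expect_identical(r0$pos, st$pos)
})

test_that("interlock localization finds the threaded gap and flags migration", {
  cfg <- meio_config(rtm = list(enabled = FALSE))
  st <- make_interlocked_config("open", cfg, seed = 66)
  pos <- interlock_position(st, cfg)
  expect_identical(pos$hp, 1L)
  expect_equal(pos$label, 50, tolerance = 3)
  expect_false(pos$migrated)
  # fully paired state has no gap: error
  st_full <- st
  st_full$paired[] <- TRUE
  expect_error(interlock_position(st_full, cfg), "no threaded unpaired gap")
  # a gap within 10 labels of the end reports migrated
  st_end <- st
  st_end$paired[] <- TRUE
  rows <- which(st_end$sites$hp == 1 & st_end$sites$label %in% 95:98)
  st_end$paired[rows] <- FALSE
  # thread the gap artificially: move a chain-3 node onto the gap midline
  gl <- 95:98
  mid <- (st_end$pos[st_end$sites$iA[rows[2]], ] +
            st_end$pos[st_end$sites$iB[rows[2]], ]) / 2
  st_end$pos[201, ] <- mid + c(0.3, 0, 0)
  p2 <- interlock_position(st_end, cfg)
  expect_true(p2$migrated)
  expect_lte(p2$distance_to_end, 10)
})

test_that("the resolution timeline orders migration, unpairing, unwinding", {
  # synthetic trajectory: hand-built pairing matrices over a planted state,
  # exercising the event definitions without a long simulation
  cfg <- meio_config(rtm = list(enabled = FALSE))
  set.seed(70)
  st <- make_interlocked_config("open", cfg)
  nf <- 6
  N <- cfg$nodes_per_chain
  pos <- array(0, c(nf, nrow(st$pos), 3))
  paired <- matrix(FALSE, nf, nrow(st$sites))
  lab <- st$sites$label; hp <- st$sites$hp
  gap_at <- function(center) {
    ok <- rep(TRUE, nrow(st$sites))
    ok[hp == 1 & abs(lab - center) <= 2] <- FALSE
    ok
  }
  centers <- c(50, 30, 15, 5, 5, 5)
  for (k in seq_len(nf)) {
    pos[k, , ] <- st$pos
    paired[k, ] <- gap_at(centers[k])
    # thread the gap so localization sees the interlock
    rows <- which(hp == 1 & lab == centers[k])
    a <- st$pos[st$sites$iA[rows], ]; b <- st$pos[st$sites$iB[rows], ]
    mid <- (a + b) / 2
    # offset perpendicular to the homolog axis: threads the gap while
    # keeping excluded-volume clearance from both chains
    d <- b - a
    perp <- c(d[2], -d[1], 0)
    if (sum(perp^2) < 1e-6) perp <- c(0, d[3], -d[2])
    pos[k, 230, ] <- mid + 0.8 * perp / sqrt(sum(perp^2))
  }
  # after migration, clear the terminal bonds (telomeric unpairing)
  tailrows <- lab <= 10 | lab > N - 10
  paired[5, tailrows] <- FALSE
  paired[6, tailrows] <- FALSE
  traj <- structure(list(steps = (0:(nf - 1)) * 2000,
                         times = (0:(nf - 1)) * 1.0,
                         pos = pos, paired = paired, sites = st$sites,
                         chain = st$chain, label = st$label,
                         tether = st$tether, config = cfg),
                    class = "meio_trajectory")
  tl <- resolution_timeline(traj, cfg, unwind_check = FALSE)
  expect_equal(tl$t_migration, 3)          # first frame with distance <= 10
  expect_equal(tl$t_telomere_unpair, 4)
  expect_true(is.na(tl$t_unwind))   # unwind check disabled
  expect_true(tl$t_migration <= tl$t_telomere_unpair)
})
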