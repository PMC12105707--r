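test_that("zero-noise trajectories are static with a constant 56-bond count", {
  tube <- make_octamer()
  traj <- jitter_trajectory(tube, 20L, sigma = 0, frame_dt = 0.1, seed = 1)
  for (k in seq_len(traj$n_frames))
    expect_identical(traj$frames[, , k], tube$xyz)
  ts <- hbond_timeseries(traj)
  expect_true(all(ts$counts$total == 56L))
})

test_that("jitter is reproducible per seed and seed-sensitive", {
  tube <- make_tube(8L, 2L)
  a <- jitter_trajectory(tube, 10L, 0.2, 0.1, seed = 42)
  b <- jitter_trajectory(tube, 10L, 0.2, 0.1, seed = 42)
  c <- jitter_trajectory(tube, 10L, 0.2, 0.1, seed = 43)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, c$frames))
  expect_identical(a$frames[, , 1], tube$xyz)  # frame 1 unperturbed
})

test_that("thermal jitter at 0.2 A keeps the network near-complete", {
  traj <- jitter_trajectory(make_octamer(), 100L, 0.2, 0.1, seed = 1)
  counts <- hbond_timeseries(traj)$counts$total
  expect_gte(min(counts), 48)
  expect_lte(max(counts), 56)
  expect_gte(mean(counts), 54)
})

test_that("jitter rejects bad arguments", {
  tube <- make_tube(8L, 2L)
  expect_error(jitter_trajectory(tube, 10L, sigma = -0.1, seed = 1),
               "sigma")
  expect_error(jitter_trajectory(tube, 0L, 0.1, seed = 1), "n_frames")
  expect_error(jitter_trajectory(tube, 10L, 0.1), "seed")
})

test_that("scripted cap unbinding removes exactly the terminal interface", {
  traj <- jitter_trajectory(make_octamer(), 40L, 0, 0.1, seed = 1)
  tru <- script_cap_unbinding(traj, event_frame = 21L, displacement = 10)
  ts <- hbond_timeseries(tru)
  expect_true(all(ts$counts$total[1:20] == 56L))
  expect_true(all(ts$counts$total[21:40] == 48L))
  # the six non-terminal interfaces keep all 8 bonds in every frame
  for (k in c(1L, 21L, 40L)) {
    rec <- detect_hbonds(tru$frames[, , k], tru$model)
    expect_true(all(table(factor(rec$interface, levels = 1:6)) == 8L))
  }
})

test_that("cap unbinding of a dimer empties the network", {
  traj <- jitter_trajectory(make_tube(8L, 2L), 10L, 0, 0.1, seed = 1)
  tru <- script_cap_unbinding(traj, 6L, displacement = 10)
  counts <- hbond_timeseries(tru)$counts$total
  expect_identical(counts, c(rep(8L, 5), rep(0L, 5)))
})

test_that("cap unbinding validates its event window", {
  traj <- jitter_trajectory(make_tube(8L, 2L), 10L, 0, 0.1, seed = 1)
  expect_error(script_cap_unbinding(traj, 0L), "out of range")
  expect_error(script_cap_unbinding(traj, 11L), "out of range")
  expect_error(script_cap_unbinding(traj, 5L, displacement = 0),
               "displacement")
})

test_that("Markov bond chains honour degenerate and invalid rates", {
  bs <- simulate_bond_states(16L, 40L, k_break_cap = 0, k_break_core = 0,
                             k_reform = 1, frame_dt = 0.1,
                             n_frames = 200L, seed = 5)
  expect_true(all(bs$presence))
  expect_identical(broken_bonds_per_ns(bs)$bhb_total, 0)
  expect_identical(table(bs$labels)[["cap"]], 16L)
  expect_identical(table(bs$labels)[["core"]], 40L)
  expect_error(simulate_bond_states(16L, 40L, -0.1, 0.1, 1, 0.1, 10L, 1),
               "rates")
})

test_that("Markov chains are reproducible per seed", {
  a <- simulate_bond_states(16L, 40L, 0.2, 0.05, 2, 0.1, 500L, seed = 9)
  b <- simulate_bond_states(16L, 40L, 0.2, 0.05, 2, 0.1, 500L, seed = 9)
  expect_identical(a$presence, b$presence)
})

test_that("empirical transition frequencies match the discretized rates", {
  k_break <- 0.3; k_reform <- 2; dt <- 0.1
  bs <- simulate_bond_states(0L, 60L, 0, k_break, k_reform, dt,
                             n_frames = 10000L, seed = 11)
  p <- bs$presence
  from <- p[, -ncol(p)]; to <- p[, -1]
  n_formed <- sum(from); n_broken <- sum(!from)
  f_break <- sum(from & !to) / n_formed
  f_reform <- sum(!from & to) / n_broken
  p_break <- 1 - exp(-k_break * dt)
  p_reform <- 1 - exp(-k_reform * dt)
  expect_lt(abs(f_break - p_break),
            3 * sqrt(p_break * (1 - p_break) / n_formed))
  expect_lt(abs(f_reform - p_reform),
            3 * sqrt(p_reform * (1 - p_reform) / n_broken))
})

test_that("estimated break rate matches the stationary expectation", {
  # 56 bonds, k_break 0.01/ns, k_reform 1/ns: expected BHB is
  # 56 * k_break * k_reform / (k_break + k_reform) = 0.5545/ns
  bs <- simulate_bond_states(16L, 40L, 0.01, 0.01, 1, 0.1,
                             n_frames = 15000L, seed = 7)
  est <- broken_bonds_per_ns(bs)
  expected <- 56 * 0.01 * 1 / 1.01
  time_ns <- (15000 - 1) * 0.1
  se <- sqrt(expected * time_ns) / time_ns  # counting error on events
  expect_lt(abs(est$bhb_total - expected), 3 * se)
})

test_that("synthetic tube lengths are positive, reproducible, on target", {
  x <- simulate_tem_lengths(2000L, mean_nm = 157, sd_nm = 60, seed = 3)
  expect_true(all(x > 0))
  expect_identical(x, simulate_tem_lengths(2000L, 157, 60, seed = 3))
  expect_lt(abs(mean(x) - 157), 3 * 60 / sqrt(2000))
  expect_error(simulate_tem_lengths(0L, 157, 60, 1), "n_tubes")
  expect_error(simulate_tem_lengths(10L, -5, 60, 1), "mean_nm")
})
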