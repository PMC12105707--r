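make_series <- function(presence, labels, frame_dt = 0.1) {
  structure(list(presence = presence, labels = labels,
                 frame_dt = frame_dt, truth = NULL),
            class = "bond_state_series")
}

test_that("BHB/ns counts raw transitions correctly", {
  # all-present: nothing breaks
  bs <- make_series(matrix(TRUE, 5, 100), rep("core", 5))
  expect_identical(broken_bonds_per_ns(bs)$bhb_total, 0)

  # one bond alternating every frame: 50 breaks over 10 ns -> 5.0/ns
  alt <- matrix(rep(c(TRUE, FALSE), length.out = 101), 1, 101)
  bs <- make_series(alt, "cap")
  est <- broken_bonds_per_ns(bs, flicker_window = 0)
  expect_equal(est$bhb_total, 5.0)
  expect_equal(est$bhb_cap, 5.0)
  expect_equal(est$bhb_core, 0)

  expect_error(broken_bonds_per_ns(make_series(matrix(TRUE, 2, 1),
                                               rep("cap", 2))),
               "insufficient")
})

test_that("the flicker window drops short absences and never adds events", {
  x <- rep(TRUE, 60)
  x[10] <- FALSE            # 1-frame flicker
  x[c(30, 31, 32)] <- FALSE # 3-frame absence
  bs <- make_series(matrix(x, 1), "core")
  expect_equal(broken_bonds_per_ns(bs, 0)$events_total, 2L)
  expect_equal(broken_bonds_per_ns(bs, 2)$events_total, 1L)
  expect_equal(broken_bonds_per_ns(bs, 4)$events_total, 0L)

  sim <- simulate_bond_states(16L, 40L, 0.4, 0.1, 2, 0.1, 3000L, seed = 21)
  rates <- vapply(c(0L, 1L, 2L, 5L, 10L),
                  function(w) broken_bonds_per_ns(sim, w)$bhb_total,
                  numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("cap and core rates add exactly to the total", {
  sim <- simulate_bond_states(16L, 40L, 0.3, 0.05, 3, 0.1, 2000L, seed = 2)
  est <- broken_bonds_per_ns(sim)
  expect_equal(est$bhb_total, est$bhb_cap + est$bhb_core,
               tolerance = 1e-12)
  expect_identical(est$events_total, est$events_cap + est$events_core)
})

test_that("the BHB estimator recovers Markov break rates across regimes", {
  # stationary-expectation oracle: n * k_break * k_reform/(k_break+k_reform),
  # valid in the fine-sampling regime (k_reform * dt = 0.025 here)
  k_reform <- 5; dt <- 0.005; nf <- 5000L
  for (k_break in c(0.005, 0.05, 0.5)) {
    for (seed in 1:7) {
      sim <- simulate_bond_states(16L, 40L, k_break, k_break, k_reform,
                                  dt, nf, seed = 100 * seed)
      est <- broken_bonds_per_ns(sim)$bhb_total
      expected <- 56 * k_break * k_reform / (k_break + k_reform)
      time_ns <- (nf - 1) * dt
      se <- sqrt(expected * time_ns) / time_ns
      expect_lt(abs(est - expected), 3 * se)
    }
  }
})

test_that("cap/core decomposition orders rates as simulated", {
  sim <- simulate_bond_states(16L, 40L, 0.5, 0.05, 5, 0.02, 5000L,
                              seed = 31)
  est <- broken_bonds_per_ns(sim)
  expect_gt(est$bhb_cap, est$bhb_core)
  expect_gt(est$bhb_cap_per_bond, est$bhb_core_per_bond)

  rev <- simulate_bond_states(16L, 40L, 0.05, 0.5, 5, 0.02, 5000L,
                              seed = 32)
  est_rev <- broken_bonds_per_ns(rev)
  expect_lt(est_rev$bhb_cap_per_bond, est_rev$bhb_core_per_bond)
})

test_that("mean inter-unimer distance is the spacing for ideal stacks", {
  tube <- make_octamer()
  expect_equal(mean_interunimer_distance(tube), 4.85, tolerance = 1e-9)
  tf <- random_rigid_transform(7)
  moved <- tube
  moved$xyz <- apply_rigid_transform(tube$xyz, tf$R, tf$t)
  expect_equal(mean_interunimer_distance(moved), 4.85, tolerance = 1e-6)
  single <- make_tube(8L, 1L)
  expect_error(mean_interunimer_distance(single), "2 rings")
})

test_that("jittered spacing stays near 4.85 A and matches a naive loop", {
  traj <- jitter_trajectory(make_octamer(), 1000L, 0.2, 0.1, seed = 11)
  d <- mean_interunimer_distance(traj)
  expect_lt(abs(d - 4.85), 0.02)

  # independent re-computation, frame by frame, ring by ring
  acc <- 0
  for (k in seq_len(traj$n_frames)) {
    xyz <- traj$frames[, , k]
    cen <- matrix(0, 8, 3)
    for (r in 1:8)
      cen[r, ] <- colMeans(xyz[traj$model$atoms$ring == r, ])
    acc <- acc + mean(sqrt(rowSums((cen[-1, ] - cen[-8, ])^2)))
  }
  expect_equal(d, acc / traj$n_frames, tolerance = 1e-12)
})

test_that("dissociation detector flags sustained drops only", {
  expect_identical(nrow(detect_dissociation_events(rep(56, 200))), 0L)

  step <- c(rep(56, 499), rep(48, 501))
  ev <- detect_dissociation_events(step, drop_threshold = 6,
                                   persistence = 50L)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$frame, 500L)
  expect_equal(ev$magnitude, 8)

  dip <- rep(56, 300); dip[100] <- 47
  expect_identical(nrow(detect_dissociation_events(dip)), 0L)

  expect_error(detect_dissociation_events(rep(56, 30), persistence = 50L),
               "persistence")
})

test_that("dissociation detector works on real scripted trajectories", {
  traj <- jitter_trajectory(make_octamer(), 300L, 0.1, 0.1, seed = 17)
  tru <- script_cap_unbinding(traj, 150L, 10)
  cs <- hbond_timeseries(tru)$counts
  ev <- detect_dissociation_events(cs)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$frame - 150L), 6)   # within the median-filter half-width
  expect_lt(abs(ev$magnitude - 8), 2)
})

test_that("length summaries and unimer conversion follow the arithmetic", {
  s <- summarize_lengths(c(157, 157, 157))
  expect_identical(s$n_tubes, 3L)
  expect_equal(s$mean_nm, 157)
  expect_equal(s$sd_nm, 0)

  x <- simulate_tem_lengths(500L, 105, 40, seed = 12)
  s2 <- summarize_lengths(x)
  expect_true(s2$mean_nm >= s2$min_nm && s2$mean_nm <= s2$max_nm)
  expect_identical(sum(s2$bins$count), 500L)

  expect_error(summarize_lengths(numeric(0)), "insufficient")
  expect_error(summarize_lengths(c(100, -3)), "positive")

  # 157 nm at a 0.485 nm repeat: 323.7 -> 324 stacked unimers
  expect_identical(length_to_unimer_count(157, 0.485), 324L)
  expect_identical(length_to_unimer_count(0.485, 0.485), 1L)
  expect_identical(length_to_unimer_count(0.1, 0.485), 1L)  # floor at 1
  expect_error(length_to_unimer_count(-1), "positive")
})

test_that("stability_report assembles all components coherently", {
  traj <- jitter_trajectory(make_octamer(), 120L, 0.2, 0.1, seed = 5)
  rep <- stability_report(traj)
  expect_equal(rep$bhb_total, rep$bhb_cap + rep$bhb_core,
               tolerance = 1e-12)
  expect_equal(rep$simulated_time, (120 - 1) * 0.1)
  expect_lt(abs(rep$mean_spacing - 4.85), 0.05)
  expect_identical(nrow(rep$dissociation_events), 0L)
})
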