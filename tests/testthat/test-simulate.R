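test_that("the quiet state is absorbing without drive", {
  net <- set_branching(test_lattice(40), 1)
  r <- simulate_steps(net, 200, p_poiss = 0, record = net$fov_indices)
  expect_true(all(r$active_count == 0))
  expect_equal(nrow(r$spikes), 0)
})

test_that("deterministic transmission activates all resting out-neighbours", {
  net <- test_lattice(40)
  net <- set_branching(net, net$k_bar)  # p_trans = 1
  u <- net$fov_indices[1]
  out <- lattice_step(net, sim_state(net, active = u))
  expect_setequal(out$active, out_neighbors(net, u))
  # the source is refractory and its neighbours active: disjoint labels
  expect_true(u %in% out$state$refr_unit)
  expect_false(u %in% out$state$active)
})

test_that("a forced unit follows the 3-step active/refractory/rest cycle", {
  net <- set_branching(test_lattice(40), 0)
  u <- net$fov_indices[1]
  r <- simulate_steps(net, 50, record = u, stim = rep(u, 50), p_stim = 1,
                      p_poiss = 0, seed = 1)
  expect_equal(nrow(r$spikes), 17)
  expect_equal(diff(r$spikes$step), rep(3, 16))
})

test_that("sigma = 0 firing rate matches the isolated-unit closed form", {
  net <- set_branching(test_lattice(40), 0)
  q <- 0.05
  r <- simulate_steps(net, 30000, p_poiss = q, seed = 11)
  frac <- r$active_count / net$n_units
  emp <- mean(frac)
  theory <- q / (1 + 2 * q)
  # Monte-Carlo error from batch means (30 batches of 1000 steps)
  bm <- colMeans(matrix(frac, nrow = 1000))
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(emp - theory), 3 * se + 1e-12)
})

test_that("stationary activity is monotone in drive and in sigma", {
  net <- test_lattice(40)
  act <- function(sigma, q, seed = 5) {
    r <- simulate_steps(set_branching(net, sigma), 6000, p_poiss = q,
                        seed = seed)
    mean(r$active_count[1001:6000])
  }
  a1 <- act(0.5, 1e-4); a2 <- act(0.5, 5e-4); a3 <- act(0.5, 2e-3)
  expect_true(a1 < a2 && a2 < a3)
  b1 <- act(0.2, 5e-4); b2 <- act(0.6, 5e-4); b3 <- act(0.95, 5e-4)
  expect_true(b1 < b2 && b2 < b3)
})

test_that("identical configuration and seed give bit-identical rasters", {
  net <- set_branching(test_lattice(40), 0.9)
  a <- simulate_steps(net, 500, p_poiss = 1e-3, record = net$fov_indices,
                      seed = 42)
  b <- simulate_steps(net, 500, p_poiss = 1e-3, record = net$fov_indices,
                      seed = 42)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$active_count, b$active_count)
})

test_that("drive calibration inverts the sigma = 0 closed form", {
  net <- set_branching(test_lattice(40), 0)
  q0 <- 0.004
  target <- 11 * q0 / (1 + 2 * q0)  # spikes per cell per 11-step frame
  net <- calibrate_poisson_drive(net, target_rate = target, seed = 3)
  expect_lt(abs(net$p_poiss - q0) / q0, 0.15)
  net0 <- calibrate_poisson_drive(net, target_rate = 0)
  expect_equal(net0$p_poiss, 0)
})

test_that("supercritical self-sustained activity makes tiny targets infeasible", {
  net <- set_branching(test_lattice(40), 1.2)
  expect_error(calibrate_poisson_drive(net, target_rate = 1e-4, seed = 3),
               "infeasible")
})

test_that("subcritical drive response is linear (slope ~1)", {
  net <- test_lattice(40)
  f <- drive_response_curve(net, sigma = 0, steps_per_point = 5000,
                            burn_in = 500, seed = 2)
  expect_equal(f$gamma, 1, tolerance = 0.1)
})

test_that("protocol trials are spaced and logged correctly", {
  net <- set_branching(test_lattice(40), 0)
  net$p_poiss <- 0
  tcs <- select_tcs(net, 2, seed = 1)
  prot <- stim_protocol(tcs, stim_steps = 50, iti_steps = 1000,
                        trials_per_tc = 3, p_stim = 1)
  ras <- run_protocol(net, prot, seed = 2)
  expect_equal(nrow(ras$trials), 6)
  expect_true(all(diff(ras$trials$onset_step) >= 1050))
  expect_setequal(unique(ras$trials$tc), match(tcs, net$fov_indices))
  # forced target with no transmission: 17 spikes per stimulation window
  tc_local <- ras$trials$tc[1]
  on <- ras$trials$onset_step[1]
  n_spk <- sum(ras$events$unit == tc_local &
                 ras$events$step >= on & ras$events$step < on + 50)
  expect_equal(n_spk, 17)
})

test_that("an empty protocol yields a spontaneous raster", {
  net <- set_branching(test_lattice(40), 0.5)
  net$p_poiss <- 1e-3
  tcs <- select_tcs(net, 2, seed = 1)
  ras <- run_protocol(net, stim_protocol(tcs, trials_per_tc = 0, p_stim = 0),
                      seed = 3)
  expect_equal(nrow(ras$trials), 0)
  expect_gt(nrow(ras$events), 0)
})

test_that("targets outside the FoV are rejected", {
  net <- set_branching(test_lattice(40), 0.5)
  net$p_poiss <- 1e-3
  outside <- setdiff(seq_len(net$n_units), net$fov_indices)[1]
  expect_error(run_protocol(net, stim_protocol(outside, trials_per_tc = 1,
                                               p_stim = 1), seed = 1),
               "FoV")
})

test_that("frame binning conserves counts and maps onsets", {
  net <- set_branching(test_lattice(40), 0.8)
  net$p_poiss <- 2e-3
  tcs <- select_tcs(net, 2, seed = 1)
  ras <- run_protocol(net, stim_protocol(tcs, iti_steps = 300,
                                         trials_per_tc = 5, p_stim = 0.2),
                      seed = 4)
  rec <- bin_to_frames(ras)
  n_frames <- ncol(rec$spikes)
  covered <- ras$events$step <= n_frames * 11
  expect_equal(sum(rec$spikes), sum(covered))
  expect_equal(rec$trials$onset_frame,
               (ras$trials$onset_step - 1) %/% 11 + 1)
  expect_error(bin_to_frames(ras, frame_ms = 21), "multiple")
})
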