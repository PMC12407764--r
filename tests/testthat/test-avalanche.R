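test_that("soft thresholding clips and shifts as defined", {
  expect_equal(soft_threshold(c(0, 3, 1, 5, 0), 1), c(0, 2, 0, 4, 0))
  x <- c(2, 0, 7, 1)
  expect_equal(soft_threshold(x, 0), x)
  expect_equal(soft_threshold(x, 7), rep(0, 4))
})

test_that("coarse graining builds the phase ensemble with dropped tails", {
  cg <- coarse_grain(c(1, 2, 3, 4), 2)
  expect_equal(cg[[1]], c(3, 7))
  expect_equal(cg[[2]], c(5))
  expect_equal(coarse_grain(c(1, 5, 2), 1)[[1]], c(1, 5, 2))
  # phase-0 sums conserve the covered range
  set.seed(2)
  x <- rpois(101, 2)
  for (k in c(2, 4, 8)) {
    ph0 <- coarse_grain(x, k)[[1]]
    nt <- (length(x) %/% k) * k
    expect_equal(sum(ph0), sum(x[seq_len(nt)]))
  }
})

test_that("avalanche extraction matches hand enumeration", {
  ev <- extract_avalanches(c(0, 2, 0, 4, 3, 0))
  expect_equal(ev$size, c(2, 7))
  expect_equal(ev$duration, c(1L, 2L))
  expect_equal(nrow(extract_avalanches(rep(0, 10))), 0)
  # leading unbounded run discarded
  expect_equal(nrow(extract_avalanches(c(2, 1, 0))), 0)
  expect_equal(nrow(extract_avalanches(c(0, 2, 1))), 0)
})

test_that("avalanche extraction agrees with a brute-force oracle", {
  set.seed(7)
  for (r in 1:30) {
    x <- rpois(sample(10:60, 1), 0.8)
    a <- extract_avalanches(x)
    b <- avalanche_brute(x)
    expect_equal(a$size, b$size)
    expect_equal(a$duration, b$duration)
    # bounded events can never exceed the total activity
    expect_lte(sum(a$size), sum(x))
  }
})

test_that("event sizes sum to the thresholded activity when runs are bounded", {
  x <- c(0, 3, 2, 0, 0, 5, 0, 1, 1, 0)
  ev <- extract_avalanches(x)
  expect_equal(sum(ev$size), sum(x))
})

test_that("k = 1 cataloguing reduces to direct extraction", {
  x <- make_branching_trace(5000, m = 0.8, immigration = 0.1, seed = 3)
  cat1 <- avalanche_catalog(as.numeric(x), k_values = 1, theta = 0)
  direct <- extract_avalanches(as.numeric(x))
  expect_equal(cat1$events$size, direct$size)
  expect_equal(cat1$events$duration, direct$duration)
})

test_that("threshold selection degrades gracefully and recovers shapes", {
  expect_error(select_threshold(rep(0, 100)), "all-zero")
  # isolated unit-height events vanish at theta = 1
  x <- rep(c(0, 1), 50)
  tf <- select_threshold(x, k = 1, theta_grid = 0:3)
  expect_lte(tf$theta_star, 1)
  # lognormal curve fit recovers planted shape parameters within 5%
  th <- seq(0.5, 30, by = 0.5)
  nn <- 400 * dlnorm(th, log(6), 0.5)
  fit <- critperturb:::fit_lognormal_curve(th, nn)
  expect_equal(fit$mu, log(6), tolerance = 0.05)
  expect_equal(fit$sigma_ln, 0.5, tolerance = 0.05)
})

test_that("per-k thresholds are selected on realistic population traces", {
  x <- make_branching_trace(20000, m = 0.95, immigration = 0.3, seed = 5)
  cat <- avalanche_catalog(as.numeric(x), k_values = c(1, 2, 4))
  expect_equal(nrow(cat$thresholds), 3)
  expect_true(all(is.finite(cat$thresholds$theta_star)))
  expect_gt(nrow(cat$events), 50)
  expect_true(all(cat$events$size > 0))
  expect_true(all(cat$events$duration >= 1))
})

test_that("mean size versus duration reproduces planted relations", {
  ev <- data.frame(size = 1:20, duration = 1:20, phase = 0L, k = 1L)
  ms <- mean_size_vs_duration(ev)
  sl <- coef(lm(log(mean_size) ~ log(duration), ms))[2]
  expect_equal(unname(sl), 1, tolerance = 1e-10)
  ev2 <- data.frame(size = 2 * (1:20)^2, duration = 1:20, phase = 0L, k = 1L)
  sl2 <- coef(lm(log(mean_size) ~ log(duration),
                 mean_size_vs_duration(ev2)))[2]
  expect_equal(unname(sl2), 2, tolerance = 1e-10)
  expect_error(mean_size_vs_duration(ev[0, ]), "empty")
})

test_that("double power-law fits recover planted parameters", {
  d <- unique(round(10^seq(0, 2.2, length.out = 25)))
  s_true <- 3 * d^2 * (1 + (d / 30)^4)^((1 - 2) / 4)
  fit <- fit_scaling_curve(data.frame(duration = d, mean_size = s_true))
  expect_equal(fit$chi_sh, 2, tolerance = 0.05)
  expect_equal(fit$chi_lg, 1, tolerance = 0.05)
  expect_equal(fit$Phi, 30, tolerance = 0.05 * 30)
  expect_false(fit$phi_unidentifiable)
})

test_that("double power-law recovery holds under log-space noise", {
  d <- unique(round(10^seq(0, 2.2, length.out = 25)))
  s_true <- 3 * d^2 * (1 + (d / 30)^4)^((1 - 2) / 4)
  err <- matrix(NA_real_, 20, 3)
  for (s in 1:20) {
    set.seed(s)
    obs <- exp(log(s_true) + rnorm(length(d), 0, 0.05))
    f <- fit_scaling_curve(data.frame(duration = d, mean_size = obs))
    err[s, ] <- abs(c(f$chi_sh - 2, f$chi_lg - 1, f$Phi - 30) / c(2, 1, 30))
  }
  expect_lt(median(err[, 1]), 0.05)
  expect_lt(median(err[, 2]), 0.05)
  expect_lt(median(err[, 3]), 0.05)
})

test_that("pure power laws flag an unidentifiable crossover", {
  d <- unique(round(10^seq(0, 2, length.out = 20)))
  fit <- fit_scaling_curve(data.frame(duration = d, mean_size = 2 * d^1.5))
  expect_equal(fit$chi_sh, 1.5, tolerance = 0.05)
  expect_equal(fit$chi_lg, 1.5, tolerance = 0.05)
  expect_true(fit$phi_unidentifiable)
})

test_that("parabolic summaries count events and spikes below a cutoff", {
  ev <- data.frame(size = c(10, 20, 30, 60), duration = c(1, 2, 3, 10),
                   phase = 0L, k = 1L)
  ps <- parabolic_summary(ev, d_max = 5)
  expect_equal(ps$event_frac, 0.75)
  expect_equal(ps$spike_frac, 0.5)
  expect_equal(parabolic_summary(ev, d_max = 100)$event_frac, 1)
  expect_equal(parabolic_summary(ev, d_max = 1)$event_frac, 0)
})

test_that("subcritical size distributions decay faster than critical ones", {
  x_sub <- make_branching_trace(40000, m = 0.5, immigration = 0.1, seed = 8)
  x_cr <- make_branching_trace(40000, m = 1, immigration = 0.1, seed = 8)
  ev_s <- extract_avalanches(as.numeric(x_sub))
  ev_c <- extract_avalanches(as.numeric(x_cr))
  q_s <- quantile(ev_s$size, c(0.5, 0.99))
  # heavier tail: critical tail ratio (P99/P50) far larger, beyond noise
  q_c <- quantile(ev_c$size, c(0.5, 0.99))
  expect_gt(q_c[2] / q_c[1], 3 * q_s[2] / q_s[1])
})
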