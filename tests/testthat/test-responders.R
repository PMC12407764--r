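test_that("trial windows sit at the documented offsets", {
  counts <- matrix(0L, 2, 130)
  counts[1, ] <- seq_len(130)          # cell 1 counts its own frame index
  rec <- manual_recording(counts, tc = 2L, onsets = 100L)
  tc <- extract_trial_counts(rec)
  expect_equal(tc$resp[1, 1], sum(100:105))
  expect_equal(tc$base[1, 1], sum(88:93))
  expect_equal(tc$base_prime[1, 1], sum(82:87))
})

test_that("constant rasters give window counts of 6", {
  counts <- matrix(1L, 3, 80)
  rec <- manual_recording(counts, tc = 3L, onsets = c(30L, 60L))
  tc <- extract_trial_counts(rec)
  expect_true(all(tc$resp == 6L) && all(tc$base == 6L) &&
                all(tc$base_prime == 6L))
})

test_that("trials too close to the recording start are dropped", {
  counts <- matrix(1L, 2, 80)
  rec <- manual_recording(counts, tc = 2L, onsets = c(10L, 40L),
                          tc_per_trial = c(2L, 2L))
  expect_warning(tc <- extract_trial_counts(rec), "dropped")
  expect_equal(nrow(tc$trials), 1)
})

test_that("outlier trials beyond 10 SD are masked", {
  counts <- matrix(0L, 2, 300)
  onsets <- c(30L, 80L, 130L, 180L, 230L)
  # cell 1 response counts: 1,1,1,1,500
  for (i in seq_along(onsets)) counts[1, onsets[i]] <- c(1L, 1L, 1L, 1L, 500L)[i]
  rec <- manual_recording(counts, tc = 2L, onsets = onsets)
  tc <- remove_outlier_trials(extract_trial_counts(rec))
  expect_equal(unname(which(tc$removed[1, ])), 5)
  # all-equal counts: nothing removed
  counts2 <- matrix(1L, 2, 300)
  rec2 <- manual_recording(counts2, tc = 2L, onsets = onsets)
  tc2 <- remove_outlier_trials(extract_trial_counts(rec2))
  expect_false(any(tc2$removed))
})

test_that("unresponsive targets are filtered out", {
  set.seed(3)
  n_tr <- 40
  counts <- matrix(rpois(3 * 3000, 0.3), 3, 3000)
  onsets <- seq(30L, by = 60L, length.out = n_tr)
  # target 1 responds strongly in 30% of trials; target 2 never
  resp_trials <- seq_len(round(0.3 * n_tr))
  for (i in resp_trials) counts[1, onsets[i]] <- 20L
  counts[2, ] <- 0L
  rec <- manual_recording(counts, tc = c(1L, 2L), onsets = rep(onsets, 2),
                          tc_per_trial = rep(c(1L, 2L), each = n_tr))
  tc <- extract_trial_counts(rec)
  kept <- filter_targets(tc)
  expect_true(1L %in% kept)
  expect_false(2L %in% kept)
  # fewer than 10 trials: unreliable, not excluded
  rec3 <- manual_recording(counts, tc = c(1L, 2L), onsets = onsets[1:5],
                           tc_per_trial = rep(1L, 5))
  kept3 <- filter_targets(extract_trial_counts(rec3))
  expect_true(1L %in% attr(kept3, "unreliable"))
})

test_that("classification is exhaustive, calibrated and powerful", {
  gt <- fixture_ground_truth(n_cells = 150, n_tc = 5, frac_posr = 0.08,
                             frac_negr = 0, base_mean = 0.6, dispersion = 1,
                             ar_sd = 0, effect_size = 8, seed = 21)
  rec <- make_recording(gt, trials_per_tc = 80, seed = 22)
  cnt <- remove_outlier_trials(extract_trial_counts(rec))
  tab <- classify_responders(cnt)
  # exhaustive partition over tested pairs
  expect_equal(sum(tab$class %in% c("PosR", "NegR", "NonR")), nrow(tab))
  expect_equal(nrow(tab), 5 * (150 - 5))
  # all strongly planted responders found
  for (k in seq_along(gt$tcs)) {
    sub <- tab[tab$tc == gt$tcs[k], ]
    expect_true(all(gt$posr_ids[[k]] %in% sub$cell[sub$class == "PosR"]))
  }
  # false-positive rate among unplanted cells near alpha
  planted <- unlist(gt$posr_ids)
  null_rows <- !(tab$cell %in% planted)
  fp <- mean(tab$class[null_rows] == "PosR")
  se <- sqrt(0.025 * 0.975 / sum(null_rows))
  expect_lt(abs(fp - 0.025), 4 * se)
})

test_that("degenerate zero-variance baselines are flagged NonR", {
  counts <- matrix(0L, 3, 800)
  onsets <- seq(30L, by = 60L, length.out = 10)
  counts[1, ] <- 1L  # constant: zero baseline SD, zero response change
  rec <- manual_recording(counts, tc = 3L, onsets = onsets)
  tab <- classify_responders(extract_trial_counts(rec))
  expect_true(all(tab$degenerate[tab$cell == 1]))
  expect_true(all(tab$class[tab$cell == 1] == "NonR"))
})

test_that("BH adjustment matches the hand step-up oracle and is monotone", {
  set.seed(5)
  p <- c(rep(0.0005, 4), runif(16))
  expect_equal(p.adjust(p, "BH"), bh_brute(p))
  # on a responder table: planted small p survive, flat p do not
  gt <- fixture_ground_truth(n_cells = 100, n_tc = 3, frac_posr = 0.1,
                             frac_negr = 0, base_mean = 0.6, dispersion = 1,
                             ar_sd = 0, effect_size = 8, seed = 31)
  rec <- make_recording(gt, trials_per_tc = 60, seed = 32)
  tab <- classify_responders(extract_trial_counts(rec))
  t1 <- fdr_adjust(tab, q = 0.01)
  t2 <- fdr_adjust(tab, q = 0.05)
  d1 <- which(t1$class == "PosR"); d2 <- which(t2$class == "PosR")
  expect_true(all(d1 %in% d2))
  planted <- unlist(gt$posr_ids)
  expect_true(all(planted %in% t1$cell[t1$class == "PosR"]))
  # all p = 1: no discoveries
  tab1 <- tab
  tab1$p <- 1; tab1$p_lower <- 1
  expect_true(all(fdr_adjust(tab1)$class == "NonR"))
})

test_that("responder fractions track alpha on null fixtures", {
  gt <- fixture_ground_truth(n_cells = 120, n_tc = 5, frac_posr = 0,
                             frac_negr = 0, base_mean = 1, dispersion = 1,
                             ar_sd = 0, seed = 41)
  rec <- make_recording(gt, trials_per_tc = 80, seed = 42)
  cnt <- extract_trial_counts(rec)
  rv <- responders_vs_alpha(cnt, alpha_grid = c(0.01, 0.05, 0.2, 0.4))
  expect_true(all(diff(rv$frac_pos) > 0))
  expect_equal(rv$frac_pos, rv$alpha, tolerance = 0.5)
  expect_lt(rv$frac_non[4], rv$frac_non[1])
})

test_that("scaling fits recover degenerate and planted exponents", {
  # response independent of TC count: h ~ 0; proportional: h = 1
  set.seed(51)
  n_tr <- 120
  counts <- matrix(0L, 10, n_tr * 40 + 50)
  onsets <- seq(30L, by = 40L, length.out = n_tr)
  tc_counts <- sample(1:7, n_tr, replace = TRUE)
  for (i in seq_len(n_tr)) {
    counts[1, onsets[i]] <- tc_counts[i]                    # the target
    counts[2:6, onsets[i]] <- 5L                            # flat responders
    counts[7:10, onsets[i]] <- as.integer(2L * tc_counts[i]) # proportional
  }
  rec <- manual_recording(counts, tc = 1L, onsets = onsets)
  cnt <- extract_trial_counts(rec)
  flat <- data.frame(tc = 1L, cell = 2:6, class = "PosR")
  prop <- data.frame(tc = 1L, cell = 7:10, class = "PosR")
  class(flat) <- class(prop) <- c("responder_table", "data.frame")
  expect_equal(scaling_fit(cnt, flat)$h, 0, tolerance = 1e-8)
  expect_equal(scaling_fit(cnt, prop)$h, 1, tolerance = 1e-8)
})

test_that("planted power-law exponents are recovered within the CI", {
  hits <- 0
  for (s in 1:3) {
    gt <- fixture_ground_truth(n_cells = 80, n_tc = 4, frac_posr = 0.15,
                               frac_negr = 0, h_true = 0.3, effect_size = 4,
                               base_mean = 0.01, ar_sd = 0, dispersion = 1,
                               seed = 60 + s)
    rec <- make_recording(gt, trials_per_tc = 100, seed = 70 + s)
    cnt <- extract_trial_counts(rec)
    planted <- do.call(rbind, lapply(seq_along(gt$tcs), function(k)
      data.frame(tc = gt$tcs[k], cell = gt$posr_ids[[k]], class = "PosR")))
    class(planted) <- c("responder_table", "data.frame")
    sf <- scaling_fit(cnt, planted, mode = "per_neuron")
    if (sf$ci[1] <= 0.3 && 0.3 <= sf$ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("correlation analysis separates planted structure from noise", {
  gt <- fixture_ground_truth(n_cells = 100, n_tc = 3, frac_posr = 0.15,
                             frac_negr = 0, effect_size = 5, base_mean = 0.3,
                             dispersion = 1, ar_sd = 0, seed = 81)
  rec <- make_recording(gt, trials_per_tc = 80, seed = 82)
  cnt <- extract_trial_counts(rec)
  tab <- classify_responders(cnt)
  co <- correlations(cnt, tab)
  # i.i.d. baseline: ongoing autocorrelation ~ 0
  expect_lt(abs(mean(co$auto$r_base_prime_base[co$auto$class == "NonR"])),
            0.05)
  # planted responders track the target's stimulated spike count
  expect_gt(mean(co$cross$r_tc_resp[co$cross$class == "PosR"]), 0.1)
  expect_lt(abs(mean(co$cross$r_tc_resp[co$cross$class == "NonR"])), 0.05)
})

test_that("Fano factors match hand arithmetic and scale linearly", {
  counts <- matrix(0L, 2, 300)
  onsets <- c(30L, 90L, 150L, 210L)
  for (i in seq_along(onsets)) {
    counts[1, onsets[i]] <- c(0L, 2L, 0L, 2L)[i]            # response
    counts[1, onsets[i] - 12L] <- c(0L, 2L, 0L, 2L)[i]      # baseline
  }
  rec <- manual_recording(counts, tc = 2L, onsets = onsets)
  cnt <- extract_trial_counts(rec)
  fr <- fano(cnt, matched = FALSE)
  row <- fr[fr$cell == 1, ]
  expect_equal(row$ff_resp_raw, 4 / 3)       # mean 1, sample var 4/3
  expect_equal(row$ff_base, 4 / 3)
  # integer scaling multiplies FF exactly
  rec3 <- manual_recording(counts * 3L, tc = 2L, onsets = onsets)
  fr3 <- fano(extract_trial_counts(rec3), matched = FALSE)
  expect_equal(fr3$ff_resp_raw[fr3$cell == 1], 3 * 4 / 3)
})

test_that("mean matching excludes cells with irreducible rate mismatch", {
  set.seed(91)
  counts <- matrix(rpois(2 * 4000, 0.2), 2, 4000)
  onsets <- seq(30L, by = 40L, length.out = 90)
  for (o in onsets) counts[1, o:(o + 5L)] <- counts[1, o:(o + 5L)] + 5L
  rec <- manual_recording(counts, tc = 2L, onsets = onsets)
  fr <- fano(extract_trial_counts(rec))
  expect_true(fr$excluded[fr$cell == 1])     # 25x rate jump cannot be matched
  gt <- fixture_ground_truth(n_cells = 60, n_tc = 2, frac_posr = 0,
                             frac_negr = 0, base_mean = 0.8, dispersion = 1,
                             ar_sd = 0, seed = 92)
  rec2 <- make_recording(gt, trials_per_tc = 60, seed = 93)
  fr2 <- fano(extract_trial_counts(rec2))
  ok <- fr2[!fr2$excluded, ]
  expect_equal(mean(ok$ff_base, na.rm = TRUE), 1, tolerance = 0.12)
  expect_equal(mean(ok$ff_resp_matched, na.rm = TRUE), 1, tolerance = 0.12)
})

test_that("trial splits partition as documented", {
  gt <- fixture_ground_truth(n_cells = 80, n_tc = 3, seed = 95)
  rec <- make_recording(gt, trials_per_tc = 60, seed = 96)
  cnt <- extract_trial_counts(rec)
  sp <- split_trials(cnt)
  expect_false(any(sp$tc_low & sp$tc_high))
  expect_false(any(sp$base_low & sp$base_high))
  expect_equal(mean(sp$base_low), 0.25, tolerance = 0.05)
  expect_equal(mean(sp$base_high), 0.25, tolerance = 0.05)
  expect_equal(sp$late[1], sp$early[2] + 1L)  # adjacent, non-overlapping
  expect_equal(sp$early[2] - sp$early[1], 5L)
  expect_equal(sp$late[2] - sp$late[1], 5L)
})

test_that("baseline-regime slopes separate coupled and independent responses", {
  set.seed(97)
  n_cells <- 150
  base_mean <- runif(n_cells, 0.05, 3)
  n_tr <- 60
  counts <- matrix(0L, n_cells + 1, n_tr * 40 + 60)
  onsets <- seq(30L, by = 40L, length.out = n_tr)
  for (i in seq_len(n_tr)) {
    f <- onsets[i]
    counts[seq_len(n_cells), (f - 12L):(f - 7L)] <-
      matrix(rpois(n_cells * 6, base_mean), n_cells)
    counts[seq_len(n_cells), f:(f + 5L)] <-
      matrix(rpois(n_cells * 6, base_mean), n_cells)   # response = base
    counts[n_cells + 1, f] <- 2L
  }
  rec <- manual_recording(counts, tc = n_cells + 1L, onsets = onsets)
  brs <- baseline_regime_scaling(extract_trial_counts(rec),
                                 theta_grid = c(0.3))
  expect_equal(brs$slopes$slope_high, 1, tolerance = 0.15)
})

test_that("distance profiles reflect planted responder geometry", {
  gt <- fixture_ground_truth(n_cells = 200, n_tc = 4, frac_posr = 0.12,
                             frac_negr = 0, effect_size = 8, base_mean = 0.4,
                             dispersion = 1, ar_sd = 0, posr_radius_um = 50,
                             seed = 98)
  rec <- make_recording(gt, trials_per_tc = 60, seed = 99)
  tab <- classify_responders(extract_trial_counts(rec))
  prof <- responder_distance_profile(tab, rec$positions,
                                     radii = c(0, 50, 150, 300, 500))
  expect_gt(prof$frac_pos[1], 0.5)
  expect_lt(max(prof$frac_pos[3:4], na.rm = TRUE), 0.15)
})
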