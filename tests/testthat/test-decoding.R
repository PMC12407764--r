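# One moderately informative fixture shared across decoding tests: each
# target drives its own small set of planted cells strongly.
dec_fixture <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$rec)) {
      gt <- fixture_ground_truth(n_cells = 60, n_tc = 3, frac_posr = 0.12,
                                 frac_negr = 0, effect_size = 5,
                                 base_mean = 0.05, dispersion = 1,
                                 ar_sd = 0, seed = 301)
      cache$gt <- gt
      cache$rec <- make_recording(gt, trials_per_tc = 40, seed = 302)
    }
    list(gt = cache$gt, rec = cache$rec)
  }
})

test_that("dataset construction applies the documented filters", {
  fx <- dec_fixture()
  ds <- build_dataset(fx$rec)          # targets always spike: nothing dropped
  expect_equal(nrow(ds$X), 120)
  expect_equal(nlevels(ds$y), 3)
  expect_false(any(fx$rec$tc %in% ds$cells))
  # a target active in under half its trials is removed
  rec2 <- fx$rec
  tc1 <- rec2$tc[1]
  idx <- which(rec2$trials$tc == tc1)
  for (i in idx[seq_len(round(0.6 * length(idx)))]) {
    f <- rec2$trials$onset_frame[i]
    rec2$spikes[tc1, f:(f + 5)] <- 0L
  }
  ds2 <- build_dataset(rec2)
  expect_false(as.character(tc1) %in% levels(ds2$y))
  # negative offsets read the baseline window
  ds_b <- build_dataset(fx$rec, offset_frames = -12, filtered = FALSE)
  expect_false(isTRUE(all.equal(ds_b$X, ds$X)))
})

test_that("planted signals decode nearly perfectly with both models", {
  fx <- dec_fixture()
  ds <- build_dataset(fx$rec)
  r_xgb <- train_eval(ds, "xgb", n_splits = 5, nrounds = 30, seed = 1)
  r_rf <- train_eval(ds, "rf", n_splits = 5, num_trees = 200, seed = 1)
  expect_gt(r_xgb$mean_accuracy, r_xgb$chance + 5 * r_xgb$se_accuracy)
  expect_gt(r_xgb$mean_accuracy, 0.85)
  expect_gt(r_rf$mean_accuracy, 0.85)
  expect_lt(abs(r_xgb$mean_accuracy - r_rf$mean_accuracy), 0.1)
  expect_true(all(r_xgb$per_class$f1 >= 0 & r_xgb$per_class$f1 <= 1))
})

test_that("shuffled labels decode at chance", {
  fx <- dec_fixture()
  ds <- build_dataset(fx$rec)
  accs <- numeric(5)
  for (s in 1:5) {
    set.seed(400 + s)
    ds_sh <- ds
    ds_sh$y <- sample(ds$y)
    r <- train_eval(ds_sh, "xgb", n_splits = 3, nrounds = 20, seed = s)
    accs[s] <- r$mean_accuracy
  }
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 1 / 3), 3 * se + 0.06)
})

test_that("eliminating Shapley-ranked features collapses performance", {
  fx <- dec_fixture()
  ds <- build_dataset(fx$rec)
  dc <- shapley_drop(ds, "xgb", repeats = 2, eliminate_per_step = 5,
                     nrounds = 20, seed = 2)
  first <- mean(vapply(dc$accuracy, `[`, numeric(1), 1))
  last <- mean(vapply(dc$accuracy, function(a) a[length(a)], numeric(1)))
  expect_gt(first, 0.85)
  expect_lt(last, 1 / 3 + 0.25)
  # elimination order is a permutation over feature cells
  ord <- dc$elimination_order[[1]]
  expect_true(all(ord %in% ds$cells))
  expect_false(anyDuplicated(ord) > 0)
  # planted informative cells dominate the earliest removals
  planted <- unique(unlist(fx$gt$posr_ids))
  early <- unlist(lapply(dc$elimination_order, head, 10))
  expect_gt(mean(early %in% planted), 0.5)
})

test_that("PosR drop probability is a bounded average over targets", {
  fx <- dec_fixture()
  ds <- build_dataset(fx$rec)
  dc <- shapley_drop(ds, "xgb", repeats = 2, eliminate_per_step = 10,
                     nrounds = 15, seed = 3)
  tab <- classify_responders(extract_trial_counts(fx$rec))
  lp <- posr_drop_probability(dc, tab)
  expect_true(all(lp$l_posr >= 0 & lp$l_posr <= 1))
  # with no PosR at all the probability is identically zero
  tab0 <- tab
  tab0$class <- "NonR"
  expect_true(all(posr_drop_probability(dc, tab0)$l_posr == 0))
})

test_that("radius zero reproduces the baseline F1 exactly", {
  fx <- dec_fixture()
  ds <- build_dataset(fx$rec)
  rx <- radius_exclusion(ds, radius_grid = c(0, 0, 600), model = "xgb",
                         n_splits = 2, nrounds = 15, seed = 4)
  expect_equal(rx$f1_by_radius[, 1], rx$f1_by_radius[, 2])
  # removing every feature collapses to zero F1
  expect_true(all(rx$f1_by_radius[, 3] == 0))
  expect_equal(sum(rx$p_ex), 1)
})

test_that("decoding information is confined to the stimulation window", {
  fx <- dec_fixture()
  tp <- temporal_profile(fx$rec, window_frames = 6,
                         offsets = c(-12, 0, 12), model = "xgb",
                         n_splits = 3, nrounds = 20, seed = 5)
  expect_gt(tp$accuracy[tp$offset == 0], tp$chance[1] + 0.3)
  expect_lt(tp$accuracy[tp$offset == -12], tp$chance[1] + 0.15)
  expect_lt(tp$accuracy[tp$offset == 12], tp$chance[1] + 0.15)
})

test_that("baseline pseudo-trials are scanned and downsampled correctly", {
  # hand-built raster: TC1 spikes alone in 3 windows, TC2 in 2, one window
  # has both targets spiking and is excluded
  counts <- matrix(0L, 4, 120)
  counts[1, c(2, 14, 26)] <- 1L       # windows 1, 3, 5
  counts[2, c(38, 50)] <- 1L          # windows 7, 9
  counts[1, 62] <- 1L; counts[2, 63] <- 1L  # window 11: co-spiking
  rec <- recording(spikes = counts,
                   positions = cbind(1:4 * 10, rep(0, 4)),
                   tc = c(1L, 2L), trials = NULL, frame_ms = 22)
  ps <- baseline_pseudotrials(rec)
  expect_equal(sum(ps$y == "1"), 3)
  expect_equal(sum(ps$y == "2"), 2)
  # downsampling matches a reference class histogram
  fx <- dec_fixture()
  ds <- build_dataset(fx$rec)
  ps2 <- baseline_pseudotrials(fx$rec, match_to = ds, seed = 6)
  want <- table(as.character(ds$y))
  got <- table(as.character(ps2$y))
  for (cl in names(got)) expect_lte(got[[cl]], want[[cl]])
})

test_that("regime partitions are disjoint and exhaustive", {
  fx <- dec_fixture()
  rs <- regime_split_decoding(fx$rec, model = "xgb", n_splits = 2,
                              nrounds = 15, seed = 7)
  expect_equal(rs$n_low + rs$n_high, rep(120, nrow(rs)))
  expect_true(all(rs$n_low > 0))
})
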