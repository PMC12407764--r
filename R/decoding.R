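#' Build a decoding dataset from a recording
#'
#' Features are the spike counts of non-target cells in a window of
#' `window_frames` frames starting `offset_frames` after each trial onset;
#' the class label is the stimulated target. With `filtered = TRUE`
#' (default) trials in which the target fired no spike in its response
#' window are dropped, and targets active in fewer than half of their
#' trials are removed entirely; unfiltered mode keeps everything (used for
#' temporal profiles).
#'
#' @param rec A [recording()] with trials.
#' @param window_frames Feature window length (default 6).
#' @param offset_frames Window offset from onset (default 0; negative
#'   offsets reach into the baseline).
#' @param filtered Apply trial/target filtering (default TRUE).
#' @return A `decoding_dataset`: `X` (trials x cells), `y` (factor of
#'   target ids), feature cell ids, positions and provenance.
#' @export
build_dataset <- function(rec, window_frames = 6L, offset_frames = 0L,
                          filtered = TRUE) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(rec$trials) || nrow(rec$trials) == 0)
    stop("recording has no trials")
  w <- as.integer(window_frames)
  trials <- rec$trials
  nf <- ncol(rec$spikes)
  ok <- trials$onset_frame + offset_frames >= 1 &
    trials$onset_frame + offset_frames + w - 1L <= nf
  trials <- trials[ok, , drop = FALSE]

  # response-window spike of the target (used by both filters)
  tc_resp <- vapply(seq_len(nrow(trials)), function(i) {
    f0 <- trials$onset_frame[i]
    f1 <- min(f0 + w - 1L, nf)
    sum(rec$spikes[trials$tc[i], f0:f1])
  }, numeric(1))

  keep_trial <- rep(TRUE, nrow(trials))
  keep_tc <- unique(trials$tc)
  if (filtered) {
    keep_trial <- tc_resp >= 1
    frac_active <- vapply(keep_tc, function(tc)
      mean(tc_resp[trials$tc == tc] >= 1), numeric(1))
    keep_tc <- keep_tc[frac_active >= 0.5]
    keep_trial <- keep_trial & trials$tc %in% keep_tc
  }
  trials <- trials[keep_trial, , drop = FALSE]
  if (length(unique(trials$tc)) < 2)
    stop("fewer than 2 target classes survive filtering")

  cells <- setdiff(seq_len(nrow(rec$spikes)), rec$tc)
  X <- matrix(0L, nrow(trials), length(cells),
              dimnames = list(NULL, paste0("c", cells)))
  for (i in seq_len(nrow(trials))) {
    f0 <- trials$onset_frame[i] + offset_frames
    X[i, ] <- rowSums(rec$spikes[cells, f0:(f0 + w - 1L), drop = FALSE])
  }
  structure(list(X = X, y = factor(trials$tc), cells = cells,
                 positions = rec$positions, tc = rec$tc,
                 window_frames = w, offset_frames = as.integer(offset_frames),
                 filtered = filtered, trials = trials),
            class = "decoding_dataset")
}

# -- internal model wrappers ------------------------------------------------

fit_clf <- function(X, y, model = c("xgb", "rf"), nrounds = 100L,
                    num_trees = 500L, max_depth = 6L) {
  model <- match.arg(model)
  lev <- levels(y)
  if (model == "xgb") {
    dtr <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
    bst <- xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = length(lev),
                    max_depth = max_depth, eta = 0.3, nthread = 1,
                    verbosity = 0),
      data = dtr, nrounds = nrounds)
    list(model = bst, kind = "xgb", levels = lev, n_feat = ncol(X))
  } else {
    df <- data.frame(y = y, X, check.names = FALSE)
    rf <- ranger::ranger(y ~ ., data = df, num.trees = num_trees,
                         importance = "impurity", num.threads = 1,
                         respect.unordered.factors = TRUE)
    list(model = rf, kind = "rf", levels = lev, n_feat = ncol(X))
  }
}

predict_clf <- function(fit, X) {
  if (fit$kind == "xgb") {
    pr <- predict(fit$model, xgboost::xgb.DMatrix(X))
    if (is.null(dim(pr)))
      pr <- matrix(pr, ncol = length(fit$levels), byrow = TRUE)
    factor(fit$levels[max.col(pr, ties.method = "first")],
           levels = fit$levels)
  } else {
    p <- predict(fit$model, data = data.frame(X, check.names = FALSE),
                 num.threads = 1)$predictions
    factor(as.character(p), levels = fit$levels)
  }
}

# mean |attribution| per feature: TreeSHAP for the boosted model,
# impurity importance for the random forest (documented fallback).
feature_importance <- function(fit, X) {
  if (fit$kind == "xgb") {
    contrib <- predict(fit$model, xgboost::xgb.DMatrix(X),
                       predcontrib = TRUE)
    if (is.list(contrib)) {            # one matrix per class
      imp <- Reduce(`+`, lapply(contrib, function(m)
        colMeans(abs(m[, seq_len(fit$n_feat), drop = FALSE]))))
    } else if (length(dim(contrib)) == 3) {  # n x class x (p + bias)
      imp <- apply(abs(contrib[, , seq_len(fit$n_feat), drop = FALSE]),
                   3, mean)
    } else {                           # flat n x (class * (p + bias))
      nc <- ncol(contrib) / (fit$n_feat + 1L)
      imp <- numeric(fit$n_feat)
      for (k in seq_len(nc)) {
        off <- (k - 1L) * (fit$n_feat + 1L)
        imp <- imp + colMeans(abs(contrib[, off + seq_len(fit$n_feat),
                                          drop = FALSE]))
      }
    }
    stats::setNames(imp, colnames(X))
  } else {
    ranger::importance(fit$model)[colnames(X)]
  }
}

class_metrics <- function(truth, pred) {
  lev <- levels(truth)
  tab <- table(factor(truth, lev), factor(pred, lev))
  tp <- diag(tab)
  prec <- tp / pmax(colSums(tab), 1)
  rec <- tp / pmax(rowSums(tab), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = mean(truth == pred),
       per_class = data.frame(class = lev, precision = as.numeric(prec),
                              recall = as.numeric(rec), f1 = as.numeric(f1)))
}

stratified_split <- function(y, test_frac) {
  test <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    n_test <- max(1L, round(test_frac * length(idx)))
    n_test <- min(n_test, length(idx) - 1L)  # keep at least one for training
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

#' Train and evaluate a decoder over repeated random splits
#'
#' Stratified 80/20 train/test splits repeated `n_splits` times; overall
#' accuracy, per-class precision/recall/F1 and their means and standard
#' errors are reported, along with the chance level 1/n_classes.
#'
#' @param ds A `decoding_dataset`.
#' @param model `"xgb"` (gradient-boosted trees) or `"rf"` (random forest).
#' @param n_splits Number of repeated splits (default 100).
#' @param test_frac Test fraction (default 0.2).
#' @param seed Integer seed.
#' @param nrounds,num_trees,max_depth Model hyperparameters.
#' @return A `decoding_result`.
#' @export
train_eval <- function(ds, model = c("xgb", "rf"), n_splits = 100L,
                       test_frac = 0.2, seed = 1L, nrounds = 100L,
                       num_trees = 500L, max_depth = 6L) {
  stopifnot(inherits(ds, "decoding_dataset"))
  model <- match.arg(model)
  set.seed(as.integer(seed))
  acc <- numeric(n_splits)
  f1m <- numeric(n_splits)
  pc_acc <- NULL
  for (s in seq_len(n_splits)) {
    test <- stratified_split(ds$y, test_frac)
    train <- setdiff(seq_along(ds$y), test)
    fit <- fit_clf(ds$X[train, , drop = FALSE], ds$y[train], model,
                   nrounds, num_trees, max_depth)
    pred <- predict_clf(fit, ds$X[test, , drop = FALSE])
    m <- class_metrics(ds$y[test], pred)
    acc[s] <- m$accuracy
    f1m[s] <- mean(m$per_class$f1)
    pc_acc <- if (is.null(pc_acc)) m$per_class[, -1] else
      pc_acc + m$per_class[, -1]
  }
  per_class <- cbind(class = levels(ds$y), pc_acc / n_splits)
  structure(list(model = model, n_splits = n_splits,
                 accuracy = acc, f1_macro = f1m,
                 mean_accuracy = mean(acc), se_accuracy = stats::sd(acc) /
                   sqrt(n_splits),
                 mean_f1 = mean(f1m), se_f1 = stats::sd(f1m) / sqrt(n_splits),
                 per_class = per_class,
                 chance = 1 / nlevels(ds$y)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(paste0("decoding_result (%s, %d splits): accuracy %.3f ",
                     "+/- %.3f (chance %.3f), macro F1 %.3f\n"),
              x$model, x$n_splits, x$mean_accuracy, x$se_accuracy,
              x$chance, x$mean_f1))
  invisible(x)
}

#' Shapley-guided iterative neuron elimination
#'
#' Trains the decoder, ranks feature cells by mean absolute Shapley
#' attribution (TreeSHAP for the boosted model; impurity importance for
#' the forest), removes the top-ranked cell(s), retrains, and repeats
#' until one feature remains. The whole procedure is replicated over
#' independent train/test splits.
#'
#' @param ds A `decoding_dataset`.
#' @param model `"xgb"` or `"rf"`.
#' @param repeats Number of replications (default 100).
#' @param eliminate_per_step Features removed per iteration (default 1).
#' @param test_frac Test fraction per replication.
#' @param seed Integer seed.
#' @param nrounds,num_trees,max_depth Model hyperparameters.
#' @return A `drop_curve`: per repeat, the elimination order (cell ids)
#'   and the accuracy/macro-F1 after each removal (position 1 = no removal).
#' @export
shapley_drop <- function(ds, model = c("xgb", "rf"), repeats = 100L,
                         eliminate_per_step = 1L, test_frac = 0.2,
                         seed = 1L, nrounds = 50L, num_trees = 300L,
                         max_depth = 6L) {
  stopifnot(inherits(ds, "decoding_dataset"))
  model <- match.arg(model)
  set.seed(as.integer(seed))
  p <- ncol(ds$X)
  orders <- list(); acc_cur <- list(); f1_cur <- list()
  for (r in seq_len(repeats)) {
    test <- stratified_split(ds$y, test_frac)
    train <- setdiff(seq_along(ds$y), test)
    feats <- colnames(ds$X)
    order_r <- character(0)
    acc_r <- numeric(0); f1_r <- numeric(0)
    repeat {
      Xtr <- ds$X[train, feats, drop = FALSE]
      fit <- fit_clf(Xtr, ds$y[train], model, nrounds, num_trees, max_depth)
      m <- class_metrics(ds$y[test],
                         predict_clf(fit, ds$X[test, feats, drop = FALSE]))
      acc_r <- c(acc_r, m$accuracy)
      f1_r <- c(f1_r, mean(m$per_class$f1))
      if (length(feats) <= 1) break
      imp <- feature_importance(fit, Xtr)
      # ties broken by cell index for determinism
      ord <- order(-imp, seq_along(imp))
      drop_n <- min(eliminate_per_step, length(feats) - 1L)
      dropped <- feats[ord[seq_len(drop_n)]]
      order_r <- c(order_r, dropped)
      feats <- setdiff(feats, dropped)
    }
    orders[[r]] <- as.integer(sub("^c", "", order_r))
    acc_cur[[r]] <- acc_r
    f1_cur[[r]] <- f1_r
  }
  structure(list(model = model, repeats = repeats,
                 elimination_order = orders,
                 accuracy = acc_cur, f1_macro = f1_cur,
                 chance = 1 / nlevels(ds$y),
                 cells = ds$cells),
            class = "drop_curve")
}

#' Probability that the cell dropped at each rank is a positive responder
#'
#' For each target, builds the binary sequence "was the cell eliminated at
#' rank r a PosR of this target", and averages over targets and
#' replications.
#'
#' @param curve A `drop_curve`.
#' @param table A `responder_table`.
#' @return A data.frame with `rank` and `l_posr` in `[0, 1]`.
#' @export
posr_drop_probability <- function(curve, table) {
  stopifnot(inherits(curve, "drop_curve"), inherits(table, "responder_table"))
  tcs <- unique(table$tc)
  max_rank <- max(lengths(curve$elimination_order))
  acc <- matrix(0, length(tcs), max_rank)
  cnt <- matrix(0, length(tcs), max_rank)
  for (r in seq_along(curve$elimination_order)) {
    ord <- curve$elimination_order[[r]]
    for (i in seq_along(tcs)) {
      posr <- table$cell[table$tc == tcs[i] & table$class == "PosR"]
      hits <- as.numeric(ord %in% posr)
      acc[i, seq_along(ord)] <- acc[i, seq_along(ord)] + hits
      cnt[i, seq_along(ord)] <- cnt[i, seq_along(ord)] + 1
    }
  }
  l <- colMeans(acc / pmax(cnt, 1))
  data.frame(rank = seq_len(max_rank), l_posr = l)
}

# Gaussian-kernel smoothing with sd = `sigma` grid steps
gauss_smooth <- function(x, sigma = 1) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- stats::dnorm(seq_len(n) - i, sd = sigma)
    ok <- !is.na(x)
    out[i] <- sum(w[ok] * x[ok]) / sum(w[ok])
  }
  out
}

#' Spatial exclusion-zone analysis of decoding performance
#'
#' For each target and each radius r, feature cells within r of that
#' target's soma are removed, the decoder is retrained, and the target's
#' F1-score recorded. Reports the mean F1 versus radius, the exclusion
#' probability profile P_ex(r), and the critical radius at which the
#' (Gaussian-smoothed, sd = 1 grid step) F1 decrease first exceeds three
#' standard deviations below the mean rate of change.
#'
#' @param ds A `decoding_dataset`.
#' @param radius_grid Radii in micrometres.
#' @param model,n_splits,test_frac,seed,nrounds,num_trees,max_depth As in
#'   [train_eval()].
#' @return A list: `f1_by_radius` (targets x radii), `mean_f1`, `p_ex`,
#'   `critical_radius`.
#' @export
radius_exclusion <- function(ds, radius_grid = seq(0, 250, by = 25),
                             model = c("xgb", "rf"), n_splits = 10L,
                             test_frac = 0.2, seed = 1L, nrounds = 50L,
                             num_trees = 300L, max_depth = 6L) {
  stopifnot(inherits(ds, "decoding_dataset"))
  model <- match.arg(model)
  tcs <- as.integer(levels(ds$y))
  f1 <- matrix(NA_real_, length(tcs), length(radius_grid),
               dimnames = list(tcs, radius_grid))
  n_excl <- matrix(0L, length(tcs), length(radius_grid))
  for (i in seq_along(tcs)) {
    d <- sqrt((ds$positions[ds$cells, 1] - ds$positions[tcs[i], 1])^2 +
                (ds$positions[ds$cells, 2] - ds$positions[tcs[i], 2])^2)
    for (j in seq_along(radius_grid)) {
      keep <- which(d > radius_grid[j])
      n_excl[i, j] <- length(ds$cells) - length(keep)
      if (length(keep) == 0) { f1[i, j] <- 0; next }
      # seed depends on the radius value, not its grid position, so equal
      # radii reproduce identical splits (r = 0 recovers the baseline F1)
      set.seed(as.integer(seed) + 7919L * i +
                 as.integer(round(radius_grid[j] * 10)) %% 7919L)
      accs <- numeric(n_splits)
      for (s in seq_len(n_splits)) {
        test <- stratified_split(ds$y, test_frac)
        train <- setdiff(seq_along(ds$y), test)
        fit <- fit_clf(ds$X[train, keep, drop = FALSE], ds$y[train], model,
                       nrounds, num_trees, max_depth)
        m <- class_metrics(ds$y[test],
                           predict_clf(fit, ds$X[test, keep, drop = FALSE]))
        accs[s] <- m$per_class$f1[m$per_class$class == as.character(tcs[i])]
      }
      f1[i, j] <- mean(accs)
    }
  }
  mean_f1 <- colMeans(f1)
  sm <- gauss_smooth(mean_f1, sigma = 1)
  dch <- diff(sm)
  crit <- NA_real_
  if (length(dch) > 2) {
    thr <- mean(dch) - 3 * stats::sd(dch)
    hit <- which(dch < thr)
    if (length(hit) > 0) crit <- radius_grid[hit[1] + 1]
  }
  dn <- colSums(n_excl)
  newly <- diff(c(0, dn))
  list(radius_grid = radius_grid, f1_by_radius = f1, mean_f1 = mean_f1,
       smoothed_f1 = sm, p_ex = newly / max(sum(newly), 1),
       n_excluded = dn, critical_radius = crit)
}

#' Temporal profile of decoding accuracy
#'
#' Slides the (unfiltered) feature window in steps of one frame across the
#' peri-stimulus interval and decodes at each offset. Offset 0 is the
#' first window fully overlapping the stimulation.
#'
#' @param rec A [recording()].
#' @param window_frames Window length, 1 or 6 frames.
#' @param offsets Vector of window offsets in frames relative to onset.
#' @param model,n_splits,seed,nrounds,num_trees,max_depth As in
#'   [train_eval()].
#' @return A data.frame: `offset`, `accuracy`, `se`, `chance`.
#' @export
temporal_profile <- function(rec, window_frames = 1L,
                             offsets = seq(-9L, 12L, by = 1L),
                             model = c("xgb", "rf"), n_splits = 10L,
                             seed = 1L, nrounds = 50L, num_trees = 300L,
                             max_depth = 6L) {
  model <- match.arg(model)
  out <- lapply(offsets, function(off) {
    ds <- try(build_dataset(rec, window_frames = window_frames,
                            offset_frames = off, filtered = FALSE),
              silent = TRUE)
    if (inherits(ds, "try-error"))
      return(data.frame(offset = off, accuracy = NA, se = NA, chance = NA))
    r <- train_eval(ds, model = model, n_splits = n_splits,
                    seed = seed + off, nrounds = nrounds,
                    num_trees = num_trees, max_depth = max_depth)
    data.frame(offset = off, accuracy = r$mean_accuracy, se = r$se_accuracy,
               chance = r$chance)
  })
  do.call(rbind, out)
}

#' Baseline pseudo-trial dataset from inter-trial activity
#'
#' Segments the inter-trial (spontaneous) activity into non-overlapping
#' windows, keeps those in which exactly one of the targets spiked
#' (labelled by that target), excludes windows within `margin_windows`
#' windows of any stimulation, and downsamples classes to match the class
#' histogram of a reference stimulation dataset.
#'
#' @param rec A [recording()].
#' @param match_to Optional `decoding_dataset` whose class counts are
#'   matched by downsampling.
#' @param window_frames Window length (default 6).
#' @param margin_windows Peri-stimulus exclusion margin in windows
#'   (default 1).
#' @param seed Seed for the downsampling.
#' @return A `decoding_dataset` of pseudo-trials.
#' @export
baseline_pseudotrials <- function(rec, match_to = NULL, window_frames = 6L,
                                  margin_windows = 1L, seed = 1L) {
  stopifnot(inherits(rec, "recording"))
  w <- as.integer(window_frames)
  nf <- ncol(rec$spikes)
  starts <- seq(1L, nf - w + 1L, by = w)
  # exclude windows overlapping any stimulation +/- margin
  if (!is.null(rec$trials) && nrow(rec$trials) > 0) {
    bad_lo <- rec$trials$onset_frame - (margin_windows + 1L) * w + 1L
    bad_hi <- rec$trials$onset_frame + (margin_windows + 1L) * w + w - 1L
    excl <- vapply(starts, function(s) any(s + w - 1L >= bad_lo &
                                             s <= bad_hi), logical(1))
    starts <- starts[!excl]
  }
  if (length(starts) == 0) stop("no inter-trial windows available")
  tc_counts <- vapply(starts, function(s)
    rowSums(rec$spikes[rec$tc, s:(s + w - 1L), drop = FALSE]), numeric(length(rec$tc)))
  if (length(rec$tc) == 1) tc_counts <- matrix(tc_counts, nrow = 1)
  one <- colSums(tc_counts > 0) == 1
  starts <- starts[one]
  lab <- rec$tc[apply(tc_counts[, one, drop = FALSE] > 0, 2, which)]
  if (length(unique(lab)) < 2)
    stop("fewer than 2 target classes among pseudo-trials")
  cells <- setdiff(seq_len(nrow(rec$spikes)), rec$tc)
  X <- t(vapply(starts, function(s)
    rowSums(rec$spikes[cells, s:(s + w - 1L), drop = FALSE]),
    numeric(length(cells))))
  colnames(X) <- paste0("c", cells)
  y <- factor(lab)
  if (!is.null(match_to)) {
    set.seed(as.integer(seed))
    want <- table(as.character(match_to$y))
    keep <- integer(0)
    for (cl in names(want)) {
      idx <- which(as.character(y) == cl)
      if (length(idx) == 0) next
      keep <- c(keep, sample(idx, min(length(idx), want[[cl]])))
    }
    keep <- sort(keep)
    X <- X[keep, , drop = FALSE]
    y <- droplevels(y[keep])
    starts <- starts[keep]
  }
  structure(list(X = X, y = y, cells = cells, positions = rec$positions,
                 tc = rec$tc, window_frames = w, offset_frames = NA_integer_,
                 filtered = FALSE,
                 trials = data.frame(tc = as.integer(as.character(y)),
                                     onset_frame = starts)),
            class = "decoding_dataset")
}

#' Decoding accuracy split by baseline-activity regime
#'
#' Partitions trials by the population baseline count (6-frame window
#' ending 264 ms before onset, summed over non-target cells) at each
#' threshold of `theta_grid`, decodes within each partition, and reports
#' the accuracy difference.
#'
#' @param rec A [recording()].
#' @param theta_grid Thresholds on the per-trial population baseline
#'   count; default the 25/50/75% quantiles of its distribution.
#' @param model,n_splits,seed,nrounds,num_trees,max_depth As in
#'   [train_eval()].
#' @return A data.frame per theta: `acc_low`, `acc_high`, `diff`, sizes.
#' @export
regime_split_decoding <- function(rec, theta_grid = NULL,
                                  model = c("xgb", "rf"), n_splits = 10L,
                                  seed = 1L, nrounds = 50L,
                                  num_trees = 300L, max_depth = 6L) {
  stopifnot(inherits(rec, "recording"))
  model <- match.arg(model)
  counts <- extract_trial_counts(rec)
  non_tc <- setdiff(seq_len(nrow(rec$spikes)), rec$tc)
  pop_base <- colSums(counts$base[non_tc, , drop = FALSE])
  if (is.null(theta_grid))
    theta_grid <- unname(stats::quantile(pop_base, c(0.25, 0.5, 0.75)))
  ds_all <- build_dataset(rec, filtered = FALSE)
  # align trials of the dataset with the windowed trials
  key_ds <- paste(ds_all$trials$tc, ds_all$trials$onset_frame)
  key_tc <- paste(counts$trials$tc, counts$trials$onset_frame)
  pb <- pop_base[match(key_ds, key_tc)]
  run <- function(sel) {
    y <- droplevels(ds_all$y[sel])
    if (nlevels(y) < 2 || min(table(y)) < 4) return(c(NA, NA))
    sub <- structure(list(X = ds_all$X[sel, , drop = FALSE], y = y,
                          cells = ds_all$cells, positions = ds_all$positions,
                          tc = ds_all$tc, window_frames = ds_all$window_frames,
                          offset_frames = 0L, filtered = FALSE,
                          trials = ds_all$trials[sel, , drop = FALSE]),
                     class = "decoding_dataset")
    r <- train_eval(sub, model = model, n_splits = n_splits, seed = seed,
                    nrounds = nrounds, num_trees = num_trees,
                    max_depth = max_depth)
    c(r$mean_accuracy, r$chance)
  }
  out <- lapply(theta_grid, function(th) {
    lo <- which(pb <= th); hi <- which(pb > th)
    a_lo <- run(lo); a_hi <- run(hi)
    data.frame(theta = th, acc_low = a_lo[1], acc_high = a_hi[1],
               diff = a_lo[1] - a_hi[1], n_low = length(lo),
               n_high = length(hi), chance = a_lo[2])
  })
  do.call(rbind, out)
}
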