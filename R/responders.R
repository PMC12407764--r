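#' Extract trial-windowed spike counts
#'
#' For every trial with onset frame f, three 6-frame (132 ms) windows are
#' counted per cell: the response window `[f, f+5]` (stimulus duration plus
#' one frame), the baseline window `[f-12, f-7]` (starting 264 ms before
#' onset) and a pre-baseline window `[f-18, f-13]` lagging the baseline by
#' a further 132 ms. Trials too close to the recording start are dropped
#' with a warning.
#'
#' @param rec A [recording()] with a trial table.
#' @param window_frames Window length in frames (default 6).
#' @return A `trial_counts` object: matrices `resp`, `base`, `base_prime`
#'   (cells x trials), the trial table, target ids, a removal mask (see
#'   [remove_outlier_trials()]) and a reference to the recording.
#' @export
extract_trial_counts <- function(rec, window_frames = 6L) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(rec$trials) || nrow(rec$trials) == 0)
    stop("recording has no trials")
  w <- as.integer(window_frames)
  margin <- 3L * w  # base_prime starts 3 windows before onset
  trials <- rec$trials
  ok <- trials$onset_frame > margin &
    trials$onset_frame + w - 1L <= ncol(rec$spikes)
  if (any(!ok)) {
    warning(sprintf("%d trial(s) dropped: onset too close to recording edge",
                    sum(!ok)))
    trials <- trials[ok, , drop = FALSE]
  }
  if (nrow(trials) == 0) stop("no usable trials")

  win_count <- function(start_off) {
    out <- matrix(0L, nrow(rec$spikes), nrow(trials))
    for (i in seq_len(nrow(trials))) {
      f0 <- trials$onset_frame[i] + start_off
      out[, i] <- rowSums(rec$spikes[, f0:(f0 + w - 1L), drop = FALSE])
    }
    out
  }
  structure(list(
    resp = win_count(0L), base = win_count(-2L * w),
    base_prime = win_count(-3L * w),
    trials = trials, tc = rec$tc, window_frames = w,
    frame_ms = rec$frame_ms, positions = rec$positions,
    removed = matrix(FALSE, nrow(rec$spikes), nrow(trials)),
    rec = rec
  ), class = "trial_counts")
}

#' Remove outlier trials per cell
#'
#' Deconvolution artefacts can produce implausibly large counts; per cell,
#' trials whose response or baseline count exceeds the cell's mean by more
#' than 10 standard deviations are masked out of all downstream statistics.
#' Mean and SD are computed leaving the candidate trial out, so a single
#' gross artefact cannot inflate its own threshold; the SD is floored at
#' one spike so that near-constant counts are never flagged.
#'
#' @param counts A `trial_counts` object.
#' @param n_sd Threshold in standard deviations (default 10).
#' @return The `trial_counts` with its `removed` mask updated; the fraction
#'   removed is stored in `attr(, "fraction_removed")`.
#' @export
remove_outlier_trials <- function(counts, n_sd = 10) {
  stopifnot(inherits(counts, "trial_counts"))
  flag <- function(m) {
    n <- ncol(m)
    if (n < 3) return(matrix(FALSE, nrow(m), n))
    s1 <- rowSums(m)
    s2 <- rowSums(m^2)
    loo_mean <- (s1 - m) / (n - 1)
    loo_var <- pmax((s2 - m^2) - (n - 1) * loo_mean^2, 0) / (n - 2)
    m > loo_mean + n_sd * pmax(sqrt(loo_var), 1)
  }
  rem <- flag(counts$resp) | flag(counts$base)
  counts$removed <- counts$removed | rem
  attr(counts, "fraction_removed") <- mean(rem)
  counts
}

#' Filter unresponsive stimulation targets
#'
#' A target is retained only if at least `min_frac` of its trials evoke a
#' response count above the `pctl` percentile of its own baseline counts.
#'
#' @param counts A `trial_counts` object.
#' @param min_frac Minimum fraction of responsive trials (default 0.2).
#' @param pctl Baseline percentile defining a response (default 0.91).
#' @param min_trials Targets with fewer trials are flagged unreliable.
#' @return Integer vector of retained target cell ids; excluded and
#'   unreliable targets are reported in attributes.
#' @export
filter_targets <- function(counts, min_frac = 0.2, pctl = 0.91,
                           min_trials = 10L) {
  stopifnot(inherits(counts, "trial_counts"))
  keep <- logical(length(counts$tc))
  unreliable <- logical(length(counts$tc))
  for (i in seq_along(counts$tc)) {
    tc <- counts$tc[i]
    cols <- which(counts$trials$tc == tc)
    if (length(cols) < min_trials) { unreliable[i] <- TRUE; next }
    thr <- stats::quantile(counts$base[tc, cols], pctl, names = FALSE)
    keep[i] <- mean(counts$resp[tc, cols] > thr) >= min_frac
  }
  out <- counts$tc[keep]
  attr(out, "excluded") <- counts$tc[!keep & !unreliable]
  attr(out, "unreliable") <- counts$tc[unreliable]
  out
}

# Masked row means / sds over a cells x trials matrix restricted to `cols`.
row_stats <- function(m, removed, cols) {
  x <- m[, cols, drop = FALSE]
  x[removed[, cols, drop = FALSE]] <- NA_integer_
  n <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums(x^2, na.rm = TRUE) - n * mu^2
  s <- sqrt(pmax(ss, 0) / pmax(n - 1, 1))
  s[n < 2] <- NA_real_
  list(n = n, mean = mu, sd = s)
}

#' Classify positive, negative and non-significant responders
#'
#' Per (target, cell) pair, the mean response count is tested against the
#' mean baseline count across that target's trials, one-tailed in each
#' direction at level `alpha`. The default statistic is the mean-difference
#' z score `z = (mean_resp - mean_base) / sqrt((sd_base^2 + sd_resp^2)/n)`,
#' which is asymptotically standard normal under the null of exchangeable
#' windows and keeps the empirical type-I rate at its nominal level.
#' `method = "welch"` is the same statistic referred to t quantiles with
#' Welch-Satterthwaite degrees of freedom; `method = "z_sem"` normalises by
#' `sd_base / sqrt(n)` alone (anticonservative; provided for comparability
#' with pipelines that treat the baseline moments as population values).
#'
#' Cells with zero baseline variability are flagged degenerate and
#' classified NonR. Target cells themselves are excluded. Classes are
#' mutually exclusive and exhaustive: PosR above the upper alpha quantile,
#' NegR below the lower, NonR otherwise.
#'
#' @param counts A `trial_counts` object.
#' @param alpha One-tailed significance level (default 0.025).
#' @param method `"z"` (default), `"welch"` or `"z_sem"`.
#' @param targets Optional subset of target cells to test (default all).
#' @return A `responder_table` data.frame: one row per (tc, cell) pair with
#'   the statistic, one-sided p-values, class and summary statistics.
#' @export
classify_responders <- function(counts, alpha = 0.025,
                                method = c("z", "welch", "z_sem"),
                                targets = NULL) {
  stopifnot(inherits(counts, "trial_counts"), alpha > 0, alpha < 0.5)
  method <- match.arg(method)
  if (is.null(targets)) targets <- counts$tc
  n_cells <- nrow(counts$resp)
  cells <- setdiff(seq_len(n_cells), counts$tc)
  out <- vector("list", length(targets))

  for (k in seq_along(targets)) {
    tc <- targets[k]
    cols <- which(counts$trials$tc == tc)
    if (length(cols) < 2) stop("fewer than 2 trials for a target")
    b <- row_stats(counts$base, counts$removed, cols)
    r <- row_stats(counts$resp, counts$removed, cols)
    n <- pmin(b$n, r$n)
    degen <- !is.na(b$sd) & b$sd == 0
    stat <- rep(NA_real_, n_cells)
    p_up <- rep(NA_real_, n_cells)
    p_lo <- rep(NA_real_, n_cells)
    valid <- !degen & n >= 2
    d <- r$mean - b$mean
    if (method == "z") {
      z <- d / sqrt((b$sd^2 + r$sd^2) / n)
      stat[valid] <- z[valid]
      p_up[valid] <- stats::pnorm(z[valid], lower.tail = FALSE)
      p_lo[valid] <- stats::pnorm(z[valid])
      up <- stats::qnorm(1 - alpha); lo <- stats::qnorm(alpha)
      cls <- ifelse(stat > up, "PosR", ifelse(stat < lo, "NegR", "NonR"))
    } else if (method == "z_sem") {
      z <- d / (b$sd / sqrt(n))
      stat[valid] <- z[valid]
      p_up[valid] <- stats::pnorm(z[valid], lower.tail = FALSE)
      p_lo[valid] <- stats::pnorm(z[valid])
      up <- stats::qnorm(1 - alpha); lo <- stats::qnorm(alpha)
      cls <- ifelse(stat > up, "PosR", ifelse(stat < lo, "NegR", "NonR"))
    } else {
      se2 <- b$sd^2 / n + r$sd^2 / n
      tt <- d / sqrt(se2)
      df <- se2^2 / ((b$sd^2 / n)^2 / (n - 1) + (r$sd^2 / n)^2 / (n - 1))
      valid <- valid & is.finite(tt) & is.finite(df)
      stat[valid] <- tt[valid]
      p_up[valid] <- stats::pt(tt[valid], df[valid], lower.tail = FALSE)
      p_lo[valid] <- stats::pt(tt[valid], df[valid])
      cls <- ifelse(p_up < alpha, "PosR", ifelse(p_lo < alpha, "NegR", "NonR"))
    }
    cls[!valid | is.na(cls)] <- "NonR"
    out[[k]] <- data.frame(
      tc = tc, cell = cells, n_trials = n[cells],
      base_mean = b$mean[cells], base_sd = b$sd[cells],
      resp_mean = r$mean[cells],
      stat = stat[cells], p = p_up[cells], p_lower = p_lo[cells],
      class = cls[cells], degenerate = (degen | n < 2)[cells]
    )
  }
  res <- do.call(rbind, out)
  structure(res, alpha = alpha, method = method, fdr = FALSE,
            class = c("responder_table", "data.frame"))
}

#' False-discovery-rate adjustment of responder classes
#'
#' Adjusts the one-sided p-values of a responder table across all (target,
#' cell) pairs and re-derives the classes at FDR level `q`. The default is
#' Benjamini-Hochberg; `method = "storey"` applies Storey's pi0 estimate
#' (lambda = 0.5) on top of the BH q-values, mirroring common practice in
#' genomics toolboxes.
#'
#' @param table A `responder_table`.
#' @param q FDR level (default 0.025).
#' @param method `"BH"` or `"storey"`.
#' @return The table with `q_pos`, `q_neg` columns and classes re-derived.
#' @export
fdr_adjust <- function(table, q = 0.025, method = c("BH", "storey")) {
  stopifnot(inherits(table, "responder_table"))
  method <- match.arg(method)
  adj <- function(p) {
    qq <- stats::p.adjust(p, method = "BH")
    if (method == "storey") {
      lam <- 0.5
      pi0 <- min(1, mean(p > lam, na.rm = TRUE) / (1 - lam))
      qq <- pmin(1, qq * pi0)
    }
    qq
  }
  table$q_pos <- adj(table$p)
  table$q_neg <- adj(table$p_lower)
  cls <- ifelse(!is.na(table$q_pos) & table$q_pos <= q, "PosR",
                ifelse(!is.na(table$q_neg) & table$q_neg <= q, "NegR", "NonR"))
  cls[table$degenerate] <- "NonR"
  table$class <- cls
  attr(table, "fdr") <- TRUE
  attr(table, "fdr_q") <- q
  table
}

#' Responder fractions as a function of the significance level
#'
#' Repeats the classification over a grid of one-tailed significance levels
#' and reports the fraction of tested pairs in each class, with and without
#' FDR correction at the same level.
#'
#' @param counts A `trial_counts` object.
#' @param alpha_grid Vector of significance levels.
#' @param method Test statistic, as in [classify_responders()].
#' @return A data.frame with one row per alpha.
#' @export
responders_vs_alpha <- function(counts, alpha_grid = c(0.005, 0.01, 0.025,
                                                       0.05, 0.1, 0.2, 0.4),
                                method = "z") {
  res <- lapply(alpha_grid, function(a) {
    tab <- classify_responders(counts, alpha = a, method = method)
    tabf <- fdr_adjust(tab, q = a)
    data.frame(alpha = a,
               frac_pos = mean(tab$class == "PosR"),
               frac_neg = mean(tab$class == "NegR"),
               frac_non = mean(tab$class == "NonR"),
               frac_pos_fdr = mean(tabf$class == "PosR"),
               frac_neg_fdr = mean(tabf$class == "NegR"))
  })
  do.call(rbind, res)
}

#' Power-law response-scaling fit
#'
#' Trials are binned by the integer spike count of the stimulated target in
#' the relevant window (default bins 1..7); the mean spike count of the
#' chosen responder class is computed per bin and the exponent h is the
#' least-squares slope of log(mean response) versus log(target count), with
#' a 95% confidence interval from the regression. `mode = "population"`
#' sums class counts per trial; `mode = "per_neuron"` averages them.
#' `phase = "base"` uses baseline windows for both target and responders
#' (ongoing-activity scaling); `phase = "stim"` uses response windows.
#'
#' @param counts A `trial_counts` object.
#' @param table Optional `responder_table` defining the class membership;
#'   when `NULL` all non-target cells are used.
#' @param mode `"population"` (default) or `"per_neuron"`.
#' @param phase `"stim"` (default) or `"base"`.
#' @param resp_class Responder class used (default `"PosR"`).
#' @param bins Integer target-count bins (default 1:7).
#' @param min_bin_n Minimum trials per occupied bin (default 3).
#' @return A `scaling_fit` with exponent `h`, intercept, `ci`, `r2` and the
#'   bin table.
#' @export
scaling_fit <- function(counts, table = NULL, mode = c("population",
                                                       "per_neuron"),
                        phase = c("stim", "base"), resp_class = "PosR",
                        bins = 1:7, min_bin_n = 3L) {
  stopifnot(inherits(counts, "trial_counts"))
  mode <- match.arg(mode)
  phase <- match.arg(phase)
  mat <- if (phase == "stim") counts$resp else counts$base
  n_cells <- nrow(mat)

  tc_count <- numeric(nrow(counts$trials))
  response <- numeric(nrow(counts$trials))
  for (i in seq_len(nrow(counts$trials))) {
    tc <- counts$trials$tc[i]
    tc_count[i] <- mat[tc, i]
    if (is.null(table)) {
      cells <- setdiff(seq_len(n_cells), counts$tc)
    } else {
      cells <- table$cell[table$tc == tc & table$class == resp_class]
    }
    if (length(cells) == 0) { response[i] <- NA; next }
    v <- mat[cells, i]
    response[i] <- if (mode == "population") sum(v) else mean(v)
  }
  keep <- !is.na(response) & tc_count %in% bins
  if (!any(keep)) stop(sprintf("no trials with class %s cells in the bin range",
                               resp_class))
  bm <- tapply(response[keep], factor(tc_count[keep], levels = bins), mean)
  bn <- tapply(response[keep], factor(tc_count[keep], levels = bins), length)
  bin_tab <- data.frame(tc_count = bins, mean_response = as.numeric(bm),
                        n_trials = ifelse(is.na(bn), 0L, as.integer(bn)))
  use <- !is.na(bin_tab$mean_response) & bin_tab$mean_response > 0 &
    bin_tab$n_trials >= min_bin_n
  if (sum(use) < 3) stop("fewer than 3 occupied bins; cannot fit the exponent")
  fit <- stats::lm(log(mean_response) ~ log(tc_count), data = bin_tab[use, ])
  ci <- stats::confint(fit)[2, ]
  structure(list(h = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 ci = unname(ci), r2 = summary(fit)$r.squared,
                 mode = mode, phase = phase, resp_class = resp_class,
                 bins = bin_tab, bins_used = bin_tab$tc_count[use]),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("scaling_fit (%s, %s, %s): h = %.3f [%.3f, %.3f], R2 = %.3f\n",
              x$resp_class, x$mode, x$phase, x$h, x$ci[1], x$ci[2], x$r2))
  invisible(x)
}

#' Window auto- and cross-correlations of trial counts
#'
#' Per cell, Pearson correlations across trials between the pre-baseline and
#' baseline windows (ongoing autocorrelation at 132-ms lag) and between the
#' baseline and response windows, averaged per responder class; plus
#' cross-correlations between the target's window count and each cell's
#' same-phase count.
#'
#' @param counts A `trial_counts` object.
#' @param table A `responder_table` assigning classes.
#' @return A list of data.frames `auto` (per class: base'-base, base-resp)
#'   and `cross` (per class: TC-base vs cell-base, TC-resp vs cell-resp).
#' @export
correlations <- function(counts, table) {
  stopifnot(inherits(counts, "trial_counts"),
            inherits(table, "responder_table"))
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  res_auto <- list(); res_cross <- list()
  for (tc in unique(table$tc)) {
    cols <- which(counts$trials$tc == tc)
    sub <- table[table$tc == tc, ]
    for (cl in c("TC", "PosR", "NegR", "NonR")) {
      cells <- if (cl == "TC") tc else sub$cell[sub$class == cl]
      if (length(cells) == 0) next
      r_bb <- vapply(cells, function(cc)
        safe_cor(counts$base_prime[cc, cols], counts$base[cc, cols]), numeric(1))
      r_br <- vapply(cells, function(cc)
        safe_cor(counts$base[cc, cols], counts$resp[cc, cols]), numeric(1))
      res_auto[[length(res_auto) + 1]] <- data.frame(
        tc = tc, class = cl, r_base_prime_base = mean(r_bb, na.rm = TRUE),
        r_base_resp = mean(r_br, na.rm = TRUE), n_cells = length(cells))
      if (cl != "TC") {
        x_b <- counts$base[tc, cols]; x_r <- counts$resp[tc, cols]
        c_b <- vapply(cells, function(cc)
          safe_cor(x_b, counts$base[cc, cols]), numeric(1))
        c_r <- vapply(cells, function(cc)
          safe_cor(x_r, counts$resp[cc, cols]), numeric(1))
        res_cross[[length(res_cross) + 1]] <- data.frame(
          tc = tc, class = cl, r_tc_base = mean(c_b, na.rm = TRUE),
          r_tc_resp = mean(c_r, na.rm = TRUE), n_cells = length(cells))
      }
    }
  }
  list(auto = do.call(rbind, res_auto), cross = do.call(rbind, res_cross))
}

#' Mean-matched Fano factors
#'
#' The Fano factor (variance/mean of spike counts across trials) is
#' computed per cell for the baseline window and for a stimulus window
#' whose length (1..9 frames from onset) is chosen to minimise the
#' normalised difference between mean baseline and mean stimulus counts,
#' correcting for firing-rate changes. Cells whose best window still
#' mismatches by more than `max_mismatch` are excluded. The raw
#' (unmatched, 6-frame) stimulus Fano factor is also reported.
#'
#' @param counts A `trial_counts` object (its recording is reused to
#'   recount stimulus windows of varying length).
#' @param matched Apply mean matching (default TRUE).
#' @param max_mismatch Maximum tolerated normalised mean difference
#'   (default 0.2).
#' @return A `fano_result` data.frame per (tc, cell).
#' @export
fano <- function(counts, matched = TRUE, max_mismatch = 0.2) {
  stopifnot(inherits(counts, "trial_counts"))
  rec <- counts$rec
  w <- counts$window_frames
  ff <- function(x) {
    m <- mean(x)
    if (m == 0) return(NA_real_)
    stats::var(x) / m
  }
  out <- list()
  for (tc in unique(counts$trials$tc)) {
    cols <- which(counts$trials$tc == tc)
    onsets <- counts$trials$onset_frame[cols]
    for (cell in seq_len(nrow(counts$resp))) {
      bc <- counts$base[cell, cols]
      rc6 <- counts$resp[cell, cols]
      mb <- mean(bc)
      win <- w; mism <- NA_real_; rc <- rc6
      if (matched && mb > 0) {
        cs <- c(0L, cumsum(rec$spikes[cell, ]))
        best <- Inf
        for (L in 1:9) {
          cnt <- cs[onsets + L] - cs[onsets]
          # normalise stimulus count to the 6-frame baseline footing
          d <- abs(mean(cnt) * (w / L) - mb) / mb
          if (d < best) { best <- d; win <- L; rc <- cnt }
        }
        mism <- best
      }
      out[[length(out) + 1]] <- data.frame(
        tc = tc, cell = cell, ff_base = ff(bc), ff_resp_raw = ff(rc6),
        ff_resp_matched = ff(rc), win_len = win, mismatch = mism,
        excluded = is.na(mism) || (matched && mism > max_mismatch) ||
          mean(bc) == 0 || mean(rc) == 0)
    }
  }
  structure(do.call(rbind, out), matched = matched,
            class = c("fano_result", "data.frame"))
}

#' Split trials into control subsets
#'
#' Returns logical trial masks for the standard controls: target-count
#' split (low = response count between the 91st percentile of the target's
#' baseline distribution and twice that value; high = above twice), the
#' population-baseline split (below the 25th / above the 75th percentile of
#' the per-trial population baseline count) and the early/late timing
#' windows (two consecutive 6-frame windows around the peak of the mean
#' target response).
#'
#' Percentiles use the linear-interpolation definition (type 7); ties at a
#' boundary fall into the lower subset.
#'
#' @param counts A `trial_counts` object.
#' @return A list with masks `tc_low`, `tc_high`, `base_low`, `base_high`
#'   (per trial) and window offsets `early`, `late` (frames from onset).
#' @export
split_trials <- function(counts) {
  stopifnot(inherits(counts, "trial_counts"))
  n_tr <- nrow(counts$trials)
  tc_low <- tc_high <- logical(n_tr)
  for (tc in unique(counts$trials$tc)) {
    cols <- which(counts$trials$tc == tc)
    thr <- stats::quantile(counts$base[tc, cols], 0.91, names = FALSE)
    rc <- counts$resp[tc, cols]
    tc_low[cols] <- rc > thr & rc <= 2 * thr
    tc_high[cols] <- rc > 2 * thr
  }
  non_tc <- setdiff(seq_len(nrow(counts$base)), counts$tc)
  pop_base <- colSums(counts$base[non_tc, , drop = FALSE])
  q25 <- stats::quantile(pop_base, 0.25, names = FALSE)
  q75 <- stats::quantile(pop_base, 0.75, names = FALSE)
  base_low <- pop_base <= q25
  base_high <- pop_base > q75

  # peak of the mean target response, in frames from onset
  w <- counts$window_frames
  rec <- counts$rec
  prof <- numeric(w)
  for (i in seq_len(n_tr)) {
    f <- counts$trials$onset_frame[i]
    prof <- prof + rec$spikes[counts$trials$tc[i], f:(f + w - 1L)]
  }
  peak <- which.max(prof) - 1L
  early <- c(peak - w + 1L, peak)
  late <- c(peak + 1L, peak + w)

  list(tc_low = tc_low, tc_high = tc_high,
       base_low = base_low, base_high = base_high,
       early = early, late = late, peak_offset = peak)
}

#' Baseline-regime response scaling
#'
#' Non-target cells are binned by their mean baseline count; the mean
#' response per bin is regressed (log-log) separately below and above each
#' candidate regime threshold. A LOW baseline regime (threshold ~0.3
#' spikes/132 ms) shows responses nearly independent of baseline (slope
#' ~0), while the HIGH regime couples response to baseline (slope towards
#' 1).
#'
#' @param counts A `trial_counts` object.
#' @param theta_grid Regime thresholds in spikes per window (default
#'   includes 0.3).
#' @param n_bins Number of baseline bins for the summary curve.
#' @return A list: `cells` (per-cell base/resp means and LOW/HIGH label at
#'   the first theta), `curve` (binned means) and `slopes` (per theta:
#'   log-log slope below and above).
#' @export
baseline_regime_scaling <- function(counts, theta_grid = c(0.1, 0.2, 0.3,
                                                           0.5, 1),
                                    n_bins = 12L) {
  stopifnot(inherits(counts, "trial_counts"))
  non_tc <- setdiff(seq_len(nrow(counts$base)), counts$tc)
  mb <- rowMeans(counts$base[non_tc, , drop = FALSE])
  mr <- rowMeans(counts$resp[non_tc, , drop = FALSE])
  ok <- mb > 0 & mr > 0
  br <- range(mb[ok])
  brks <- exp(seq(log(br[1]), log(br[2] + 1e-9), length.out = n_bins + 1))
  bin <- cut(mb[ok], brks, include.lowest = TRUE)
  curve <- data.frame(base_mean = as.numeric(tapply(mb[ok], bin, mean)),
                      resp_mean = as.numeric(tapply(mr[ok], bin, mean)),
                      n_cells = as.integer(table(bin)))
  slopes <- lapply(theta_grid, function(th) {
    lo <- ok & mb < th
    hi <- ok & mb >= th
    sl <- function(sel) {
      if (sum(sel) < 3) return(NA_real_)
      unname(stats::coef(stats::lm(log(mr[sel]) ~ log(mb[sel])))[2])
    }
    data.frame(theta = th, slope_low = sl(lo), slope_high = sl(hi),
               n_low = sum(lo), n_high = sum(hi))
  })
  cells <- data.frame(cell = non_tc, base_mean = mb, resp_mean = mr,
                      regime = ifelse(mb < theta_grid[1], "LOW", "HIGH"))
  list(cells = cells, curve = curve, slopes = do.call(rbind, slopes))
}

#' Fraction of positive responders versus distance from the target
#'
#' Per radial annulus around each target, the fraction of tested cells
#' classified PosR for that target, averaged over targets. Empty annuli
#' yield NA and are flagged.
#'
#' @param table A `responder_table`.
#' @param positions Cells x 2 matrix of positions in micrometres.
#' @param radii Annulus edges in micrometres.
#' @return A data.frame with columns `r_lo`, `r_hi`, `r_mid`, `frac_pos`,
#'   `n_cells`.
#' @export
responder_distance_profile <- function(table, positions,
                                       radii = seq(0, 300, by = 25)) {
  stopifnot(inherits(table, "responder_table"), length(radii) >= 2)
  tcs <- unique(table$tc)
  acc_pos <- matrix(0, length(tcs), length(radii) - 1)
  acc_n <- matrix(0, length(tcs), length(radii) - 1)
  for (i in seq_along(tcs)) {
    sub <- table[table$tc == tcs[i], ]
    d <- sqrt((positions[sub$cell, 1] - positions[tcs[i], 1])^2 +
                (positions[sub$cell, 2] - positions[tcs[i], 2])^2)
    for (j in seq_len(length(radii) - 1)) {
      sel <- d > radii[j] & d <= radii[j + 1]
      acc_n[i, j] <- sum(sel)
      acc_pos[i, j] <- sum(sub$class[sel] == "PosR")
    }
  }
  frac <- colSums(acc_pos) / pmax(colSums(acc_n), 1)
  frac[colSums(acc_n) == 0] <- NA_real_
  data.frame(r_lo = radii[-length(radii)], r_hi = radii[-1],
             r_mid = (radii[-1] + radii[-length(radii)]) / 2,
             frac_pos = frac, n_cells = colSums(acc_n))
}

#' Direct-connectivity composition of positive responders
#'
#' For a simulated recording, relates the responder classification to the
#' underlying synaptic structure: per target, the fraction of its direct
#' FoV out-neighbours classified PosR, and the fraction of its PosR set
#' receiving a direct connection; both averaged over targets.
#'
#' @param table A `responder_table` from a simulated recording.
#' @param net The `lattice_network` that generated it.
#' @param rec The [recording()] (provides the FoV unit ids).
#' @return A list: `frac_direct_posr` (direct targets classified PosR),
#'   `frac_posr_direct` (PosR with a direct connection), and the per-target
#'   table.
#' @export
posr_connectivity <- function(table, net, rec) {
  stopifnot(inherits(table, "responder_table"),
            inherits(net, "lattice_network"))
  fov <- rec$meta$fov_units
  if (is.null(fov)) fov <- net$fov_indices
  per_tc <- lapply(unique(table$tc), function(tc) {
    sub <- table[table$tc == tc, ]
    tc_global <- fov[tc]
    direct <- match(out_neighbors(net, tc_global), fov)
    direct <- direct[!is.na(direct)]
    direct <- intersect(direct, sub$cell)  # tested cells only
    posr <- sub$cell[sub$class == "PosR"]
    data.frame(tc = tc, n_direct_fov = length(direct), n_posr = length(posr),
               frac_direct_posr = if (length(direct)) mean(direct %in% posr)
                                  else NA_real_,
               frac_posr_direct = if (length(posr)) mean(posr %in% direct)
                                  else NA_real_)
  })
  per_tc <- do.call(rbind, per_tc)
  list(frac_direct_posr = mean(per_tc$frac_direct_posr, na.rm = TRUE),
       frac_posr_direct = mean(per_tc$frac_posr_direct, na.rm = TRUE),
       per_tc = per_tc)
}
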