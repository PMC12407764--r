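#' Ground truth for a synthetic recording
#'
#' Defines the planted structure of a synthetic spike-count recording:
#' which cells respond positively/negatively to each target, the
#' response-scaling exponent, per-responder effect sizes, the baseline
#' count model (negative-binomial marginal with a latent AR(1) rate
#' modulator) and the target spike-count distribution per stimulation.
#'
#' @param n_cells Number of cells.
#' @param n_tc Number of pseudo-targets (default 10).
#' @param frac_posr,frac_negr Fractions of non-target cells planted as
#'   positive/negative responders per target (defaults 0.10 / 0.02).
#' @param h_true Planted response-scaling exponent (default 0.3).
#' @param effect_size Mean response increment at a single target spike;
#'   per-responder effects are jittered by +/-25%.
#' @param base_mean Baseline mean spikes per cell per frame (default 0.05,
#'   a sparse rate typical of deconvolved two-photon data).
#' @param dispersion Count dispersion (Fano factor) of the
#'   negative-binomial baseline, >= 1; 1 gives Poisson counts.
#' @param ar_coef,ar_sd Per-frame AR(1) coefficient and stationary SD of
#'   the latent log-rate modulator; the defaults target a window-count
#'   autocorrelation of ~0.2 at a 132-ms lag. Set `ar_sd = 0` to disable.
#' @param shared_frac Fraction of modulator variance shared across cells
#'   (population-wide activity fluctuations), default 0.3.
#' @param tc_count_mean Mean extra spikes of a stimulated target per
#'   response window (counts are 1 + Poisson(mean - 1), capped at 9).
#' @param posr_radius_um Optional radius: planted PosR are placed within
#'   this distance of their target (default `NULL`, uniform).
#' @param seed Integer seed for the planted assignment.
#' @return A `fixture_ground_truth` list.
#' @export
fixture_ground_truth <- function(n_cells = 200L, n_tc = 10L,
                                 frac_posr = 0.10, frac_negr = 0.02,
                                 h_true = 0.3, effect_size = 3,
                                 base_mean = 0.05, dispersion = 1.5,
                                 ar_coef = 0.9, ar_sd = 1.3,
                                 shared_frac = 0.3, tc_count_mean = 2.5,
                                 posr_radius_um = NULL, seed = 1L) {
  stopifnot(n_cells > n_tc, h_true >= 0, dispersion >= 1, frac_posr >= 0,
            frac_negr >= 0, frac_posr + frac_negr <= 1)
  set.seed(as.integer(seed))
  tcs <- sort(sample.int(n_cells, n_tc))
  non_tc <- setdiff(seq_len(n_cells), tcs)
  posr <- list(); negr <- list(); effects <- list()
  for (k in seq_len(n_tc)) {
    np <- round(frac_posr * length(non_tc))
    nn <- round(frac_negr * length(non_tc))
    pick <- sample(non_tc, np + nn)
    posr[[k]] <- sort(pick[seq_len(np)])
    negr[[k]] <- sort(pick[np + seq_len(nn)])
    effects[[k]] <- stats::runif(np, 0.75, 1.25) * effect_size
  }
  structure(list(n_cells = as.integer(n_cells), tcs = tcs,
                 posr_ids = posr, negr_ids = negr,
                 effect_sizes = effects, h_true = h_true,
                 baseline_model = list(mean = base_mean,
                                       dispersion = dispersion,
                                       ar_coef = ar_coef, ar_sd = ar_sd,
                                       shared_frac = shared_frac),
                 tc_count_mean = tc_count_mean,
                 posr_radius_um = posr_radius_um, seed = as.integer(seed)),
            class = "fixture_ground_truth")
}

# latent AR(1) log-rate paths: cells x frames multiplicative modulator
ar1_modulator <- function(n_cells, n_frames, phi, s, shared_frac) {
  if (s <= 0) return(matrix(1, n_cells, n_frames))
  innov_sd <- s * sqrt(1 - phi^2)
  path <- function() stats::filter(stats::rnorm(n_frames, 0, innov_sd),
                                   phi, method = "recursive",
                                   init = stats::rnorm(1, 0, s))
  g <- as.numeric(path())
  a <- matrix(0, n_cells, n_frames)
  for (i in seq_len(n_cells))
    a[i, ] <- sqrt(1 - shared_frac) * as.numeric(path()) +
      sqrt(shared_frac) * g
  exp(a - s^2 / 2)  # unit-mean log-normal modulator
}

#' Generate a synthetic recording with planted ground truth
#'
#' Baseline counts are negative-binomial with a latent AR(1) rate
#' modulator (overdispersed, temporally autocorrelated, optionally with a
#' population-shared component). During each trial the stimulated target
#' emits `1 + Poisson(tc_count_mean - 1)` extra spikes in the 6-frame
#' response window; each planted positive responder receives extra Poisson
#' spikes with mean `effect * tc_count^h_true`, and each negative
#' responder loses Poisson spikes with the same scaling, floored at zero
#' counts.
#'
#' @param gt A [fixture_ground_truth()] (or arguments to build one, passed
#'   via `...`).
#' @param n_frames Number of frames; enlarged if the trials do not fit.
#' @param trials_per_tc Trials per target (default 100); 0 gives a
#'   spontaneous-only recording.
#' @param iti_frames Frames between consecutive onsets (default 45).
#' @param fov_um Field-of-view side length for the uniform cell positions.
#' @param seed Integer seed for the realisation.
#' @param ... Forwarded to [fixture_ground_truth()] when `gt` is `NULL`.
#' @return A [recording()]; the ground truth is attached as
#'   `rec$meta$ground_truth`.
#' @export
make_recording <- function(gt = NULL, n_frames = NULL, trials_per_tc = 100L,
                           iti_frames = 45L, fov_um = 456, seed = 1L, ...) {
  if (is.null(gt)) gt <- fixture_ground_truth(...)
  stopifnot(inherits(gt, "fixture_ground_truth"))
  bm <- gt$baseline_model
  n_cells <- gt$n_cells
  set.seed(as.integer(seed))
  n_tc <- length(gt$tcs)
  w <- 6L
  margin <- 19L
  n_trials <- n_tc * trials_per_tc
  onsets <- integer(0); order_tc <- integer(0)
  if (n_trials > 0) {
    order_tc <- unlist(lapply(seq_len(trials_per_tc),
                              function(b) sample(gt$tcs)))
    onsets <- margin + (seq_len(n_trials) - 1L) * (w + iti_frames)
    need <- max(onsets) + w + iti_frames
    if (is.null(n_frames) || n_frames < need) n_frames <- need
  } else if (is.null(n_frames)) n_frames <- 2000L

  # positions: targets spread on a grid, other cells uniform (or clustered
  # around their target when posr_radius_um is set)
  pos <- cbind(stats::runif(n_cells, 0, fov_um),
               stats::runif(n_cells, 0, fov_um))
  gp <- ceiling(sqrt(n_tc))
  tc_xy <- expand.grid(x = seq(fov_um / (gp + 1), fov_um * gp / (gp + 1),
                               length.out = gp),
                       y = seq(fov_um / (gp + 1), fov_um * gp / (gp + 1),
                               length.out = gp))[seq_len(n_tc), ]
  pos[gt$tcs, ] <- as.matrix(tc_xy)
  if (!is.null(gt$posr_radius_um)) {
    for (k in seq_len(n_tc)) for (cc in gt$posr_ids[[k]]) {
      th <- stats::runif(1, 0, 2 * pi)
      rr <- gt$posr_radius_um * sqrt(stats::runif(1))
      pos[cc, ] <- pmin(pmax(pos[gt$tcs[k], ] + rr * c(cos(th), sin(th)), 0),
                        fov_um)
    }
  }

  mod <- ar1_modulator(n_cells, n_frames, bm$ar_coef, bm$ar_sd,
                       bm$shared_frac)
  mu <- bm$mean * mod
  if (bm$dispersion > 1) {
    size <- mu / (bm$dispersion - 1)
    counts <- matrix(stats::rnbinom(n_cells * n_frames, size = size,
                                    mu = mu), n_cells, n_frames)
  } else {
    counts <- matrix(stats::rpois(n_cells * n_frames, mu), n_cells, n_frames)
  }

  spread <- function(total, f0) {  # distribute spikes over the window
    fr <- f0 + sample(0:(w - 1L), total, replace = TRUE)
    tabulate(fr - f0 + 1L, nbins = w)
  }
  for (i in seq_along(onsets)) {
    k <- match(order_tc[i], gt$tcs)
    f0 <- onsets[i]
    tc_cnt <- min(1L + stats::rpois(1, max(gt$tc_count_mean - 1, 0)), 9L)
    counts[order_tc[i], f0:(f0 + w - 1L)] <-
      counts[order_tc[i], f0:(f0 + w - 1L)] + spread(tc_cnt, f0)
    pr <- gt$posr_ids[[k]]
    if (length(pr) > 0) {
      extra <- stats::rpois(length(pr), gt$effect_sizes[[k]] * tc_cnt^gt$h_true)
      for (j in seq_along(pr)) if (extra[j] > 0)
        counts[pr[j], f0:(f0 + w - 1L)] <-
          counts[pr[j], f0:(f0 + w - 1L)] + spread(extra[j], f0)
    }
    nr <- gt$negr_ids[[k]]
    if (length(nr) > 0) {
      drop_n <- stats::rpois(length(nr), tc_cnt^gt$h_true)
      for (j in seq_along(nr)) if (drop_n[j] > 0) {
        seg <- counts[nr[j], f0:(f0 + w - 1L)]
        for (d in seq_len(drop_n[j])) {
          nz <- which(seg > 0)
          if (length(nz) == 0) break
          pick <- if (length(nz) == 1) nz else sample(nz, 1)
          seg[pick] <- seg[pick] - 1L
        }
        counts[nr[j], f0:(f0 + w - 1L)] <- seg
      }
    }
  }

  trials <- if (n_trials > 0)
    data.frame(tc = order_tc, onset_frame = onsets) else NULL
  recording(spikes = counts, positions = pos, tc = gt$tcs, trials = trials,
            frame_ms = 22, meta = list(ground_truth = gt,
                                       seed = as.integer(seed)))
}

#' Galton-Watson population trace with immigration
#'
#' Per step, each of the current individuals leaves Poisson(`m`) offspring
#' and Poisson(`immigration`) new immigrants arrive. At `m = 1` the
#' cluster-size distribution is heavy-tailed; well below 1 it decays
#' (near-)exponentially. Used as an analytically tractable fixture for the
#' avalanche pipeline.
#'
#' @param n_steps Number of steps.
#' @param m Offspring mean (branching parameter), >= 0.
#' @param immigration Immigration rate per step.
#' @param seed Integer seed.
#' @return Integer vector of population counts, with the per-step
#'   immigrant counts in `attr(, "immigrants")`.
#' @export
make_branching_trace <- function(n_steps, m = 1, immigration = 0.05,
                                 seed = 1L) {
  stopifnot(m >= 0, immigration >= 0, n_steps >= 1)
  set.seed(as.integer(seed))
  n <- integer(n_steps)
  imm <- integer(n_steps)
  cur <- 0L
  for (t in seq_len(n_steps)) {
    off <- if (cur > 0 && m > 0) sum(stats::rpois(cur, m)) else 0L
    imm[t] <- stats::rpois(1, immigration)
    cur <- as.integer(off + imm[t])
    n[t] <- cur
  }
  attr(n, "immigrants") <- imm
  n
}
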