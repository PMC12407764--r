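#' Select target cells inside the field of view
#'
#' Draws `n` distinct units from the central analysis block, optionally
#' enforcing a minimum pairwise distance so that stimulation targets do not
#' overlap.
#'
#' @param net A `lattice_network`.
#' @param n Number of target cells (default 10).
#' @param min_dist_um Minimum pairwise distance in micrometres (default 24,
#'   i.e. targets are not lattice neighbours).
#' @param seed Integer seed.
#' @return Integer vector of unit ids (1-based).
#' @export
select_tcs <- function(net, n = 10L, min_dist_um = 24, seed = 1L) {
  stopifnot(inherits(net, "lattice_network"), n >= 1)
  set.seed(as.integer(seed))
  pool <- sample(net$fov_indices)
  chosen <- integer(0)
  for (u in pool) {
    if (length(chosen) == 0) { chosen <- u; next }
    d <- sqrt(colSums((t(net$positions[chosen, , drop = FALSE]) -
                         net$positions[u, ])^2))
    if (min(d) >= min_dist_um) chosen <- c(chosen, u)
    if (length(chosen) == n) break
  }
  if (length(chosen) < n) stop("could not place that many targets in the FoV")
  sort(chosen)
}

#' Define a stimulation protocol
#'
#' Each trial stimulates one target cell for `stim_steps` steps (default 50
#' steps = 100 ms) followed by an inter-trial interval of `iti_steps`
#' (default 1000 steps = 2 s). Trials are ordered as a semi-random
#' interleave: every block of `length(tc_indices)` trials is a fresh
#' permutation of the targets, so stimulation windows never overlap and all
#' targets progress evenly.
#'
#' @param tc_indices Target unit ids, all inside the field of view.
#' @param stim_steps Stimulation duration in steps.
#' @param iti_steps Inter-trial interval in steps.
#' @param trials_per_tc Trials per target (default 100).
#' @param p_stim Per-step activation probability of the stimulated target;
#'   `NULL` means calibrate at run time (see [calibrate_stim()]).
#' @return A `stim_protocol` list.
#' @export
stim_protocol <- function(tc_indices, stim_steps = 50L, iti_steps = 1000L,
                          trials_per_tc = 100L, p_stim = NULL) {
  stopifnot(length(tc_indices) >= 1, !anyDuplicated(tc_indices),
            stim_steps >= 1, iti_steps >= 0, trials_per_tc >= 0)
  structure(list(tc_indices = as.integer(tc_indices),
                 stim_steps = as.integer(stim_steps),
                 iti_steps = as.integer(iti_steps),
                 trials_per_tc = as.integer(trials_per_tc),
                 p_stim = p_stim),
            class = "stim_protocol")
}

#' Calibrate the per-step stimulation probability of a target
#'
#' Bisection on `p_stim` so that the mean spike count of a stimulated
#' target within the 66-step (132-ms) response window matches `target`
#' spikes. Pilot runs use the full network dynamics at the calibrated
#' baseline drive, with a fixed seed per evaluation.
#'
#' @param net A calibrated `lattice_network` (with `p_trans` and `p_poiss`).
#' @param tc Target unit id used for the pilot (default: FoV centre).
#' @param target Target mean spikes per 132 ms during stimulation
#'   (default 2.5).
#' @param window_steps Measurement window from stimulus onset (default 66).
#' @param trials Pilot trials per evaluation.
#' @param tol Relative tolerance.
#' @param seed Integer seed.
#' @return The calibrated `p_stim` (numeric scalar).
#' @export
calibrate_stim <- function(net, tc = NULL, target = 2.5, window_steps = 66L,
                           trials = 40L, tol = 0.05, seed = 1L,
                           stim_steps = 50L, max_iter = 20L) {
  stopifnot(inherits(net, "lattice_network"))
  if (is.null(net$p_poiss)) stop("p_poiss not set; calibrate the drive first")
  if (is.null(tc)) tc <- net$fov_indices[ceiling(length(net$fov_indices) / 2)]
  gap <- 250L
  onsets <- gap + (seq_len(trials) - 1L) * (stim_steps + gap)
  n_steps <- max(onsets) + window_steps + gap
  stim <- rep(NA_integer_, n_steps)
  for (o in onsets) stim[o:(o + stim_steps - 1L)] <- tc

  measure <- function(p) {
    set.seed(as.integer(seed))
    r <- simulate_steps(net, n_steps, record = tc, stim = stim, p_stim = p)
    cnt <- vapply(onsets, function(o)
      sum(r$spikes$step >= o & r$spikes$step < o + window_steps), numeric(1))
    mean(cnt)
  }
  hi <- 1; lo <- 0
  if (measure(1) < target * (1 - tol))
    stop("target stimulation rate unreachable even at p_stim = 1")
  p <- 0.5
  for (i in seq_len(max_iter)) {
    p <- (lo + hi) / 2
    m <- measure(p)
    if (abs(m - target) / target <= tol) break
    if (m < target) lo <- p else hi <- p
  }
  p
}

#' Run the stimulation protocol and record the field of view
#'
#' Simulates the full trial sequence (stimulation windows plus inter-trial
#' intervals, preceded by one burn-in interval) and records step-resolution
#' spikes of the field-of-view units only, to avoid boundary effects.
#'
#' @param net A `lattice_network` with `p_trans` and `p_poiss` set.
#' @param protocol A `stim_protocol`; if its `p_stim` is `NULL` it is
#'   calibrated first via [calibrate_stim()].
#' @param seed Integer seed.
#' @return A `step_raster`: FoV spike events at 2-ms resolution, unit
#'   positions (micrometres, origin at the FoV corner), target ids and the
#'   trial log (`tc`, `onset_step`).
#' @export
run_protocol <- function(net, protocol, seed = 1L) {
  stopifnot(inherits(net, "lattice_network"), inherits(protocol, "stim_protocol"))
  if (is.null(net$p_poiss)) stop("p_poiss not set; calibrate the drive first")
  if (!all(protocol$tc_indices %in% net$fov_indices))
    stop("all target cells must lie inside the FoV")
  p_stim <- protocol$p_stim
  if (is.null(p_stim) && protocol$trials_per_tc > 0)
    p_stim <- calibrate_stim(net, tc = protocol$tc_indices[1], seed = seed)

  n_tc <- length(protocol$tc_indices)
  set.seed(as.integer(seed))
  order_tc <- unlist(lapply(seq_len(protocol$trials_per_tc),
                            function(b) sample(protocol$tc_indices)))
  n_trials <- length(order_tc)
  period <- protocol$stim_steps + protocol$iti_steps
  onsets <- protocol$iti_steps + 1L + (seq_len(n_trials) - 1L) * period
  n_steps <- if (n_trials > 0) max(onsets) + period else 5000L

  stim <- rep(NA_integer_, n_steps)
  for (i in seq_len(n_trials))
    stim[onsets[i]:(onsets[i] + protocol$stim_steps - 1L)] <- order_tc[i]

  r <- simulate_steps(net, n_steps, record = net$fov_indices,
                      stim = if (n_trials > 0) stim else NULL,
                      p_stim = if (is.null(p_stim)) 0 else p_stim)

  fov <- net$fov_indices
  pos <- net$positions[fov, , drop = FALSE]
  pos[, 1] <- pos[, 1] - min(pos[, 1])
  pos[, 2] <- pos[, 2] - min(pos[, 2])
  trials <- data.frame(tc = match(order_tc, fov), onset_step = onsets)

  structure(list(
    events = data.frame(unit = match(r$spikes$unit, fov), step = r$spikes$step),
    n_steps = n_steps, step_ms = 2,
    units = fov, positions = pos,
    tc = match(protocol$tc_indices, fov),
    trials = trials,
    meta = list(sigma = net$sigma, p_trans = net$p_trans,
                p_poiss = net$p_poiss, p_stim = p_stim,
                side = net$side, spacing_um = net$spacing_um,
                seed = as.integer(seed))
  ), class = "step_raster")
}

#' Bin a step-resolution raster into imaging frames
#'
#' Sums spikes in non-overlapping frames of `frame_ms` (default 22 ms = 11
#' steps); the incomplete tail frame is dropped. Trial onsets are mapped to
#' the frame containing the onset step.
#'
#' @param raster A `step_raster` from [run_protocol()].
#' @param frame_ms Frame duration in ms; must be divisible by `step_ms`.
#' @param step_ms Step duration in ms (default 2).
#' @return A [recording()] with integer spike counts (cells x frames).
#' @export
bin_to_frames <- function(raster, frame_ms = 22, step_ms = 2) {
  stopifnot(inherits(raster, "step_raster"))
  if (frame_ms %% step_ms != 0)
    stop("frame_ms must be an integer multiple of step_ms")
  spf <- as.integer(frame_ms / step_ms)
  n_frames <- raster$n_steps %/% spf
  n_cells <- length(raster$units)
  ev <- raster$events[raster$events$step <= n_frames * spf, , drop = FALSE]
  frame <- (ev$step - 1L) %/% spf + 1L
  counts <- matrix(0L, n_cells, n_frames)
  if (nrow(ev) > 0) {
    idx <- (frame - 1L) * n_cells + ev$unit
    tab <- tabulate(idx, nbins = n_cells * n_frames)
    counts[] <- tab
  }
  trials <- raster$trials
  trials$onset_frame <- (trials$onset_step - 1L) %/% spf + 1L
  meta <- raster$meta
  meta$fov_units <- raster$units
  recording(spikes = counts, positions = raster$positions, tc = raster$tc,
            trials = trials, frame_ms = frame_ms, meta = meta)
}

#' Construct a recording container
#'
#' The lingua franca of all analysis stages: a per-cell spike-count raster
#' at fixed frame duration, cell positions in micrometres, target-cell row
#' indices, and a trial table of stimulation onsets.
#'
#' @param spikes Integer matrix, cells x frames.
#' @param positions Numeric matrix, cells x 2 (micrometres).
#' @param tc Integer vector of target-cell row indices (may be empty).
#' @param trials Data frame with columns `tc` (row index of the stimulated
#'   target) and `onset_frame`; may be `NULL` for spontaneous recordings.
#' @param frame_ms Frame duration in milliseconds (default 22).
#' @param meta Optional provenance list.
#' @return A `recording` object.
#' @export
recording <- function(spikes, positions, tc = integer(0), trials = NULL,
                      frame_ms = 22, meta = list()) {
  spikes <- as.matrix(spikes)
  storage.mode(spikes) <- "integer"
  stopifnot(all(spikes >= 0), nrow(positions) == nrow(spikes),
            ncol(positions) == 2, all(is.finite(positions)))
  tc <- as.integer(tc)
  stopifnot(all(tc >= 1 & tc <= nrow(spikes)))
  if (!is.null(trials)) {
    stopifnot(all(c("tc", "onset_frame") %in% names(trials)),
              all(trials$tc %in% seq_len(nrow(spikes))),
              all(trials$onset_frame >= 1 & trials$onset_frame <= ncol(spikes)))
  }
  structure(list(spikes = spikes, positions = as.matrix(positions), tc = tc,
                 trials = trials, frame_ms = frame_ms, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d cells x %d frames (%.0f ms/frame)\n",
              nrow(x$spikes), ncol(x$spikes), x$frame_ms))
  cat(sprintf("  %d target cells, %s trials, mean rate %.3f spikes/cell/frame\n",
              length(x$tc),
              if (is.null(x$trials)) "no" else nrow(x$trials),
              mean(x$spikes)))
  invisible(x)
}
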