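#' Population spike-count trace of a recording
#'
#' Sums spike counts per frame over the analysis cells. When the recording
#' contains stimulation trials the target cells are excluded (their
#' externally driven spikes are not part of the ongoing population
#' dynamics); they are included for spontaneous-only recordings.
#'
#' @param rec A [recording()].
#' @param exclude_tc Override the automatic target exclusion.
#' @return A `population_trace`: integer vector with `frame_ms` attribute.
#' @export
population_trace <- function(rec, exclude_tc = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(exclude_tc))
    exclude_tc <- !is.null(rec$trials) && length(rec$tc) > 0
  rows <- if (exclude_tc) setdiff(seq_len(nrow(rec$spikes)), rec$tc)
          else seq_len(nrow(rec$spikes))
  structure(as.integer(colSums(rec$spikes[rows, , drop = FALSE])),
            frame_ms = rec$frame_ms, class = "population_trace")
}

#' Soft-threshold a population trace
#'
#' Subtracts the threshold and zeroes sub-threshold values:
#' `p_theta(t) = p(t) - theta` where `p(t) > theta`, else 0.
#'
#' @param trace Numeric population trace.
#' @param theta Threshold.
#' @return The thresholded trace (plain numeric).
#' @export
soft_threshold <- function(trace, theta) {
  stopifnot(theta >= 0)
  pmax(as.numeric(trace) - theta, 0)
}

#' Temporal coarse-graining into a phase ensemble
#'
#' For factor k, returns the ensemble of k phase-shifted series
#' `p_k^j(tau) = sum of the k source bins starting at k*tau + j`,
#' j = 0..k-1; trailing incomplete windows are dropped.
#'
#' @param x Numeric (thresholded) trace.
#' @param k Coarse-graining factor (>= 1).
#' @return A list of `k` numeric series.
#' @export
coarse_grain <- function(x, k) {
  stopifnot(k >= 1)
  k <- as.integer(k)
  x <- as.numeric(x)
  n <- length(x)
  lapply(0:(k - 1L), function(j) {
    nt <- (n - j) %/% k
    if (nt == 0) return(numeric(0))
    y <- x[(j + 1L):(j + nt * k)]
    as.numeric(colSums(matrix(y, nrow = k)))
  })
}

#' Extract avalanches (suprathreshold epochs) from a series
#'
#' An avalanche is a maximal run of positive values bounded by zeros on
#' both sides; its size is the summed activity of the run and its duration
#' the number of bins. Runs touching the series boundary lack a bounding
#' zero and are discarded.
#'
#' @param series Numeric series (already thresholded/coarse-grained).
#' @return A data.frame with columns `size`, `duration`, `start`.
#' @export
extract_avalanches <- function(series) {
  x <- as.numeric(series)
  n <- length(x)
  if (n == 0) return(data.frame(size = numeric(0), duration = integer(0),
                                start = integer(0)))
  pos <- x > 0
  d <- diff(c(FALSE, pos, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  keep <- starts > 1L & ends < n  # bounded by zeros on both sides
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) return(data.frame(size = numeric(0),
                                             duration = integer(0),
                                             start = integer(0)))
  cs <- cumsum(x)
  data.frame(size = cs[ends] - cs[starts] + x[starts],
             duration = ends - starts + 1L, start = starts)
}

#' Data-driven avalanche threshold selection
#'
#' Counts the number of epochs N(theta) obtained after soft-thresholding at
#' each theta of the grid and coarse-graining at factor k; N(theta) rises
#' from few epochs at theta = 0 (merged activity) through a maximum and
#' back to zero once all activity is removed, and is typically well
#' approximated by a log-normal shape. A log-normal curve is least-squares
#' fitted and the threshold is set to the fitted location mapped back to
#' the count axis (`exp(mu)`, the curve's median; the raw log-location is
#' also reported). If the fit degenerates the argmax of N(theta) is used.
#'
#' @param trace Numeric population trace.
#' @param k Coarse-graining factor the threshold is selected for.
#' @param theta_grid Candidate thresholds; default spans 0 to max(trace).
#' @return A `threshold_fit`: `theta_star`, `mu`, `sigma_ln`, the grid and
#'   epoch counts, and whether the fallback was used.
#' @export
select_threshold <- function(trace, k = 1L,
                             theta_grid = NULL) {
  x <- as.numeric(trace)
  if (all(x == 0)) stop("all-zero trace: no threshold can be selected")
  if (is.null(theta_grid))
    theta_grid <- seq(0, max(x), length.out = min(41, max(x) + 1))
  n_theta <- vapply(theta_grid, function(th) {
    ph <- coarse_grain(soft_threshold(x, th), k)
    sum(vapply(ph, function(s) nrow(extract_avalanches(s)), numeric(1)))
  }, numeric(1))

  pos <- theta_grid > 0
  fallback <- TRUE
  mu <- NA_real_; s_ln <- NA_real_; theta_star <- theta_grid[which.max(n_theta)]
  if (sum(pos & n_theta > 0) >= 4) {
    fit <- fit_lognormal_curve(theta_grid[pos], n_theta[pos])
    if (!is.null(fit)) {
      mu <- fit$mu; s_ln <- fit$sigma_ln
      cand <- exp(mu)
      if (cand > min(theta_grid) && cand <= max(theta_grid) * 2) {
        theta_star <- cand
        fallback <- FALSE
      }
    }
  }
  structure(list(theta_star = theta_star, mu = mu, sigma_ln = s_ln,
                 k = as.integer(k), theta_grid = theta_grid,
                 n_epochs = n_theta, fallback = fallback),
            class = "threshold_fit")
}

# Least-squares fit of A * lognormal-density(theta; mu, sigma) to a curve
# n(theta); returns NULL on failure.
fit_lognormal_curve <- function(th, nn) {
  w0 <- nn / sum(nn)
  lt <- log(pmax(th, 1e-9))
  mu0 <- sum(w0 * lt)
  s0 <- sqrt(max(sum(w0 * (lt - mu0)^2), 1e-4))
  obj <- function(par) {
    pred <- exp(par[1]) * stats::dlnorm(th, par[2], exp(par[3]))
    sum((pred - nn)^2)
  }
  a0 <- log(max(nn) / stats::dlnorm(exp(mu0), mu0, s0))
  fit <- try(stats::optim(c(a0, mu0, log(s0)), obj), silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value)) return(NULL)
  list(amplitude = exp(fit$par[1]), mu = fit$par[2],
       sigma_ln = exp(fit$par[3]), ssr = fit$value)
}

#' Build an avalanche catalogue across coarse-graining factors
#'
#' For each factor k: selects the threshold (unless given), soft-thresholds
#' the trace, coarse-grains into the k-phase ensemble, extracts epochs per
#' phase and pools them.
#'
#' @param trace Numeric population trace.
#' @param k_values Coarse-graining factors (default 1, 2, 4, 8).
#' @param theta `"auto"` (default, per-k selection via
#'   [select_threshold()]) or a fixed numeric threshold.
#' @return An `avalanche_catalog`: `events` data.frame (`size`, `duration`,
#'   `phase`, `k`) and the per-k `thresholds` table.
#' @export
avalanche_catalog <- function(trace, k_values = c(1, 2, 4, 8),
                              theta = "auto") {
  x <- as.numeric(trace)
  ev <- list(); th_tab <- list()
  for (k in as.integer(k_values)) {
    if (identical(theta, "auto")) {
      tf <- select_threshold(x, k)
      th <- tf$theta_star
      th_tab[[length(th_tab) + 1]] <- data.frame(
        k = k, theta_star = th, mu = tf$mu, sigma_ln = tf$sigma_ln,
        fallback = tf$fallback)
    } else {
      th <- as.numeric(theta)
      th_tab[[length(th_tab) + 1]] <- data.frame(
        k = k, theta_star = th, mu = NA_real_, sigma_ln = NA_real_,
        fallback = NA)
    }
    ph <- coarse_grain(soft_threshold(x, th), k)
    for (j in seq_along(ph)) {
      e <- extract_avalanches(ph[[j]])
      if (nrow(e) > 0)
        ev[[length(ev) + 1]] <- data.frame(size = e$size,
                                           duration = e$duration,
                                           phase = j - 1L, k = k)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(size = numeric(0), duration = integer(0),
                            phase = integer(0), k = integer(0))
  structure(list(events = events, thresholds = do.call(rbind, th_tab),
                 k_values = as.integer(k_values)),
            class = "avalanche_catalog")
}

#' @export
print.avalanche_catalog <- function(x, ...) {
  cat(sprintf("avalanche_catalog: %d events across k = {%s}\n",
              nrow(x$events), paste(x$k_values, collapse = ", ")))
  invisible(x)
}

#' Mean avalanche size versus duration
#'
#' @param catalog An `avalanche_catalog` (or its `events` data.frame).
#' @param k Optional subset of coarse-graining factors.
#' @return A data.frame per (k, duration): mean size and event count.
#' @export
mean_size_vs_duration <- function(catalog, k = NULL) {
  ev <- if (inherits(catalog, "avalanche_catalog")) catalog$events
        else catalog
  if (!is.null(k)) ev <- ev[ev$k %in% k, , drop = FALSE]
  if (nrow(ev) == 0) stop("empty avalanche catalogue")
  agg <- stats::aggregate(size ~ k + duration, data = ev, FUN = mean)
  cnt <- stats::aggregate(size ~ k + duration, data = ev, FUN = length)
  names(agg)[3] <- "mean_size"
  agg$n_events <- cnt$size
  agg[order(agg$k, agg$duration), ]
}

#' Fit the double power-law scaling curve
#'
#' Fits `S(d) = C d^chi_sh * (1 + (d/Phi)^gamma)^((chi_lg - chi_sh)/gamma)`
#' to the mean-size-versus-duration curve in log-log space: initial slope
#' `chi_sh`, asymptotic slope `chi_lg`, crossover at `d = Phi`, transition
#' sharpness `gamma` fixed at 4. Nonlinear least squares with multi-start
#' initialisation; the best start is returned.
#'
#' @param curve Data.frame with columns `duration` and `mean_size` (e.g.
#'   from [mean_size_vs_duration()], one k at a time).
#' @param gamma_sharp Transition sharpness (fixed, default 4).
#' @param weights Optional per-point weights (default unweighted).
#' @return A `scaling_curve_fit`: `C`, `chi_sh`, `chi_lg`, `Phi`,
#'   residuals, convergence and identifiability flags.
#' @export
fit_scaling_curve <- function(curve, gamma_sharp = 4, weights = NULL) {
  stopifnot(all(c("duration", "mean_size") %in% names(curve)))
  curve <- curve[curve$mean_size > 0 & curve$duration > 0, , drop = FALSE]
  if (length(unique(curve$duration)) < 6)
    stop("need at least 6 distinct durations for the double power-law fit")
  ld <- log(curve$duration)
  ls <- log(curve$mean_size)
  if (is.null(weights)) weights <- rep(1, length(ld))
  g <- gamma_sharp

  model <- function(p, ld) {
    # p = (logC, chi_sh, chi_lg, logPhi); stable log1p formulation
    p[1] + p[2] * ld + (p[3] - p[2]) / g * log1p(exp(g * (ld - p[4])))
  }
  starts <- expand.grid(chi_sh = c(1, 1.5, 2, 2.5), chi_lg = c(0.5, 1, 1.5),
                        lphi = stats::quantile(ld, c(0.3, 0.6, 0.9)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(mean(ls) - starts$chi_sh[i] * mean(ld), starts$chi_sh[i],
            starts$chi_lg[i], starts$lphi[i])
    # individual starts may stall at maxiter; only the best start matters
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = p0, fn = function(p) sqrt(weights) * (ls - model(p, ld)))),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(par = fit$par, ssr = ssr, info = fit$info)
  }
  if (is.null(best)) stop("double power-law fit failed to converge from any start")
  best$par <- unname(best$par)
  phi <- exp(best$par[4])
  unident <- phi > max(curve$duration) * 2 || phi < min(curve$duration) / 2 ||
    abs(best$par[3] - best$par[2]) < 0.05
  structure(list(C = exp(best$par[1]), chi_sh = best$par[2],
                 chi_lg = best$par[3], Phi = phi,
                 gamma_sharp = g, ssr = best$ssr,
                 residuals = ls - model(best$par, ld),
                 phi_unidentifiable = unident,
                 converged = best$info %in% 1:4),
            class = "scaling_curve_fit")
}

#' @export
print.scaling_curve_fit <- function(x, ...) {
  cat(sprintf(paste0("scaling_curve_fit: chi_sh = %.3f, chi_lg = %.3f, ",
                     "Phi = %.1f%s\n"),
              x$chi_sh, x$chi_lg, x$Phi,
              if (x$phi_unidentifiable) " (crossover unidentifiable)" else ""))
  invisible(x)
}

#' Fraction of avalanches (and spikes) below a duration cutoff
#'
#' @param catalog An `avalanche_catalog` or events data.frame.
#' @param d_max Duration cutoff in bins; events with `duration < d_max`
#'   count as below the cutoff.
#' @param k Optional subset of coarse-graining factors.
#' @return A list: `event_frac` and `spike_frac` (size-weighted) of events
#'   with duration below the cutoff.
#' @export
parabolic_summary <- function(catalog, d_max, k = NULL) {
  ev <- if (inherits(catalog, "avalanche_catalog")) catalog$events
        else catalog
  if (!is.null(k)) ev <- ev[ev$k %in% k, , drop = FALSE]
  if (nrow(ev) == 0) return(list(event_frac = NA_real_,
                                 spike_frac = NA_real_))
  below <- ev$duration < d_max
  list(event_frac = mean(below),
       spike_frac = sum(ev$size[below]) / sum(ev$size))
}
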