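#' Build a 2D excitable lattice network with distance-dependent connectivity
#'
#' Constructs a directed random graph on a `side` x `side` torus of excitable
#' units spaced `spacing_um` micrometres apart. Every ordered pair (i, j),
#' i != j, receives an edge independently with probability
#' \deqn{P_{conn}(r) = a_g e^{-r^2 / (2 s_g^2)} + a_e e^{-r / s_e}}
#' where r is the periodic (torus) Euclidean distance in micrometres. The
#' default amplitudes and scales give a short-range Gaussian plus long-range
#' exponential kernel typical of local cortical connectivity.
#'
#' The mean out-degree is measured on the realised graph and stored as
#' `k_bar`; the transmission probability is always normalised by this
#' measured value (see [set_branching()]), so dynamics depend on the
#' branching parameter rather than on the absolute degree. An optional hard
#' truncation radius can cap the connection range; the analytic expected
#' degree under the un-truncated kernel is available via
#' [expected_degree()].
#'
#' @param side Lattice side length in units (default 300).
#' @param spacing_um Inter-unit spacing in micrometres (default 12).
#' @param gauss_amp,gauss_scale_um Amplitude and scale of the Gaussian term.
#' @param exp_amp,exp_scale_um Amplitude and scale of the exponential term.
#' @param trunc_radius_um Optional hard cutoff radius in micrometres
#'   (default `Inf`, no truncation).
#' @param fov_side Side length of the central analysis block (field of view),
#'   default 38 units.
#' @param seed Integer seed; the construction is reproducible from it.
#' @return An object of class `lattice_network`: positions (micrometres),
#'   CSR adjacency (`adj_ptr`, `adj_idx`, 0-based), measured `k_bar`,
#'   `fov_indices`, and (once set) `sigma`, `p_trans`, `p_poiss`.
#' @export
build_lattice <- function(side = 300L, spacing_um = 12, gauss_amp = 0.05,
                          gauss_scale_um = 100, exp_amp = 0.03,
                          exp_scale_um = 290, trunc_radius_um = Inf,
                          fov_side = 38L, seed = 1L) {
  stopifnot(side >= 2, spacing_um > 0, gauss_scale_um > 0, exp_scale_um > 0,
            fov_side <= side)
  if (gauss_amp < 0 || gauss_amp > 1 || exp_amp < 0 || exp_amp > 1)
    stop("connection amplitudes must lie in [0, 1]")
  if (gauss_amp + exp_amp > 1)
    stop("Pconn(r) exceeds 1 at r = 0 for these amplitudes")
  side <- as.integer(side)
  n <- side * side

  # torus displacement per axis, in micrometres, for every offset
  ax <- pmin(0:(side - 1), side - (0:(side - 1))) * spacing_um
  r <- sqrt(outer(ax^2, ax^2, "+"))           # side x side offset distances
  p_off <- gauss_amp * exp(-r^2 / (2 * gauss_scale_um^2)) +
    exp_amp * exp(-r / exp_scale_um)
  p_off[r > trunc_radius_um] <- 0
  p_off[1, 1] <- 0                            # no self-edges
  if (any(p_off > 1)) stop("Pconn(r) > 1 at some realizable distance")

  set.seed(as.integer(seed))
  pv <- as.vector(p_off)                      # offset index k -> (dy, dx)
  m_k <- stats::rbinom(length(pv), n, pv)
  hit <- which(m_k > 0L)
  src_l <- vector("list", length(hit))
  for (i in seq_along(hit)) src_l[[i]] <- sample.int(n, m_k[hit[i]])
  src <- unlist(src_l, use.names = FALSE)     # 1-based unit ids
  offs <- rep(hit - 1L, m_k[hit])             # 0-based offset ids

  # unit id u (1-based) sits at row (u-1) %/% side, col (u-1) %% side
  s_row <- (src - 1L) %/% side
  s_col <- (src - 1L) %% side
  o_row <- offs %% side                       # offset decomposed (dy, dx)
  o_col <- offs %/% side
  dst <- ((s_row + o_row) %% side) * side + ((s_col + o_col) %% side) + 1L

  if (is.null(src)) { src <- integer(0); dst <- integer(0) }
  ord <- order(src, dst)
  src <- src[ord]; dst <- dst[ord]
  deg <- tabulate(src, nbins = n)
  adj_ptr <- c(0L, cumsum(deg))

  rows <- (seq_len(n) - 1L) %/% side
  cols <- (seq_len(n) - 1L) %% side
  positions <- cbind(x_um = cols * spacing_um, y_um = rows * spacing_um)

  lo <- (side - fov_side) %/% 2
  fov_rc <- lo:(lo + fov_side - 1L)
  fov_indices <- as.integer(outer(fov_rc * side, fov_rc + 1L, "+"))

  structure(list(
    side = side, spacing_um = spacing_um, n_units = n,
    positions = positions,
    adj_ptr = adj_ptr, adj_idx = dst - 1L,    # CSR, 0-based targets
    k_bar = length(dst) / n,
    conn = list(gauss_amp = gauss_amp, gauss_scale_um = gauss_scale_um,
                exp_amp = exp_amp, exp_scale_um = exp_scale_um,
                trunc_radius_um = trunc_radius_um),
    sigma = NULL, p_trans = NULL, p_poiss = NULL,
    refractory_steps = 1L, periodic = TRUE,
    fov_side = as.integer(fov_side), fov_indices = sort(fov_indices),
    rng_seed = as.integer(seed)
  ), class = "lattice_network")
}

#' Analytic expected out-degree of the lattice connectivity kernel
#'
#' Sums the connection kernel over all torus offsets; an independent check
#' of the realised mean degree (`k_bar`).
#' @param side,spacing_um,gauss_amp,gauss_scale_um,exp_amp,exp_scale_um,trunc_radius_um
#'   Kernel parameters as in [build_lattice()].
#' @return Expected out-degree (numeric).
#' @export
expected_degree <- function(side, spacing_um = 12, gauss_amp = 0.05,
                            gauss_scale_um = 100, exp_amp = 0.03,
                            exp_scale_um = 290, trunc_radius_um = Inf) {
  ax <- pmin(0:(side - 1), side - (0:(side - 1))) * spacing_um
  r <- sqrt(outer(ax^2, ax^2, "+"))
  p <- gauss_amp * exp(-r^2 / (2 * gauss_scale_um^2)) +
    exp_amp * exp(-r / exp_scale_um)
  p[r > trunc_radius_um] <- 0
  p[1, 1] <- 0
  sum(p)
}

#' Truncation radius reproducing a target mean degree
#'
#' The connectivity kernel and the mean degree are redundant parameters:
#' given the kernel amplitudes and scales, a hard truncation radius can be
#' chosen so that the analytic expected out-degree matches a target value
#' (for example the ~43 connections per unit of the reference cortical
#' network). Solved by root finding on [expected_degree()].
#'
#' @param target_k Target mean out-degree (default 43).
#' @inheritParams expected_degree
#' @return Truncation radius in micrometres.
#' @export
trunc_radius_for_degree <- function(target_k = 43, side = 300,
                                    spacing_um = 12, gauss_amp = 0.05,
                                    gauss_scale_um = 100, exp_amp = 0.03,
                                    exp_scale_um = 290) {
  f <- function(R) expected_degree(side, spacing_um, gauss_amp,
                                   gauss_scale_um, exp_amp, exp_scale_um,
                                   trunc_radius_um = R) - target_k
  upper <- side * spacing_um / 2
  if (f(upper) < 0)
    stop("target degree exceeds the kernel's expected degree; no radius exists")
  stats::uniroot(f, c(spacing_um, upper), tol = 1e-3)$root
}

#' Set the branching parameter of a lattice network
#'
#' Stores `sigma` and the per-edge transmission probability
#' `p_trans = sigma / k_bar`, where `k_bar` is the measured mean out-degree.
#' `sigma` is the expected number of downstream activations per spike in a
#' quiet network; `sigma = 1` is the branching-process critical point, and
#' the lattice critical point sits slightly above 1 because of spike
#' collisions (see [find_critical_sigma()]).
#'
#' @param net A `lattice_network`.
#' @param sigma Branching parameter, `sigma >= 0` and `sigma / k_bar <= 1`.
#' @return The network with `sigma` and `p_trans` set.
#' @export
set_branching <- function(net, sigma) {
  stopifnot(inherits(net, "lattice_network"), sigma >= 0)
  if (net$k_bar <= 0) stop("network has no edges (k_bar = 0); cannot set sigma")
  p <- sigma / net$k_bar
  if (p > 1) stop("sigma / k_bar exceeds 1; not a probability")
  net$sigma <- sigma
  net$p_trans <- p
  net
}

#' Structure-only output strength of every unit
#'
#' OS(i) is the sum over path orders o = 1..`max_order` of all entries of
#' row i of (p_trans * A)^o, i.e. the expected number of spikes a single
#' spike of unit i would generate through directed paths of length at most
#' `max_order`, ignoring dynamics (refractoriness, collisions).
#'
#' @param net A `lattice_network` with `p_trans` set (see [set_branching()]).
#' @param max_order Maximum path order (default 5).
#' @return A data.frame with columns `unit` and `os`, class `os_table`.
#' @export
output_strength <- function(net, max_order = 5L) {
  stopifnot(inherits(net, "lattice_network"))
  if (is.null(net$p_trans)) stop("p_trans not set; call set_branching() first")
  os <- cpp_output_strength(net$adj_ptr, net$adj_idx, net$n_units,
                            net$p_trans, as.integer(max_order))
  structure(data.frame(unit = seq_len(net$n_units), os = os),
            max_order = as.integer(max_order), class = c("os_table", "data.frame"))
}

#' Direct out-neighbours of a unit
#'
#' @param net A `lattice_network`.
#' @param unit Unit id (1-based).
#' @return Integer vector of 1-based target unit ids.
#' @export
out_neighbors <- function(net, unit) {
  stopifnot(inherits(net, "lattice_network"), unit >= 1, unit <= net$n_units)
  lo <- net$adj_ptr[unit] + 1L
  hi <- net$adj_ptr[unit + 1L]
  if (hi < lo) return(integer(0))
  net$adj_idx[lo:hi] + 1L
}

#' @export
print.lattice_network <- function(x, ...) {
  cat(sprintf("lattice_network: %d x %d torus (%d units), spacing %.1f um\n",
              x$side, x$side, x$n_units, x$spacing_um))
  cat(sprintf("  measured k_bar = %.2f", x$k_bar))
  if (!is.null(x$sigma))
    cat(sprintf(", sigma = %.4f, p_trans = %.5f", x$sigma, x$p_trans))
  cat("\n")
  if (!is.null(x$p_poiss))
    cat(sprintf("  p_poiss = %.3g per unit per step\n", x$p_poiss))
  cat(sprintf("  FoV: central %d x %d block (%d units)\n",
              x$fov_side, x$fov_side, length(x$fov_indices)))
  invisible(x)
}
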