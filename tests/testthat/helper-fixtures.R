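# Shared helpers: tiny graphs, brute-force oracles, small cached lattices.

# Minimal lattice_network wrapper around an explicit edge list, for testing
# graph-level operations (output strength, stepping) on hand-built graphs.
graph_net <- function(n, src, dst, p_trans = NULL) {
  stopifnot(length(src) == length(dst), all(src >= 1), all(dst <= n))
  ord <- order(src, dst)
  src <- src[ord]; dst <- dst[ord]
  deg <- tabulate(src, nbins = n)
  net <- structure(list(
    side = NA_integer_, spacing_um = 1, n_units = n,
    positions = cbind(x_um = seq_len(n), y_um = rep(0, n)),
    adj_ptr = c(0L, cumsum(deg)), adj_idx = as.integer(dst - 1L),
    k_bar = length(dst) / n, sigma = NULL, p_trans = NULL, p_poiss = NULL,
    refractory_steps = 1L, periodic = FALSE,
    fov_side = NA_integer_, fov_indices = seq_len(n), rng_seed = 0L
  ), class = "lattice_network")
  if (!is.null(p_trans)) {
    net$p_trans <- p_trans
    net$sigma <- p_trans * net$k_bar
  }
  net
}

# Exhaustive directed-path enumeration oracle for output strength:
# OS(i) = sum over all paths of length 1..max_order starting at i of
# p^length. Paths may revisit nodes, exactly as matrix powers do.
os_brute <- function(n, src, dst, p, max_order = 5) {
  adj <- vector("list", n)
  for (e in seq_along(src)) adj[[src[e]]] <- c(adj[[src[e]]], dst[e])
  walk <- function(node, depth) {
    if (depth == 0) return(0)
    total <- 0
    for (nb in adj[[node]]) total <- total + p + p * walk(nb, depth - 1)
    total
  }
  vapply(seq_len(n), walk, numeric(1), depth = max_order)
}

# Brute-force avalanche extraction: plain loop over the series.
avalanche_brute <- function(x) {
  sizes <- numeric(0); durs <- integer(0)
  run_sum <- 0; run_len <- 0L; started_inside <- TRUE
  for (i in seq_along(x)) {
    if (x[i] > 0) {
      if (run_len == 0L) started_inside <- (i == 1L)
      run_sum <- run_sum + x[i]; run_len <- run_len + 1L
    } else {
      if (run_len > 0L && !started_inside) {
        sizes <- c(sizes, run_sum); durs <- c(durs, run_len)
      }
      run_sum <- 0; run_len <- 0L
    }
  }
  # trailing run touches the boundary: discarded
  data.frame(size = sizes, duration = durs)
}

# Benjamini-Hochberg step-up by hand.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Small cached lattice shared across test files (built once per session).
test_lattice <- local({
  cache <- new.env()
  function(side = 40, seed = 7) {
    key <- paste0("s", side, "_", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- build_lattice(side = side, fov_side = min(side, 20),
                                    seed = seed)
    cache[[key]]
  }
})

# A recording built by hand from an explicit count matrix.
manual_recording <- function(counts, tc, onsets, tc_per_trial = NULL) {
  n <- nrow(counts)
  trials <- if (length(onsets))
    data.frame(tc = if (is.null(tc_per_trial)) rep(tc[1], length(onsets))
               else tc_per_trial,
               onset_frame = onsets) else NULL
  recording(spikes = counts,
            positions = cbind(seq_len(n) * 10, rep(0, n)),
            tc = tc, trials = trials, frame_ms = 22)
}
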