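# Small fixture builders shared across test files.

# behaviour trace from explicit vectors (unit tests construct toy tracks)
make_behavior <- function(time, position, velocity, fs, track_length) {
  out <- data.frame(time = time, position = position, velocity = velocity,
                    locomotion = velocity > 5)
  attr(out, "fs") <- fs
  attr(out, "track_length") <- track_length
  class(out) <- c("behavior_trace", "data.frame")
  out
}

# uniform occupancy over n_bins: cycle one sample per bin, all running
uniform_behavior <- function(n_bins, n_cycles, fs = 10, track_length = n_bins) {
  n <- n_bins * n_cycles
  make_behavior(time = (seq_len(n) - 1) / fs,
                position = rep(seq_len(n_bins) - 0.5, n_cycles) *
                  (track_length / n_bins),
                velocity = rep(10, n), fs = fs, track_length = track_length)
}

# session from a list of spike-time vectors
make_session <- function(spike_list, duration, behavior = NULL, ttp = NULL,
                         metadata = list()) {
  if (is.null(ttp)) ttp <- rep(0.7, length(spike_list))
  units <- lapply(seq_along(spike_list), function(i) {
    spike_train(i, spike_list[[i]], ttp[i])
  })
  session_recording(units, duration, behavior = behavior, metadata = metadata)
}

# homogeneous Poisson spike train on [0, duration)
poisson_spikes <- function(rate, duration) {
  n <- stats::rpois(1, rate * duration)
  sort(stats::runif(n, 0, duration))
}

# rate-map object from a bare rate vector (uniform occupancy), for analytic
# checks that bypass behaviour tracking
make_map <- function(lambda_x, p_x = NULL) {
  n <- length(lambda_x)
  if (is.null(p_x)) p_x <- rep(1 / n, n)
  structure(list(p_x = p_x, lambda_x = lambda_x, lambda_raw = lambda_x,
                 lambda_bar = sum(p_x * lambda_x), occupancy_s = p_x,
                 n_bins = n, smooth_width = 1),
            class = "rate_map")
}

# z-score rows of a matrix and attach the validity flag correlation_matrix uses
zscore_rows <- function(m) {
  valid <- apply(m, 1, function(x) stats::var(x) > 0)
  z <- m * 0
  z[valid, ] <- t(scale(t(m[valid, , drop = FALSE])))
  structure(z, valid = valid)
}

# exact 4-state enumeration for a 2-unit Ising model (independent oracle)
two_unit_moments <- function(h1, h2, J) {
  states <- expand.grid(s1 = 0:1, s2 = 0:1)
  w <- exp(h1 * states$s1 + h2 * states$s2 + J * states$s1 * states$s2)
  p <- w / sum(w)
  list(m1 = sum(p * states$s1), m2 = sum(p * states$s2),
       q = sum(p * states$s1 * states$s2), p = p)
}

# brute-force graph metrics: connected-triple counting (a triangle contributes
# three connected triples), the standard transitivity denominator
brute_graph_metrics <- function(adj) {
  n <- nrow(adj)
  n_edges <- sum(adj) / 2
  closed <- 0; open <- 0
  if (n >= 3) {
    trip <- utils::combn(n, 3)
    for (t in seq_len(ncol(trip))) {
      i <- trip[1, t]; j <- trip[2, t]; k <- trip[3, t]
      e <- adj[i, j] + adj[i, k] + adj[j, k]
      if (e == 3) closed <- closed + 1
      if (e == 2) open <- open + 1
    }
  }
  cc <- if (3 * closed + open == 0) 0 else 3 * closed / (3 * closed + open)
  list(relative_degree = n_edges / choose(n, 2), clustering = cc)
}

# raster whose columns are given pattern codewords
raster_from_codewords <- function(cw, n_units) {
  m <- t(enumerate_patterns(n_units)[cw + 1, , drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(seq_len(n_units))
  structure(m, bin_width = 0.010, t0 = 0,
            class = c("binned_raster", "matrix"))
}

# synthetic coding-space feature tables: Gaussian clusters per class
make_features <- function(n_per, centers, sd = 0.05, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(centers)), function(c) {
    data.frame(session = paste0("s", c), subsample = seq_len(n_per),
               mean_correlation = rnorm(n_per, centers$x[c], sd),
               entropy = rnorm(n_per, centers$y[c], sd),
               kld = rnorm(n_per, centers$z[c], sd),
               group = centers$group[c], region = centers$region[c])
  })
  do.call(rbind, rows)
}

four_centers <- data.frame(
  x = c(0, 2, 0, 2), y = c(0, 0, 2, 2), z = c(0, 2, 2, 0),
  group = rep(c("control", "model"), 2),
  region = rep(c("dorsal", "ventral"), each = 2))
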