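#' Pairwise Pearson correlation matrix of rate traces
#'
#' Correlates the z-scored sliding-window count traces of every unit pair.
#' Units flagged zero-variance (see [zscored_rate_traces()]) get `NA` rows and
#' columns and are excluded from downstream pair statistics.
#'
#' @param traces matrix from [zscored_rate_traces()] (units x windows, with a
#'   `valid` attribute), or any units-by-time numeric matrix.
#' @return object of class `correlation_matrix`: symmetric matrix with unit
#'   diagonal, `NA` for invalid units; attribute `valid`.
#' @export
correlation_matrix <- function(traces) {
  valid <- attr(traces, "valid")
  if (is.null(valid)) valid <- apply(traces, 1, function(x) stats::var(x) > 0)
  if (sum(valid) < 2) stop("need at least 2 valid traces")
  n <- nrow(traces)
  cm <- matrix(NA_real_, n, n, dimnames = list(rownames(traces), rownames(traces)))
  cm[valid, valid] <- stats::cor(t(traces[valid, , drop = FALSE]))
  diag(cm)[valid] <- 1
  structure(cm, valid = valid, class = c("correlation_matrix", "matrix"))
}

off_diagonal_pairs <- function(cm) {
  n <- nrow(cm)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  vals <- cm[upper.tri(cm)]
  ok <- !is.na(vals)
  list(i = idx[ok, 1], j = idx[ok, 2], r = vals[ok])
}

#' Mean pairwise correlation over a random pair subsample
#'
#' Draws up to `n_pairs` distinct off-diagonal unit pairs uniformly without
#' replacement (all valid pairs if fewer exist) and averages their Pearson
#' coefficients. Subsampling keeps sessions with many units from dominating
#' pooled comparisons.
#'
#' @param cm a `correlation_matrix`.
#' @param n_pairs pairs to draw, default 250.
#' @param seed RNG seed.
#' @return list with `mean_r`, `n_pairs_used`, `pair_r` (the sampled values).
#' @export
mean_pairwise_correlation <- function(cm, n_pairs = 250, seed = NULL) {
  pr <- off_diagonal_pairs(cm)
  if (!length(pr$r)) stop("no valid unit pairs")
  r <- if (length(pr$r) <= n_pairs) pr$r else
    with_seed(seed, sample(pr$r, n_pairs))
  list(mean_r = mean(r), n_pairs_used = length(r), pair_r = r)
}

#' Threshold a correlation matrix into a functional graph and measure it
#'
#' An undirected edge joins two units whenever their signed correlation
#' strictly exceeds `threshold` (default 0.06). Relative degree is the edge
#' count divided by the number of possible edges; the clustering coefficient
#' is the global transitivity, closed triplets over all connected triplets,
#' defined as 0 for triplet-free graphs.
#'
#' @param cm a `correlation_matrix`, typically restricted to a 16-unit
#'   subsample.
#' @param threshold edge threshold on signed r, default 0.06.
#' @return list with `relative_degree`, `clustering`, `n_edges`, `adjacency`
#'   (binary symmetric matrix, zero diagonal).
#' @export
graph_metrics <- function(cm, threshold = 0.06) {
  n <- nrow(cm)
  adj <- (!is.na(cm) & cm > threshold) * 1L
  diag(adj) <- 0L
  n_edges <- sum(adj) / 2
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cc <- igraph::transitivity(g, type = "global")
  if (is.nan(cc)) cc <- 0
  list(relative_degree = n_edges / choose(n, 2), clustering = cc,
       n_edges = n_edges, adjacency = adj)
}
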