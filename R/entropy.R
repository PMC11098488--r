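#' Empirical distribution of binary population patterns
#'
#' Maps each raster column (the population's active/inactive states in one
#' 10 ms bin — one "pattern") to an integer codeword, unit 1 in the least
#' significant bit, and tabulates frequencies. For `n` units there are `2^n`
#' possible patterns; the observed support is at most `min(n_bins, 2^n)`.
#'
#' @param raster a `binned_raster` (units x bins, 0/1).
#' @return object of class `pattern_distribution`: list with `n_units`,
#'   `codewords` (numeric, sorted), `probs` (> 0, summing to 1), `counts`,
#'   `n_bins`.
#' @export
pattern_distribution <- function(raster) {
  if (ncol(raster) == 0L) stop("raster has no time bins")
  n <- nrow(raster)
  cw <- as.vector(2^(seq_len(n) - 1) %*% raster)
  tab <- table(cw)
  codewords <- as.numeric(names(tab))
  counts <- as.vector(tab)
  new_pattern_distribution(codewords, counts / ncol(raster), n,
                           n_bins = ncol(raster), counts = counts)
}

#' Construct a pattern distribution from codewords and probabilities
#'
#' Low-level constructor, useful for exact (analytic) distributions in tests
#' and for model output.
#'
#' @param codewords numeric pattern codewords in `[0, 2^n_units)`.
#' @param probs matching probabilities, summing to 1.
#' @param n_units number of units.
#' @param n_bins number of bins the distribution was estimated from (`NA` for
#'   analytic distributions).
#' @param counts optional observed counts.
#' @return a `pattern_distribution`.
#' @export
new_pattern_distribution <- function(codewords, probs, n_units, n_bins = NA,
                                     counts = NULL) {
  keep <- probs > 0
  codewords <- codewords[keep]; probs <- probs[keep]
  if (!is.null(counts)) counts <- counts[keep]
  o <- order(codewords)
  if (abs(sum(probs) - 1) > 1e-10) stop("probabilities must sum to 1")
  structure(
    list(n_units = n_units, codewords = codewords[o], probs = probs[o],
         counts = counts[o], n_bins = n_bins),
    class = "pattern_distribution"
  )
}

#' Number of active units in each pattern codeword
#' @param codewords numeric codewords.
#' @param n_units number of units (bits).
#' @return integer popcount per codeword.
#' @export
pattern_popcount <- function(codewords, n_units) {
  out <- integer(length(codewords))
  cw <- codewords
  for (b in seq_len(n_units)) {
    out <- out + (cw %% 2 == 1)
    cw <- cw %/% 2
  }
  out
}

#' Shannon entropy of a pattern distribution, with normalisations
#'
#' Raw entropy is the plug-in estimate `-sum p_k log2 p_k` over the observed
#' support, in bits per bin (bounded by the unit count). Because a raw
#' per-bin entropy depends on bin width and the population's overall activity,
#' two normalisations are carried alongside: `entropy_rate` divides by the bin
#' width (bits/s) and `rate_normalized` divides by the population mean firing
#' rate. All three are always returned; `mode` selects which one is reported
#' as `value` and is recorded in the result.
#'
#' @param dist a `pattern_distribution`.
#' @param mean_population_rate mean firing rate of the population (Hz),
#'   required for `rate_normalized`.
#' @param bin_width pattern bin width (s), default 0.010.
#' @param mode one of `"entropy_rate"` (default), `"raw"`, `"rate_normalized"`.
#' @return object of class `entropy_result`: list with `raw_bits`,
#'   `entropy_rate`, `rate_normalized`, `value`, `mode`.
#' @export
normalized_entropy <- function(dist, mean_population_rate = NA, bin_width = 0.010,
                               mode = c("entropy_rate", "raw", "rate_normalized")) {
  mode <- match.arg(mode)
  raw <- entropy_bits(dist$probs)
  rate <- raw / bin_width
  norm <- if (is.finite(mean_population_rate) && mean_population_rate > 0)
    raw / mean_population_rate else NA_real_
  value <- switch(mode, raw = raw, entropy_rate = rate, rate_normalized = norm)
  structure(list(raw_bits = raw, entropy_rate = rate, rate_normalized = norm,
                 value = value, mode = mode),
            class = "entropy_result")
}

#' Probability of each coactivity category
#'
#' Collapses a pattern distribution onto the number of simultaneously active
#' units (the pattern popcount), 0 through `n_units`.
#'
#' @param dist a `pattern_distribution`.
#' @return numeric vector of length `n_units + 1`, names `"0"`..`"n"`, summing
#'   to 1.
#' @export
coactivity_distribution <- function(dist) {
  pc <- pattern_popcount(dist$codewords, dist$n_units)
  out <- vapply(0:dist$n_units, function(c) sum(dist$probs[pc == c]), numeric(1))
  names(out) <- as.character(0:dist$n_units)
  out
}

#' Mean population firing rate implied by a binary raster
#'
#' Mean over units of (active bins / total time); with at most one counted
#' spike per 10 ms bin this is the binarised rate the entropy normalisation
#' uses.
#'
#' @param raster a `binned_raster`.
#' @return rate in Hz.
#' @export
raster_mean_rate <- function(raster) {
  bw <- attr(raster, "bin_width")
  if (is.null(bw)) stop("raster carries no bin_width attribute")
  mean(rowMeans(raster)) / bw
}

#' Match subsamples across groups by mean firing rate
#'
#' For each subsample in group A, picks (seeded, uniformly) one group-B
#' subsample whose mean rate differs by at most `tolerance`; A-subsamples with
#' no candidate are dropped and reported. Used as the rate-matched control
#' that separates rate effects from pattern-structure effects.
#'
#' @param rates_A,rates_B numeric vectors of per-subsample mean rates (Hz).
#' @param tolerance maximum |rate difference| (Hz), default 0.1.
#' @param seed RNG seed.
#' @return list with `pairs` (data frame `a`, `b`, `rate_a`, `rate_b`, `diff`),
#'   `unmatched` (indices into A), `n_matched`.
#' @export
rate_matched_pairing <- function(rates_A, rates_B, tolerance = 0.1, seed = NULL) {
  if (!length(rates_A) || !length(rates_B)) stop("both groups must be non-empty")
  with_seed(seed, {
    rows <- list(); unmatched <- integer(0)
    for (a in seq_along(rates_A)) {
      cand <- which(abs(rates_B - rates_A[a]) <= tolerance)
      if (!length(cand)) {
        unmatched <- c(unmatched, a)
      } else {
        b <- if (length(cand) == 1L) cand else sample(cand, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          a = a, b = b, rate_a = rates_A[a], rate_b = rates_B[b],
          diff = rates_A[a] - rates_B[b])
      }
    }
    if (!length(rows)) {
      return(list(pairs = NULL, unmatched = unmatched, n_matched = 0L))
    }
    list(pairs = do.call(rbind, rows), unmatched = unmatched,
         n_matched = length(rows))
  })
}
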