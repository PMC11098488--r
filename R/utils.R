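#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the R random seed for the duration of `expr` and restores the previous
#' generator state afterwards, so seeded generators are pure functions of their
#' seed and never perturb the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream unchanged.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Numerically stable log-sum-exp
#' @param x numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Smooth a signal with a truncated Gaussian kernel
#'
#' Kernel of standard deviation `sigma` samples, truncated to `width` samples
#' and renormalised; edges use the renormalised partial kernel (no padding
#' artefacts).
#'
#' @param x numeric vector.
#' @param sigma kernel standard deviation in samples.
#' @param width total kernel width in samples.
#' @return smoothed vector, same length as `x`.
#' @keywords internal
gaussian_smooth <- function(x, sigma, width) {
  half <- floor(width / 2)
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  n <- length(x)
  num <- stats::convolve(x, rev(k), type = "open")
  den <- stats::convolve(rep(1, n), rev(k), type = "open")
  idx <- (half + 1L):(half + n)
  num[idx] / den[idx]
}

#' Boxcar-smooth a vector with edge renormalisation
#'
#' Square-wave (boxcar) convolution of odd width; at the edges the window is
#' truncated and renormalised rather than wrapped, because a teleporting
#' virtual track has genuine endpoints. `NA` entries (e.g. bins with zero
#' occupancy) are excluded from each window.
#'
#' @param x numeric vector, possibly with `NA`s.
#' @param width window width in samples (odd).
#' @return smoothed vector; entries that were `NA` stay `NA`.
#' @keywords internal
boxcar_smooth <- function(x, width) {
  if (width <= 1) return(x)
  half <- floor(width / 2)
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    w <- x[max(1L, i - half):min(n, i + half)]
    out[i] <- mean(w, na.rm = TRUE)
  }
  out
}

#' Zero-phase FFT band-pass filter
#'
#' Brick-wall band-pass implemented in the frequency domain; purely real gain,
#' hence exactly zero phase shift (event onset timing is unbiased).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param low,high band edges (Hz).
#' @return filtered vector, same length.
#' @keywords internal
fft_bandpass <- function(x, fs, low, high) {
  n <- length(x)
  freqs <- (seq_len(n) - 1L) / n * fs
  freqs <- pmin(freqs, fs - freqs)  # two-sided spectrum folded to [0, fs/2]
  keep <- freqs >= low & freqs <= high
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

#' Column variances of a matrix
#' @param m numeric matrix.
#' @return numeric vector of per-column sample variances.
#' @keywords internal
col_vars <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

#' Shannon entropy of a probability vector, in bits
#' @param p probabilities (zeros allowed; zero terms contribute 0).
#' @return entropy in bits.
#' @keywords internal
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
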