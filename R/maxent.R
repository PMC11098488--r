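# Pairwise maximum-entropy (Ising) modelling of binary population patterns.
# Fitting is exact: for n <= 20 units the full 2^n pattern space is enumerated,
# so likelihood, gradient (empirical minus model moments) and the partition
# function carry no Monte-Carlo error.

.pattern_cache <- new.env(parent = emptyenv())

#' Enumerate all binary patterns of n units
#'
#' @param n number of units, at most 24.
#' @return `2^n x n` 0/1 matrix; row `k+1` is the pattern with codeword `k`
#'   (unit 1 = least significant bit).
#' @export
enumerate_patterns <- function(n) {
  stopifnot(n >= 1, n <= 24)
  key <- as.character(n)
  if (!is.null(.pattern_cache[[key]])) return(.pattern_cache[[key]])
  cw <- 0:(2^n - 1)
  S <- vapply(seq_len(n), function(b) (cw %/% 2^(b - 1)) %% 2, numeric(2^n))
  if (n <= 16) .pattern_cache[[key]] <- S
  S
}

support_matrix <- function(dist) {
  n <- dist$n_units
  vapply(seq_len(n), function(b) (dist$codewords %/% 2^(b - 1)) %% 2,
         numeric(length(dist$codewords)))
}

empirical_moments <- function(dist) {
  S <- support_matrix(dist)
  list(mean = as.vector(crossprod(S, dist$probs)),
       pairs = crossprod(S, dist$probs * S))
}

#' Fit a pairwise maximum-entropy model to an empirical pattern distribution
#'
#' Finds field terms `h_i` and symmetric couplings `J_ij` such that the model
#' `P(sigma) = exp(sum_i h_i sigma_i + 1/2 sum_{i!=j} J_ij sigma_i sigma_j)/Z`
#' reproduces the empirical single-unit activation probabilities and pairwise
#' coactivation probabilities — the least-structured (maximum-entropy)
#' distribution with those moments. Fitting maximises the average
#' log-likelihood by BFGS with exact gradients obtained from full `2^n`
#' enumeration; convergence is declared when the largest absolute moment
#' residual falls below `tol`.
#'
#' Units that are always silent (or always active) in the data have no finite
#' `h`; they are removed before fitting and re-inserted as deterministic bits
#' when the model distribution is evaluated.
#'
#' @param dist a `pattern_distribution` with at most 20 units.
#' @param tol moment-residual convergence tolerance, default `1e-6`.
#' @param max_iter total BFGS iteration budget, default `1e4`.
#' @return object of class `maxent_model`: list with `h` (length n; `-Inf`
#'   for always-silent, `+Inf` for always-active units), `J` (n x n symmetric,
#'   zero diagonal and zero rows for degenerate units), `logZ` (active
#'   sub-model), `active` (indices of fitted units), `n_units`, and
#'   `diagnostics` (iterations, max moment residual, converged flag).
#' @export
fit_pairwise_maxent <- function(dist, tol = 1e-6, max_iter = 1e4) {
  n <- dist$n_units
  if (n > 20) stop("exact enumeration supports at most 20 units")
  mom <- empirical_moments(dist)
  silent <- mom$mean <= 0
  saturated <- mom$mean >= 1
  active <- which(!silent & !saturated)
  na <- length(active)

  h_full <- rep(NA_real_, n)
  h_full[silent] <- -Inf
  h_full[saturated] <- Inf
  J_full <- matrix(0, n, n)

  if (na == 0L) {
    return(structure(
      list(h = h_full, J = J_full, logZ = 0, active = active, n_units = n,
           diagnostics = list(iterations = 0L, residual = 0, converged = TRUE)),
      class = "maxent_model"))
  }

  m_emp <- mom$mean[active]
  q_emp <- mom$pairs[active, active, drop = FALSE]
  ut <- upper.tri(q_emp)
  target <- c(m_emp, q_emp[ut])

  S <- enumerate_patterns(na)
  # shared state so fn and gr reuse one enumeration pass per parameter value
  last <- new.env(parent = emptyenv())
  last$theta <- NULL

  refresh <- function(theta) {
    if (!is.null(last$theta) && identical(theta, last$theta)) return(invisible())
    h <- theta[seq_len(na)]
    J <- matrix(0, na, na)
    J[ut] <- theta[-seq_len(na)]
    J <- J + t(J)
    logp <- as.vector(S %*% h + 0.5 * rowSums((S %*% J) * S))
    lz <- logsumexp(logp)
    p <- exp(logp - lz)
    q_mod <- crossprod(S, p * S)
    last$theta <- theta
    last$logZ <- lz
    last$moments <- c(as.vector(crossprod(S, p)), q_mod[ut])
    invisible()
  }
  fn <- function(theta) { refresh(theta); last$logZ - sum(theta * target) }
  gr <- function(theta) { refresh(theta); last$moments - target }

  theta <- c(stats::qlogis(m_emp), rep(0, sum(ut)))
  total_iter <- 0L
  repeat {
    res <- stats::optim(theta, fn, gr, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-16))
    theta <- res$par
    total_iter <- total_iter + res$counts[["gradient"]]
    refresh(theta)
    residual <- max(abs(last$moments - target))
    if (residual <= tol || total_iter >= max_iter) break
  }
  if (residual > tol) {
    cond <- structure(
      class = c("popcoding_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "maxent fit did not reach tolerance: residual %.3g after %d iterations",
        residual, total_iter), call = sys.call(-1), residual = residual))
    stop(cond)
  }

  h_full[active] <- theta[seq_len(na)]
  Ja <- matrix(0, na, na)
  Ja[ut] <- theta[-seq_len(na)]
  J_full[active, active] <- Ja + t(Ja)
  structure(
    list(h = h_full, J = J_full, logZ = last$logZ, active = active,
         n_units = n,
         diagnostics = list(iterations = total_iter, residual = residual,
                            converged = TRUE)),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d units (%d fitted), logZ = %.4f, residual %.2g\n",
              x$n_units, length(x$active), x$logZ, x$diagnostics$residual))
  invisible(x)
}

#' Predicted pattern distribution of a fitted maximum-entropy model
#'
#' Enumerates all `2^n` patterns of the fitted sub-model with log-sum-exp
#' stabilisation, then maps them back to full-population codewords with
#' degenerate units fixed at their observed value (patterns violating a fixed
#' bit have probability 0 and are omitted from the support).
#'
#' @param model a `maxent_model`.
#' @return a `pattern_distribution` over the model's support.
#' @export
model_distribution <- function(model) {
  n <- model$n_units
  active <- model$active
  na <- length(active)
  base_cw <- sum(2^(which(is.infinite(model$h) & model$h > 0) - 1))
  if (na == 0L) {
    return(new_pattern_distribution(base_cw, 1, n))
  }
  S <- enumerate_patterns(na)
  h <- model$h[active]
  J <- model$J[active, active, drop = FALSE]
  logp <- as.vector(S %*% h + 0.5 * rowSums((S %*% J) * S))
  p <- exp(logp - logsumexp(logp))
  cw <- as.vector(S %*% 2^(active - 1)) + base_cw
  new_pattern_distribution(cw, p, n)
}

#' Kullback-Leibler divergence on the empirical support, in bits
#'
#' `sum_k p_emp(k) log2(p_emp(k) / p_pred(k))` over patterns with nonzero
#' empirical probability only.
#'
#' @param empirical,predicted `pattern_distribution`s on the same units.
#' @return KLD in bits (>= 0 when the predicted distribution is normalised).
#' @export
kld_on_support <- function(empirical, predicted) {
  stopifnot(empirical$n_units == predicted$n_units)
  idx <- match(empirical$codewords, predicted$codewords)
  if (anyNA(idx)) stop("predicted distribution is zero on empirical support")
  sum(empirical$probs * log2(empirical$probs / predicted$probs[idx]))
}

#' Coactivity-resolved decomposition of model prediction error
#'
#' For every pattern with nonzero empirical probability the relative error is
#' `|p_pred - p_emp| / p_emp`. Errors are summed within each coactivity
#' category (patterns sharing a popcount) to give the total prediction error,
#' and divided by the category's support count for the mean per-pattern error;
#' empty categories have total 0 and undefined (NA) mean.
#'
#' @param empirical,predicted `pattern_distribution`s on the same units.
#' @return object of class `error_decomposition`: list with `kld`,
#'   `per_pattern` (data frame `codeword`, `coactive`, `error`), and `by_category`
#'   (data frame `coactive` 0..n, `total_error`, `mean_error`, `n_support`).
#' @export
error_decomposition <- function(empirical, predicted) {
  n <- empirical$n_units
  idx <- match(empirical$codewords, predicted$codewords)
  if (anyNA(idx)) stop("predicted distribution is zero on empirical support")
  err <- abs(predicted$probs[idx] - empirical$probs) / empirical$probs
  pc <- pattern_popcount(empirical$codewords, n)
  cats <- 0:n
  total <- vapply(cats, function(c) sum(err[pc == c]), numeric(1))
  nsup <- vapply(cats, function(c) sum(pc == c), numeric(1))
  structure(
    list(kld = kld_on_support(empirical, predicted),
         per_pattern = data.frame(codeword = empirical$codewords,
                                  coactive = pc, error = err),
         by_category = data.frame(coactive = cats, total_error = total,
                                  mean_error = ifelse(nsup > 0, total / nsup,
                                                      NA_real_),
                                  n_support = nsup)),
    class = "error_decomposition")
}
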