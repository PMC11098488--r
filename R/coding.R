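# The coding space: each 16-unit subsample is summarised by three numbers —
# mean pairwise correlation, pattern entropy, and the KLD of its fitted
# pairwise maximum-entropy model — and populations are compared or decoded in
# that 3-D feature space.

#' Per-subsample coding features for one session
#'
#' Draws `n_subsamples` random `k`-unit subsamples and, for each, computes the
#' mean pairwise correlation of the z-scored count traces, the pattern
#' entropy (mode-tagged), and the KLD between the empirical pattern
#' distribution and its fitted pairwise maximum-entropy model. Subsamples
#' whose maximum-entropy fit does not converge are dropped with a message.
#'
#' @param session a `session_recording` with more than `k` units.
#' @param k subsample size, default 16.
#' @param n_subsamples number of subsamples.
#' @param bin_width pattern/correlation bin width (s), default 0.010.
#' @param entropy_mode normalisation mode passed to [normalized_entropy()].
#' @param seed RNG seed.
#' @return data frame with one row per retained subsample: `session`,
#'   `subsample`, `mean_correlation`, `entropy`, `kld`, `group`, `region`.
#' @export
coding_features <- function(session, k = 16, n_subsamples, bin_width = 0.010,
                            entropy_mode = "entropy_rate", seed = NULL) {
  raster <- binarize(session, bin_width)
  traces <- zscored_rate_traces(session, window = bin_width)
  sub <- draw_subsamples(raster, k = k, n_subsamples = n_subsamples, seed = seed)
  md <- session$metadata
  rows <- vector("list", n_subsamples)
  for (s in seq_len(n_subsamples)) {
    idx <- sub$indices[[s]]
    sub_raster <- sub$rasters[[s]]
    tr <- traces[idx, , drop = FALSE]
    attr(tr, "valid") <- attr(traces, "valid")[idx]
    cm <- tryCatch(correlation_matrix(tr), error = function(e) NULL)
    if (is.null(cm)) { message("subsample ", s, ": too few valid traces; dropped"); next }
    mean_r <- mean(cm[upper.tri(cm)], na.rm = TRUE)
    dist <- pattern_distribution(sub_raster)
    ent <- normalized_entropy(dist, mean_population_rate = raster_mean_rate(sub_raster),
                              bin_width = bin_width, mode = entropy_mode)
    kld <- tryCatch({
      model <- fit_pairwise_maxent(dist)
      kld_on_support(dist, model_distribution(model))
    }, popcoding_nonconvergence = function(e) {
      message("subsample ", s, ": maxent fit not converged; dropped"); NA_real_
    })
    if (is.na(kld)) next
    rows[[s]] <- data.frame(
      session = md$session_id %||% NA_character_, subsample = s,
      mean_correlation = mean_r, entropy = ent$value, kld = kld,
      group = md$group %||% NA_character_, region = md$region %||% NA_character_)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "entropy_mode") <- entropy_mode
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble per-subsample feature rows across sessions
#'
#' Binds per-session feature tables (from [coding_features()]) into one table,
#' dropping rows with any missing feature or label (logged).
#'
#' @param feature_list list of data frames as returned by [coding_features()].
#' @return one combined data frame.
#' @export
session_feature_vectors <- function(feature_list) {
  out <- do.call(rbind, feature_list)
  need <- c("mean_correlation", "entropy", "kld")
  ok <- stats::complete.cases(out[, need])
  if (any(!ok)) message(sum(!ok), " subsample rows dropped (incomplete features)")
  out <- out[ok, , drop = FALSE]
  if (anyNA(out$group) || anyNA(out$region)) stop("group/region labels missing")
  rownames(out) <- NULL
  out
}

knn_predict <- function(train_x, train_lab, test_x, k) {
  # squared Euclidean distances, test x train
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * test_x %*% t(train_x)
  apply_rows <- function(i) {
    ord <- order(d2[i, ])
    nn <- train_lab[ord[seq_len(k)]]
    tab <- table(nn)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else nn[nn %in% top][1]  # nearest tied label
  }
  vapply(seq_len(nrow(test_x)), apply_rows, character(1))
}

#' k-nearest-neighbour decoding of group/region identity with a shuffle null
#'
#' Classifies subsample feature triplets by the majority label of their 5
#' nearest training neighbours (Euclidean distance; ties broken by the nearest
#' tied neighbour). The data are split 80/20 into training and test sets,
#' stratified by class, and the split is repeated `n_iter` times; a null
#' distribution is built by shuffling the training labels in each iteration.
#' Features are z-scored with training-set statistics before distances are
#' computed (toggleable), so the KLD's small numeric scale is not swamped.
#'
#' @param features data frame from [session_feature_vectors()].
#' @param task `"4-way"` (group x region), `"2-way-control"` (region within
#'   the control group) or `"2-way-model"` (region within the model group).
#' @param k neighbours, default 5.
#' @param train_frac training fraction, default 0.8.
#' @param n_iter split repetitions, default 100.
#' @param standardize z-score features on training statistics, default TRUE.
#' @param seed RNG seed.
#' @return object of class `decoder_result`: data frame `iteration`,
#'   `accuracy`, `null_accuracy`; attributes `task`, `classes`.
#' @export
knn_decoder_cv <- function(features, task = c("4-way", "2-way-control",
                                              "2-way-model"),
                           k = 5, train_frac = 0.8, n_iter = 100,
                           standardize = TRUE, seed = NULL) {
  task <- match.arg(task)
  f <- switch(task,
    "4-way" = features,
    "2-way-control" = features[features$group == "control", , drop = FALSE],
    "2-way-model" = features[features$group == "model", , drop = FALSE])
  lab <- if (task == "4-way") paste(f$group, f$region) else f$region
  x <- as.matrix(f[, c("mean_correlation", "entropy", "kld")])
  classes <- sort(unique(lab))
  if (min(table(lab)) < k + 1) stop("too few points per class for k = ", k)
  with_seed(seed, {
    acc <- null_acc <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      train <- unlist(lapply(classes, function(cl) {
        i <- which(lab == cl)
        sample(i, max(1L, round(train_frac * length(i))))
      }))
      test <- setdiff(seq_along(lab), train)
      xtr <- x[train, , drop = FALSE]
      xte <- x[test, , drop = FALSE]
      if (standardize) {
        mu <- colMeans(xtr); sdv <- apply(xtr, 2, stats::sd)
        sdv[sdv == 0] <- 1
        xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
        xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
      }
      acc[it] <- mean(knn_predict(xtr, lab[train], xte, k) == lab[test])
      null_acc[it] <- mean(knn_predict(xtr, sample(lab[train]), xte, k) ==
                             lab[test])
    }
    structure(data.frame(iteration = seq_len(n_iter), accuracy = acc,
                         null_accuracy = null_acc),
              task = task, classes = classes, class = c("decoder_result",
                                                        "data.frame"))
  })
}

#' Bootstrap test for equality of firing-rate variances
#'
#' Test statistic is the ratio of sample variances `var(A)/var(B)`. Both
#' groups are resampled with replacement `n_boot` times; the p-value is the
#' proportion of bootstrap ratios exceeding 1, and the null (ratio = 1) is
#' rejected at the two-sided 5% level when `p < 0.025` or `p > 0.975`.
#' Bootstrap draws in which group B has zero variance are redrawn (counted).
#'
#' @param rates_A,rates_B numeric vectors (Hz), each of length >= 2.
#' @param n_boot bootstrap resamples, default 10000.
#' @param seed RNG seed.
#' @return object of class `variance_test_result`: list with `ratio`
#'   (empirical), `ci` (2.5/97.5 percentiles of bootstrap ratios), `p`,
#'   `reject`, `n_boot`, `n_redrawn`.
#' @export
variance_ratio_bootstrap <- function(rates_A, rates_B, n_boot = 10000,
                                     seed = NULL) {
  nA <- length(rates_A); nB <- length(rates_B)
  stopifnot(nA >= 2, nB >= 2)
  with_seed(seed, {
    draw <- function(m) {
      A <- matrix(rates_A[sample.int(nA, nA * m, replace = TRUE)], nrow = nA)
      B <- matrix(rates_B[sample.int(nB, nB * m, replace = TRUE)], nrow = nB)
      col_vars(A) / col_vars(B)
    }
    ratios <- draw(n_boot)
    n_redrawn <- 0L
    while (any(bad <- !is.finite(ratios))) {
      n_redrawn <- n_redrawn + sum(bad)
      ratios[bad] <- draw(sum(bad))
    }
    p <- mean(ratios > 1)
    structure(
      list(ratio = stats::var(rates_A) / stats::var(rates_B),
           ci = stats::quantile(ratios, c(0.025, 0.975), names = FALSE),
           p = p, reject = p < 0.025 || p > 0.975, n_boot = n_boot,
           n_redrawn = n_redrawn),
      class = "variance_test_result")
  })
}
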