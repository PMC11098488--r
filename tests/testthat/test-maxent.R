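# Pairwise maximum-entropy fitting, model distributions, KLD and the
# coactivity-resolved error decomposition.

test_that("independent data yield zero couplings and logistic fields", {
  n <- 4
  p <- c(0.1, 0.2, 0.3, 0.15)
  S <- enumerate_patterns(n)
  probs <- apply(S, 1, function(s) prod(ifelse(s == 1, p, 1 - p)))
  d <- new_pattern_distribution(0:(2^n - 1), probs, n)
  m <- fit_pairwise_maxent(d)
  expect_true(all(abs(m$J) < 1e-4))
  expect_equal(plogis(m$h), p, tolerance = 1e-5)
  expect_true(m$diagnostics$converged)
})

test_that("any full-support 2-unit distribution is fitted exactly", {
  set.seed(111)
  for (rep in 1:5) {
    pr <- runif(4) + 0.05
    pr <- pr / sum(pr)
    d <- new_pattern_distribution(0:3, pr, 2)
    m <- fit_pairwise_maxent(d)
    pred <- model_distribution(m)
    expect_equal(pred$probs, d$probs, tolerance = 1e-6)
    expect_lt(kld_on_support(d, pred), 1e-6)
  }
})

test_that("parameters are recovered from Gibbs-sampled data", {
  set.seed(112)
  n <- 6
  h <- rnorm(n, -2, 0.5)
  J <- matrix(0, n, n)
  J[upper.tri(J)] <- rnorm(choose(n, 2), 0, 0.3)
  J <- J + t(J)
  ras <- sample_ising_raster(h, J, 1e5, seed = 113)
  m <- fit_pairwise_maxent(pattern_distribution(ras))
  expect_lt(max(abs(m$h - h)), 0.15)
  expect_lt(max(abs(m$J - J)), 0.15)
})

test_that("moment matching holds to 1e-6 after every fit", {
  set.seed(114)
  ras <- sample_ising_raster(rnorm(8, -2, 0.5), n_bins = 2e4, seed = 115)
  d <- pattern_distribution(ras)
  m <- fit_pairwise_maxent(d)
  mod <- enumeration_moments(m$h, m$J)
  emp_mean <- rowMeans(ras)
  emp_pairs <- tcrossprod(unclass(ras)) / ncol(ras)
  expect_lt(max(abs(mod$mean - emp_mean)), 1e-6)
  ut <- upper.tri(emp_pairs)
  expect_lt(max(abs(mod$pairs[ut] - emp_pairs[ut])), 1e-6)
})

test_that("model distributions are normalised and stable", {
  m0 <- fit_pairwise_maxent(new_pattern_distribution(0:7, rep(1/8, 8), 3))
  pred <- model_distribution(m0)
  expect_equal(pred$probs, rep(1/8, 8), tolerance = 1e-8)

  # single unit: P(active) = logistic(h)
  d1 <- new_pattern_distribution(c(0, 1), c(0.7, 0.3), 1)
  m1 <- fit_pairwise_maxent(d1)
  expect_equal(plogis(m1$h), 0.3, tolerance = 1e-7)

  # extreme parameters do not overflow
  big <- structure(list(h = c(300, -300, 5), J = matrix(0, 3, 3), logZ = 0,
                        active = 1:3, n_units = 3,
                        diagnostics = list()), class = "maxent_model")
  pd <- model_distribution(big)
  expect_equal(sum(pd$probs), 1, tolerance = 1e-12)
  expect_false(anyNA(pd$probs))
})

test_that("always-silent units are excluded and re-inserted as zeros", {
  set.seed(116)
  ras <- sample_ising_raster(c(-2, -2, -2), n_bins = 3000, seed = 117)
  ras[2, ] <- 0L    # force a silent unit
  d <- pattern_distribution(ras)
  m <- fit_pairwise_maxent(d)
  expect_identical(m$h[2], -Inf)
  pred <- model_distribution(m)
  # no pattern with unit 2 active gets probability mass
  pc2 <- (pred$codewords %/% 2) %% 2
  expect_true(all(pc2 == 0))
  expect_equal(sum(pred$probs), 1, tolerance = 1e-12)
  expect_lt(kld_on_support(d, pred), 0.2)
})

test_that("KLD anchors: identity, parity, non-negativity", {
  d <- new_pattern_distribution(0:3, c(.4, .3, .2, .1), 2)
  expect_equal(kld_on_support(d, d), 0)

  # uniform on the even-parity patterns of 3 units: pairwise moments match
  # independence at 1/2, so the fitted model is uniform over all 8 patterns
  parity <- new_pattern_distribution(c(0, 3, 5, 6), rep(1/4, 4), 3)
  m <- fit_pairwise_maxent(parity)
  pred <- model_distribution(m)
  expect_equal(pred$probs, rep(1/8, 8), tolerance = 1e-5)
  expect_equal(kld_on_support(parity, pred), 1.0, tolerance = 1e-5)

  set.seed(118)
  for (rep in 1:100) {
    p1 <- runif(8) + 0.01; p1 <- p1 / sum(p1)
    p2 <- runif(8) + 0.01; p2 <- p2 / sum(p2)
    expect_gte(kld_on_support(new_pattern_distribution(0:7, p1, 3),
                              new_pattern_distribution(0:7, p2, 3)), 0)
  }
})

test_that("fitted model entropy is never below the empirical entropy", {
  set.seed(119)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    h <- rnorm(n, -1.5, 0.6)
    J <- matrix(0, n, n)
    J[upper.tri(J)] <- rnorm(choose(n, 2), 0, 0.4)
    J <- J + t(J)
    ras <- sample_ising_raster(h, J, 2e4, seed = 120 + rep)
    d <- pattern_distribution(ras)
    m <- fit_pairwise_maxent(d)
    pred <- model_distribution(m)
    expect_gte(-sum(pred$probs * log2(pred$probs)),
               -sum(d$probs * log2(d$probs)) - 1e-9)
  }
})

test_that("error decomposition follows the stated arithmetic", {
  # single pattern: |0.02 - 0.01| / 0.01 = 1
  emp <- new_pattern_distribution(c(0, 1), c(0.01, 0.99), 1)
  pred <- new_pattern_distribution(c(0, 1), c(0.02, 0.98), 1)
  dec <- error_decomposition(emp, pred)
  expect_equal(dec$per_pattern$error[dec$per_pattern$codeword == 0], 1)

  # perfect model: all totals zero
  d <- new_pattern_distribution(0:3, c(.4, .3, .2, .1), 2)
  dec0 <- error_decomposition(d, d)
  expect_true(all(dec0$by_category$total_error == 0))
  expect_equal(dec0$kld, 0)

  # parity example: error concentrated in popcount categories 0 and 2,
  # each pattern contributing |1/8 - 1/4| / (1/4) = 0.5
  parity <- new_pattern_distribution(c(0, 3, 5, 6), rep(1/4, 4), 3)
  m <- fit_pairwise_maxent(parity)
  decp <- error_decomposition(parity, model_distribution(m))
  bc <- decp$by_category
  expect_equal(bc$total_error[bc$coactive == 0], 0.5, tolerance = 1e-4)
  expect_equal(bc$total_error[bc$coactive == 2], 1.5, tolerance = 1e-4)
  expect_equal(bc$mean_error[bc$coactive == 2], 0.5, tolerance = 1e-4)
  expect_equal(bc$total_error[bc$coactive == 1], 0)
  expect_true(is.na(bc$mean_error[bc$coactive == 1]))
  expect_equal(bc$n_support, c(1, 0, 3, 0))
})
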