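# Synthetic-session generators: behaviour, Ising raster sampling, spiking.

test_that("simulate_behavior hits the requested running fraction and regime", {
  beh <- simulate_behavior(600, mean_run_speed = 5, run_fraction = 0.1,
                           seed = 11)
  expect_true(abs(mean(beh$velocity > 5) - 0.1) < 0.03)
  expect_true(all(beh$velocity >= 0))
  expect_true(all(beh$position >= 0 & beh$position < 190))
  expect_identical(beh$locomotion, beh$velocity > 5)
  # running speed sits in the 5-7 cm/s regime
  expect_true(mean(beh$velocity[beh$locomotion]) < 7)
})

test_that("simulate_behavior is deterministic and validates inputs", {
  a <- simulate_behavior(120, 5, 0.2, seed = 3)
  b <- simulate_behavior(120, 5, 0.2, seed = 3)
  expect_identical(a, b)
  expect_error(simulate_behavior(-1, 5, 0.1), "positive")
  expect_error(simulate_behavior(100, 0, 0.1), "positive")
  expect_error(simulate_behavior(100, 5, 0), "strictly")
  expect_error(simulate_behavior(100, 5, 1), "strictly")
})

test_that("vanishing run fraction gives a single immobile bout", {
  beh <- simulate_behavior(300, 5, 1e-6, seed = 5)
  expect_true(all(beh$velocity == 0))
  expect_true(all(beh$position == beh$position[1]))
})

test_that("uncoupled zero-field sampler is uniform over patterns", {
  ras <- sample_ising_raster(h = rep(0, 3), n_bins = 1e5, seed = 21)
  d <- pattern_distribution(ras)
  expect_equal(length(d$probs), 8)
  expect_true(all(abs(d$probs - 1 / 8) < 0.01))
})

test_that("uncoupled sampler matches the logistic closed form", {
  ras <- sample_ising_raster(h = rep(-5, 4), n_bins = 2e5, seed = 22)
  p_hat <- rowMeans(ras)
  expect_true(all(abs(p_hat - plogis(-5)) < 0.003))
})

test_that("coupled 2-unit sampler matches 4-state brute-force moments", {
  J <- matrix(c(0, 2, 2, 0), 2)
  ras <- sample_ising_raster(h = c(-1, -1), J = J, n_bins = 2e5, seed = 23)
  oracle <- two_unit_moments(-1, -1, 2)
  expect_lt(abs(mean(ras[1, ] * ras[2, ]) - oracle$q), 0.01)
  expect_lt(abs(mean(ras[1, ]) - oracle$m1), 0.01)
})

test_that("Gibbs moments match enumeration within 3 SE up to 12 units", {
  set.seed(31)
  n <- 12
  h <- rnorm(n, -2, 0.5)
  J <- matrix(0, n, n)
  J[upper.tri(J)] <- rbinom(choose(n, 2), 1, 0.2) * rnorm(choose(n, 2), 0, 0.4)
  J <- J + t(J)
  n_bins <- 5e4
  ras <- sample_ising_raster(h, J, n_bins, seed = 32)
  mom <- enumeration_moments(h, J)
  se <- sqrt(mom$mean * (1 - mom$mean) / n_bins)
  # thinning leaves residual autocorrelation; 3 SE with a small safety factor
  expect_true(all(abs(rowMeans(ras) - mom$mean) < 3.5 * se + 1e-3))
})

test_that("sampler validates couplings and determinism holds", {
  Jbad <- matrix(c(0, 1, 0, 0), 2)
  expect_error(sample_ising_raster(c(0, 0), Jbad, 10), "symmetric")
  a <- sample_ising_raster(c(-1, -1), n_bins = 100, seed = 4)
  b <- sample_ising_raster(c(-1, -1), n_bins = 100, seed = 4)
  expect_identical(a, b)
})

test_that("simulate_session reproduces ground-truth rates within 5%", {
  beh <- simulate_behavior(1200, 5, 0.1, seed = 41)
  gt <- ground_truth(unit_rates = rep(4, 16), seed = 42)
  ses <- simulate_session(gt, beh, seed = 43)
  rates <- vapply(ses$units, function(u) length(u$spike_times), numeric(1)) /
    ses$duration
  expect_true(all(abs(rates - 4) < 0.2))
  expect_identical(ses$metadata$seed, 43)
})

test_that("place-field units concentrate spikes at the field centre", {
  beh <- simulate_behavior(900, 5, 0.3, seed = 44)
  gt <- ground_truth(unit_rates = c(5, 5),
                     place_fields = data.frame(unit = 1, center_bin = 55,
                                               width_bins = 4, peak_gain = 10),
                     seed = 45)
  ses <- simulate_session(gt, beh, seed = 46)
  map <- compute_rate_map(ses$units[[1]]$spike_times, beh, smooth_width = 1)
  expect_lte(abs(which.max(map$lambda_raw) - 55), 2)
  map_s <- compute_rate_map(ses$units[[1]]$spike_times, beh, smooth_width = 5)
  expect_lte(abs(which.max(map_s$lambda_x) - 55), 2)
})

test_that("zero-rate units give empty trains; bad durations are rejected", {
  beh <- simulate_behavior(60, 5, 0.1, seed = 47)
  gt <- ground_truth(unit_rates = c(0, 2), seed = 48)
  ses <- simulate_session(gt, beh, seed = 49)
  expect_length(ses$units[[1]]$spike_times, 0)
  expect_error(simulate_session(gt, beh, duration = 120), "behaviour trace")
})

test_that("ground_truth derives rates from couplings by enumeration", {
  h <- c(-3, -2)
  gt <- ground_truth(h = h, seed = 50)
  mom <- enumeration_moments(h, matrix(0, 2, 2))
  expect_equal(gt$unit_rates, mom$mean / 0.010)
  beh <- simulate_behavior(600, 5, 0.1, seed = 51)
  ses <- simulate_session(gt, beh, seed = 52)
  rates <- vapply(ses$units, function(u) length(u$spike_times), numeric(1)) / 600
  expect_true(all(abs(rates - gt$unit_rates) / gt$unit_rates < 0.05))
})

test_that("LFP generator places ripples in immobility with 1 s gaps", {
  beh <- simulate_behavior(300, 5, 0.1, seed = 53)
  gt <- ground_truth(unit_rates = 3, seed = 54)
  sim <- simulate_lfp_with_swrs(300, fs = 1250, ripple_rate = 0.08,
                                behavior = beh, gt = gt,
                                seed = 55)
  ev <- sim$ripple_events
  expect_true(all(diff(ev$start) > 1))
  expect_true(all(ev$end - ev$start >= 0.030 & ev$end - ev$start <= 0.100))
  beh_idx <- findInterval(ev$start, beh$time)
  expect_true(all(!beh$locomotion[beh_idx]))
  expect_error(
    simulate_lfp_with_swrs(60, fs = 1250, ripple_rate = 3, ripple_amp = 10,
                           behavior = simulate_behavior(60, 5, 0.1, seed = 1),
                           gt = gt, seed = 2),
    "too high")
})
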