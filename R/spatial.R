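#' Compute an occupancy-normalised spatial rate map
#'
#' The track is divided into `n_bins` bins (default 111 over 190 cm, ~1.7 cm
#' each). Only behaviour samples with velocity strictly above `velocity_min`
#' contribute, both to occupancy and to spike assignment; spikes are assigned
#' to the behaviour sample at or before their time. The per-bin rate is spike
#' count divided by occupancy time, then smoothed by convolution with a
#' `smooth_width`-bin square wave (truncated and renormalised at the track
#' ends). Bins never visited at running speed are `NA` and excluded from the
#' information sum, with occupancy renormalised over the visited bins.
#'
#' @param spike_times numeric vector of spike times (s).
#' @param behavior a `behavior_trace` covering the spikes.
#' @param n_bins number of spatial bins, default 111.
#' @param velocity_min locomotion threshold (cm/s), default 5; strict.
#' @param smooth_width boxcar width in bins, default 5; 1 disables smoothing.
#' @return object of class `rate_map`: list with `p_x` (occupancy probability,
#'   `NA` for unvisited bins, sums to 1 over visited bins), `lambda_x`
#'   (smoothed rate, Hz), `lambda_raw` (pre-smoothing rate), `lambda_bar`
#'   (occupancy-weighted mean rate), `occupancy_s`, `n_bins`, `smooth_width`.
#'   `NULL` with a warning if the animal never ran.
#' @export
compute_rate_map <- function(spike_times, behavior, n_bins = 111,
                             velocity_min = 5, smooth_width = 5) {
  fs <- attr(behavior, "fs")
  track_length <- attr(behavior, "track_length")
  bin_cm <- track_length / n_bins
  run <- behavior$velocity > velocity_min
  if (!any(run)) {
    warning("no samples above the velocity threshold; map undefined")
    return(NULL)
  }
  pos_bin <- pmin(floor(behavior$position / bin_cm) + 1L, n_bins)
  occ_counts <- tabulate(pos_bin[run], nbins = n_bins)
  occupancy_s <- occ_counts / fs

  # spike -> behaviour sample at or before the spike
  si <- findInterval(spike_times, behavior$time)
  si <- si[si >= 1L]
  si <- si[run[si]]
  spike_counts <- tabulate(pos_bin[si], nbins = n_bins)

  visited <- occ_counts > 0L
  lambda_raw <- ifelse(visited, spike_counts / occupancy_s, NA_real_)
  lambda_x <- boxcar_smooth(lambda_raw, smooth_width)
  p_x <- ifelse(visited, occ_counts / sum(occ_counts), NA_real_)
  lambda_bar <- sum(p_x[visited] * lambda_x[visited])
  structure(
    list(p_x = p_x, lambda_x = lambda_x, lambda_raw = lambda_raw,
         lambda_bar = lambda_bar, occupancy_s = occupancy_s,
         n_bins = n_bins, smooth_width = smooth_width),
    class = "rate_map"
  )
}

#' Skaggs spatial information of a rate map, in bits per spike
#'
#' `I = sum_x p_x (lambda_x / lambda) log2(lambda_x / lambda)` over visited
#' bins, where `p_x` is the occupancy probability of bin `x`, `lambda_x` the
#' firing rate there and `lambda` the occupancy-weighted mean rate. Bins with
#' zero rate contribute zero; maps with zero mean rate are undefined.
#'
#' @param map a `rate_map`.
#' @return spatial information in bits/spike (>= 0), or `NA` if the unit never
#'   fired at running speed.
#' @export
spatial_information <- function(map) {
  if (is.null(map)) return(NA_real_)
  ok <- !is.na(map$p_x)
  p <- map$p_x[ok]
  lam <- map$lambda_x[ok]
  lbar <- map$lambda_bar
  if (!is.finite(lbar) || lbar <= 0) return(NA_real_)
  rel <- lam / lbar
  terms <- ifelse(lam > 0, p * rel * log2(rel), 0)
  max(sum(terms), 0)
}

#' Circular-shuffle null distribution for spatial information
#'
#' Each shuffle shifts all of a unit's spikes by one uniform random offset and
#' wraps them modulo the recording duration, preserving the spike count and
#' inter-spike structure while destroying the spike-position relationship; the
#' rate map and spatial information are then recomputed.
#'
#' @param spike_times spike times (s).
#' @param duration recording duration (s).
#' @param behavior a `behavior_trace`.
#' @param n_shuffles number of shuffles, default 100.
#' @param seed RNG seed.
#' @param ... passed to [compute_rate_map()].
#' @return object of class `spatial_info_result`: list with `info` (empirical
#'   bits/spike), `null_infos` (length `n_shuffles`), `percentile` (fraction of
#'   null values strictly below the empirical value), `n_spikes`.
#' @export
circular_shuffle_null <- function(spike_times, duration, behavior,
                                  n_shuffles = 100, seed = NULL, ...) {
  stopifnot(duration > 0)
  emp <- spatial_information(compute_rate_map(spike_times, behavior, ...))
  null_infos <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      shifted <- (spike_times + stats::runif(1, 0, duration)) %% duration
      spatial_information(compute_rate_map(shifted, behavior, ...))
    }, numeric(1))
  })
  structure(
    list(info = emp, null_infos = null_infos,
         percentile = mean(null_infos < emp, na.rm = TRUE),
         n_spikes = length(spike_times)),
    class = "spatial_info_result"
  )
}

#' Split-half spatial stability score
#'
#' Pearson correlation between the smoothed rate maps computed from the two
#' halves of a session; undefined (NA) when either half has zero rate
#' variance across bins.
#'
#' @param map_first,map_second `rate_map`s from the two session halves, on the
#'   same bins.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
stability_score <- function(map_first, map_second) {
  if (is.null(map_first) || is.null(map_second)) return(NA_real_)
  stopifnot(map_first$n_bins == map_second$n_bins)
  ok <- !is.na(map_first$lambda_x) & !is.na(map_second$lambda_x)
  a <- map_first$lambda_x[ok]
  b <- map_second$lambda_x[ok]
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Per-unit spatial summary for a session
#'
#' Convenience driver: rate map, spatial information, circular-shuffle null
#' and split-half stability for every unit of a session.
#'
#' @param session a `session_recording`.
#' @param n_shuffles shuffles per unit, default 100.
#' @param seed RNG seed.
#' @param ... passed to [compute_rate_map()].
#' @return data frame with one row per unit: `unit_id`, `info`, `null_mean`,
#'   `null_p95`, `percentile`, `stability`.
#' @export
spatial_summary <- function(session, n_shuffles = 100, seed = NULL, ...) {
  beh <- session$behavior
  half <- session$duration / 2
  fs <- attr(beh, "fs")
  first <- beh[beh$time < half, , drop = FALSE]
  second <- beh[beh$time >= half, , drop = FALSE]
  second$time <- second$time - half
  attr(first, "fs") <- fs; attr(first, "track_length") <- attr(beh, "track_length")
  attr(second, "fs") <- fs; attr(second, "track_length") <- attr(beh, "track_length")
  rows <- lapply(session$units, function(u) {
    res <- circular_shuffle_null(u$spike_times, session$duration, beh,
                                 n_shuffles = n_shuffles, seed = seed, ...)
    st1 <- u$spike_times[u$spike_times < half]
    st2 <- u$spike_times[u$spike_times >= half] - half
    stab <- stability_score(compute_rate_map(st1, first, ...),
                            compute_rate_map(st2, second, ...))
    data.frame(unit_id = as.character(u$unit_id), info = res$info,
               null_mean = mean(res$null_infos, na.rm = TRUE),
               null_p95 = stats::quantile(res$null_infos, 0.95, na.rm = TRUE,
                                          names = FALSE),
               percentile = res$percentile, stability = stab)
  })
  do.call(rbind, rows)
}
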