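# Sharp-wave/ripple (SWR) detection and peri-event statistics. SWRs are brief
# 150-250 Hz LFP oscillations occurring mainly during immobility; detection
# thresholds band-limited multichannel power, and unit modulation is assessed
# against circular-shuffle nulls.

#' Detect sharp-wave/ripple epochs from multichannel LFP
#'
#' Each channel is band-pass filtered (zero-phase, default 150-250 Hz),
#' squared, and summed across channels; the summed power is smoothed with a
#' Gaussian kernel (sd 4 ms, width 32 ms) and thresholded at the mean plus
#' `threshold` standard deviations. Each contiguous supra-threshold run is a
#' candidate epoch (end = last sample above threshold). Candidates shorter
#' than `min_dur`, overlapping locomotion (any behaviour sample with velocity
#' above 5 cm/s), or starting within `refractory` of the previous kept
#' epoch's end (the earlier event is kept) are eliminated. Because the
#' threshold is expressed in SD units, detection is invariant to a global LFP
#' gain.
#'
#' @param lfp numeric matrix, samples x channels.
#' @param fs sampling rate (Hz), at least twice the upper band edge.
#' @param behavior optional `behavior_trace` for the locomotion exclusion.
#' @param band band edges (Hz), default `c(150, 250)`.
#' @param smooth_sigma,smooth_width Gaussian smoothing of the power trace, in
#'   seconds; defaults 0.004 and 0.032.
#' @param threshold detection threshold in SDs above the mean, default 2.
#' @param min_dur minimum epoch duration (s), default 0.015.
#' @param refractory minimum gap after the previous epoch's end (s), default 1.
#' @return object of class `swr_event_set`: list with `events` (data frame
#'   `start`, `end`, `duration`, seconds), `abundance` (events/s),
#'   `power_mean`, `power_sd`, `threshold_value`, and the parameters used.
#' @export
detect_swrs <- function(lfp, fs, behavior = NULL, band = c(150, 250),
                        smooth_sigma = 0.004, smooth_width = 0.032,
                        threshold = 2, min_dur = 0.015, refractory = 1) {
  if (!is.matrix(lfp)) lfp <- matrix(lfp, ncol = 1)
  if (fs < 2 * band[2]) stop("fs must be at least twice the upper band edge")
  n <- nrow(lfp)
  power <- numeric(n)
  for (ch in seq_len(ncol(lfp))) {
    power <- power + fft_bandpass(lfp[, ch], fs, band[1], band[2])^2
  }
  power <- gaussian_smooth(power, sigma = smooth_sigma * fs,
                           width = smooth_width * fs)
  mu <- mean(power); sdev <- stats::sd(power)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0))
  if (sdev == 0) {
    warning("flat LFP: zero power variance, no events detectable")
    return(structure(list(events = empty, abundance = 0, power_mean = mu,
                          power_sd = sdev, threshold_value = NA_real_,
                          params = list(band = band, threshold = threshold,
                                        min_dur = min_dur,
                                        refractory = refractory)),
                     class = "swr_event_set"))
  }
  thr <- mu + threshold * sdev
  above <- power > thr
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- c(1L, utils::head(ends_i, -1L) + 1L)
  keep <- which(r$values)
  ev <- data.frame(start = (starts_i[keep] - 1L) / fs, end = ends_i[keep] / fs)
  ev$duration <- ev$end - ev$start
  ev <- ev[ev$duration >= min_dur, , drop = FALSE]
  if (!is.null(behavior) && nrow(ev)) {
    loco <- vapply(seq_len(nrow(ev)), function(i) {
      sel <- behavior$time >= ev$start[i] & behavior$time <= ev$end[i]
      any(behavior$velocity[sel] > 5)
    }, logical(1))
    ev <- ev[!loco, , drop = FALSE]
  }
  if (nrow(ev) > 1) {
    kept <- 1L
    last_end <- ev$end[1]
    for (i in 2:nrow(ev)) {
      if (ev$start[i] - last_end > refractory) {
        kept <- c(kept, i)
        last_end <- ev$end[i]
      }
    }
    ev <- ev[kept, , drop = FALSE]
  }
  rownames(ev) <- NULL
  structure(
    list(events = ev, abundance = nrow(ev) / (n / fs), power_mean = mu,
         power_sd = sdev, threshold_value = thr,
         params = list(band = band, threshold = threshold, min_dur = min_dur,
                       refractory = refractory)),
    class = "swr_event_set")
}

#' @export
print.swr_event_set <- function(x, ...) {
  cat(sprintf("<swr_event_set> %d events (%.3f /s)\n", nrow(x$events),
              x$abundance))
  invisible(x)
}

event_starts <- function(events) {
  if (inherits(events, "swr_event_set")) events$events$start
  else if (is.data.frame(events)) events$start
  else as.numeric(events)
}

# binned counts of spike times relative to each event start, summed over events
peri_counts <- function(spikes_sorted, starts, window, bin) {
  nb <- as.integer(round(2 * window / bin))
  counts <- integer(nb)
  lo <- findInterval(starts - window, spikes_sorted)
  hi <- findInterval(starts + window - 1e-12, spikes_sorted)
  for (e in seq_along(starts)) {
    if (hi[e] > lo[e]) {
      rel <- spikes_sorted[(lo[e] + 1L):hi[e]] - starts[e]
      b <- floor((rel + window) / bin) + 1L
      b <- b[b >= 1L & b <= nb]
      counts <- counts + tabulate(b, nbins = nb)
    }
  }
  counts
}

#' Peri-SWR time histogram (pSWR-TH)
#'
#' Spike rate as a function of time from event start, from `window` seconds
#' before to `window` seconds after, averaged over events.
#'
#' @param spike_times spike times (s).
#' @param events an `swr_event_set`, data frame with `start`, or numeric onsets.
#' @param window half-window (s), default 0.5.
#' @param bin histogram bin (s), default 0.010.
#' @return list with `time` (bin centres, s, relative to onset), `rate` (Hz),
#'   `counts`, `n_events`.
#' @export
peri_swr_histogram <- function(spike_times, events, window = 0.5, bin = 0.010) {
  starts <- event_starts(events)
  if (!length(starts)) stop("no events")
  counts <- peri_counts(sort(spike_times), starts, window, bin)
  nb <- length(counts)
  centres <- -window + (seq_len(nb) - 0.5) * bin
  list(time = centres, rate = counts / (length(starts) * bin), counts = counts,
       n_events = length(starts))
}

# circularly shift a sorted spike train; result stays sorted
circular_shift <- function(spikes_sorted, offset, duration) {
  w <- spikes_sorted + offset %% duration
  wrap <- w >= duration
  c(w[wrap] - duration, w[!wrap])
}

#' SWR modulation index of a unit with a circular-shuffle null
#'
#' The unit's spike train is circularly shifted `n_shuffles` times (uniform
#' offsets modulo the session duration) and a mean shuffled pSWR-TH computed.
#' The modulation index is the summed squared difference between the empirical
#' and mean-shuffled histograms over the `stat_window` (default 0-200 ms after
#' onset). A unit is significantly modulated when its index exceeds the 95th
#' percentile of the per-shuffle indices; the sign of the extremal deviation in
#' the window gives the modulation class, and the lag is the time of the
#' pSWR-TH extremum relative to event onset.
#'
#' @param spike_times spike times (s).
#' @param events events as in [peri_swr_histogram()].
#' @param duration session duration (s).
#' @param n_shuffles default 500.
#' @param stat_window window for the index, seconds from onset; default
#'   `c(0, 0.2)`.
#' @param window,bin histogram parameters as in [peri_swr_histogram()].
#' @param seed RNG seed.
#' @return object of class `modulation_result`: list with `mi`, `log10_mi`,
#'   `null_p95`, `percentile`, `class` (`positive`/`negative`/`non-modulated`),
#'   `lag` (s, `NA` for non-modulated), `psth` (empirical), `psth_null_mean`.
#' @export
swr_modulation <- function(spike_times, events, duration, n_shuffles = 500,
                           stat_window = c(0, 0.2), window = 0.5, bin = 0.010,
                           seed = NULL) {
  starts <- event_starts(events)
  if (!length(starts)) stop("no events")
  spikes <- sort(spike_times)
  emp <- peri_swr_histogram(spikes, starts, window, bin)
  nb <- length(emp$counts)
  if (!length(spikes)) {
    return(structure(list(mi = 0, log10_mi = -Inf, null_p95 = NA_real_,
                          percentile = NA_real_, class = "non-modulated",
                          lag = NA_real_, psth = emp,
                          psth_null_mean = rep(0, nb)),
                     class = "modulation_result"))
  }
  shuf_rates <- with_seed(seed, {
    offs <- stats::runif(n_shuffles, 0, duration)
    vapply(offs, function(o) {
      peri_counts(circular_shift(spikes, o, duration), starts, window, bin) /
        (length(starts) * bin)
    }, numeric(nb))
  })
  null_mean <- rowMeans(shuf_rates)
  centres <- emp$time
  in_win <- centres >= stat_window[1] & centres < stat_window[2]
  mi <- sum((emp$rate[in_win] - null_mean[in_win])^2)
  null_mi <- colSums((shuf_rates[in_win, , drop = FALSE] - null_mean[in_win])^2)
  p95 <- stats::quantile(null_mi, 0.95, names = FALSE)
  significant <- mi > p95
  if (significant) {
    dev <- emp$rate[in_win] - null_mean[in_win]
    cls <- if (dev[which.max(abs(dev))] > 0) "positive" else "negative"
    lag <- centres[if (cls == "positive") which.max(emp$rate) else
      which.min(emp$rate)]
  } else {
    cls <- "non-modulated"
    lag <- NA_real_
  }
  structure(
    list(mi = mi, log10_mi = log10(mi), null_p95 = p95,
         percentile = mean(null_mi < mi), class = cls, lag = lag,
         psth = emp, psth_null_mean = null_mean),
    class = "modulation_result")
}

#' Pairwise correlations inside versus outside SWR epochs
#'
#' Builds two concatenated spike-train sets of equal total duration: one from
#' the `epoch` seconds following each SWR onset, one from an equal number of
#' randomly placed SWR-free intervals (non-overlapping with each other and
#' with any event), then computes the same z-scored count correlations on
#' both.
#'
#' @param session a `session_recording`.
#' @param events events as in [peri_swr_histogram()] (needs `start`/`end`).
#' @param epoch interval length (s), default 0.5.
#' @param bin correlation bin width (s), default 0.010.
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling budget per interval, default 1000.
#' @return list with `swr` and `non_swr` correlation matrices, `mean_swr`,
#'   `mean_non_swr`, and `intervals` (the sampled SWR-free starts).
#' @export
epoch_correlation_comparison <- function(session, events, epoch = 0.5,
                                         bin = 0.010, seed = NULL,
                                         max_attempts = 1000) {
  ev <- if (inherits(events, "swr_event_set")) events$events else events
  if (!nrow(ev)) stop("no SWR events: nothing to compare")
  n_ev <- nrow(ev)
  duration <- session$duration
  with_seed(seed, {
    ctrl <- numeric(0)
    overlaps <- function(s, a, b) any(s < b & s + epoch > a)
    for (i in seq_len(n_ev)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        s <- stats::runif(1, 0, duration - epoch)
        if (!overlaps(s, ev$start, ev$end) &&
            (!length(ctrl) || !overlaps(s, ctrl, ctrl + epoch))) {
          ctrl <- c(ctrl, s); placed <- TRUE; break
        }
      }
      if (!placed) {
        stop("insufficient SWR-free time: placed ", length(ctrl), " of ",
             n_ev, " control intervals")
      }
    }
    corr_of <- function(starts) {
      nb_per <- round(epoch / bin)
      nb <- nb_per * length(starts)
      counts <- matrix(0L, nrow = n_units(session), ncol = nb)
      for (u in seq_len(n_units(session))) {
        st <- sort(session$units[[u]]$spike_times)
        for (e in seq_along(starts)) {
          lo <- findInterval(starts[e], st)
          hi <- findInterval(starts[e] + epoch - 1e-12, st)
          if (hi > lo) {
            rel <- st[(lo + 1L):hi] - starts[e]
            b <- floor(rel / bin) + 1L
            b <- b[b >= 1L & b <= nb_per] + (e - 1L) * nb_per
            counts[u, ] <- counts[u, ] + tabulate(b, nbins = nb)
          }
        }
      }
      valid <- apply(counts, 1, function(x) stats::var(x) > 0)
      if (sum(valid) < 2) stop("fewer than 2 active units in an epoch set")
      z <- counts
      z[valid, ] <- t(scale(t(counts[valid, , drop = FALSE])))
      structure(z, valid = valid) |> correlation_matrix()
    }
    swr_cm <- corr_of(ev$start)
    ctrl_cm <- corr_of(sort(ctrl))
    list(swr = swr_cm, non_swr = ctrl_cm,
         mean_swr = mean(swr_cm[upper.tri(swr_cm)], na.rm = TRUE),
         mean_non_swr = mean(ctrl_cm[upper.tri(ctrl_cm)], na.rm = TRUE),
         intervals = sort(ctrl))
  })
}
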