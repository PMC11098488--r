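#' Assemble a ground-truth parameter set for a synthetic session
#'
#' Holds the generating parameters for a simulated recording: per-unit mean
#' rates, optional Ising couplings (field terms `h`, symmetric pairwise terms
#' `J` with zero diagonal), optional place fields, ripple times and per-unit
#' ripple-modulation classes. When couplings are supplied, `unit_rates` is
#' derived from the model's exact-enumeration activation probabilities (one
#' 10 ms bin per pattern), so generated spike trains match it by construction.
#'
#' @param unit_rates per-unit mean firing rates (Hz); ignored (recomputed) when
#'   `h` is supplied.
#' @param h optional per-unit field terms (dimensionless).
#' @param J optional symmetric coupling matrix, zero diagonal.
#' @param place_fields optional data frame with columns `unit`, `center_bin`,
#'   `width_bins`, `peak_gain` (track of `n_track_bins` bins).
#' @param modulation data frame with columns `unit`, `class`
#'   (`positive`/`negative`/`none`), `gain`; default all `none`.
#' @param trough_to_peak per-unit waveform trough-to-peak (ms); default draws
#'   a 2:1 excitatory/inhibitory bimodal mixture.
#' @param n_track_bins spatial bins on the track, default 111.
#' @param bin_width pattern bin width (s) used to convert Ising activation
#'   probabilities to rates, default 0.010.
#' @param seed RNG seed for the trough-to-peak draw.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(unit_rates = NULL, h = NULL, J = NULL,
                         place_fields = NULL, modulation = NULL,
                         trough_to_peak = NULL, n_track_bins = 111,
                         bin_width = 0.010, seed = NULL) {
  if (is.null(unit_rates) && is.null(h)) {
    stop("supply unit_rates or Ising fields h")
  }
  if (!is.null(h)) {
    n <- length(h)
    if (is.null(J)) J <- matrix(0, n, n)
    check_coupling(h, J)
    m <- enumeration_moments(h, J)
    unit_rates <- m$mean / bin_width
  } else {
    n <- length(unit_rates)
    if (any(unit_rates < 0)) stop("rates must be >= 0")
  }
  if (is.null(modulation)) {
    modulation <- data.frame(unit = seq_len(n), class = "none", gain = 1)
  }
  stopifnot(all(modulation$class %in% c("positive", "negative", "none")))
  if (is.null(trough_to_peak)) {
    trough_to_peak <- with_seed(seed, {
      exc <- stats::runif(n) < 2 / 3
      ifelse(exc, stats::rnorm(n, 0.75, 0.08), stats::rnorm(n, 0.30, 0.05))
    })
    trough_to_peak <- pmax(trough_to_peak, 0.15)
  }
  structure(
    list(n_units = n, unit_rates = unit_rates, h = h, J = J,
         place_fields = place_fields, modulation = modulation,
         trough_to_peak = trough_to_peak, n_track_bins = n_track_bins,
         bin_width = bin_width, ripple_times = NULL),
    class = "ground_truth"
  )
}

check_coupling <- function(h, J) {
  n <- length(h)
  if (!is.matrix(J) || any(dim(J) != n)) stop("J must be n x n")
  if (max(abs(J - t(J))) > 1e-12) stop("J must be symmetric")
  if (any(abs(diag(J)) > 1e-12)) stop("J must have zero diagonal")
  invisible(TRUE)
}

#' Simulate a head-fixed virtual-track behaviour trace
#'
#' Alternates immobility and running bouts (gamma-distributed durations) on a
#' 190 cm one-dimensional virtual track; position integrates velocity and
#' teleports to 0 at the end of each lap. Running speed per bout is drawn
#' just above the nominal speed so that the fraction of samples flagged as
#' locomotion (velocity > 5 cm/s) tracks `run_fraction`. Defaults emulate a
#' regime of roughly 10% time spent running at 5-6 cm/s.
#'
#' @param duration session length (s), > 0.
#' @param mean_run_speed nominal running speed (cm/s), > 0; default 5.
#' @param run_fraction target fraction of time spent running, in (0,1);
#'   default 0.1.
#' @param fs behaviour sampling rate (Hz), default 50.
#' @param track_length virtual track length (cm), default 190.
#' @param seed RNG seed.
#' @return a `behavior_trace` data frame with columns `time` (s), `position`
#'   (cm in `[0, track_length)`), `velocity` (cm/s, >= 0), `locomotion`
#'   (logical, velocity > 5 cm/s); attributes `fs`, `track_length`.
#' @export
simulate_behavior <- function(duration, mean_run_speed = 5, run_fraction = 0.1,
                              fs = 50, track_length = 190, seed = NULL) {
  if (duration <= 0) stop("duration must be positive")
  if (mean_run_speed <= 0) stop("mean_run_speed must be positive")
  if (run_fraction <= 0 || run_fraction >= 1) {
    stop("run_fraction must lie strictly in (0, 1)")
  }
  with_seed(seed, {
    n <- floor(duration * fs)
    tt <- (seq_len(n) - 1L) / fs
    mean_run <- 2                                   # s per running bout
    mean_immobile <- mean_run * (1 - run_fraction) / run_fraction
    running <- logical(n)
    t_cur <- 0
    state <- FALSE                                  # start immobile
    while (t_cur < duration) {
      m <- if (state) mean_run else mean_immobile
      len <- stats::rgamma(1, shape = 4, scale = m / 4)
      i0 <- floor(t_cur * fs) + 1L
      i1 <- min(n, floor((t_cur + len) * fs))
      if (i1 >= i0) running[i0:i1] <- state
      t_cur <- t_cur + len
      state <- !state
    }
    velocity <- numeric(n)
    # per-bout speed slightly above nominal; keeps flagged samples > threshold
    r <- rle(running)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (b in seq_along(r$values)) {
      if (r$values[b]) {
        velocity[starts[b]:ends[b]] <-
          mean_run_speed * stats::runif(1, 1.05, 1.35)
      }
    }
    position <- cumsum(velocity / fs) %% track_length
    out <- data.frame(time = tt, position = position, velocity = velocity,
                      locomotion = velocity > 5)
    attr(out, "fs") <- fs
    attr(out, "track_length") <- track_length
    class(out) <- c("behavior_trace", "data.frame")
    out
  })
}

#' Exact moments of a pairwise maximum-entropy model by enumeration
#'
#' @param h field terms; `length(h) <= 24`.
#' @param J symmetric coupling matrix, zero diagonal.
#' @return list with `mean` (per-unit activation probability), `pairs`
#'   (n x n matrix of coactivation probabilities) and `probs` (full 2^n
#'   pattern distribution, codeword order).
#' @export
enumeration_moments <- function(h, J) {
  check_coupling(h, J)
  S <- enumerate_patterns(length(h))
  logp <- as.vector(S %*% h + 0.5 * rowSums((S %*% J) * S))
  logp <- logp - logsumexp(logp)
  p <- exp(logp)
  list(mean = as.vector(crossprod(S, p)),
       pairs = crossprod(S, p * S),
       probs = p)
}

#' Gibbs-sample a binary raster from a pairwise maximum-entropy model
#'
#' Samples columns of a units-by-bins raster from the Ising family
#' `P(sigma) = exp(sum h_i sigma_i + 1/2 sum_{i!=j} J_ij sigma_i sigma_j)/Z`
#' by single-site Gibbs sweeps. Empirical first and second moments converge to
#' the exact-enumeration moments of `(h, J)` as `n_bins` grows; with `J = 0`
#' units are independent Bernoulli with `p_i = plogis(h_i)`.
#'
#' @param h per-unit field terms; at most 24 units.
#' @param J symmetric coupling matrix with zero diagonal.
#' @param n_bins number of columns to retain.
#' @param burn_in discarded initial sweeps, default 100.
#' @param thin full sweeps between retained columns, default 5.
#' @param seed RNG seed.
#' @return a `binned_raster` (units x bins, 0/1) with `bin_width` 0.010.
#' @export
sample_ising_raster <- function(h, J = NULL, n_bins, burn_in = 100, thin = 5,
                                seed = NULL) {
  n <- length(h)
  if (n > 24) stop("at most 24 units supported for Ising sampling")
  if (is.null(J)) J <- matrix(0, n, n)
  check_coupling(h, J)
  stopifnot(n_bins >= 1)
  m <- with_seed(seed, gibbs_ising(as.numeric(h), J, as.integer(n_bins),
                                   as.integer(burn_in), as.integer(thin)))
  rownames(m) <- as.character(seq_len(n))
  structure(m, bin_width = 0.010, t0 = 0, class = c("binned_raster", "matrix"))
}

place_field_gain <- function(pos_bin, center_bin, width_bins, peak_gain) {
  1 + (peak_gain - 1) * exp(-(pos_bin - center_bin)^2 / (2 * width_bins^2))
}

#' Simulate a full spiking session from ground truth
#'
#' Two generation modes. Without couplings, each unit is an inhomogeneous
#' Poisson process: base rate `unit_rates[i]`, multiplied during locomotion by
#' a Gaussian place-field gain profile (if the unit has one), and renormalised
#' so that the session-mean rate equals the ground-truth rate. With couplings
#' (`h` present in the ground truth), 10 ms binary patterns are Gibbs-sampled
#' from the Ising model and one spike is placed uniformly inside each active
#' bin; rates are then the model's enumeration rates (stored in the ground
#' truth by construction).
#'
#' @param gt a [ground_truth()] object.
#' @param behavior a `behavior_trace` covering the session.
#' @param duration session length (s); must not exceed the behaviour trace.
#'   Default: full behaviour duration.
#' @param seed RNG seed, recorded in the session metadata.
#' @param metadata extra metadata entries (e.g. `group`, `region`).
#' @return a [session_recording()].
#' @export
simulate_session <- function(gt, behavior, duration = NULL, seed = NULL,
                             metadata = list()) {
  stopifnot(inherits(gt, "ground_truth"))
  fs <- attr(behavior, "fs")
  beh_dur <- nrow(behavior) / fs
  if (is.null(duration)) duration <- beh_dur
  if (duration > beh_dur + 1e-9) {
    stop("duration exceeds the behaviour trace (", round(beh_dur, 1), " s)")
  }
  n <- gt$n_units
  track_length <- attr(behavior, "track_length")
  bin_cm <- track_length / gt$n_track_bins
  with_seed(seed, {
    units <- vector("list", n)
    if (!is.null(gt$h)) {
      n_bins <- floor(duration / gt$bin_width)
      raster <- gibbs_ising(gt$h, gt$J, n_bins, 100L, 5L)
      for (i in seq_len(n)) {
        act <- which(raster[i, ] == 1L)
        st <- sort((act - 1L + stats::runif(length(act))) * gt$bin_width)
        units[[i]] <- spike_train(i, st, gt$trough_to_peak[i])
      }
    } else {
      keep <- behavior$time < duration
      tt <- behavior$time[keep]
      dt <- 1 / fs
      pos_bin <- pmin(floor(behavior$position[keep] / bin_cm) + 1,
                      gt$n_track_bins)
      loco <- behavior$locomotion[keep]
      for (i in seq_len(n)) {
        r <- gt$unit_rates[i]
        if (r <= 0) {
          units[[i]] <- spike_train(i, numeric(0), gt$trough_to_peak[i])
          next
        }
        gain <- rep(1, length(tt))
        pf <- gt$place_fields
        if (!is.null(pf) && i %in% pf$unit) {
          row <- pf[pf$unit == i, ][1, ]
          g <- place_field_gain(pos_bin, row$center_bin, row$width_bins,
                                row$peak_gain)
          gain[loco] <- g[loco]
        }
        rate <- r * gain / mean(gain)
        counts <- stats::rpois(length(tt), rate * dt)
        idx <- rep.int(seq_along(tt), counts)
        st <- sort(tt[idx] + stats::runif(length(idx)) * dt)
        st <- st[st < duration]
        units[[i]] <- spike_train(i, st, gt$trough_to_peak[i])
      }
    }
    md <- utils::modifyList(list(seed = seed), metadata)
    session_recording(units, duration, behavior = behavior, metadata = md)
  })
}

#' Simulate multichannel LFP with sharp-wave/ripple bursts
#'
#' Background is Gaussian 1/f noise (power spectral exponent 1) on every
#' channel; ripple events are 150-250 Hz sinusoid bursts of 30-100 ms duration
#' under a Tukey envelope (Hann-shaped 8 ms on/off ramps, sustained plateau),
#' placed only during immobility with inter-event gaps of at least 1 s. The
#' cosine ramps keep the onset free of filter ringing while rising fast enough
#' that threshold-crossing detection recovers onsets to within a few
#' milliseconds. Spike trains are generated from the ground truth with
#' positively modulated units firing at `rate * gain` and negatively modulated
#' units at `rate / gain` inside the 200 ms window after each burst onset.
#'
#' @param duration session length (s).
#' @param fs LFP sampling rate (Hz), >= 1000.
#' @param n_channels number of LFP channels, default 4.
#' @param ripple_rate target event rate (events/s).
#' @param ripple_amp burst amplitude relative to the unit-SD broadband
#'   background; the default 4 is 15-20x the 150-250 Hz in-band noise SD,
#'   a strong but physiological ripple.
#' @param behavior a `behavior_trace` for the session.
#' @param gt a [ground_truth()] giving unit rates and modulation classes.
#' @param seed RNG seed.
#' @return list with `session` (a [session_recording()] carrying the LFP),
#'   `ripple_events` (data frame `start`, `end` in s) and `fs`.
#' @export
simulate_lfp_with_swrs <- function(duration, fs = 1250, n_channels = 4,
                                   ripple_rate = 0.1, ripple_amp = 4,
                                   behavior, gt, seed = NULL) {
  if (fs < 1000) stop("fs must be at least 1000 Hz")
  n_events <- round(ripple_rate * duration)
  with_seed(seed, {
    beh_fs <- attr(behavior, "fs")
    immobile <- !behavior$locomotion
    # candidate onsets: immobile samples at least 1.2 s from any run sample
    ok <- immobile
    guard <- round(1.2 * beh_fs)
    run_idx <- which(!immobile)
    for (i in run_idx) {
      ok[max(1, i - guard):min(length(ok), i + guard)] <- FALSE
    }
    cand_t <- behavior$time[ok]
    cand_t <- cand_t[cand_t > 1 & cand_t < duration - 1]
    if (!length(cand_t)) stop("no immobile time available for ripple placement")
    onsets <- numeric(0)
    pool <- sort(cand_t)
    for (e in seq_len(n_events)) {
      avail <- pool[vapply(pool, function(tt)
        !length(onsets) || min(abs(tt - onsets)) > 1.2, logical(1))]
      if (!length(avail)) {
        stop("ripple_rate too high for the 1 s inter-event gap constraint: ",
             "placed ", length(onsets), " of ", n_events, " events")
      }
      onsets <- c(onsets, sample(avail, 1))
    }
    onsets <- sort(onsets)
    durs <- stats::runif(n_events, 0.030, 0.100)
    freqs <- stats::runif(n_events, 150, 250)

    n_samp <- floor(duration * fs)
    lfp <- matrix(0, nrow = n_samp, ncol = n_channels)
    # 1/f Gaussian background, per channel
    f <- (seq_len(n_samp) - 1) / n_samp * fs
    f <- pmin(f, fs - f)
    shape <- ifelse(f > 0, 1 / sqrt(f), 0)
    for (ch in seq_len(n_channels)) {
      w <- stats::fft(stats::rnorm(n_samp))
      x <- Re(stats::fft(w * shape, inverse = TRUE)) / n_samp
      lfp[, ch] <- x / stats::sd(x)
    }
    for (e in seq_len(n_events)) {
      i0 <- floor(onsets[e] * fs) + 1L
      len <- round(durs[e] * fs)
      i1 <- min(n_samp, i0 + len - 1L)
      idx <- i0:i1
      # Tukey envelope: Hann-shaped 8 ms ramps with a sustained plateau, so
      # onset is smooth (no filter ringing) yet sharp enough for +-5 ms
      # detection timing
      ramp_n <- min(round(0.008 * fs), floor(length(idx) / 2))
      env <- rep(1, length(idx))
      up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
      env[seq_len(ramp_n)] <- up
      env[length(idx) + 1 - seq_len(ramp_n)] <- up
      burst <- ripple_amp * env *
        sin(2 * pi * freqs[e] * (idx - i0) / fs)
      lfp[idx, ] <- lfp[idx, ] + burst
    }

    # modulated spiking: piecewise-constant rate at behaviour resolution
    n <- gt$n_units
    tt <- behavior$time[behavior$time < duration]
    dt <- 1 / beh_fs
    in_win <- rep(FALSE, length(tt))
    for (on in onsets) in_win[tt >= on & tt < on + 0.200] <- TRUE
    units <- vector("list", n)
    for (i in seq_len(n)) {
      r <- gt$unit_rates[i]
      cls <- gt$modulation$class[gt$modulation$unit == i][1]
      g <- gt$modulation$gain[gt$modulation$unit == i][1]
      rate <- rep(r, length(tt))
      if (identical(cls, "positive")) rate[in_win] <- r * g
      if (identical(cls, "negative")) rate[in_win] <- r / g
      counts <- stats::rpois(length(tt), rate * dt)
      idx <- rep.int(seq_along(tt), counts)
      st <- sort(tt[idx] + stats::runif(length(idx)) * dt)
      st <- st[st < duration]
      units[[i]] <- spike_train(i, st, gt$trough_to_peak[i])
    }
    session <- session_recording(units, duration, behavior = behavior,
                                 lfp = lfp, lfp_fs = fs,
                                 metadata = list(seed = seed))
    list(session = session,
         ripple_events = data.frame(start = onsets, end = onsets + durs),
         fs = fs)
  })
}
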