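#' Construct a spike train
#'
#' @param unit_id unique unit identifier (integer or character).
#' @param spike_times numeric vector of spike times in seconds, sorted ascending.
#' @param trough_to_peak waveform trough-to-peak time in ms (`NA` if unknown).
#' @param probe_xy optional length-2 numeric, approximate probe coordinates (um).
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(unit_id, spike_times, trough_to_peak = NA_real_,
                        probe_xy = NULL) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) {
    stop("spike_times must be non-decreasing for unit ", unit_id)
  }
  if (!is.na(trough_to_peak) && trough_to_peak <= 0) {
    stop("trough_to_peak must be positive (ms)")
  }
  structure(
    list(unit_id = unit_id, spike_times = spike_times,
         trough_to_peak = trough_to_peak, probe_xy = probe_xy),
    class = "spike_train"
  )
}

#' Construct a session recording
#'
#' Container for one head-fixed recording session: spike trains, duration,
#' behaviour trace, optional LFP, and metadata (group label `control`/`model`,
#' region label `dorsal`/`ventral`, session id, generator seed).
#'
#' @param units list of [spike_train()] objects with unique ids.
#' @param duration session duration (s); all spikes must lie in `[0, duration)`.
#' @param behavior a `behavior_trace` data frame (see [simulate_behavior()]).
#' @param lfp optional samples-by-channels numeric matrix.
#' @param lfp_fs LFP sampling rate (Hz), required when `lfp` is given.
#' @param metadata named list; recognised entries `group`, `region`,
#'   `session_id`, `seed`.
#' @return an object of class `session_recording`.
#' @export
session_recording <- function(units, duration, behavior = NULL, lfp = NULL,
                              lfp_fs = NULL, metadata = list()) {
  ids <- vapply(units, function(u) as.character(u$unit_id), character(1))
  if (anyDuplicated(ids)) stop("unit ids must be unique")
  for (u in units) {
    if (length(u$spike_times) &&
        (u$spike_times[1] < 0 || u$spike_times[length(u$spike_times)] >= duration)) {
      stop("spike times of unit ", u$unit_id, " fall outside [0, duration)")
    }
  }
  if (!is.null(lfp) && is.null(lfp_fs)) stop("lfp_fs required when lfp is given")
  structure(
    list(units = units, duration = duration, behavior = behavior,
         lfp = lfp, lfp_fs = lfp_fs, metadata = metadata),
    class = "session_recording"
  )
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %d units, %.1f s", length(x$units), x$duration))
  if (!is.null(x$metadata$group)) {
    cat(sprintf(" [%s/%s]", x$metadata$group, x$metadata$region))
  }
  cat(if (is.null(x$lfp)) ", no LFP\n" else
    sprintf(", LFP %d ch @ %g Hz\n", ncol(x$lfp), x$lfp_fs))
  invisible(x)
}

n_units <- function(session) length(session$units)

#' Binarize a session into a units-by-bins 0/1 raster
#'
#' Spiking is discretised into non-overlapping bins of `bin_width` seconds
#' (default 10 ms): a bin is 1 if the unit fired at least one spike in the
#' half-open interval `[t0 + b*dt, t0 + (b+1)*dt)`, else 0. Columns of this
#' raster are the binary activity patterns whose distribution the entropy and
#' maximum-entropy analyses consume.
#'
#' @param session a `session_recording`.
#' @param bin_width bin width in seconds; default 0.010.
#' @param t0 start of the first bin (s); default 0.
#' @return an object of class `binned_raster`: a binary integer matrix
#'   (units x bins) with attributes `bin_width`, `t0`, and rownames the unit
#'   ids.
#' @export
binarize <- function(session, bin_width = 0.010, t0 = 0) {
  stopifnot(bin_width > 0)
  n_bins <- floor((session$duration - t0) / bin_width)
  nu <- n_units(session)
  if (nu == 0L || n_bins <= 0L) {
    warning("empty session: returning empty raster")
    m <- matrix(0L, nrow = nu, ncol = max(n_bins, 0L))
  } else {
    m <- matrix(0L, nrow = nu, ncol = n_bins)
    for (i in seq_len(nu)) {
      st <- session$units[[i]]$spike_times
      st <- st[st >= t0 & st < t0 + n_bins * bin_width]
      if (length(st)) {
        b <- floor((st - t0) / bin_width) + 1L
        m[i, unique(b)] <- 1L
      }
    }
  }
  rownames(m) <- vapply(session$units, function(u) as.character(u$unit_id),
                        character(1))
  structure(m, bin_width = bin_width, t0 = t0, class = c("binned_raster", "matrix"))
}

#' Z-scored sliding-window firing-rate traces
#'
#' Counts spikes of each unit in a sliding window (default 10 ms) advanced by
#' `step` seconds and standardises each unit's count series to zero mean and
#' unit variance. Units whose counts have zero variance are left as all-zero
#' traces and flagged invalid (Pearson correlation is undefined for them).
#'
#' @param session a `session_recording`.
#' @param window window length (s), default 0.010.
#' @param step window step (s); default equal to `window` (non-overlapping).
#' @return numeric matrix units x windows with attribute `valid` (logical per
#'   unit) and `window`, `step`.
#' @export
zscored_rate_traces <- function(session, window = 0.010, step = window) {
  stopifnot(window > 0, step > 0)
  n_win <- floor((session$duration - window) / step) + 1L
  nu <- n_units(session)
  m <- matrix(0, nrow = nu, ncol = n_win)
  valid <- logical(nu)
  starts <- (seq_len(n_win) - 1L) * step
  for (i in seq_len(nu)) {
    st <- sort(session$units[[i]]$spike_times)
    # count spikes in [start, start + window) per window
    counts <- findInterval(starts + window, st, left.open = TRUE) -
      findInterval(starts, st, left.open = TRUE)
    v <- stats::var(counts)
    if (v > 0) {
      m[i, ] <- (counts - mean(counts)) / sqrt(v)
      valid[i] <- TRUE
    }
  }
  rownames(m) <- vapply(session$units, function(u) as.character(u$unit_id),
                        character(1))
  structure(m, valid = valid, window = window, step = step)
}

#' Classify units as excitatory or inhibitory from waveform width
#'
#' Putative excitatory cells have broad waveforms (trough-to-peak over 0.5 ms),
#' putative inhibitory interneurons narrow ones. Trough-to-peak of exactly
#' 0.5 ms is assigned to the inhibitory side; missing values yield `unknown`
#' and such units are excluded from E/I-restricted analyses.
#'
#' @param units list of `spike_train` objects or numeric vector of
#'   trough-to-peak times (ms).
#' @return character vector in `{excitatory, inhibitory, unknown}`.
#' @export
classify_unit_waveforms <- function(units) {
  ttp <- if (is.numeric(units)) units else
    vapply(units, function(u) as.numeric(u$trough_to_peak), numeric(1))
  out <- ifelse(is.na(ttp), "unknown",
                ifelse(ttp > 0.5, "excitatory", "inhibitory"))
  as.character(out)
}

#' Draw random 16-unit subsamples from a raster
#'
#' Repeatedly samples `k` distinct units uniformly without replacement
#' (independently across draws; draws may share units). Sessions must carry
#' strictly more than `k` units to be eligible.
#'
#' @param raster a `binned_raster` (or any units-by-bins matrix).
#' @param k subsample size, default 16.
#' @param n_subsamples number of draws.
#' @param seed RNG seed.
#' @return list with `indices` (list of integer vectors) and `rasters`
#'   (list of k-row sub-matrices).
#' @export
draw_subsamples <- function(raster, k = 16, n_subsamples, seed = NULL) {
  nu <- nrow(raster)
  if (nu <= k) {
    stop("session has ", nu, " units; strictly more than ", k, " required")
  }
  idx <- with_seed(seed, replicate(n_subsamples, sort(sample.int(nu, k)),
                                   simplify = FALSE))
  take <- function(i) {
    m <- raster[i, , drop = FALSE]
    attr(m, "bin_width") <- attr(raster, "bin_width")
    attr(m, "t0") <- attr(raster, "t0")
    class(m) <- class(raster)
    m
  }
  list(indices = idx, rasters = lapply(idx, take))
}
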