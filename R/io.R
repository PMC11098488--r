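# Plain-text session interchange formats: spikes and behaviour as TSV, LFP as
# flat little-endian int16 with a JSON sidecar, and a JSON manifest binding
# the pieces with group/region labels. Spike and behaviour times are written
# at microsecond precision; round-tripping is lossless at that precision.

#' Write a session recording to a directory
#'
#' Produces `spikes.tsv` (`unit_id`, `spike_time_s`), `units.tsv` (`unit_id`,
#' `trough_to_peak_ms`, `x_um`, `y_um`), `behavior.tsv` (`time_s`,
#' `position_cm`, `velocity_cm_s`), optionally `lfp.bin` (channel-major int16)
#' with `lfp.json` (`n_channels`, `fs_hz`, `scale_uV`), and `manifest.json`.
#'
#' @param session a `session_recording`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) sprintf("%.6f", x)
  sp <- do.call(rbind, lapply(session$units, function(u) {
    if (!length(u$spike_times)) return(NULL)
    data.frame(unit_id = u$unit_id, spike_time_s = fmt(u$spike_times))
  }))
  if (is.null(sp)) sp <- data.frame(unit_id = character(0),
                                    spike_time_s = character(0))
  utils::write.table(sp, file.path(dir, "spikes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  un <- do.call(rbind, lapply(session$units, function(u) {
    xy <- u$probe_xy %||% c(NA_real_, NA_real_)
    data.frame(unit_id = u$unit_id, trough_to_peak_ms = u$trough_to_peak,
               x_um = xy[1], y_um = xy[2])
  }))
  utils::write.table(un, file.path(dir, "units.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(session$behavior)) {
    b <- session$behavior
    utils::write.table(
      data.frame(time_s = fmt(b$time), position_cm = fmt(b$position),
                 velocity_cm_s = fmt(b$velocity)),
      file.path(dir, "behavior.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  has_lfp <- !is.null(session$lfp)
  if (has_lfp) {
    scale_uV <- max(abs(session$lfp)) / 32000
    if (scale_uV == 0) scale_uV <- 1
    con <- file(file.path(dir, "lfp.bin"), "wb")
    # channel-major: all samples of channel 1, then channel 2, ...
    writeBin(as.integer(round(as.vector(session$lfp) / scale_uV)), con,
             size = 2, endian = "little")
    close(con)
    jsonlite::write_json(
      list(n_channels = ncol(session$lfp), fs_hz = session$lfp_fs,
           scale_uV = scale_uV),
      file.path(dir, "lfp.json"), auto_unbox = TRUE, digits = NA)
  }
  md <- session$metadata
  jsonlite::write_json(
    list(duration_s = session$duration,
         group = md$group %||% NA, region = md$region %||% NA,
         session_id = md$session_id %||% NA, seed = md$seed %||% NA,
         behavior_fs = if (!is.null(session$behavior))
           attr(session$behavior, "fs") else NA,
         track_length_cm = if (!is.null(session$behavior))
           attr(session$behavior, "track_length") else NA,
         files = c("spikes.tsv", "units.tsv",
                   if (!is.null(session$behavior)) "behavior.tsv",
                   if (has_lfp) c("lfp.bin", "lfp.json"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session recording written by [write_session()]
#'
#' @param dir session directory containing `manifest.json`.
#' @return a `session_recording`.
#' @export
read_session <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  un <- utils::read.table(file.path(dir, "units.tsv"), header = TRUE,
                          sep = "\t", colClasses = c(unit_id = "character"))
  sp <- utils::read.table(file.path(dir, "spikes.tsv"), header = TRUE,
                          sep = "\t", colClasses = c(unit_id = "character"))
  units <- lapply(seq_len(nrow(un)), function(i) {
    st <- sort(as.numeric(sp$spike_time_s[sp$unit_id == un$unit_id[i]]))
    xy <- c(un$x_um[i], un$y_um[i])
    spike_train(un$unit_id[i], st, un$trough_to_peak_ms[i],
                probe_xy = if (all(is.na(xy))) NULL else xy)
  })
  behavior <- NULL
  beh_path <- file.path(dir, "behavior.tsv")
  if (file.exists(beh_path)) {
    b <- utils::read.table(beh_path, header = TRUE, sep = "\t")
    behavior <- data.frame(time = b$time_s, position = b$position_cm,
                           velocity = b$velocity_cm_s,
                           locomotion = b$velocity_cm_s > 5)
    attr(behavior, "fs") <- man$behavior_fs
    attr(behavior, "track_length") <- man$track_length_cm
    class(behavior) <- c("behavior_trace", "data.frame")
  }
  lfp <- NULL; lfp_fs <- NULL
  if (file.exists(file.path(dir, "lfp.bin"))) {
    side <- jsonlite::read_json(file.path(dir, "lfp.json"),
                                simplifyVector = TRUE)
    n16 <- file.size(file.path(dir, "lfp.bin")) / 2
    con <- file(file.path(dir, "lfp.bin"), "rb")
    raw <- readBin(con, "integer", n = n16, size = 2, endian = "little")
    close(con)
    lfp <- matrix(raw * side$scale_uV, ncol = side$n_channels)
    lfp_fs <- side$fs_hz
  }
  na_null <- function(x) if (is.null(x) || all(is.na(x))) NULL else x
  session_recording(
    units, man$duration_s, behavior = behavior, lfp = lfp, lfp_fs = lfp_fs,
    metadata = list(group = na_null(man$group), region = na_null(man$region),
                    session_id = na_null(man$session_id),
                    seed = na_null(man$seed)))
}
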