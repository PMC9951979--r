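#' Nearest-neighbour upsampling
#'
#' Resamples a channel to a higher rate by nearest-neighbour interpolation:
#' the output sample at time `t` copies the input sample whose timestamp is
#' closest to `t`. Used to bring the 128 Hz angular-velocity traces onto the
#' common 200 Hz clock. No new values are introduced.
#'
#' @param ch A [signal_channel()].
#' @param target_fs Target rate in Hz; must be >= `ch$fs`.
#' @return The resampled channel at `target_fs`, duration preserved to within
#'   one output sample.
#' @export
upsample_nearest <- function(ch, target_fs) {
  stopifnot(inherits(ch, "signal_channel"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop("`target_fs` must be a positive rate in Hz", call. = FALSE)
  if (target_fs < ch$fs)
    stop("`target_fs` must be >= the channel's rate; use downsample()",
         call. = FALSE)
  if (target_fs == ch$fs) return(ch)
  n_in <- length(ch$samples)
  n_out <- round(n_in * target_fs / ch$fs)
  t_out <- (seq_len(n_out) - 1) / target_fs
  idx <- pmin(pmax(round(t_out * ch$fs) + 1, 1L), n_in)
  out <- ch
  out$fs <- as.numeric(target_fs)
  out$samples <- ch$samples[idx]
  out
}

#' Integer-factor downsampling by decimation
#'
#' Keeps every `fs/target_fs`-th sample starting at the first. Used to take
#' bandpass-filtered, rectified EMG from 1000 Hz to the common 200 Hz clock;
#' the subsequent 200 ms median smoothing dominates any aliasing the plain
#' decimation could leave.
#'
#' @param ch A [signal_channel()].
#' @param target_fs Target rate; `ch$fs` must be an integer multiple of it.
#' @return The decimated channel.
#' @export
downsample <- function(ch, target_fs) {
  stopifnot(inherits(ch, "signal_channel"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop("`target_fs` must be a positive rate in Hz", call. = FALSE)
  ratio <- ch$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    stop("channel rate must be an integer multiple of `target_fs`",
         call. = FALSE)
  ratio <- as.integer(round(ratio))
  out <- ch
  out$fs <- as.numeric(target_fs)
  out$samples <- ch$samples[seq(1L, length(ch$samples), by = ratio)]
  out
}

#' Align all channels to the first TTL rising edge
#'
#' Both recording devices receive a TTL pulse at trial start; shifting each
#' stream so that its first TTL rising edge sits at `t = 0` synchronizes the
#' EMG and IMU clocks. Samples preceding the TTL edge are dropped.
#'
#' @param rec A [gait_recording()] with known TTL onsets for every stream
#'   that has channels.
#' @return The aligned recording; TTL onsets become 0 and the TTL offsets and
#'   walking bounds are re-expressed on the aligned timeline.
#' @export
align_to_ttl <- function(rec) {
  stopifnot(inherits(rec, "gait_recording"))
  kinds <- unique(vapply(rec$channels, `[[`, character(1), "kind"))
  if (anyNA(rec$ttl_onset_s[kinds]))
    stop("TTL onset unknown for stream(s): ",
         paste(kinds[is.na(rec$ttl_onset_s[kinds])], collapse = ", "),
         call. = FALSE)
  rec$channels <- lapply(rec$channels, function(ch) {
    shift <- rec$ttl_onset_s[[ch$kind]]
    drop <- round(shift * ch$fs)
    if (drop >= length(ch$samples))
      stop("TTL onset beyond extent of channel '", ch$label, "'",
           call. = FALSE)
    if (drop > 0) ch$samples <- ch$samples[-seq_len(drop)]
    ch
  })
  rec$ttl_offset_s <- rec$ttl_offset_s - rec$ttl_onset_s
  rec$ttl_onset_s[] <- 0
  rec
}

#' Crop a recording to the walking period
#'
#' Restricts every channel to the annotated walking on/offset window and
#' re-zeroes the timeline so the crop start becomes `t = 0`. The walking
#' bounds are required metadata; no automatic walk-bout detection is done.
#'
#' @param rec A [gait_recording()] with `walk_start_s`/`walk_end_s` set.
#' @return The cropped recording (walking bounds become `0` and the
#'   walking duration).
#' @export
crop_walking <- function(rec) {
  stopifnot(inherits(rec, "gait_recording"))
  if (is.na(rec$walk_start_s) || is.na(rec$walk_end_s))
    stop("walking bounds are not annotated", call. = FALSE)
  if (rec$walk_start_s < 0)
    stop("walking bounds outside the recording", call. = FALSE)
  rec$channels <- lapply(rec$channels, function(ch) {
    i0 <- round(rec$walk_start_s * ch$fs)
    i1 <- round(rec$walk_end_s * ch$fs)
    if (i1 > length(ch$samples))
      stop("walking bounds outside extent of channel '", ch$label, "'",
           call. = FALSE)
    ch$samples <- ch$samples[(i0 + 1):i1]
    ch
  })
  rec$walk_end_s <- rec$walk_end_s - rec$walk_start_s
  rec$walk_start_s <- 0
  rec
}

#' Restrict an event table to a time window
#'
#' Companion to [crop_walking()]: keeps events inside `[start_s, end_s)` and,
#' if `rezero = TRUE`, expresses the survivors relative to `start_s`.
#'
#' @param events Event table from [gait_events()].
#' @param start_s,end_s Window in seconds.
#' @param rezero Subtract `start_s` from the surviving times.
#' @return The filtered event table.
#' @export
crop_events <- function(events, start_s, end_s, rezero = TRUE) {
  keep <- events$time_s >= start_s & events$time_s < end_s
  out <- events[keep, , drop = FALSE]
  if (rezero) out$time_s <- out$time_s - start_s
  rownames(out) <- NULL
  out
}
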