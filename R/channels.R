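#' Construct a signal channel
#'
#' A `signal_channel` holds one uniformly sampled trace: either a raw/processed
#' surface-EMG channel or a shank angular-velocity trace about the
#' medio-lateral axis. Sample `i` (1-based) is taken at time `(i - 1) / fs`
#' seconds from the channel's own stream origin.
#'
#' @param label Channel label, unique within a recording (e.g. `"LVl"`,
#'   `"RTa"`, `"L_IMU"`).
#' @param side `"left"` or `"right"`.
#' @param kind `"emg"` or `"angular_velocity"`.
#' @param fs Sampling rate in Hz (> 0).
#' @param samples Numeric vector of finite sample values (`NA` allowed only
#'   for prediction outputs at embedding boundaries).
#' @param units Unit string; `"a.u."` for EMG, `"deg/s"` for angular velocity.
#' @param allow_na Permit `NA` samples (used by regression predictions whose
#'   embedding window exits the trial).
#' @return An object of class `signal_channel`.
#' @export
signal_channel <- function(label, side, kind, fs, samples,
                           units = if (kind == "emg") "a.u." else "deg/s",
                           allow_na = FALSE) {
  side <- match.arg(side, c("left", "right"))
  kind <- match.arg(kind, c("emg", "angular_velocity"))
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("`label` must be a non-empty string", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  samples <- as.numeric(samples)
  if (!allow_na && anyNA(samples))
    stop("channel '", label, "' contains missing samples", call. = FALSE)
  if (any(!is.finite(samples) & !is.na(samples)))
    stop("channel '", label, "' contains non-finite samples", call. = FALSE)
  structure(
    list(label = label, side = side, kind = kind, fs = as.numeric(fs),
         samples = samples, units = units),
    class = "signal_channel"
  )
}

#' @export
print.signal_channel <- function(x, ...) {
  cat(sprintf("<signal_channel> %s [%s %s] %g Hz, %d samples (%.2f s), %s\n",
              x$label, x$side, x$kind, x$fs, length(x$samples),
              length(x$samples) / x$fs, x$units))
  invisible(x)
}

#' Duration of a channel in seconds
#' @param ch A `signal_channel`.
#' @return Length of the trace in seconds.
#' @export
channel_duration <- function(ch) length(ch$samples) / ch$fs

#' Sample times of a channel
#' @param ch A `signal_channel`.
#' @return Numeric vector of timestamps in seconds, starting at 0.
#' @export
channel_times <- function(ch) (seq_along(ch$samples) - 1) / ch$fs

#' Construct a synchronized multichannel gait recording
#'
#' Bundles the EMG and angular-velocity channels of one walking trial together
#' with the TTL synchronization marks and the manually annotated walking
#' on/offsets. TTL onsets are given per device stream (EMG amplifier vs IMU)
#' on each stream's own clock; [align_to_ttl()] brings both streams onto a
#' common origin. Walking bounds are interpreted on the TTL-aligned timeline.
#'
#' @param patient_id,trial_id Identifier strings.
#' @param channels List of [signal_channel()] objects with unique labels.
#' @param ttl_onset_s,ttl_offset_s Named numeric vectors with entries `emg`
#'   and `angular_velocity` (a single unnamed value applies to both streams):
#'   rising-edge times of the first/last TTL pulse in seconds on each
#'   device's own clock.
#' @param walk_start_s,walk_end_s Walking-period bounds in seconds on the
#'   TTL-aligned timeline, or `NA` if not yet annotated.
#' @return An object of class `gait_recording`.
#' @export
gait_recording <- function(patient_id, trial_id, channels,
                           ttl_onset_s = 0, ttl_offset_s = NA_real_,
                           walk_start_s = NA_real_, walk_end_s = NA_real_) {
  if (length(channels) == 0L)
    stop("a recording must contain at least one channel", call. = FALSE)
  if (!all(vapply(channels, inherits, logical(1), "signal_channel")))
    stop("`channels` must be a list of signal_channel objects", call. = FALSE)
  labels <- vapply(channels, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  names(channels) <- labels
  av <- Filter(function(ch) ch$kind == "angular_velocity", channels)
  if (length(av) > 0L) {
    sides <- sort(unname(vapply(av, `[[`, character(1), "side")))
    if (length(av) != 2L || !identical(sides, c("left", "right")))
      stop("a recording with angular-velocity channels must have exactly one ",
           "per side", call. = FALSE)
  }
  ttl_onset_s <- .ttl_by_kind(ttl_onset_s)
  ttl_offset_s <- .ttl_by_kind(ttl_offset_s)
  ok <- !is.na(ttl_onset_s) & !is.na(ttl_offset_s)
  if (any(ok & ttl_offset_s <= ttl_onset_s))
    stop("TTL offset must come after TTL onset", call. = FALSE)
  if (any(ttl_onset_s < 0, na.rm = TRUE))
    stop("TTL onset must be >= 0", call. = FALSE)
  if (!is.na(walk_start_s) && !is.na(walk_end_s) && walk_end_s <= walk_start_s)
    stop("walk_end_s must exceed walk_start_s", call. = FALSE)
  structure(
    list(patient_id = as.character(patient_id),
         trial_id = as.character(trial_id),
         channels = channels,
         ttl_onset_s = ttl_onset_s, ttl_offset_s = ttl_offset_s,
         walk_start_s = as.numeric(walk_start_s),
         walk_end_s = as.numeric(walk_end_s)),
    class = "gait_recording"
  )
}

# Normalize a TTL time argument to a named c(emg=, angular_velocity=) vector.
.ttl_by_kind <- function(x) {
  kinds <- c("emg", "angular_velocity")
  if (is.null(x) || (length(x) == 1L && is.null(names(x))))
    return(stats::setNames(rep(as.numeric(x), 2L), kinds))
  out <- stats::setNames(rep(NA_real_, 2L), kinds)
  bad <- setdiff(names(x), kinds)
  if (length(bad)) stop("unknown TTL stream: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out[names(x)] <- as.numeric(x)
  out
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> patient %s, trial %s: %d channels\n",
              x$patient_id, x$trial_id, length(x$channels)))
  for (ch in x$channels) print(ch)
  invisible(x)
}

#' Extract channels of one kind (optionally one side)
#' @param rec A `gait_recording`.
#' @param kind `"emg"` or `"angular_velocity"`.
#' @param side Optional `"left"` or `"right"` filter.
#' @return Named list of matching channels.
#' @export
recording_channels <- function(rec, kind, side = NULL) {
  out <- Filter(function(ch) ch$kind == kind, rec$channels)
  if (!is.null(side)) out <- Filter(function(ch) ch$side == side, out)
  out
}

#' Build a gait-event table
#'
#' Events are kept in an ordinary data frame with columns `leg`
#' (`"left"`/`"right"`), `type` (`"SWP"`, `"HC"`, `"TO"`) and `time_s`
#' (seconds on the trial's common timeline), the same layout used by the
#' on-disk `*.events.csv` files.
#'
#' @param leg,type,time_s Vectors of equal length.
#' @return A validated `data.frame` sorted by leg then time.
#' @export
gait_events <- function(leg = character(), type = character(),
                        time_s = numeric()) {
  leg <- as.character(leg); type <- as.character(type)
  time_s <- as.numeric(time_s)
  stopifnot(length(leg) == length(type), length(type) == length(time_s))
  if (!all(leg %in% c("left", "right")))
    stop("`leg` must be 'left' or 'right'", call. = FALSE)
  if (!all(type %in% c("SWP", "HC", "TO")))
    stop("`type` must be one of SWP, HC, TO", call. = FALSE)
  if (anyNA(time_s) || any(!is.finite(time_s)))
    stop("event times must be finite", call. = FALSE)
  df <- data.frame(leg = leg, type = type, time_s = time_s,
                   stringsAsFactors = FALSE)
  df <- df[order(df$leg, df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  for (l in unique(df$leg)) {
    swp <- df$time_s[df$leg == l & df$type == "SWP"]
    if (any(diff(swp) <= 0))
      stop("SWP times must be strictly increasing per leg", call. = FALSE)
  }
  df
}
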