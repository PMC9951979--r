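#' Preprocessing configuration
#'
#' Collects every tunable of the raw-signal conditioning pipeline. Defaults
#' implement the reference processing chain: EMG is bandpass-filtered
#' (20-450 Hz, 4th-order zero-phase Butterworth -- the standard surface-EMG
#' band), rectified, decimated to 200 Hz, smoothed with a centred 200 ms
#' moving median then a 40 ms moving mean, high-pass corrected by
#' subtracting a 10 s moving minimum, and normalized per recording by
#' subtracting the 1st percentile and dividing by the 95th percentile of the
#' baseline-subtracted trace. IMU angular velocity is upsampled to 200 Hz by
#' nearest neighbour and smoothed with a 100 ms median followed by a 40 ms
#' mean.
#'
#' @param emg_bandpass_hz Length-2 numeric, bandpass corner frequencies (Hz).
#' @param bandpass_order Butterworth order (applied forward-backward).
#' @param emg_target_fs,imu_target_fs Common output rate (Hz).
#' @param imu_median_ms,imu_mean_ms,emg_median_ms,emg_mean_ms Smoothing
#'   window lengths (ms).
#' @param baseline_window_s Moving-minimum window (s) for EMG baseline
#'   removal.
#' @param norm_low_pct,norm_high_pct Percentiles for the EMG amplitude
#'   normalization.
#' @return A `preprocessing_config` list.
#' @export
preprocessing_config <- function(emg_bandpass_hz = c(20, 450),
                                 bandpass_order = 4,
                                 emg_target_fs = 200, imu_target_fs = 200,
                                 imu_median_ms = 100, imu_mean_ms = 40,
                                 emg_median_ms = 200, emg_mean_ms = 40,
                                 baseline_window_s = 10,
                                 norm_low_pct = 1, norm_high_pct = 95) {
  stopifnot(length(emg_bandpass_hz) == 2L, all(emg_bandpass_hz > 0),
            emg_bandpass_hz[1] < emg_bandpass_hz[2],
            emg_target_fs > 0, imu_target_fs > 0,
            imu_median_ms > 0, imu_mean_ms > 0,
            emg_median_ms > 0, emg_mean_ms > 0, baseline_window_s > 0,
            norm_low_pct >= 0, norm_low_pct < norm_high_pct,
            norm_high_pct <= 100)
  structure(as.list(environment()), class = "preprocessing_config")
}

# ---- moving-window primitives ----------------------------------------------
# All centred windows; ms are converted to samples as round(ms * fs / 1000)
# forced odd so the window is exactly centred. At the edges the window
# shrinks symmetrically (no padding).

.window_samples <- function(window_ms, fs) {
  k <- round(window_ms * fs / 1000)
  if (k < 1) stop("window shorter than one sample at this rate",
                  call. = FALSE)
  if (k %% 2 == 0) k <- k + 1
  as.integer(k)
}

.moving_median_vec <- function(x, k) {
  n <- length(x)
  if (k > n) k <- if (n %% 2 == 1L) n else n - 1L  # runmed needs k <= n
  if (k <= 1 || n < 2) return(x)
  out <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  h <- (k - 1L) %/% 2L
  for (i in seq_len(min(h, n))) {
    hh <- min(i - 1L, n - i)
    out[i] <- stats::median(x[(i - hh):(i + hh)])
    j <- n - i + 1L
    hh <- min(j - 1L, n - j)
    out[j] <- stats::median(x[(j - hh):(j + hh)])
  }
  out
}

.moving_mean_vec <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n < 2) return(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  hh <- pmin(h, i - 1L, n - i)
  (cs[i + hh + 1L] - cs[i - hh]) / (2 * hh + 1)
}

.moving_min_vec <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n < 2) return(x)
  h <- (k - 1L) %/% 2L
  i <- seq_len(n)
  hh <- pmin(h, i - 1L, n - i)
  vapply(i, function(j) min(x[(j - hh[j]):(j + hh[j])]), numeric(1))
}

#' Full-wave rectification
#'
#' Replaces an EMG channel's samples by their absolute values.
#'
#' @param ch An EMG [signal_channel()].
#' @return The rectified channel.
#' @export
rectify <- function(ch) {
  stopifnot(inherits(ch, "signal_channel"))
  if (ch$kind != "emg")
    stop("rectification applies to EMG channels only", call. = FALSE)
  ch$samples <- abs(ch$samples)
  ch
}

#' Zero-phase Butterworth bandpass filter
#'
#' Forward-backward (`signal::filtfilt`) Butterworth filtering, so the output
#' is band-limited with no phase distortion.
#'
#' @param ch A [signal_channel()].
#' @param low,high Corner frequencies in Hz, `0 < low < high < fs/2`.
#' @param order Filter order (applied twice by the zero-phase pass).
#' @return Filtered channel, same length and rate.
#' @export
bandpass <- function(ch, low, high, order = 4) {
  stopifnot(inherits(ch, "signal_channel"))
  if (!(low > 0 && low < high && high < ch$fs / 2))
    stop("invalid band: need 0 < low < high < fs/2", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (ch$fs / 2), type = "pass")
  ch$samples <- as.numeric(signal::filtfilt(bf, ch$samples))
  ch
}

#' Centred moving-median filter
#'
#' @param ch A [signal_channel()].
#' @param window_ms Window length in ms (converted to an odd sample count).
#' @return Smoothed channel, same length; the window shrinks symmetrically
#'   at the edges.
#' @export
moving_median <- function(ch, window_ms) {
  stopifnot(inherits(ch, "signal_channel"))
  k <- .window_samples(window_ms, ch$fs)
  ch$samples <- .moving_median_vec(ch$samples, k)
  ch
}

#' Centred moving-mean filter
#' @inheritParams moving_median
#' @return Smoothed channel, same length.
#' @export
moving_mean <- function(ch, window_ms) {
  stopifnot(inherits(ch, "signal_channel"))
  k <- .window_samples(window_ms, ch$fs)
  ch$samples <- .moving_mean_vec(ch$samples, k)
  ch
}

#' Moving-minimum baseline subtraction
#'
#' Subtracts the centred moving minimum (window in seconds) from the signal,
#' acting as a simple high-pass that removes slow baseline drift from EMG
#' envelopes. Wherever the window covers the sample itself the output is
#' nonnegative.
#'
#' @param ch A [signal_channel()].
#' @param window_s Window length in seconds.
#' @return Baseline-corrected channel.
#' @export
subtract_moving_min <- function(ch, window_s) {
  stopifnot(inherits(ch, "signal_channel"))
  if (window_s <= 0) stop("`window_s` must be positive", call. = FALSE)
  k <- .window_samples(window_s * 1000, ch$fs)
  ch$samples <- ch$samples - .moving_min_vec(ch$samples, k)
  ch
}

#' Percentile amplitude normalization
#'
#' Standardizes EMG amplitude scales across patients:
#' `(x - P_low(x)) / P_high(x - P_low(x))`, with percentiles estimated by
#' linear interpolation between order statistics, separately for each channel
#' of each recording.
#'
#' @param ch A [signal_channel()].
#' @param low_pct,high_pct Percentiles (defaults 1 and 95).
#' @return Normalized channel.
#' @export
percentile_normalize <- function(ch, low_pct = 1, high_pct = 95) {
  stopifnot(inherits(ch, "signal_channel"))
  p_low <- stats::quantile(ch$samples, low_pct / 100, names = FALSE, type = 7)
  x <- ch$samples - p_low
  p_high <- stats::quantile(x, high_pct / 100, names = FALSE, type = 7)
  if (!is.finite(p_high) || p_high <= .Machine$double.eps * max(1, abs(p_low)))
    stop("degenerate signal in channel '", ch$label,
         "': high percentile is zero after baseline subtraction",
         call. = FALSE)
  ch$samples <- x / p_high
  ch
}

#' Preprocess a raw recording onto the common 200 Hz timeline
#'
#' Applies the complete conditioning chain. EMG channels: bandpass ->
#' rectify -> decimate to 200 Hz -> 200 ms moving median -> 40 ms moving
#' mean -> subtract 10 s moving minimum -> percentile normalization. IMU
#' channels: nearest-neighbour upsample to 200 Hz -> 100 ms moving median ->
#' 40 ms moving mean. Streams are then aligned to the first TTL rising edge
#' and cropped to the annotated walking period, leaving every channel on a
#' shared 200 Hz clock of equal length.
#'
#' Note the pipeline is not idempotent: re-running it on an already
#' preprocessed recording re-filters and re-normalizes the traces.
#'
#' @param rec A raw [gait_recording()] at native rates with TTL and walking
#'   metadata.
#' @param cfg A [preprocessing_config()].
#' @return The preprocessed recording.
#' @export
preprocess_recording <- function(rec, cfg = preprocessing_config()) {
  stopifnot(inherits(rec, "gait_recording"),
            inherits(cfg, "preprocessing_config"))
  rec$channels <- lapply(rec$channels, function(ch) {
    if (ch$kind == "emg") {
      ch <- bandpass(ch, cfg$emg_bandpass_hz[1], cfg$emg_bandpass_hz[2],
                     order = cfg$bandpass_order)
      ch <- rectify(ch)
      ch <- downsample(ch, cfg$emg_target_fs)
      ch <- moving_median(ch, cfg$emg_median_ms)
      ch <- moving_mean(ch, cfg$emg_mean_ms)
      ch <- subtract_moving_min(ch, cfg$baseline_window_s)
      percentile_normalize(ch, cfg$norm_low_pct, cfg$norm_high_pct)
    } else {
      ch <- upsample_nearest(ch, cfg$imu_target_fs)
      ch <- moving_median(ch, cfg$imu_median_ms)
      moving_mean(ch, cfg$imu_mean_ms)
    }
  })
  rec <- align_to_ttl(rec)
  rec <- crop_walking(rec)
  n <- vapply(rec$channels, function(ch) length(ch$samples), integer(1))
  if (length(unique(n)) > 1L) {
    # rounding at stream boundaries can leave a one-sample length mismatch
    n_min <- min(n)
    if (max(n) - n_min > 1L)
      stop("channel lengths disagree by more than one sample after cropping",
           call. = FALSE)
    rec$channels <- lapply(rec$channels, function(ch) {
      ch$samples <- ch$samples[seq_len(n_min)]
      ch
    })
  }
  rec
}
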