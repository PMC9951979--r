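#' Gait-event extraction configuration
#'
#' Rule set for deriving gait events from a shank angular-velocity trace
#' (medio-lateral axis). Swing-peak (SWP) events are local maxima of at
#' least 150 deg/s amplitude separated by at least 0.7 s. Two consecutive
#' SWP events delimit one gait cycle; heel contact (HC) is the earliest
#' local minimum in the 10--45% sub-interval of the cycle and toe-off (TO)
#' the latest local minimum in the 55--90% sub-interval, falling back to the
#' sub-interval's global minimum when no interior local minimum exists.
#'
#' @param swp_min_height Minimum SWP amplitude (deg/s).
#' @param swp_min_separation_s Minimum inter-peak distance (s).
#' @param hc_window,to_window Length-2 cycle-fraction windows for HC and TO.
#' @param invert_av Negate the trace first (for sensors mounted with the
#'   opposite polarity, where the swing peak is negative).
#' @return An `event_config` list.
#' @export
event_config <- function(swp_min_height = 150, swp_min_separation_s = 0.7,
                         hc_window = c(0.10, 0.45),
                         to_window = c(0.55, 0.90),
                         invert_av = FALSE) {
  stopifnot(swp_min_height > 0, swp_min_separation_s > 0,
            length(hc_window) == 2L, length(to_window) == 2L,
            0 < hc_window[1], hc_window[1] < hc_window[2],
            hc_window[2] <= to_window[1], to_window[1] < to_window[2],
            to_window[2] < 1)
  structure(as.list(environment()), class = "event_config")
}

# Indices of strict local maxima; plateaus resolve to their first sample.
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  # collapse plateaus: compare each sample to the previous distinct value
  # (left) and the next distinct value (right)
  rle_x <- rle(x)
  ends <- cumsum(rle_x$lengths)
  starts <- ends - rle_x$lengths + 1L
  v <- rle_x$values
  m <- length(v)
  if (m < 3L) return(integer())
  inner <- 2:(m - 1L)
  peak <- v[inner] > v[inner - 1L] & v[inner] > v[inner + 1L]
  starts[inner][peak]
}

.local_minima <- function(x) .local_maxima(-x)

#' Detect swing-peak (SWP) events
#'
#' Local maxima with at least `swp_min_height` amplitude; when two
#' candidates fall within the minimum separation, the higher peak is kept
#' (ties resolve to the earlier one).
#'
#' @param av An angular-velocity [signal_channel()].
#' @param cfg An [event_config()].
#' @return Event table ([gait_events()]) of SWP events for `av$side`.
#' @export
detect_swp <- function(av, cfg = event_config()) {
  stopifnot(inherits(av, "signal_channel"),
            av$kind == "angular_velocity")
  x <- av$samples
  if (cfg$invert_av) x <- -x
  x_f <- ifelse(is.na(x), -Inf, x)
  if (sum(!is.na(x)) < 3L)
    stop("signal too short for peak detection", call. = FALSE)
  cand <- .local_maxima(x_f)
  cand <- cand[x_f[cand] >= cfg$swp_min_height]
  # enforce separation: strongest first, earlier wins ties
  cand <- cand[order(-x_f[cand], cand)]
  min_gap <- cfg$swp_min_separation_s * av$fs
  kept <- integer()
  for (i in cand) {
    if (all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  gait_events(rep(av$side, length(kept)), rep("SWP", length(kept)),
              (kept - 1) / av$fs)
}

#' Detect heel-contact and toe-off events within each gait cycle
#'
#' For each cycle between consecutive SWP events, HC is the earliest local
#' minimum in the `hc_window` fraction of the cycle and TO the latest local
#' minimum in the `to_window` fraction; if a sub-interval contains no
#' interior local minimum its global minimum is used instead (for HC the
#' first, for TO the last occurrence of the minimum value). Sub-interval
#' fractions map to samples by rounding toward the interior.
#'
#' @param av Angular-velocity [signal_channel()] the SWP events came from.
#' @param swp SWP event table for the same leg.
#' @param cfg An [event_config()].
#' @return Event table with one HC and one TO per cycle (empty if fewer
#'   than two SWP events).
#' @export
detect_hc_to <- function(av, swp, cfg = event_config()) {
  stopifnot(inherits(av, "signal_channel"))
  swp <- swp[swp$type == "SWP" & swp$leg == av$side, , drop = FALSE]
  if (nrow(swp) < 2L)
    return(gait_events())
  x <- av$samples
  if (cfg$invert_av) x <- -x
  x <- ifelse(is.na(x), Inf, x)  # NA boundary samples never become minima
  fs <- av$fs
  idx_swp <- round(swp$time_s * fs) + 1
  mins <- .local_minima(x)
  pick <- function(i0, i1, window, earliest) {
    span <- i1 - i0
    lo <- i0 + ceiling(window[1] * span)
    hi <- i0 + floor(window[2] * span)
    if (hi < lo) return(NA_integer_)
    local <- mins[mins >= lo & mins <= hi]
    if (length(local) > 0L)
      return(if (earliest) local[1L] else local[length(local)])
    seg <- x[lo:hi]
    if (all(!is.finite(seg))) return(NA_integer_)
    at <- which(seg == min(seg))
    lo + (if (earliest) at[1L] else at[length(at)]) - 1L
  }
  legs <- character(); types <- character(); times <- numeric()
  for (c_i in seq_len(length(idx_swp) - 1L)) {
    i0 <- idx_swp[c_i]; i1 <- idx_swp[c_i + 1L]
    hc <- pick(i0, i1, cfg$hc_window, earliest = TRUE)
    to <- pick(i0, i1, cfg$to_window, earliest = FALSE)
    for (ev in list(c("HC", hc), c("TO", to))) {
      if (!is.na(ev[2])) {
        legs <- c(legs, av$side); types <- c(types, ev[1])
        times <- c(times, (as.integer(ev[2]) - 1) / fs)
      }
    }
  }
  gait_events(legs, types, times)
}

#' Extract all gait events from an angular-velocity trace
#'
#' Convenience wrapper running [detect_swp()] then [detect_hc_to()].
#'
#' @inheritParams detect_swp
#' @return Combined SWP/HC/TO event table for the channel's leg.
#' @export
extract_events <- function(av, cfg = event_config()) {
  swp <- detect_swp(av, cfg)
  hcto <- detect_hc_to(av, swp, cfg)
  gait_events(c(swp$leg, hcto$leg), c(swp$type, hcto$type),
              c(swp$time_s, hcto$time_s))
}

#' Convert HC/TO events into a swing/stance phase series
#'
#' Each HC starts a stance segment lasting to the next TO (exclusive); each
#' TO starts a swing segment lasting to the next HC (exclusive). Samples
#' before the first and after the last defining event are undefined. HC and
#' TO must strictly alternate.
#'
#' @param events Event table for one leg (SWP entries are ignored).
#' @param n_samples Length of the trial on the common clock.
#' @param fs Sampling rate of the clock (Hz).
#' @return A `phase_series`: `labels` (integer vector, 1 = swing,
#'   0 = stance, `NA` = undefined), `defined` (logical), plus `leg` and
#'   `fs`.
#' @export
events_to_phases <- function(events, n_samples, fs = 200) {
  ev <- events[events$type %in% c("HC", "TO"), , drop = FALSE]
  leg <- unique(ev$leg)
  if (length(leg) > 1L)
    stop("phase series is per leg; got events for both", call. = FALSE)
  labels <- rep(NA_integer_, n_samples)
  if (nrow(ev) >= 2L) {
    ev <- ev[order(ev$time_s), , drop = FALSE]
    if (any(ev$type[-1] == ev$type[-nrow(ev)]))
      stop("HC and TO events must alternate", call. = FALSE)
    idx <- pmin(pmax(round(ev$time_s * fs) + 1, 1L), n_samples)
    for (i in seq_len(nrow(ev) - 1L)) {
      lab <- if (ev$type[i] == "HC") 0L else 1L  # stance after HC, swing after TO
      if (idx[i + 1L] > idx[i]) labels[idx[i]:(idx[i + 1L] - 1L)] <- lab
    }
  }
  structure(list(labels = labels, defined = !is.na(labels),
                 leg = if (length(leg)) leg else NA_character_, fs = fs),
            class = "phase_series")
}

#' Gait-cycle summary statistics
#'
#' Cycle durations are successive SWP differences. Cadence is
#' `60000 / median duration (ms)` cycles per minute; variability is the
#' median absolute deviation of durations from their median.
#'
#' @param swp SWP event table for one leg (>= 3 events).
#' @return List with `median_duration_ms`, `cadence_cpm`,
#'   `mad_variability_ms`, `n_cycles`.
#' @export
cycle_statistics <- function(swp) {
  swp <- swp[swp$type == "SWP", , drop = FALSE]
  if (nrow(swp) < 3L)
    stop("need at least three SWP events for cycle statistics",
         call. = FALSE)
  dur_ms <- diff(sort(swp$time_s)) * 1000
  med <- stats::median(dur_ms)
  list(median_duration_ms = med,
       cadence_cpm = 60000 / med,
       mad_variability_ms = stats::median(abs(dur_ms - med)),
       n_cycles = length(dur_ms))
}
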