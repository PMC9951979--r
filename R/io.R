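#' Write a recording to delimited text plus a YAML sidecar
#'
#' Signals go to a UTF-8 comma-delimited file with one header row of channel
#' labels and one column per channel; because raw EMG (1000 Hz) and IMU
#' (128 Hz) columns have different lengths, shorter columns are padded with
#' empty fields and the per-channel sample counts recorded in the sidecar.
#' Values are written with 9 significant digits, so a write/read round trip
#' is lossless at that precision. The sidecar carries patient/trial identity,
#' per-channel metadata (side, kind, fs, units, n_samples), TTL times and
#' walking bounds.
#'
#' @param rec A [gait_recording()].
#' @param signal_file,meta_file Output paths (conventionally `<trial>.csv`
#'   and `<trial>.meta.yaml`).
#' @return Invisibly, the recording.
#' @export
write_recording <- function(rec, signal_file, meta_file) {
  stopifnot(inherits(rec, "gait_recording"))
  chs <- rec$channels
  n <- vapply(chs, function(ch) length(ch$samples), integer(1))
  cols <- lapply(chs, function(ch) {
    v <- formatC(ch$samples, digits = 9, format = "g")
    c(v, rep("", max(n) - length(v)))
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(chs)
  utils::write.table(mat, signal_file, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  meta <- list(
    patient_id = rec$patient_id,
    trial_id = rec$trial_id,
    channels = lapply(chs, function(ch)
      list(side = ch$side, kind = ch$kind, fs = ch$fs, units = ch$units,
           n_samples = length(ch$samples))),
    ttl = list(onset_s = as.list(rec$ttl_onset_s),
               offset_s = as.list(rec$ttl_offset_s)),
    walk = list(start_s = rec$walk_start_s, end_s = rec$walk_end_s)
  )
  yaml::write_yaml(meta, meta_file)
  invisible(rec)
}

#' Read a recording from delimited text plus its YAML sidecar
#'
#' Inverse of [write_recording()]. Every channel listed in the signal
#' header must be described in the sidecar (and vice versa); a mismatch is a
#' format error. Non-finite sample values are a data error.
#'
#' @param signal_file,meta_file Paths written by [write_recording()].
#' @return A validated [gait_recording()].
#' @export
read_recording <- function(signal_file, meta_file) {
  if (!file.exists(signal_file)) stop("signal file not found: ", signal_file,
                                      call. = FALSE)
  if (!file.exists(meta_file)) stop("metadata file not found: ", meta_file,
                                    call. = FALSE)
  meta <- yaml::read_yaml(meta_file)
  dat <- utils::read.csv(signal_file, check.names = FALSE,
                         colClasses = "numeric")
  labels <- colnames(dat)
  meta_labels <- names(meta$channels)
  if (!setequal(labels, meta_labels)) {
    miss <- c(setdiff(labels, meta_labels), setdiff(meta_labels, labels))
    stop("channel labels in signal header and metadata disagree: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  channels <- lapply(labels, function(lb) {
    m <- meta$channels[[lb]]
    if (is.null(m$side) || is.null(m$kind) || is.null(m$fs))
      stop("incomplete metadata for channel '", lb, "'", call. = FALSE)
    x <- dat[[lb]]
    ns <- m$n_samples %||% sum(!is.na(x))
    x <- x[seq_len(ns)]
    if (anyNA(x) || any(!is.finite(x)))
      stop("non-finite samples in channel '", lb, "'", call. = FALSE)
    signal_channel(lb, m$side, m$kind, m$fs, x,
                   units = m$units %||% "a.u.")
  })
  ttl_on <- unlist(meta$ttl$onset_s %||% NA_real_)
  ttl_off <- unlist(meta$ttl$offset_s %||% NA_real_)
  gait_recording(meta$patient_id, meta$trial_id, channels,
                 ttl_onset_s = ttl_on, ttl_offset_s = ttl_off,
                 walk_start_s = meta$walk$start_s %||% NA_real_,
                 walk_end_s = meta$walk$end_s %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a gait-event table
#'
#' Events live in `<trial>.events.csv` with columns `leg,type,time_s`.
#'
#' @param events Event table ([gait_events()] layout).
#' @param file Path to the events CSV.
#' @return `read_events` returns the validated event table; `write_events`
#'   returns it invisibly.
#' @export
write_events <- function(events, file) {
  stopifnot(all(c("leg", "type", "time_s") %in% names(events)))
  utils::write.csv(events[, c("leg", "type", "time_s")], file,
                   row.names = FALSE, quote = FALSE)
  invisible(events)
}

#' @rdname write_events
#' @export
read_events <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  gait_events(df$leg, df$type, df$time_s)
}
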