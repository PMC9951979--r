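#' Pearson correlation over jointly valid samples
#'
#' Product-moment correlation between two channels on the same clock,
#' computed over samples where both are non-missing (regression predictions
#' carry `NA` at embedding boundaries).
#'
#' @param a,b [signal_channel()]s of equal length.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  stopifnot(inherits(a, "signal_channel"), inherits(b, "signal_channel"))
  if (length(a$samples) != length(b$samples))
    stop("channels differ in length", call. = FALSE)
  ok <- !is.na(a$samples) & !is.na(b$samples)
  if (sum(ok) < 2L) stop("fewer than two jointly valid samples",
                         call. = FALSE)
  x <- a$samples[ok]; y <- b$samples[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant signal", call. = FALSE)
  stats::cor(x, y)
}

#' Match predicted against ground-truth events
#'
#' One-to-one matching of events closer than `max_match_distance_ms`,
#' computed as the assignment that maximizes the number of matched pairs
#' and, among those, minimizes the total absolute time difference (a
#' non-crossing dynamic program over the two sorted event lists; on
#' well-separated gait events this coincides with greedy nearest-pair
#' matching). Unmatched true events are misses (false negatives);
#' unmatched predictions are false detections. Displacement is signed
#' predicted-minus-true (positive = late prediction).
#'
#' @param true_ev,pred_ev Event tables of one leg and one type.
#' @param max_match_distance_ms Maximum separation of a matching pair (ms).
#' @return An `event_match` list: `matches` (data frame `true_s`, `pred_s`,
#'   `displacement_ms`), `misses`, `false_detections` (numeric times),
#'   `n_true`, `n_pred`.
#' @export
match_events <- function(true_ev, pred_ev, max_match_distance_ms = 600) {
  both <- rbind(true_ev[, c("leg", "type")], pred_ev[, c("leg", "type")])
  if (nrow(both) > 0 &&
      (length(unique(both$type)) > 1L || length(unique(both$leg)) > 1L))
    stop("event matching requires a single leg and event type",
         call. = FALSE)
  tt <- sort(true_ev$time_s); pp <- sort(pred_ev$time_s)
  n <- length(tt); m <- length(pp)
  tol_s <- max_match_distance_ms / 1000
  # dp over prefixes: an optimal tolerance-gated assignment can always be
  # made non-crossing, so prefix DP attains the global optimum
  card <- matrix(0L, n + 1L, m + 1L)
  cost <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      # skip true i or pred j
      if (card[i, j + 1L] > card[i + 1L, j] ||
          (card[i, j + 1L] == card[i + 1L, j] &&
           cost[i, j + 1L] <= cost[i + 1L, j])) {
        card[i + 1L, j + 1L] <- card[i, j + 1L]
        cost[i + 1L, j + 1L] <- cost[i, j + 1L]
      } else {
        card[i + 1L, j + 1L] <- card[i + 1L, j]
        cost[i + 1L, j + 1L] <- cost[i + 1L, j]
      }
      d <- abs(pp[j] - tt[i])
      if (d < tol_s) {
        c2 <- card[i, j] + 1L
        w2 <- cost[i, j] + d
        if (c2 > card[i + 1L, j + 1L] ||
            (c2 == card[i + 1L, j + 1L] && w2 < cost[i + 1L, j + 1L])) {
          card[i + 1L, j + 1L] <- c2
          cost[i + 1L, j + 1L] <- w2
        }
      }
    }
  }
  # backtrack
  mi <- integer(); mj <- integer()
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    d <- abs(pp[j] - tt[i])
    if (d < tol_s && card[i + 1L, j + 1L] == card[i, j] + 1L &&
        abs(cost[i + 1L, j + 1L] - (cost[i, j] + d)) < 1e-12) {
      mi <- c(i, mi); mj <- c(j, mj)
      i <- i - 1L; j <- j - 1L
    } else if (card[i + 1L, j + 1L] == card[i, j + 1L] &&
               cost[i + 1L, j + 1L] == cost[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  used_t <- logical(n); used_p <- logical(m)
  used_t[mi] <- TRUE; used_p[mj] <- TRUE
  structure(list(
    matches = data.frame(true_s = tt[mi], pred_s = pp[mj],
                         displacement_ms = (pp[mj] - tt[mi]) * 1000),
    misses = tt[!used_t],
    false_detections = pp[!used_p],
    n_true = length(tt), n_pred = length(pp),
    max_match_distance_ms = max_match_distance_ms),
    class = "event_match")
}

#' False-discovery and false-negative rates of an event matching
#'
#' FDR = false detections / total detections; FNR = misses / total true
#' events. A zero denominator yields `NA` (undefined), not an error.
#'
#' @param match An [match_events()] result.
#' @return List with `fdr` and `fnr`.
#' @export
event_rates <- function(match) {
  stopifnot(inherits(match, "event_match"))
  list(
    fdr = if (match$n_pred > 0) length(match$false_detections) / match$n_pred
          else NA_real_,
    fnr = if (match$n_true > 0) length(match$misses) / match$n_true
          else NA_real_)
}

#' F1-score between two swing/stance phase series
#'
#' Sample-wise F1 on the intersection of the defined masks, with swing as
#' the positive class: `F1 = 2 p r / (p + r)` for precision `p` and recall
#' `r`. Also reports the macro average over both classes.
#'
#' @param true_ph,pred_ph [events_to_phases()] series on the same clock.
#' @return List with `f1` (swing-positive), `f1_stance`, `f1_macro`,
#'   `n_samples` (joint defined samples). `f1` is `NA` if the joint mask is
#'   empty.
#' @export
phase_f1 <- function(true_ph, pred_ph) {
  stopifnot(inherits(true_ph, "phase_series"),
            inherits(pred_ph, "phase_series"))
  if (length(true_ph$labels) != length(pred_ph$labels))
    stop("phase series differ in length", call. = FALSE)
  ok <- true_ph$defined & pred_ph$defined
  if (!any(ok))
    return(list(f1 = NA_real_, f1_stance = NA_real_, f1_macro = NA_real_,
                n_samples = 0L))
  t <- true_ph$labels[ok]; p <- pred_ph$labels[ok]
  f1_of <- function(pos) {
    tp <- sum(t == pos & p == pos)
    fp <- sum(t != pos & p == pos)
    fn <- sum(t == pos & p != pos)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }
  f1s <- f1_of(1L); f1st <- f1_of(0L)
  list(f1 = f1s, f1_stance = f1st, f1_macro = mean(c(f1s, f1st)),
       n_samples = sum(ok))
}

#' Lagged cross-correlogram of an EMG channel against an IMU trace
#'
#' Correlates temporally shifted EMG activity `x(t + tau)` with the angular
#' velocity `y(t)` at each lag of the grid, over the jointly valid overlap.
#' Positive lag therefore means the informative EMG activity occurs after
#' (lags behind) the IMU signal. Two-sided p-values come from the
#' t-distribution of the correlation; significance is Bonferroni-corrected
#' for `n_tests` comparisons (default 420 = 10 muscles x 21 lags x 2 sides).
#'
#' @param emg,imu Preprocessed [signal_channel()]s on the same 200 Hz clock
#'   (concatenate trials beforehand with `NA` separators to keep shifted
#'   windows from crossing seams).
#' @param grid A [lag_grid()].
#' @param n_tests Bonferroni family size.
#' @param alpha Family-wise significance level.
#' @return A data frame with columns `lag_ms`, `r`, `p`, `significant`.
#' @export
correlogram <- function(emg, imu, grid = lag_grid(), n_tests = 420,
                        alpha = 0.05) {
  stopifnot(inherits(emg, "signal_channel"), inherits(imu, "signal_channel"))
  if (length(emg$samples) != length(imu$samples))
    stop("channels differ in length", call. = FALSE)
  shifts <- .lag_samples(grid, emg$fs)
  n <- length(emg$samples)
  res <- lapply(seq_along(shifts), function(k) {
    s <- shifts[k]
    idx <- seq_len(n)
    src <- idx + s
    ok <- src >= 1L & src <= n
    x <- emg$samples[src[ok]]; y <- imu$samples[idx[ok]]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    m <- length(x)
    r <- stats::cor(x, y)
    tstat <- r * sqrt((m - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = m - 2)
    data.frame(lag_ms = grid$tau_ms[k], r = r, p = p, n = m)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha / n_tests
  out
}

#' Evaluate a predicted angular-velocity trace against the measured one
#'
#' Runs the full per-trial, per-leg comparison: Pearson correlation of the
#' traces, rule-based event extraction on both, per-type event matching
#' with displacement statistics and FDR/FNR, swing/stance segmentation F1,
#' and cycle statistics of the measured trace.
#'
#' @param true_av,pred_av Measured and predicted angular-velocity channels
#'   on the same clock (one leg).
#' @param cfg An [event_config()].
#' @param max_match_distance_ms Event-matching tolerance (ms).
#' @return A `trial_metrics` list: `r`, `f1`, per-type `events` (list with
#'   `match`, `fdr`, `fnr`, `median_abs_displacement_ms`,
#'   `iqr_abs_displacement_ms`), and `cycles`.
#' @export
evaluate_trial <- function(true_av, pred_av, cfg = event_config(),
                           max_match_distance_ms = 600) {
  r <- pearson_r(true_av, pred_av)
  ev_t <- extract_events(true_av, cfg)
  ev_p <- extract_events(pred_av, cfg)
  n <- length(true_av$samples)
  per_type <- lapply(c(SWP = "SWP", HC = "HC", TO = "TO"), function(ty) {
    m <- match_events(ev_t[ev_t$type == ty, , drop = FALSE],
                      ev_p[ev_p$type == ty, , drop = FALSE],
                      max_match_distance_ms)
    rates <- event_rates(m)
    disp <- abs(m$matches$displacement_ms)
    list(match = m, fdr = rates$fdr, fnr = rates$fnr,
         median_abs_displacement_ms =
           if (length(disp)) stats::median(disp) else NA_real_,
         iqr_abs_displacement_ms = if (length(disp) > 1)
           diff(stats::quantile(disp, c(.25, .75), names = FALSE))
           else NA_real_)
  })
  f1 <- phase_f1(
    events_to_phases(ev_t[ev_t$type != "SWP", , drop = FALSE], n, true_av$fs),
    events_to_phases(ev_p[ev_p$type != "SWP", , drop = FALSE], n, pred_av$fs))
  cyc <- tryCatch(cycle_statistics(ev_t), error = function(e) NULL)
  structure(list(leg = true_av$side, r = r, f1 = f1$f1,
                 f1_macro = f1$f1_macro, events = per_type, cycles = cyc),
            class = "trial_metrics")
}

#' Flatten trial metrics into a one-row data frame
#' @param tm A [evaluate_trial()] result.
#' @return One-row `data.frame`.
#' @export
metrics_row <- function(tm) {
  stopifnot(inherits(tm, "trial_metrics"))
  row <- data.frame(leg = tm$leg, r = tm$r, f1 = tm$f1)
  for (ty in names(tm$events)) {
    e <- tm$events[[ty]]
    row[[paste0(tolower(ty), "_disp_ms")]] <- e$median_abs_displacement_ms
    row[[paste0(tolower(ty), "_fdr")]] <- e$fdr
    row[[paste0(tolower(ty), "_fnr")]] <- e$fnr
    row[[paste0(tolower(ty), "_n_true")]] <- e$match$n_true
    row[[paste0(tolower(ty), "_n_pred")]] <- e$match$n_pred
    row[[paste0(tolower(ty), "_n_miss")]] <- length(e$match$misses)
    row[[paste0(tolower(ty), "_n_false")]] <- length(e$match$false_detections)
  }
  row
}

#' Aggregate per-trial metrics across a cohort
#'
#' Continuous metrics (r, F1, displacements) are summarized as median and
#' IQR of the per-trial values. Error rates are pooled: pooled FNR is the
#' total missed events over total true events across trials, and likewise
#' for FDR -- not an average of per-trial rates.
#'
#' @param rows Data frame of [metrics_row()] rows (possibly with extra id
#'   columns).
#' @return List with `summary` (median/IQR per metric) and pooled
#'   `fdr`/`fnr` per event type.
#' @export
aggregate_metrics <- function(rows) {
  stopifnot(nrow(rows) >= 1L)
  summ <- function(x) {
    x <- x[!is.na(x)]
    c(median = stats::median(x),
      q25 = stats::quantile(x, .25, names = FALSE),
      q75 = stats::quantile(x, .75, names = FALSE))
  }
  cont <- c("r", "f1", "swp_disp_ms", "hc_disp_ms", "to_disp_ms")
  summary <- do.call(rbind, lapply(cont, function(m) {
    data.frame(metric = m, t(summ(rows[[m]])))
  }))
  pooled <- lapply(c(swp = "swp", hc = "hc", to = "to"), function(ty) {
    n_true <- sum(rows[[paste0(ty, "_n_true")]], na.rm = TRUE)
    n_pred <- sum(rows[[paste0(ty, "_n_pred")]], na.rm = TRUE)
    n_miss <- sum(rows[[paste0(ty, "_n_miss")]], na.rm = TRUE)
    n_false <- sum(rows[[paste0(ty, "_n_false")]], na.rm = TRUE)
    list(fnr = if (n_true > 0) n_miss / n_true else NA_real_,
         fdr = if (n_pred > 0) n_false / n_pred else NA_real_,
         n_true = n_true, n_pred = n_pred)
  })
  list(summary = summary, pooled = pooled)
}
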