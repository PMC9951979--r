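#' Temporal-embedding lag grid
#'
#' The regression predicts angular velocity at time `t` from EMG activity in
#' a window around `t`: each channel is complemented by time-shifted copies
#' `x(t + tau_k)`. The default grid uses 21 equally spaced shifts from
#' -500 ms to +500 ms in steps of 50 ms, i.e. a one-second window.
#'
#' @param tau_start_ms,tau_end_ms,step_ms Grid extent and spacing in ms.
#' @return A `lag_grid` with fields `tau_ms` (the shifts) and `K`.
#' @export
lag_grid <- function(tau_start_ms = -500, tau_end_ms = 500, step_ms = 50) {
  stopifnot(step_ms > 0, tau_end_ms >= tau_start_ms)
  span <- tau_end_ms - tau_start_ms
  if (abs(span / step_ms - round(span / step_ms)) > 1e-9)
    stop("lag grid extent must be a multiple of `step_ms`", call. = FALSE)
  tau <- seq(tau_start_ms, tau_end_ms, by = step_ms)
  structure(list(tau_start_ms = tau_start_ms, tau_end_ms = tau_end_ms,
                 step_ms = step_ms, tau_ms = tau, K = length(tau)),
            class = "lag_grid")
}

# Shifts in samples; every lag must land on an integer sample at this rate.
.lag_samples <- function(grid, fs) {
  s <- grid$tau_ms * fs / 1000
  if (any(abs(s - round(s)) > 1e-9))
    stop("lag grid does not align with the sampling grid at ", fs, " Hz",
         call. = FALSE)
  as.integer(round(s))
}

#' Build the lagged EMG design matrix
#'
#' For `M` channels and `K` lags the design has `K * M + 1` features: the
#' feature for channel `m` and lag `tau_k` at time `t` is `x_m(t + tau_k)`,
#' plus a constant offset feature. Features are ordered channel-major,
#' lag-minor, offset last. Times at which any shift exits the trial are
#' flagged invalid and excluded from fitting; they receive `NA` predictions.
#'
#' @param emg List of EMG [signal_channel()]s sharing rate and length.
#' @param grid A [lag_grid()].
#' @return An `embedded_design`: `X` (T x (K*M+1) matrix), `valid` (logical
#'   length T), `muscle_labels`, `grid`, `fs`.
#' @export
embed_emg <- function(emg, grid = lag_grid()) {
  stopifnot(length(emg) >= 1L,
            all(vapply(emg, inherits, logical(1), "signal_channel")))
  fs <- unique(vapply(emg, `[[`, numeric(1), "fs"))
  if (length(fs) != 1L)
    stop("all EMG channels must share one sampling rate", call. = FALSE)
  len <- unique(vapply(emg, function(ch) length(ch$samples), integer(1)))
  if (length(len) != 1L)
    stop("all EMG channels must share one length", call. = FALSE)
  shifts <- .lag_samples(grid, fs)
  span <- max(shifts) - min(shifts)
  if (len <= span)
    stop("trial shorter than the embedding span (",
         (grid$tau_end_ms - grid$tau_start_ms) / 1000, " s)", call. = FALSE)
  M <- length(emg)
  K <- grid$K
  labels <- vapply(emg, `[[`, character(1), "label")
  X <- matrix(NA_real_, nrow = len, ncol = K * M + 1L)
  t_idx <- seq_len(len)
  for (m in seq_len(M)) {
    x <- emg[[m]]$samples
    for (k in seq_len(K)) {
      src <- t_idx + shifts[k]
      ok <- src >= 1L & src <= len
      col <- rep(NA_real_, len)
      col[ok] <- x[src[ok]]
      X[, (m - 1L) * K + k] <- col
    }
  }
  X[, K * M + 1L] <- 1
  valid <- t_idx + min(shifts) >= 1L & t_idx + max(shifts) <= len
  colnames(X) <- c(paste0(rep(labels, each = K), "_lag",
                          rep(grid$tau_ms, M), "ms"), "offset")
  structure(list(X = X, valid = valid, muscle_labels = labels,
                 grid = grid, fs = fs),
            class = "embedded_design")
}

#' Fit the angular-velocity regression by ordinary least squares
#'
#' Estimates the `(K*M+1)`-dimensional coefficient vector minimizing the
#' mean-squared error between the measured angular velocity and the linear
#' readout of the embedded EMG, over the valid (complete-window) samples.
#' The solve uses a QR factorization; on rank-deficient designs it falls
#' back to the SVD pseudoinverse with a warning. No regularization is
#' applied by default (`ridge = 0`).
#'
#' @param design An [embed_emg()] design (or a list of designs, concatenated
#'   so that no embedding window spans two trials).
#' @param target The target angular-velocity [signal_channel()] (or list,
#'   matching `design`).
#' @param ridge Optional nonnegative ridge penalty on the non-offset
#'   coefficients.
#' @return An `av_model` with `beta`, `muscle_labels`, `grid`,
#'   `target_side`, `target_label`, `training_patients`.
#' @export
fit_ols <- function(design, target, ridge = 0) {
  if (inherits(design, "embedded_design")) design <- list(design)
  if (inherits(target, "signal_channel")) target <- list(target)
  stopifnot(length(design) == length(target), length(design) >= 1L)
  labels <- design[[1L]]$muscle_labels
  grid <- design[[1L]]$grid
  rows <- vector("list", length(design))
  ys <- vector("list", length(design))
  for (i in seq_along(design)) {
    d <- design[[i]]; y <- target[[i]]
    if (!identical(d$muscle_labels, labels))
      stop("designs disagree on muscle channels", call. = FALSE)
    if (length(y$samples) != nrow(d$X))
      stop("target length does not match design", call. = FALSE)
    ok <- d$valid & !is.na(y$samples)
    rows[[i]] <- d$X[ok, , drop = FALSE]
    ys[[i]] <- y$samples[ok]
  }
  X <- do.call(rbind, rows)
  y <- do.call(c, ys)
  p <- ncol(X)
  if (nrow(X) < p)
    stop("fewer valid samples than coefficients", call. = FALSE)
  if (ridge > 0) {
    pen <- diag(sqrt(ridge), p); pen[p, p] <- 0  # offset unpenalized
    X <- rbind(X, pen)
    y <- c(y, rep(0, p))
  }
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    warning("rank-deficient design; using SVD pseudoinverse", call. = FALSE)
    sv <- svd(X)
    keep <- sv$d > max(sv$d) * max(dim(X)) * .Machine$double.eps
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
    beta <- as.numeric(beta)
  }
  names(beta) <- colnames(design[[1L]]$X)
  structure(list(beta = beta, muscle_labels = labels, grid = grid,
                 target_side = target[[1L]]$side,
                 target_label = target[[1L]]$label,
                 training_patients = character()),
            class = "av_model")
}

#' @export
print.av_model <- function(x, ...) {
  cat(sprintf("<av_model> target %s (%s side), %d channels x %d lags + offset\n",
              x$target_label, x$target_side, length(x$muscle_labels),
              x$grid$K))
  invisible(x)
}

#' Predict angular velocity from an embedded design
#'
#' Applies the fitted linear readout to every sample of a design built from
#' (held-out) EMG. Boundary samples whose embedding window exits the trial
#' carry `NA`.
#'
#' @param model An [fit_ols()] model.
#' @param design An [embed_emg()] design with matching channels and grid.
#' @param label Label for the output channel.
#' @return A [signal_channel()] of kind `angular_velocity` with `NA` at
#'   invalid boundary samples.
#' @export
predict_av <- function(model, design, label = paste0(model$target_label, "_pred")) {
  stopifnot(inherits(model, "av_model"), inherits(design, "embedded_design"))
  if (!identical(design$muscle_labels, model$muscle_labels) ||
      !identical(design$grid$tau_ms, model$grid$tau_ms))
    stop("design does not match the model's channels/lag grid", call. = FALSE)
  yhat <- as.numeric(design$X %*% model$beta)
  yhat[!design$valid] <- NA_real_
  signal_channel(label, model$target_side, "angular_velocity",
                 design$fs, yhat, units = "deg/s", allow_na = TRUE)
}

#' Serialize a fitted model to JSON
#'
#' Writes/reads the coefficient vector together with everything needed to
#' apply it: muscle labels, lag grid, target side and the training patient
#' ids.
#'
#' @param model An [fit_ols()] model.
#' @param path JSON file path.
#' @return `write_model` returns the model invisibly; `read_model` the
#'   reconstructed `av_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "av_model"))
  jsonlite::write_json(
    list(beta = unname(model$beta),
         feature_names = names(model$beta),
         muscle_labels = model$muscle_labels,
         lag_grid = list(tau_start_ms = model$grid$tau_start_ms,
                         tau_end_ms = model$grid$tau_end_ms,
                         step_ms = model$grid$step_ms),
         target_side = model$target_side,
         target_label = model$target_label,
         training_patients = model$training_patients),
    path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- lag_grid(as.numeric(j$lag_grid$tau_start_ms),
                as.numeric(j$lag_grid$tau_end_ms),
                as.numeric(j$lag_grid$step_ms))
  beta <- as.numeric(j$beta)
  names(beta) <- j$feature_names
  if (length(beta) != g$K * length(j$muscle_labels) + 1L)
    stop("model file is inconsistent: coefficient count does not match ",
         "muscles x lags + 1", call. = FALSE)
  structure(list(beta = beta, muscle_labels = j$muscle_labels, grid = g,
                 target_side = j$target_side, target_label = j$target_label,
                 training_patients = j$training_patients),
            class = "av_model")
}

#' Enumerate all bilateral muscle subsets
#'
#' Every model includes either none or both sides of each of the five
#' recorded muscles (Ta, S, Gm, Gl, Vl), giving `2^5 - 1 = 31` candidate
#' subsets of one to five bilateral pairs (two to ten EMG channels).
#'
#' @param muscles Muscle short names to combine.
#' @return List of `muscle_subset` objects with fields `pairs` and
#'   `channels` (both-side labels, `L`/`R` prefixed).
#' @export
enumerate_subsets <- function(muscles = c("Ta", "S", "Gm", "Gl", "Vl")) {
  n <- length(muscles)
  out <- list()
  for (size in seq_len(n)) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      pairs <- muscles[idx]
      out[[length(out) + 1L]] <- structure(
        list(pairs = pairs,
             channels = as.vector(t(outer(c("L", "R"), pairs, paste0)))),
        class = "muscle_subset")
    }
  }
  out
}

#' Leave-one-patient-out fitting and prediction
#'
#' For each patient, fits one model per target side on the concatenated
#' trials of all other patients (embedding each trial separately so no lag
#' window straddles a trial seam) and predicts every trial of the held-out
#' patient. This gives an unbiased out-of-sample assessment: the held-out
#' patient's data never enter the fit.
#'
#' @param recordings List of preprocessed [gait_recording()]s (common
#'   200 Hz clock) from at least two patients.
#' @param channels Character vector of EMG channel labels to use (e.g. a
#'   [enumerate_subsets()] element's `$channels`); default all EMG channels.
#' @param grid A [lag_grid()].
#' @param ridge Passed to [fit_ols()].
#' @return A list with one element per recording:
#'   `patient_id`, `trial_id`, `pred` (named list of left/right predicted
#'   channels), `truth` (the measured angular-velocity channels), and
#'   `models` (per held-out patient, per side) in attribute-free form.
#' @export
fit_lopo <- function(recordings, channels = NULL, grid = lag_grid(),
                     ridge = 0) {
  stopifnot(length(recordings) >= 2L,
            all(vapply(recordings, inherits, logical(1), "gait_recording")))
  patients <- vapply(recordings, `[[`, character(1), "patient_id")
  if (length(unique(patients)) < 2L)
    stop("leave-one-patient-out needs at least two distinct patients",
         call. = FALSE)
  get_emg <- function(rec) {
    emg <- recording_channels(rec, "emg")
    if (is.null(channels)) emg else {
      miss <- setdiff(channels, names(emg))
      if (length(miss)) stop("missing EMG channels: ",
                             paste(miss, collapse = ", "), call. = FALSE)
      emg[channels]
    }
  }
  designs <- lapply(recordings, function(rec) embed_emg(get_emg(rec), grid))
  targets <- lapply(recordings, function(rec) {
    list(left = recording_channels(rec, "angular_velocity", "left")[[1L]],
         right = recording_channels(rec, "angular_velocity", "right")[[1L]])
  })
  out <- vector("list", length(recordings))
  for (p in unique(patients)) {
    train <- which(patients != p)
    test <- which(patients == p)
    models <- lapply(c(left = "left", right = "right"), function(side) {
      m <- fit_ols(designs[train], lapply(targets[train], `[[`, side),
                   ridge = ridge)
      m$training_patients <- sort(unique(patients[train]))
      m
    })
    for (i in test) {
      out[[i]] <- list(
        patient_id = patients[i],
        trial_id = recordings[[i]]$trial_id,
        pred = lapply(models, function(m) predict_av(m, designs[[i]])),
        truth = targets[[i]],
        models = models)
    }
  }
  out
}
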