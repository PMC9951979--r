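# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately avoid the package's own vectorized/factorized
# code paths.

mk_emg <- function(x, label = "LVl", side = "left", fs = 200)
  signal_channel(label, side, "emg", fs, x)

mk_av <- function(x, side = "left", fs = 200,
                  label = paste0(toupper(substr(side, 1, 1)), "_IMU"))
  signal_channel(label, side, "angular_velocity", fs, x)

# per-window moving statistic with symmetric edge truncation
bf_moving <- function(x, k, fun) {
  n <- length(x)
  h <- (k - 1) %/% 2
  vapply(seq_len(n), function(i) {
    hh <- min(h, i - 1, n - i)
    fun(x[(i - hh):(i + hh)])
  }, numeric(1))
}

# textbook product-moment correlation
bf_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# normal-equations OLS (the closed form kept only as a test oracle)
bf_ols <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))

# F1 from an explicit confusion matrix, swing (1) positive
bf_f1 <- function(t, p) {
  tp <- sum(t == 1 & p == 1); fp <- sum(t == 0 & p == 1)
  fn <- sum(t == 1 & p == 0)
  2 * tp / (2 * tp + fp + fn)
}

# maximum-cardinality one-to-one matching under the <tol pairing constraint,
# by exhaustive branch-and-bound (fine for <= 10 events per side)
bf_match_cardinality <- function(tt, pp, tol_ms = 600) {
  ok <- outer(tt, pp, function(a, b) abs(b - a) * 1000 < tol_ms)
  n <- length(tt); m <- length(pp)
  if (n == 0 || m == 0) return(0L)
  best <- 0L
  rec <- function(i, used) {
    if (i > n) { best <<- max(best, sum(used)); return(invisible()) }
    rec(i + 1L, used)  # leave true event i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && ok[i, j]) {
        used[j] <- TRUE
        rec(i + 1L, used)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(m))
  best
}

events_of <- function(times, type, leg = "left")
  gait_events(rep(leg, length(times)), rep(type, length(times)), times)

# a minimal two-sided raw recording for I/O tests
mk_recording <- function(n_emg = 2, fs_emg = 1000, fs_imu = 128,
                         duration_s = 3, seed = 1) {
  set.seed(seed)
  n1 <- duration_s * fs_emg; n2 <- duration_s * fs_imu
  chs <- list()
  for (i in seq_len(n_emg)) {
    side <- if (i %% 2 == 1) "left" else "right"
    lb <- paste0(if (side == "left") "L" else "R",
                 c("Vl", "Ta", "S", "Gm", "Gl")[(i + 1) %/% 2])
    chs[[lb]] <- signal_channel(lb, side, "emg", fs_emg, rnorm(n1))
  }
  chs$L_IMU <- mk_av(rnorm(n2), "left", fs_imu)
  chs$R_IMU <- mk_av(rnorm(n2), "right", fs_imu, "R_IMU")
  gait_recording("P01", "T01", chs,
                 ttl_onset_s = c(emg = 0.5, angular_velocity = 0.25),
                 ttl_offset_s = c(emg = 2.9, angular_velocity = 2.65),
                 walk_start_s = 0.5, walk_end_s = 2)
}
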