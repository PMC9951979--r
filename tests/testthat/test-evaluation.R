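test_that("pearson_r matches the textbook formula and flags degenerate input", {
  set.seed(51)
  x <- rnorm(300); y <- 0.4 * x + rnorm(300)
  expect_equal(pearson_r(mk_av(x), mk_av(y)), bf_pearson(x, y),
               tolerance = 1e-12)
  expect_equal(pearson_r(mk_av(x), mk_av(x)), 1)
  expect_equal(pearson_r(mk_av(x), mk_av(-x)), -1)
  # NA masks restrict to jointly valid samples
  y2 <- y; y2[1:50] <- NA
  ch <- signal_channel("p", "left", "angular_velocity", 200, y2,
                       allow_na = TRUE)
  expect_equal(pearson_r(mk_av(x), ch), bf_pearson(x[-(1:50)], y[-(1:50)]))
  expect_error(pearson_r(mk_av(rep(1, 10)), mk_av(rnorm(10))), "constant")
})

test_that("event matching is one-to-one, tolerance-bounded and shift-aware", {
  tt <- seq(0.5, 10, by = 1.1)
  same <- match_events(events_of(tt, "SWP"), events_of(tt, "SWP"))
  expect_equal(nrow(same$matches), length(tt))
  expect_true(all(same$matches$displacement_ms == 0))
  r <- event_rates(same)
  expect_equal(r$fdr, 0); expect_equal(r$fnr, 0)

  shifted <- match_events(events_of(tt, "SWP"), events_of(tt + 0.1, "SWP"))
  expect_true(all(abs(shifted$matches$displacement_ms - 100) < 1e-9))

  # beyond the 600 ms gate nothing matches
  far <- match_events(events_of(c(1, 3), "SWP"), events_of(c(1.7, 3.7), "SWP"))
  expect_equal(nrow(far$matches), 0L)
  expect_equal(event_rates(far)$fnr, 1)

  expect_error(
    match_events(events_of(1, "SWP"),
                 gait_events("left", "HC", 1)), "single leg and event type")
})

test_that("greedy matching attains brute-force optimal cardinality on small cases", {
  set.seed(52)
  for (i in 1:40) {
    n_t <- sample(0:8, 1); n_p <- sample(0:8, 1)
    tt <- sort(runif(n_t, 0, 8))
    pp <- sort(runif(n_p, 0, 8))
    m <- match_events(events_of(tt, "HC"), events_of(pp, "HC"))
    expect_equal(nrow(m$matches), bf_match_cardinality(tt, pp),
                 info = paste("case", i))
    # symmetry: swapping roles swaps misses and false detections
    m_sw <- match_events(events_of(pp, "HC"), events_of(tt, "HC"))
    expect_equal(nrow(m_sw$matches), nrow(m$matches))
    expect_equal(sort(m_sw$misses), sort(m$false_detections))
    expect_equal(sort(m_sw$false_detections), sort(m$misses))
  }
})

test_that("event rates follow their definitions including undefined cases", {
  tt <- seq(0, 99) * 1.1
  pp <- tt[-(1:2)]  # two missed
  m <- match_events(events_of(tt, "TO"), events_of(pp, "TO"))
  r <- event_rates(m)
  expect_equal(r$fnr, 0.02)
  expect_equal(r$fdr, 0)
  none <- match_events(events_of(tt, "TO"), events_of(numeric(), "TO"))
  r <- event_rates(none)
  expect_equal(r$fnr, 1)
  expect_true(is.na(r$fdr))
})

test_that("phase F1 equals the confusion-matrix formula", {
  mk_ph <- function(lab) structure(list(labels = lab, defined = !is.na(lab),
                                        leg = "left", fs = 200),
                                   class = "phase_series")
  set.seed(53)
  t <- sample(c(0L, 1L), 500, replace = TRUE)
  p <- ifelse(runif(500) < 0.85, t, 1L - t)
  expect_equal(phase_f1(mk_ph(t), mk_ph(p))$f1, bf_f1(t, p),
               tolerance = 1e-12)
  expect_equal(phase_f1(mk_ph(t), mk_ph(t))$f1, 1)
  expect_equal(phase_f1(mk_ph(c(1L, 1L, 0L)), mk_ph(c(0L, 0L, 0L)))$f1, 0)
  # undefined on empty joint mask
  expect_true(is.na(phase_f1(mk_ph(rep(NA_integer_, 10)),
                             mk_ph(rep(0L, 10)))$f1))
})

test_that("correlograms recover a planted delay and stay null on noise", {
  set.seed(54)
  fs <- 200
  n <- 6000
  base <- as.numeric(filter(rnorm(n + 400), rep(1, 40) / 40, sides = 2))
  imu <- mk_av(base[201:(200 + n)])
  # EMG is the IMU delayed by 150 ms: informative activity occurs after the
  # IMU signal, so the peak sits at +150 ms in the x(t + tau) convention
  delayed <- base[201:(200 + n) - 30] + rnorm(n, 0, 0.05)
  emg <- mk_emg(delayed)
  cg <- correlogram(emg, imu, lag_grid())
  expect_equal(cg$lag_ms[which.max(cg$r)], 150)
  expect_true(cg$significant[cg$lag_ms == 150])
  # direct-shift oracle at the peak lag
  r_direct <- cor(delayed[31:n], imu$samples[1:(n - 30)])
  expect_equal(max(cg$r), r_direct, tolerance = 1e-12)
  # zero lag, identical signals
  cg0 <- correlogram(mk_emg(imu$samples), imu, lag_grid(0, 0, 50))
  expect_equal(cg0$r, 1)

  white <- correlogram(mk_emg(rnorm(10000)), mk_av(rnorm(10000)), lag_grid())
  expect_lt(max(abs(white$r)), 0.05)
  expect_equal(sum(white$significant), 0L)
})

test_that("trial evaluation is exact on identical traces and tracks shifts", {
  set.seed(55)
  tr <- generate_cycle_train(gait_template(), 30, fs = 200,
                             cycle_jitter_ms = 10)
  tm <- evaluate_trial(tr$channel, tr$channel)
  expect_equal(tm$r, 1)
  expect_equal(tm$f1, 1)
  for (e in tm$events) {
    expect_equal(e$fdr, 0); expect_equal(e$fnr, 0)
    expect_equal(e$median_abs_displacement_ms, 0)
  }

  # uniform 50 ms shift: all displacements 50 ms
  shift <- 10  # samples
  x <- tr$channel$samples
  pred <- mk_av(c(x[-seq_len(shift)], rep(0, shift)))
  tm <- evaluate_trial(tr$channel, pred)
  for (e in tm$events)
    expect_equal(e$median_abs_displacement_ms, 50)
})

test_that("aggregation uses per-trial medians and pooled counts", {
  rows <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(leg = "left", r = c(0.8, 0.85, 0.9)[i],
               f1 = c(0.8, 0.85, 0.9)[i],
               swp_disp_ms = 10 * i, hc_disp_ms = 10, to_disp_ms = 10,
               swp_n_true = c(10, 100, 10)[i],
               swp_n_pred = c(10, 100, 10)[i],
               swp_n_miss = c(5, 1, 0)[i], swp_n_false = c(0, 2, 0)[i],
               hc_n_true = 10, hc_n_pred = 10, hc_n_miss = 0,
               hc_n_false = 0,
               to_n_true = 10, to_n_pred = 10, to_n_miss = 0,
               to_n_false = 0)
  }))
  agg <- aggregate_metrics(rows)
  expect_equal(agg$summary$median[agg$summary$metric == "r"], 0.85)
  # pooled, not averaged: (5+1+0)/(10+100+10)
  expect_equal(agg$pooled$swp$fnr, 6 / 120)
  expect_equal(agg$pooled$swp$fdr, 2 / 120)
  single <- aggregate_metrics(rows[1, ])
  expect_equal(single$summary$median[single$summary$metric == "f1"], 0.8)
  expect_equal(single$pooled$swp$fnr, 0.5)
})

test_that("metrics are invariant under a common time shift of both traces", {
  set.seed(56)
  tr <- generate_cycle_train(gait_template(), 25, fs = 200,
                             cycle_jitter_ms = 10)
  x <- tr$channel$samples
  noisy <- x + as.numeric(filter(rnorm(length(x), 0, 8), rep(1, 20) / 20,
                                 sides = 2))
  noisy[is.na(noisy)] <- x[is.na(noisy)]
  pred <- mk_av(noisy)
  tm0 <- evaluate_trial(tr$channel, pred)
  k <- 40  # shift both by 0.2 s
  tm1 <- evaluate_trial(mk_av(x[-seq_len(k)]), mk_av(noisy[-seq_len(k)]))
  for (ty in c("SWP", "HC", "TO")) {
    expect_equal(tm1$events[[ty]]$fnr, tm0$events[[ty]]$fnr,
                 tolerance = 0.02)
    expect_equal(tm1$events[[ty]]$median_abs_displacement_ms,
                 tm0$events[[ty]]$median_abs_displacement_ms,
                 tolerance = 10)
  }
})
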