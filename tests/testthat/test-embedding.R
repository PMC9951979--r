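test_that("the default lag grid has 21 shifts spanning one second", {
  g <- lag_grid()
  expect_equal(g$K, 21L)
  expect_equal(g$tau_ms, seq(-500, 500, by = 50))
  expect_error(lag_grid(-500, 500, 33), "multiple")
})

test_that("embedding ten muscles over 21 lags gives 210 features plus offset", {
  set.seed(21)
  emg <- lapply(names(default_muscle_templates()), function(lb)
    mk_emg(rnorm(600), label = lb,
           side = if (startsWith(lb, "L")) "left" else "right"))
  d <- embed_emg(emg, lag_grid())
  expect_equal(ncol(d$X), 211L)
  expect_equal(sum(colnames(d$X) != "offset"), 210L)
  expect_true(all(d$X[, 211] == 1))
  expect_equal(sum(d$valid), 600L - 200L)  # +-100 samples trimmed
})

test_that("embedded features equal directly indexed shifted samples", {
  set.seed(22)
  x1 <- rnorm(300); x2 <- rnorm(300)
  g <- lag_grid(-100, 100, 50)
  d <- embed_emg(list(mk_emg(x1, "LVl"), mk_emg(x2, "RVl", "right")), g)
  shifts <- g$tau_ms * 200 / 1000
  for (m in 1:2) {
    x <- list(x1, x2)[[m]]
    for (k in seq_along(shifts)) {
      col <- d$X[, (m - 1) * g$K + k]
      for (t0 in c(30, 150, 250)) {
        expect_equal(col[t0], x[t0 + shifts[k]])
      }
    }
  }
  # single zero lag is the identity embedding
  d0 <- embed_emg(list(mk_emg(x1, "LVl")), lag_grid(0, 0, 50))
  expect_equal(d0$X[, 1], x1)
  expect_error(embed_emg(list(mk_emg(rnorm(100))), lag_grid()),
               "shorter than the embedding span")
})

test_that("OLS recovers an exact linear target and matches normal equations", {
  set.seed(23)
  g <- lag_grid(-100, 100, 50)
  emg <- list(mk_emg(rnorm(800), "LVl"), mk_emg(rnorm(800), "RVl", "right"))
  d <- embed_emg(emg, g)
  beta_true <- rnorm(ncol(d$X))
  y <- as.numeric(d$X %*% beta_true)
  fit <- fit_ols(d, signal_channel("L_IMU", "left", "angular_velocity", 200,
                                   ifelse(d$valid, y, NA), allow_na = TRUE))
  expect_equal(unname(fit$beta), beta_true, tolerance = 1e-6)
  resid <- y[d$valid] - as.numeric(d$X[d$valid, ] %*% fit$beta)
  expect_lt(mean(resid^2) / mean(y[d$valid]^2), 1e-18)

  # intercept-only target
  fit0 <- fit_ols(d, mk_av(rep(2.5, 800), "left"))
  expect_equal(unname(fit0$beta[ncol(d$X)]), 2.5, tolerance = 1e-8)
  expect_true(all(abs(fit0$beta[-ncol(d$X)]) < 1e-8))

  # 20 random small instances against the closed-form normal equations
  for (i in 1:20) {
    n <- 500; p <- 20
    X <- cbind(matrix(rnorm(n * (p - 1)), n), 1)
    yy <- rnorm(n)
    d2 <- list(X = X, valid = rep(TRUE, n),
               muscle_labels = "LVl", grid = lag_grid(0, 0, 50), fs = 200)
    class(d2) <- "embedded_design"
    fit2 <- fit_ols(d2, mk_av(yy, "left", fs = 200))
    expect_equal(unname(fit2$beta), bf_ols(X, yy), tolerance = 1e-8)
  }
})

test_that("prediction applies the readout and flags boundary samples", {
  set.seed(24)
  g <- lag_grid(-100, 100, 50)
  x <- rnorm(500)
  d <- embed_emg(list(mk_emg(x, "LVl")), g)
  # one-hot beta reproduces the corresponding shifted channel exactly
  model <- structure(list(beta = c(1, rep(0, g$K)), muscle_labels = "LVl",
                          grid = g, target_side = "left",
                          target_label = "L_IMU",
                          training_patients = character()),
                     class = "av_model")
  pred <- predict_av(model, d)
  tt <- which(d$valid)
  expect_equal(pred$samples[tt], x[tt - 20])  # first lag is -100 ms
  expect_true(all(is.na(pred$samples[!d$valid])))

  # zero design plus offset: constant prediction at the intercept
  model$beta <- c(rep(0, g$K), 4.2)
  expect_equal(unique(predict_av(model, d)$samples[d$valid]), 4.2)

  # training-set prediction correlates at least as well as any single feature
  beta_true <- rnorm(g$K + 1)
  y <- as.numeric(d$X %*% beta_true) + rnorm(500, 0, 0.5)
  fit <- fit_ols(d, signal_channel("L_IMU", "left", "angular_velocity", 200,
                                   ifelse(d$valid, y, NA), allow_na = TRUE))
  pr <- predict_av(fit, d)
  r_fit <- cor(pr$samples[d$valid], y[d$valid])
  r_single <- apply(d$X[d$valid, seq_len(g$K), drop = FALSE], 2,
                    function(col) abs(cor(col, y[d$valid])))
  expect_true(r_fit >= max(r_single) - 1e-12)

  d_bad <- embed_emg(list(mk_emg(x, "RVl", "right")), g)
  expect_error(predict_av(fit, d_bad), "does not match")
})

test_that("bilateral subset enumeration yields 31 even-sized channel sets", {
  subs <- enumerate_subsets()
  expect_length(subs, 31L)
  sizes <- vapply(subs, function(s) length(s$pairs), integer(1))
  expect_equal(sum(sizes == 1), 5L)
  expect_equal(table(sizes), table(c(rep(1, 5), rep(2, 10), rep(3, 10),
                                     rep(4, 5), 5)), ignore_attr = TRUE)
  keys <- vapply(subs, function(s) paste(sort(s$pairs), collapse = "+"),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
  for (s in subs) {
    expect_true(length(s$channels) %% 2 == 0)
    expect_true(length(s$channels) >= 2 && length(s$channels) <= 10)
    expect_setequal(s$channels,
                    c(paste0("L", s$pairs), paste0("R", s$pairs)))
  }
})

test_that("trial concatenation never lets a window straddle a seam", {
  set.seed(25)
  g <- lag_grid(-100, 100, 50)
  # sentinel: second trial is all NA-free but huge; if any training row of
  # trial 1 saw trial 2's samples, coefficients would blow up detectably
  mk <- function(x) {
    d <- embed_emg(list(mk_emg(x, "LVl")), g)
    y <- signal_channel("L_IMU", "left", "angular_velocity", 200,
                        as.numeric(d$X %*% c(rnorm(g$K), 1)),
                        allow_na = TRUE)
    list(d = d, y = y)
  }
  a <- mk(rnorm(300)); b <- mk(rnorm(300))
  fit_ab <- fit_ols(list(a$d, b$d), list(a$y, b$y))
  # rows used = valid rows only; verify count
  expect_equal(sum(a$d$valid) + sum(b$d$valid), 2 * (300 - 40))
  # replacing trial b's boundary-adjacent samples (invalid rows only) must
  # not change the fit
  b2 <- b
  b2$d$X[!b2$d$valid, 1:g$K] <- 1e9
  fit_ab2 <- fit_ols(list(a$d, b2$d), list(a$y, b2$y))
  expect_identical(fit_ab$beta, fit_ab2$beta)
})

test_that("LOPO holds out each patient exactly once with no leakage", {
  cfg <- simulation_config(n_patients = 3, trials_per_patient = 2,
                           trial_duration_s = 25,
                           linear_ground_truth = TRUE, seed = 31)
  trials <- generate_cohort(cfg,
                            templates = default_muscle_templates()[c("LVl", "RVl")])
  recs <- lapply(trials, function(t) preprocess_recording(t$recording))
  lopo <- fit_lopo(recs, channels = c("LVl", "RVl"))
  expect_length(lopo, length(recs))
  pids <- vapply(lopo, `[[`, character(1), "patient_id")
  expect_equal(sort(unique(pids)), c("P01", "P02", "P03"))
  for (res in lopo)
    expect_false(res$patient_id %in% res$models$left$training_patients)

  # perturbing the held-out patient's IMU traces leaves coefficients
  # bit-identical
  recs2 <- recs
  for (i in which(pids == "P01")) {
    for (lb in c("L_IMU", "R_IMU")) {
      recs2[[i]]$channels[[lb]]$samples <-
        recs2[[i]]$channels[[lb]]$samples * 3 + 17
    }
  }
  lopo2 <- fit_lopo(recs2, channels = c("LVl", "RVl"))
  i1 <- which(pids == "P01")[1]
  expect_identical(lopo[[i1]]$models$left$beta, lopo2[[i1]]$models$left$beta)
  expect_identical(lopo[[i1]]$models$right$beta, lopo2[[i1]]$models$right$beta)
  expect_identical(lopo[[i1]]$pred$left$samples, lopo2[[i1]]$pred$left$samples)

  expect_error(fit_lopo(recs[1:2], channels = c("LVl", "RVl")),
               "two distinct patients")
})

test_that("models round-trip through their JSON file format", {
  set.seed(26)
  g <- lag_grid(-100, 100, 50)
  d <- embed_emg(list(mk_emg(rnorm(400), "LVl"),
                      mk_emg(rnorm(400), "RVl", "right")), g)
  fit <- fit_ols(d, mk_av(rnorm(400), "left"))
  fit$training_patients <- c("P01", "P02")
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f)
  back <- read_model(f)
  expect_equal(back$beta, fit$beta)
  expect_identical(back$muscle_labels, fit$muscle_labels)
  expect_identical(back$grid$tau_ms, fit$grid$tau_ms)
  expect_identical(back$target_side, "left")
  expect_identical(back$training_patients, c("P01", "P02"))
  # predictions from the reloaded model agree to serialized precision
  expect_equal(predict_av(back, d)$samples, predict_av(fit, d)$samples,
               tolerance = 1e-12)
})
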