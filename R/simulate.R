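#' Angular-velocity cycle template
#'
#' Geometry of one gait cycle of the shank angular velocity about the
#' medio-lateral axis, delimited by two consecutive swing peaks (SWP). The
#' trace is built from piecewise cubic "smoothstep" segments between knots
#' with zero slope, so extrema are strict and sit exactly at the knots: the
#' positive swing peak at the cycle start, the HC minimum at `hc_phase`, a
#' small positive mid-stance hump, and the TO minimum at `to_phase`.
#'
#' @param cycle_duration_ms Nominal cycle duration (default 1100 ms, in the
#'   1045--1140 ms range typical of self-paced overground walking in mildly
#'   affected parkinsonian patients).
#' @param swp_amplitude Swing-peak amplitude in deg/s (> 150 so the peak
#'   clears the detection threshold).
#' @param hc_phase,to_phase Cycle fractions of the HC and TO minima; must
#'   lie inside the detector's 10--45% and 55--90% windows.
#' @param hc_depth,to_depth Trough depths (deg/s, positive numbers).
#' @param mid_amplitude Height of the hump separating the two troughs
#'   (deg/s, kept well below the SWP threshold).
#' @return A `gait_template` list.
#' @export
gait_template <- function(cycle_duration_ms = 1100, swp_amplitude = 250,
                          hc_phase = 0.25, to_phase = 0.70,
                          hc_depth = 120, to_depth = 150,
                          mid_amplitude = 50) {
  stopifnot(cycle_duration_ms > 0, swp_amplitude > 150,
            hc_phase > 0.10, hc_phase < 0.45,
            to_phase > 0.55, to_phase < 0.90,
            hc_depth > 0, to_depth > 0, mid_amplitude < 150)
  structure(as.list(environment()), class = "gait_template")
}

#' Phase-locked muscle activation template
#'
#' One muscle's activation burst, phase-locked to its own leg's gait cycle
#' (cycle fraction 0 = SWP). Defaults follow the physiological pattern:
#' vastus lateralis bursts around heel contact, tibialis anterior during
#' swing, and the plantar flexors (soleus, both gastrocnemii) during
#' stance.
#'
#' @param muscle One of `"Ta"`, `"S"`, `"Gm"`, `"Gl"`, `"Vl"`.
#' @param side `"left"` or `"right"`.
#' @param burst_phase Cycle fraction of the burst centre, in `[0, 1)`.
#' @param burst_width Full width of the raised-cosine burst (cycle
#'   fraction).
#' @param gain Burst amplitude (a.u., > 0).
#' @return A `muscle_template` list.
#' @export
muscle_template <- function(muscle, side, burst_phase, burst_width = 0.25,
                            gain = 1) {
  muscle <- match.arg(muscle, c("Ta", "S", "Gm", "Gl", "Vl"))
  side <- match.arg(side, c("left", "right"))
  stopifnot(burst_phase >= 0, burst_phase < 1, burst_width > 0, gain > 0)
  structure(list(muscle = muscle, side = side, burst_phase = burst_phase,
                 burst_width = burst_width, gain = gain),
            class = "muscle_template")
}

#' Default bilateral muscle templates
#'
#' Both sides of all five recorded muscles with physiologically motivated
#' burst timings (fractions of the muscle's own leg cycle, SWP = 0, HC at
#' 0.25, TO at 0.70): Ta in swing around the swing peak with a loading
#' contribution after HC, Vl confined to heel contact, and S/Gm/Gl in
#' stance.
#'
#' @return Named list of [muscle_template()]s, labels `LTa`, `RTa`, ...
#' @export
default_muscle_templates <- function() {
  timing <- list(
    Ta = list(phase = 0.90, width = 0.35),
    S  = list(phase = 0.45, width = 0.35),
    Gm = list(phase = 0.50, width = 0.30),
    Gl = list(phase = 0.55, width = 0.30),
    Vl = list(phase = 0.25, width = 0.20))
  out <- list()
  for (m in names(timing)) {
    for (s in c("left", "right")) {
      lb <- paste0(if (s == "left") "L" else "R", m)
      out[[lb]] <- muscle_template(m, s, timing[[m]]$phase, timing[[m]]$width)
    }
  }
  out
}

#' Simulation configuration for a synthetic gait cohort
#'
#' Defaults emulate a small overground-walking study: six patients with
#' four trials each of three minutes of steady walking, cycle-duration
#' jitter at the 15 ms MAD scale, moderate patient-level variability in
#' muscle gains (30%) and burst timing (3% of the cycle), and mild sensor
#' noise. When `linear_ground_truth` is `TRUE`, each muscle's activation
#' envelope is an exact affine function of its leg's angular velocity
#' delayed by a muscle-specific lag, so a lagged linear readout can in
#' principle reconstruct the angular velocity perfectly.
#'
#' @param n_patients,trials_per_patient,trial_duration_s Cohort size.
#' @param cycle_jitter_ms Cycle-duration variability (MAD scale, ms).
#' @param patient_gain_cv Patient-level coefficient of variation of muscle
#'   gains.
#' @param patient_phase_sd Patient-level SD of burst-phase shifts (cycle
#'   fraction).
#' @param patient_amp_cv,cycle_amp_cv Patient- and cycle-level CV of the
#'   swing-peak amplitude.
#' @param emg_noise_sd Additive sensor noise on raw EMG (a.u.).
#' @param imu_noise_sd Additive noise on raw angular velocity (deg/s).
#' @param linear_ground_truth Use the exactly linear EMG-envelope model.
#' @param emg_carrier Amplitude-modulate an in-band carrier (broadband
#'   noise in burst mode, a deterministic 90 Hz sinusoid in linear
#'   ground-truth mode; see [generate_emg()]); `FALSE` emits the envelope
#'   itself, useful for closed-loop tests that bypass the bandpass stage.
#' @param emg_fs,imu_fs Raw device rates (Hz).
#' @param seed Mandatory RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 6, trials_per_patient = 4,
                              trial_duration_s = 180,
                              cycle_jitter_ms = 15,
                              patient_gain_cv = 0.3,
                              patient_phase_sd = 0.03,
                              patient_amp_cv = 0.08,
                              cycle_amp_cv = 0.04,
                              emg_noise_sd = 0.02,
                              imu_noise_sd = 2,
                              linear_ground_truth = FALSE,
                              emg_carrier = TRUE,
                              emg_fs = 1000, imu_fs = 128,
                              seed = 1L) {
  stopifnot(n_patients >= 1, trials_per_patient >= 1, trial_duration_s > 5,
            cycle_jitter_ms >= 0, patient_gain_cv >= 0,
            patient_phase_sd >= 0, patient_amp_cv >= 0, cycle_amp_cv >= 0,
            emg_noise_sd >= 0, imu_noise_sd >= 0,
            emg_fs > 0, imu_fs > 0, length(seed) == 1L, is.finite(seed))
  structure(as.list(environment()), class = "simulation_config")
}

# Evaluate a piecewise-smoothstep knot sequence at arbitrary times.
# knots: data.frame(t, v); zero outside the outermost knots.
.eval_knots <- function(knots, times) {
  out <- numeric(length(times))
  kt <- knots$t; kv <- knots$v
  seg <- findInterval(times, kt)
  inside <- seg >= 1L & seg < length(kt)
  s0 <- seg[inside]
  u <- (times[inside] - kt[s0]) / (kt[s0 + 1L] - kt[s0])
  sm <- u * u * (3 - 2 * u)
  out[inside] <- kv[s0] + (kv[s0 + 1L] - kv[s0]) * sm
  out[!inside & times >= kt[length(kt)]] <- kv[length(kv)]
  out[!inside & times < kt[1L]] <- kv[1L]
  out
}

# Build the knot sequence and event list for one leg's cycle train.
# Returns list(knots, events = data.frame(type, time_s), swp_times).
.build_cycle_knots <- function(tmpl, duration_s, start_offset_s,
                               cycle_jitter_sd_s, amp_scale, cycle_amp_cv) {
  D0 <- tmpl$cycle_duration_ms / 1000
  lead <- 0.5
  swp <- start_offset_s + lead
  swp_times <- numeric(); durs <- numeric()
  repeat {
    d <- D0 + stats::rnorm(1, 0, cycle_jitter_sd_s)
    d <- max(d, 0.75 * D0)  # keep inter-peak distance above the separation rule
    if (swp + d > duration_s - lead) break
    swp_times <- c(swp_times, swp)
    durs <- c(durs, d)
    swp <- swp + d
  }
  swp_times <- c(swp_times, swp)  # final peak
  n <- length(swp_times)
  amps <- tmpl$swp_amplitude * amp_scale *
    (1 + stats::rnorm(n, 0, cycle_amp_cv))
  amps <- pmax(amps, 170)  # amplitudes must clear the 150 deg/s threshold
  mid_phase <- (tmpl$hc_phase + tmpl$to_phase) / 2
  kt <- c(swp_times[1L] - 0.3 * D0); kv <- c(0)
  ev_type <- character(); ev_time <- numeric()
  for (i in seq_len(n)) {
    kt <- c(kt, swp_times[i]); kv <- c(kv, amps[i])
    ev_type <- c(ev_type, "SWP"); ev_time <- c(ev_time, swp_times[i])
    if (i < n) {
      d <- durs[i]; s <- swp_times[i]
      hc_t <- s + tmpl$hc_phase * d
      to_t <- s + tmpl$to_phase * d
      kt <- c(kt, hc_t, s + mid_phase * d, to_t)
      kv <- c(kv, -tmpl$hc_depth, tmpl$mid_amplitude, -tmpl$to_depth)
      ev_type <- c(ev_type, "HC", "TO"); ev_time <- c(ev_time, hc_t, to_t)
    }
  }
  kt <- c(kt, swp_times[n] + 0.3 * D0); kv <- c(kv, 0)
  list(knots = data.frame(t = kt, v = kv),
       events = data.frame(type = ev_type, time_s = ev_time,
                           stringsAsFactors = FALSE),
       swp_times = swp_times)
}

#' Generate one leg's angular-velocity cycle train
#'
#' Produces a sampled angular-velocity trace containing one swing peak
#' (above the 150 deg/s detection threshold) and planted HC/TO minima per
#' cycle, together with the exact ground-truth event times. Cycle durations
#' are the nominal duration plus Gaussian jitter scaled so its median
#' absolute deviation equals `cycle_jitter_ms`.
#'
#' Uses the R session RNG; seed upstream (as [generate_cohort()] does).
#'
#' @param tmpl A [gait_template()].
#' @param duration_s Trace duration (s).
#' @param fs Sampling rate (Hz).
#' @param side Leg.
#' @param cycle_jitter_ms MAD-scale duration jitter (ms).
#' @param start_offset_s Shifts the first swing peak (used to put the two
#'   legs in antiphase).
#' @param amp_scale Multiplicative swing-amplitude factor (patient level).
#' @param cycle_amp_cv Cycle-level amplitude CV.
#' @param noise_sd Additive Gaussian noise (deg/s).
#' @param label Channel label.
#' @return List: `channel` (the sampled [signal_channel()]), `events`
#'   ([gait_events()] table, times on the channel's own clock), `knots`
#'   (the exact piecewise representation, for re-evaluation at other
#'   rates).
#' @export
generate_cycle_train <- function(tmpl, duration_s, fs = 200,
                                 side = "left", cycle_jitter_ms = 0,
                                 start_offset_s = 0, amp_scale = 1,
                                 cycle_amp_cv = 0, noise_sd = 0,
                                 label = paste0(toupper(substr(side, 1, 1)),
                                                "_IMU")) {
  stopifnot(inherits(tmpl, "gait_template"), duration_s > 2, fs > 0)
  jitter_sd_s <- cycle_jitter_ms / 1000 * 1.4826  # MAD -> SD for a Gaussian
  built <- .build_cycle_knots(tmpl, duration_s, start_offset_s,
                              jitter_sd_s, amp_scale, cycle_amp_cv)
  n <- round(duration_s * fs)
  times <- (seq_len(n) - 1) / fs
  x <- .eval_knots(built$knots, times)
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  ch <- signal_channel(label, side, "angular_velocity", fs, x)
  ev <- built$events
  ev <- ev[ev$time_s >= 0 & ev$time_s < duration_s, , drop = FALSE]
  list(channel = ch,
       events = gait_events(rep(side, nrow(ev)), ev$type, ev$time_s),
       knots = built$knots)
}

# Raised-cosine burst envelope on [phase-width/2, phase+width/2] of each cycle.
.burst_envelope <- function(times, swp_times, durs, phase, width, gain) {
  env <- numeric(length(times))
  for (i in seq_along(swp_times)) {
    d <- durs[i]
    centre <- swp_times[i] + phase * d
    half <- width * d / 2
    lo <- centre - half; hi <- centre + half
    j <- which(times >= lo & times <= hi)
    if (length(j))
      env[j] <- env[j] +
        gain * 0.5 * (1 + cos(pi * (times[j] - centre) / half))
  }
  env
}

#' Generate raw EMG channels for one trial
#'
#' For each muscle template, builds an activation envelope phase-locked to
#' its own leg's cycle train (or, in linear ground-truth mode, an affine
#' function of the leg's angular velocity delayed by a muscle-specific
#' lag), then emits raw EMG as a zero-mean in-band carrier amplitude-
#' modulated by the envelope, plus additive sensor noise. Rectification and
#' smoothing in the preprocessing chain recover the envelope up to scale.
#' Burst mode uses a broadband Gaussian carrier (realistic surface-EMG
#' statistics, with the corresponding stochastic envelope-estimation
#' noise); linear ground-truth mode uses a deterministic 90 Hz sinusoidal
#' carrier so the recovered envelope is an exact known linear function of
#' the delayed angular velocity, enabling perfect-recovery tests.
#'
#' @param leg_trains Named list (`left`, `right`) of
#'   [generate_cycle_train()] results.
#' @param templates List of [muscle_template()]s (see
#'   [default_muscle_templates()]).
#' @param duration_s Trial duration (s).
#' @param fs EMG sampling rate (Hz).
#' @param linear_ground_truth,carrier,noise_sd See [simulation_config()].
#' @param linear_delays_ms Named per-muscle delays (ms) of the EMG envelope
#'   behind the angular velocity in linear mode.
#' @param phase_shift,gain_scale Named per-template patient-level
#'   perturbations (cycle-fraction shift; multiplicative gain), defaults
#'   none.
#' @return List: `channels` (raw EMG [signal_channel()]s), `envelopes`
#'   (noise-free envelopes as channels, same rate).
#' @export
generate_emg <- function(leg_trains, templates, duration_s, fs = 1000,
                         linear_ground_truth = FALSE, carrier = TRUE,
                         noise_sd = 0,
                         linear_delays_ms = c(Ta = -100, S = 50, Gm = 80,
                                              Gl = 120, Vl = 150),
                         phase_shift = NULL, gain_scale = NULL) {
  n <- round(duration_s * fs)
  times <- (seq_len(n) - 1) / fs
  channels <- list(); envelopes <- list()
  for (lb in names(templates)) {
    tp <- templates[[lb]]
    train <- leg_trains[[tp$side]]
    gain <- tp$gain * (gain_scale[[lb]] %||% 1)
    if (linear_ground_truth) {
      delay_s <- linear_delays_ms[[tp$muscle]] / 1000
      av <- .eval_knots(train$knots, times - delay_s)
      lohi <- range(train$knots$v)
      env <- gain * (0.1 + 0.9 * (av - lohi[1]) / diff(lohi))
    } else {
      swp <- sort(train$events$time_s[train$events$type == "SWP"])
      durs <- c(diff(swp), stats::median(diff(swp)))
      ph <- (tp$burst_phase + (phase_shift[[lb]] %||% 0)) %% 1
      env <- 0.05 * gain +
        .burst_envelope(times, swp, durs, ph, tp$burst_width, gain)
    }
    x <- if (!carrier) env
    else if (linear_ground_truth)
      # deterministic in-band carrier: its decimated phase orbit is
      # periodic, so rectification + the moving median demodulate it to an
      # exact constant factor and the recovered envelope stays an exact
      # affine image of the delayed angular velocity
      sin(2 * pi * 90 * times) * env
    else stats::rnorm(n) * env
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    channels[[lb]] <- signal_channel(lb, tp$side, "emg", fs, x)
    envelopes[[lb]] <- signal_channel(paste0(lb, "_env"), tp$side, "emg",
                                      fs, env)
  }
  list(channels = channels, envelopes = envelopes)
}

#' Generate a synthetic gait cohort
#'
#' Produces raw-format recordings (EMG at `emg_fs`, angular velocity at
#' `imu_fs`, device-specific TTL marks, annotated walking bounds) plus
#' ground-truth event tables on the walking timeline, for
#' `n_patients x trials_per_patient` trials. Patients differ in muscle
#' gains, burst timing and swing amplitude; the two legs walk in
#' antiphase. Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @param tmpl A [gait_template()].
#' @param templates Muscle templates ([default_muscle_templates()] by
#'   default); subset to fewer muscles for faster runs.
#' @param out_dir Optional directory: when given, each trial is written as
#'   `<patient>_<trial>.csv` / `.meta.yaml` / `.truth.events.csv`.
#' @return List of trials, each with `recording` (raw [gait_recording()]),
#'   `truth` (event table on the walking timeline) and ids.
#' @export
generate_cohort <- function(cfg = simulation_config(),
                            tmpl = gait_template(),
                            templates = default_muscle_templates(),
                            out_dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  ttl <- c(emg = 0.5, angular_velocity = 0.25)
  walk_start <- 1.0
  D0 <- tmpl$cycle_duration_ms / 1000
  trials <- list()
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    amp_scale <- max(0.7, 1 + stats::rnorm(1, 0, cfg$patient_amp_cv))
    gain_scale <- lapply(templates, function(tp)
      max(0.2, 1 + stats::rnorm(1, 0, cfg$patient_gain_cv)))
    phase_shift <- lapply(templates, function(tp)
      stats::rnorm(1, 0, cfg$patient_phase_sd))
    for (tr in seq_len(cfg$trials_per_patient)) {
      tid <- sprintf("T%02d", tr)
      dur <- cfg$trial_duration_s
      trains <- list(
        left = generate_cycle_train(tmpl, dur, fs = 200, side = "left",
                                    cycle_jitter_ms = cfg$cycle_jitter_ms,
                                    amp_scale = amp_scale,
                                    cycle_amp_cv = cfg$cycle_amp_cv),
        right = generate_cycle_train(tmpl, dur, fs = 200, side = "right",
                                     cycle_jitter_ms = cfg$cycle_jitter_ms,
                                     start_offset_s = 0.5 * D0,
                                     amp_scale = amp_scale,
                                     cycle_amp_cv = cfg$cycle_amp_cv))
      emg <- generate_emg(trains, templates, dur, fs = cfg$emg_fs,
                          linear_ground_truth = cfg$linear_ground_truth,
                          carrier = cfg$emg_carrier,
                          noise_sd = cfg$emg_noise_sd,
                          phase_shift = phase_shift,
                          gain_scale = gain_scale)
      # raw device streams: re-evaluate the exact trains at the IMU rate,
      # then pad so the TTL edge and walking onset land where annotated
      imu_raw <- lapply(trains, function(tn) {
        n <- round(dur * cfg$imu_fs)
        t_i <- (seq_len(n) - 1) / cfg$imu_fs
        x <- .eval_knots(tn$knots, t_i)
        if (cfg$imu_noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$imu_noise_sd)
        signal_channel(tn$channel$label, tn$channel$side, "angular_velocity",
                       cfg$imu_fs, x)
      })
      pad_channel <- function(ch, pre_s, post_s, pad_sd) {
        n_pre <- round(pre_s * ch$fs); n_post <- round(post_s * ch$fs)
        pad <- function(k) if (pad_sd > 0) stats::rnorm(k, 0, pad_sd)
                           else numeric(k)
        ch$samples <- c(pad(n_pre), ch$samples, pad(n_post))
        ch
      }
      chans <- c(
        lapply(emg$channels, pad_channel,
               pre_s = ttl[["emg"]] + walk_start, post_s = 0.5,
               pad_sd = max(cfg$emg_noise_sd, 1e-3)),
        lapply(imu_raw, pad_channel,
               pre_s = ttl[["angular_velocity"]] + walk_start, post_s = 0.5,
               pad_sd = cfg$imu_noise_sd))
      rec <- gait_recording(pid, tid, chans,
                            ttl_onset_s = ttl,
                            ttl_offset_s = ttl + walk_start + dur + 0.25,
                            walk_start_s = walk_start,
                            walk_end_s = walk_start + dur)
      truth <- rbind(trains$left$events, trains$right$events)
      truth <- gait_events(truth$leg, truth$type, truth$time_s)
      if (!is.null(out_dir)) {
        base <- file.path(out_dir, paste0(pid, "_", tid))
        write_recording(rec, paste0(base, ".csv"),
                        paste0(base, ".meta.yaml"))
        write_events(truth, paste0(base, ".truth.events.csv"))
      }
      trials[[length(trials) + 1L]] <-
        list(patient_id = pid, trial_id = tid, recording = rec,
             truth = truth)
    }
  }
  trials
}
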