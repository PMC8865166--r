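# Synthetic driving-session simulator: cohorts of participants with known
# ground truth (beat times, injected cardiac templates, speed profiles,
# exclusion flags) so every downstream stage is testable without raw data.

#' Biphasic evoked-cardiac-response template
#'
#' Describes the stereotyped anticipatory cardiac signature: an initial
#' heart-rate deceleration (freezing/orienting, "ECR1") followed by an
#' acceleration (fight-or-flight mobilisation, "ECR2"). Each lobe is a
#' compact raised-cosine bump of half-width `2 * lobe_width`, so the
#' template is continuous, is exactly zero for `t <= 0`, and vanishes
#' beyond `accel_peak_time + 3 * lobe_width`.
#'
#' @param decel_amplitude Deceleration depth in bpm (must be `<= 0`).
#' @param decel_peak_time Time of maximal deceleration, seconds after onset.
#' @param accel_amplitude Acceleration height in bpm (must be `>= 0`).
#' @param accel_peak_time Time of maximal acceleration, seconds after onset.
#' @param lobe_width Lobe scale in seconds; each lobe spans
#'   `peak_time +/- 2 * lobe_width`.
#' @return An object of class `ecr_template`.
#' @examples
#' tpl <- ecr_template(-5, 1, 6, 3)
#' eval_ecr(tpl, c(0, 1, 3, 6))
#' @export
ecr_template <- function(decel_amplitude = -5, decel_peak_time = 1,
                         accel_amplitude = 6, accel_peak_time = 3,
                         lobe_width = 0.5) {
  stopifnot_scalar_num(decel_amplitude, "decel_amplitude", hi = 0)
  stopifnot_scalar_num(accel_amplitude, "accel_amplitude", lo = 0)
  stopifnot_scalar_num(lobe_width, "lobe_width", lo = 1e-6)
  if (!(decel_peak_time < accel_peak_time)) {
    abort("decel_peak_time must precede accel_peak_time")
  }
  if (decel_peak_time < 2 * lobe_width) {
    abort("decel_peak_time must be at least 2 * lobe_width so the template is zero at t <= 0")
  }
  structure(
    list(decel_amplitude = decel_amplitude, decel_peak_time = decel_peak_time,
         accel_amplitude = accel_amplitude, accel_peak_time = accel_peak_time,
         lobe_width = lobe_width),
    class = "ecr_template"
  )
}

raised_cosine_bump <- function(t, peak, halfwidth) {
  u <- (t - peak) / halfwidth
  ifelse(abs(u) < 1, cos(pi * u / 2)^2, 0)
}

#' Evaluate an ECR template
#'
#' @param template An [ecr_template()].
#' @param t Times in seconds relative to the anchoring onset.
#' @return Heart-rate offsets in bpm (vectorised over `t`).
#' @export
eval_ecr <- function(template, t) {
  stopifnot(inherits(template, "ecr_template"))
  w <- 2 * template$lobe_width
  template$decel_amplitude * raised_cosine_bump(t, template$decel_peak_time, w) +
    template$accel_amplitude * raised_cosine_bump(t, template$accel_peak_time, w)
}

#' @export
print.ecr_template <- function(x, ...) {
  cat(sprintf("<ecr_template> decel %.2f bpm @ %.2f s, accel %.2f bpm @ %.2f s, lobe %.2f s\n",
              x$decel_amplitude, x$decel_peak_time,
              x$accel_amplitude, x$accel_peak_time, x$lobe_width))
  invisible(x)
}

default_ecr_by_condition <- function() {
  list(
    U = list(
      postcue = NULL, # cue invisible: no anticipatory response
      postevent = ecr_template(-4, 1, 6, 3, 0.5)
    ),
    P = list(
      postcue = ecr_template(-5, 1, 6, 3, 0.5),
      postevent = ecr_template(-3, 1, 4, 3, 0.5)
    ),
    PF = list(
      postcue = ecr_template(-4, 2, 5, 5, 1),
      postevent = ecr_template(-3, 1.5, 4, 4, 0.75)
    )
  )
}

#' Session configuration for the synthetic simulator
#'
#' Defaults reproduce the study conditions: ECG at 500 Hz, speed at 10 Hz,
#' 10-minute trips, the printed mean cue/event durations for the three
#' hazard-predictability conditions (U unpredictable, P predictable,
#' PF predictable and familiar), and two perceived-stress subpopulations
#' rating on a 1-5 Likert scale. PF's cue and event also occur in the
#' control trip (Trip 1) — its first exposure carries the same cardiac
#' template attenuated by `pf_control_scale`.
#'
#' @param baseline_hr Resting heart rate, bpm.
#' @param hrv_sd Beat-to-beat rate noise SD, bpm.
#' @param rsa_amplitude Amplitude of a sinusoidal respiratory modulation, bpm.
#' @param rsa_freq Respiratory frequency, Hz.
#' @param rsa_phase Respiratory phase offset, radians (randomised per
#'   participant at the cohort level so the modulation averages out).
#' @param ecg_fs ECG sampling rate, Hz (must exceed twice the 40 Hz filter
#'   edge).
#' @param speed_fs Speed sampling rate, Hz.
#' @param base_speed Cruising speed, km/h.
#' @param speed_noise_sd White-noise SD on the speed trace, km/h.
#' @param trip_duration_s Duration of each recorded trip, seconds.
#' @param condition_timings Named list per condition with
#'   `cue_duration_s`, `event_duration_s` and `cue_event_gap_s` (cue onset to
#'   event onset).
#' @param cue_onsets_s Named vector of cue-onset times (seconds from trip
#'   start) for U, P and PF; identical in both trips (same route).
#' @param ecr_by_condition Nested list `condition -> window -> ecr_template`
#'   (or `NULL` for no injected response).
#' @param pf_control_scale Amplitude factor applied to PF templates in
#'   Trip 1 (first exposure).
#' @param speed_decel_profile List with `onset_lag_s`, `magnitude_kmh`,
#'   `ramp_s`: the event-locked deceleration shape.
#' @param stress_group `"high"` or `"low"` perceived-stress subpopulation.
#' @param rating_distributions Named list giving, per group, a probability
#'   vector over ratings 1..5.
#' @param ecg_noise_sd Broadband ECG noise SD, in units of the R amplitude
#'   (R apex is 1).
#' @return A list of class `session_config`.
#' @export
session_config <- function(baseline_hr = 75,
                           hrv_sd = 2.5,
                           rsa_amplitude = 2,
                           rsa_freq = 0.25,
                           rsa_phase = 0,
                           ecg_fs = 500,
                           speed_fs = 10,
                           base_speed = 70,
                           speed_noise_sd = 0.4,
                           trip_duration_s = 600,
                           condition_timings = list(
                             U  = list(cue_duration_s = 0,    event_duration_s = 1.83, cue_event_gap_s = 4.5),
                             P  = list(cue_duration_s = 4.41, event_duration_s = 3.01, cue_event_gap_s = 4.5),
                             PF = list(cue_duration_s = 7.24, event_duration_s = 3.73, cue_event_gap_s = 7.5)
                           ),
                           cue_onsets_s = c(U = 120, P = 300, PF = 480),
                           ecr_by_condition = default_ecr_by_condition(),
                           pf_control_scale = 0.6,
                           speed_decel_profile = list(onset_lag_s = 0.5,
                                                      magnitude_kmh = 12,
                                                      ramp_s = 2),
                           stress_group = "high",
                           rating_distributions = list(
                             high = c(0, 0, 1, 1, 1) / 3,
                             low  = c(1, 1, 0, 0, 0) / 2
                           ),
                           ecg_noise_sd = 0.05) {
  stopifnot_scalar_num(baseline_hr, "baseline_hr", 30, 200)
  stopifnot_scalar_num(hrv_sd, "hrv_sd", 0)
  stopifnot_scalar_num(ecg_fs, "ecg_fs", lo = 1)
  if (ecg_fs <= 2 * 40) abort("ecg_fs must exceed 80 Hz so the 2-40 Hz band is representable")
  stopifnot_scalar_num(trip_duration_s, "trip_duration_s", lo = 1e-9)
  stopifnot(stress_group %in% c("high", "low"))
  for (cond in names(condition_timings)) {
    tm <- condition_timings[[cond]]
    if (tm$event_duration_s <= 0 || tm$cue_event_gap_s <= 0) {
      abort(sprintf("durations for condition %s must be positive", cond))
    }
  }
  structure(
    list(baseline_hr = baseline_hr, hrv_sd = hrv_sd,
         rsa_amplitude = rsa_amplitude, rsa_freq = rsa_freq,
         rsa_phase = rsa_phase,
         ecg_fs = ecg_fs, speed_fs = speed_fs,
         base_speed = base_speed, speed_noise_sd = speed_noise_sd,
         trip_duration_s = trip_duration_s,
         condition_timings = condition_timings,
         cue_onsets_s = cue_onsets_s,
         ecr_by_condition = ecr_by_condition,
         pf_control_scale = pf_control_scale,
         speed_decel_profile = speed_decel_profile,
         stress_group = stress_group,
         rating_distributions = rating_distributions,
         ecg_noise_sd = ecg_noise_sd),
    class = "session_config"
  )
}

#' Sample an R-R beat train from an instantaneous-rate model
#'
#' Beats are generated iteratively: the next interval is `60 / rate(t)`
#' where `rate(t) = baseline_hr + ecr_delta(t) + rsa(t) + noise`, with
#' zero-mean Gaussian noise of SD `hrv_sd` on the bpm scale. Intervals are
#' clamped to the physiological range \[0.3, 2.0\] s. With noise and
#' modulation off the scheme is exact: a constant 60 bpm rate over 10 s
#' yields beats at 0, 1, ..., 10 s.
#'
#' @param config A [session_config()].
#' @param ecr_delta Function of time (s) returning a bpm offset, or `NULL`.
#' @param duration Duration to cover, seconds.
#' @param seed Integer seed for the beat-to-beat noise.
#' @return Numeric vector of strictly increasing beat times in seconds.
#' @export
sample_rr_train <- function(config, ecr_delta = NULL, duration, seed = 1L) {
  stopifnot(inherits(config, "session_config"))
  stopifnot_scalar_num(duration, "duration", lo = 1e-9)
  delta <- if (is.null(ecr_delta)) function(t) 0 else ecr_delta
  rsa <- function(t) {
    if (config$rsa_amplitude == 0) 0
    else config$rsa_amplitude * sin(2 * pi * config$rsa_freq * t + config$rsa_phase)
  }
  with_seed(seed, {
    n_guess <- ceiling(duration * (config$baseline_hr + 40) / 60) + 8L
    beats <- numeric(n_guess)
    t <- 0
    n <- 1L
    beats[1L] <- 0
    repeat {
      noise_i <- if (config$hrv_sd > 0) rnorm(1L, 0, config$hrv_sd) else 0
      rate_at <- function(tt) {
        d <- delta(tt)
        if (!is.finite(d)) abort("ecr_delta returned a non-finite value; rejecting config")
        config$baseline_hr + d + rsa(tt) + noise_i
      }
      # interval solved so that 60 / RRI equals the instantaneous rate at the
      # *closing* beat (where the heart-rate knot is placed downstream);
      # fixed-point iteration, exact in the constant-rate limit
      rri <- min(2.0, max(0.3, 60 / rate_at(t)))
      for (it in 1:3) rri <- min(2.0, max(0.3, 60 / rate_at(t + rri)))
      if (t + rri > duration + 1e-9) break
      t <- t + rri
      n <- n + 1L
      if (n > length(beats)) beats <- c(beats, numeric(n_guess))
      beats[n] <- t
    }
    beats[seq_len(n)]
  })
}

default_ecg_morphology <- function() {
  # offsets/widths in seconds, amplitudes relative to R = 1
  list(
    P = list(offset = -0.20, width = 0.025, amp = 0.15),
    Q = list(offset = -0.03, width = 0.010, amp = -0.10),
    R = list(offset =  0.00, width = 0.012, amp = 1.00),
    S = list(offset =  0.03, width = 0.010, amp = -0.20),
    T = list(offset =  0.25, width = 0.045, amp = 0.30)
  )
}

#' Render a beat train as a uniform synthetic ECG
#'
#' Each beat is drawn as a fixed P-QRS-T template (a sum of localized
#' Gaussian bumps) with the R apex snapped to the sample grid at the beat
#' time; broadband Gaussian noise is added on top. The R wave dominates the
#' other waves by more than 3x, which is what the downstream detector needs.
#'
#' @param beat_times Strictly increasing beat times, seconds.
#' @param ecg_fs Sampling rate, Hz.
#' @param morphology Wave parameter list (see `default_ecg_morphology`).
#' @param noise_sd Additive noise SD in units of the R amplitude.
#' @param duration Recording length in seconds; defaults to the last beat
#'   plus half a second (1 s for an empty beat list).
#' @param seed Integer seed for the noise.
#' @return A tibble with columns `time_s`, `mv` and attribute `fs`.
#' @export
synthesize_ecg <- function(beat_times, ecg_fs = 500,
                           morphology = default_ecg_morphology(),
                           noise_sd = 0, duration = NULL, seed = 1L) {
  if (length(beat_times) >= 2 && any(diff(beat_times) < 0.3)) {
    abort("beat intervals below 0.3 s: P-QRS-T templates would overlap")
  }
  if (is.null(duration)) {
    duration <- if (length(beat_times)) max(beat_times) + 0.5 else 1
  }
  n <- floor(duration * ecg_fs) + 1L
  time_s <- (seq_len(n) - 1L) / ecg_fs
  mv <- numeric(n)
  half_support <- 0.35 # seconds each side of the R apex worth rendering
  for (bt in beat_times) {
    centre <- round(bt * ecg_fs) / ecg_fs
    i0 <- max(1L, floor((centre - half_support) * ecg_fs) + 1L)
    i1 <- min(n, ceiling((centre + half_support) * ecg_fs) + 1L)
    if (i0 > i1) next
    tt <- time_s[i0:i1] - centre
    seg <- numeric(length(tt))
    for (w in morphology) {
      seg <- seg + w$amp * exp(-0.5 * ((tt - w$offset) / w$width)^2)
    }
    mv[i0:i1] <- mv[i0:i1] + seg
  }
  if (noise_sd > 0) {
    mv <- mv + with_seed(seed, rnorm(n, 0, noise_sd))
  }
  out <- tibble(time_s = time_s, mv = mv)
  attr(out, "fs") <- ecg_fs
  out
}

# time-locked bpm offset built from all templates injected in one trip
trip_delta_fun <- function(anchors) {
  # anchors: list of list(onset, template, scale)
  force(anchors)
  function(t) {
    total <- 0
    for (a in anchors) {
      rel <- t - a$onset
      if (rel > 0 && rel < a$template$accel_peak_time + 3 * a$template$lobe_width) {
        total <- total + a$scale * eval_ecr(a$template, rel)
      }
    }
    total
  }
}

speed_trace <- function(config, decel_onsets, scale_by_onset, seed) {
  dt <- 1 / config$speed_fs
  time_s <- seq(0, config$trip_duration_s, by = dt)
  prof <- config$speed_decel_profile
  kmh <- rep(config$base_speed, length(time_s))
  for (i in seq_along(decel_onsets)) {
    t0 <- decel_onsets[i] + prof$onset_lag_s
    mag <- prof$magnitude_kmh * scale_by_onset[i]
    ramp <- prof$ramp_s
    rel <- time_s - t0
    drop <- numeric(length(time_s))
    drop[rel >= 0 & rel < ramp] <- mag * rel[rel >= 0 & rel < ramp] / ramp
    drop[rel >= ramp & rel < 2 * ramp] <- mag
    recov <- rel >= 2 * ramp & rel < 4 * ramp
    drop[recov] <- mag * (1 - (rel[recov] - 2 * ramp) / (2 * ramp))
    kmh <- kmh - drop
  }
  if (config$speed_noise_sd > 0) {
    kmh <- kmh + with_seed(seed, rnorm(length(time_s), 0, config$speed_noise_sd))
  }
  tibble(time_s = time_s, kmh = kmh)
}

template_params <- function(tpl) {
  if (is.null(tpl)) NULL else unclass(tpl)
}

#' Generate one synthetic driving session
#'
#' Emits a two-trip session: Trip 1 is the control drive on the simulated
#' route, Trip 2 the experimental drive on the same route. Cue and event
#' markers sit at identical route positions in both trips. Trip 2 injects
#' the configured cardiac templates and event-locked speed decelerations;
#' Trip 1 injects none for U and P (safe passages) but carries PF's first
#' exposure at `pf_control_scale` amplitude, since PF's cue and event are
#' present in the control drive too. A perceived-stress rating (1-5) is
#' drawn from the participant's group distribution for U and P only; the PF
#' condition has no safe Trip 1 counterpart to rate against.
#'
#' @param config A [session_config()].
#' @param seed Integer seed; identical `(config, seed)` give byte-identical
#'   output.
#' @param pid Participant identifier.
#' @param render_ecg Render the raw ECG waveform? With `FALSE` the session
#'   carries only the ground-truth beat times (fast path for calibration
#'   studies that skip the detector).
#' @return A list of class `driver_session` with tibbles `ecg`, `speed`,
#'   `markers`, `ratings` and a ground-truth manifest `truth`.
#' @export
generate_session <- function(config, seed = 1L, pid = "p01", render_ecg = TRUE) {
  stopifnot(inherits(config, "session_config"))
  conds <- names(config$cue_onsets_s)

  markers <- purrr::map_dfr(1:2, function(trip) {
    purrr::map_dfr(conds, function(cond) {
      tm <- config$condition_timings[[cond]]
      cue_on <- unname(config$cue_onsets_s[[cond]])
      tibble(trip = trip, condition = cond,
             marker_type = c("cue_onset", "event_onset"),
             onset_s = c(cue_on, cue_on + tm$cue_event_gap_s),
             duration_s = c(tm$cue_duration_s, tm$event_duration_s))
    })
  })
  if (any(markers$onset_s + 8 > config$trip_duration_s)) {
    abort("marker within 8 s of recording end: epoch would be truncated")
  }
  if (any(markers$onset_s < 0.5)) {
    abort("marker before 0.5 s: baseline sample would precede the recording")
  }

  trips <- lapply(1:2, function(trip) {
    anchors <- list()
    for (cond in conds) {
      cue_on <- unname(config$cue_onsets_s[[cond]])
      ev_on <- cue_on + config$condition_timings[[cond]]$cue_event_gap_s
      for (win in c("postcue", "postevent")) {
        tpl <- config$ecr_by_condition[[cond]][[win]]
        if (is.null(tpl)) next
        scale <- if (trip == 2) 1
                 else if (cond == "PF") config$pf_control_scale
                 else 0
        if (scale == 0) next
        anchors[[length(anchors) + 1L]] <- list(
          onset = if (win == "postcue") cue_on else ev_on,
          template = tpl, scale = scale, condition = cond, window = win
        )
      }
    }
    delta <- trip_delta_fun(anchors)
    beats <- sample_rr_train(config, delta, config$trip_duration_s,
                             seed = substream_seed(seed, trip, salt = 1L))
    ecg <- if (render_ecg) {
      synthesize_ecg(beats, config$ecg_fs,
                     noise_sd = config$ecg_noise_sd,
                     duration = config$trip_duration_s,
                     seed = substream_seed(seed, trip, salt = 2L))
    } else NULL
    decel_onsets <- vapply(conds, function(cond) {
      unname(config$cue_onsets_s[[cond]]) +
        config$condition_timings[[cond]]$cue_event_gap_s
    }, numeric(1))
    decel_scale <- vapply(conds, function(cond) {
      if (trip == 2) 1 else if (cond == "PF") config$pf_control_scale else 0
    }, numeric(1))
    keep <- decel_scale > 0
    speed <- speed_trace(config, decel_onsets[keep], decel_scale[keep],
                         seed = substream_seed(seed, trip, salt = 3L))
    list(beats = beats, ecg = ecg, speed = speed, anchors = anchors)
  })

  probs <- config$rating_distributions[[config$stress_group]]
  ratings <- with_seed(substream_seed(seed, 0L, salt = 4L), {
    tibble(condition = c("U", "P"),
           rating = as.integer(sample(1:5, 2, replace = TRUE, prob = probs)))
  })

  ecg <- if (render_ecg) {
    dplyr::bind_rows(lapply(1:2, function(k) {
      dplyr::mutate(trips[[k]]$ecg, trip = k, .before = 1)
    }))
  } else NULL
  speed <- dplyr::bind_rows(lapply(1:2, function(k) {
    dplyr::mutate(trips[[k]]$speed, trip = k, .before = 1)
  }))

  truth <- list(
    pid = pid,
    stress_group = config$stress_group,
    exclusion_flag = "none",
    baseline_hr = config$baseline_hr,
    base_speed = config$base_speed,
    beat_times = list(trip1 = trips[[1]]$beats, trip2 = trips[[2]]$beats),
    injected_templates = lapply(1:2, function(k) {
      lapply(trips[[k]]$anchors, function(a) {
        c(list(condition = a$condition, window = a$window,
               onset_s = a$onset, scale = a$scale),
          template_params(a$template))
      })
    }),
    speed_profile = config$speed_decel_profile,
    seed = seed
  )

  structure(
    list(pid = pid, ecg = ecg, speed = speed, markers = markers,
         ratings = dplyr::mutate(ratings, pid = pid, .before = 1),
         truth = truth, config = config),
    class = "driver_session"
  )
}

#' @export
print.driver_session <- function(x, ...) {
  cat(sprintf("<driver_session> %s: %d trips, %.0f s each, %d markers, stress group %s\n",
              x$pid, length(unique(x$speed$trip)),
              x$config$trip_duration_s, nrow(x$markers),
              x$truth$stress_group))
  invisible(x)
}

#' Generate a synthetic cohort of driving sessions
#'
#' Participants get per-person jitter on baseline heart rate and cruising
#' speed, a perceived-stress group, and (optionally) exclusion flags
#' mirroring the study's bookkeeping: `motion_sickness` participants did
#' not complete the experiment, `bad_ecg` participants have an
#' unsatisfactory ECG recording (the simulator corrupts their signal with
#' artifact spikes so the automated beat correction also condemns it).
#' One global seed fans out to per-participant substreams, so participant
#' `i`'s session is the same whatever the cohort size or order.
#'
#' @param n Number of enrolled participants.
#' @param config Base [session_config()] shared by the cohort.
#' @param exclusions Named list or vector with counts `motion_sickness` and
#'   `bad_ecg`; their sum must not exceed `n`.
#' @param stress_counts Optional named vector `c(high = ..., low = ...)`
#'   forcing exact group sizes (must sum to `n`); otherwise groups are drawn
#'   with probability `prop_high`.
#' @param prop_high Probability of the high-perceived-stress group when
#'   `stress_counts` is `NULL`.
#' @param hr_jitter_sd SD of the between-participant baseline-HR jitter, bpm.
#' @param speed_jitter_sd SD of the cruising-speed jitter, km/h.
#' @param render_ecg Render raw ECG waveforms (see [generate_session()]).
#' @param seed Global integer seed.
#' @return A list of class `driver_cohort`: `sessions` (named list of
#'   [generate_session()] outputs) and `manifest` (tibble: pid,
#'   stress_group, exclusion_flag, baseline_hr, base_speed).
#' @export
generate_cohort <- function(n, config = session_config(),
                            exclusions = list(motion_sickness = 0, bad_ecg = 0),
                            stress_counts = NULL, prop_high = 0.45,
                            hr_jitter_sd = 7, speed_jitter_sd = 4,
                            render_ecg = TRUE, seed = 1L) {
  if (n < 1) abort("n must be at least 1")
  n_ms <- as.integer(exclusions$motion_sickness %||% 0)
  n_bad <- as.integer(exclusions$bad_ecg %||% 0)
  if (n_ms + n_bad > n) abort("exclusion counts exceed cohort size")

  pids <- sprintf("p%02d", seq_len(n))
  # per-participant draws live in the participant's own substream so a given
  # (seed, index) pair yields the same session whatever the cohort size
  per <- lapply(seq_len(n), function(i) {
    with_seed(substream_seed(seed, i, salt = 11L), {
      list(hr_jit = rnorm(1, 0, hr_jitter_sd),
           sp_jit = rnorm(1, 0, speed_jitter_sd),
           rsa_phase = runif(1, 0, 2 * pi),
           group_u = runif(1))
    })
  })
  assign_df <- with_seed(substream_seed(seed, 0L, salt = 10L), {
    groups <- if (!is.null(stress_counts)) {
      if (sum(stress_counts) != n) abort("stress_counts must sum to n")
      sample(rep(c("high", "low"), times = c(stress_counts[["high"]],
                                             stress_counts[["low"]])))
    } else {
      ifelse(vapply(per, `[[`, numeric(1), "group_u") < prop_high,
             "high", "low")
    }
    flagged <- sample(seq_len(n), n_ms + n_bad)
    flags <- rep("none", n)
    flags[flagged[seq_len(n_ms)]] <- "motion_sickness"
    if (n_bad > 0) flags[flagged[n_ms + seq_len(n_bad)]] <- "bad_ecg"
    tibble(pid = pids, stress_group = groups, exclusion_flag = flags,
           hr_jit = vapply(per, `[[`, numeric(1), "hr_jit"),
           sp_jit = vapply(per, `[[`, numeric(1), "sp_jit"),
           rsa_phase = vapply(per, `[[`, numeric(1), "rsa_phase"))
  })

  sessions <- lapply(seq_len(n), function(i) {
    cfg_i <- config
    cfg_i$baseline_hr <- clamp(config$baseline_hr + assign_df$hr_jit[i], 45, 120)
    cfg_i$base_speed <- config$base_speed + assign_df$sp_jit[i]
    cfg_i$stress_group <- assign_df$stress_group[i]
    cfg_i$rsa_phase <- assign_df$rsa_phase[i]
    s <- generate_session(cfg_i, seed = substream_seed(seed, i), pid = pids[i],
                          render_ecg = render_ecg)
    flag <- assign_df$exclusion_flag[i]
    s$truth$exclusion_flag <- flag
    if (flag == "bad_ecg" && render_ecg) {
      s$ecg <- corrupt_ecg(s$ecg, seed = substream_seed(seed, i, salt = 5L))
    }
    s
  })
  names(sessions) <- pids

  manifest <- dplyr::transmute(
    assign_df, pid = .data$pid, stress_group = .data$stress_group,
    exclusion_flag = .data$exclusion_flag,
    baseline_hr = clamp(config$baseline_hr + .data$hr_jit, 45, 120),
    base_speed = config$base_speed + .data$sp_jit
  )
  structure(list(sessions = sessions, manifest = manifest, seed = seed),
            class = "driver_cohort")
}

# electrode-artifact corruption: dropout windows (detached-lead noise) that
# swallow ~30% of the beats, plus occasional motion spikes. The automated
# beat correction then has to repair well over its edit budget and condemns
# the record, mirroring a recording of unsatisfactory quality.
corrupt_ecg <- function(ecg, dropout_frac = 0.3, window_s = 2,
                        spike_rate_hz = 0.2, seed = 1L) {
  fs <- infer_fs(ecg$time_s[ecg$trip == ecg$trip[1]])
  with_seed(seed, {
    for (k in unique(ecg$trip)) {
      idx <- which(ecg$trip == k)
      dur <- diff(range(ecg$time_s[idx]))
      n_win <- ceiling(dropout_frac * dur / window_s)
      starts <- runif(n_win, 0, dur - window_s)
      t_rel <- ecg$time_s[idx] - min(ecg$time_s[idx])
      for (s0 in starts) {
        hit <- idx[t_rel >= s0 & t_rel < s0 + window_s]
        ecg$mv[hit] <- rnorm(length(hit), 0, 0.05)
      }
      n_spike <- max(1L, round(spike_rate_hz * dur))
      at <- sample(idx, n_spike)
      w <- round(0.006 * fs)
      for (j in at) {
        lo <- max(min(idx), j - w); hi <- min(max(idx), j + w)
        ecg$mv[lo:hi] <- ecg$mv[lo:hi] + 1.5
      }
    }
    ecg
  })
}

#' @export
print.driver_cohort <- function(x, ...) {
  tab <- table(x$manifest$exclusion_flag)
  cat(sprintf("<driver_cohort> %d participants (%s)\n",
              nrow(x$manifest),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Write a session bundle to disk
#'
#' Layout: `<pid>/trip<k>_ecg.tsv` (time_s, mv), `<pid>/trip<k>_speed.tsv`
#' (time_s, kmh), `<pid>/markers.tsv`, `<pid>/ratings.tsv` and a
#' `<pid>/truth.json` ground-truth manifest. Tab-delimited, header row,
#' UTF-8, '.' decimal separator; identical sessions write identical bytes.
#'
#' @param session A `driver_session`.
#' @param dir Target directory (the `<pid>` folder is created inside it).
#' @return The participant directory, invisibly.
#' @export
write_session_bundle <- function(session, dir) {
  stopifnot(inherits(session, "driver_session"))
  pdir <- file.path(dir, session$pid)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  for (k in unique(session$speed$trip)) {
    if (!is.null(session$ecg)) {
      write_tsv_det(dplyr::select(dplyr::filter(session$ecg, .data$trip == k), -"trip"),
                    file.path(pdir, sprintf("trip%d_ecg.tsv", k)))
    }
    write_tsv_det(dplyr::select(dplyr::filter(session$speed, .data$trip == k), -"trip"),
                  file.path(pdir, sprintf("trip%d_speed.tsv", k)))
  }
  write_tsv_det(session$markers, file.path(pdir, "markers.tsv"))
  write_tsv_det(dplyr::select(session$ratings, -"pid"),
                file.path(pdir, "ratings.tsv"))
  writeLines(jsonlite::toJSON(session$truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(pdir, "truth.json"))
  invisible(pdir)
}

#' Write a whole cohort bundle (sessions plus `cohort_manifest.tsv`)
#'
#' @param cohort A `driver_cohort`.
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(cohort, dir) {
  stopifnot(inherits(cohort, "driver_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$sessions) write_session_bundle(s, dir)
  write_tsv_det(dplyr::select(cohort$manifest, "pid", "stress_group",
                              "exclusion_flag"),
                file.path(dir, "cohort_manifest.tsv"))
  invisible(dir)
}

#' Read a session bundle written by [write_session_bundle()]
#'
#' @param pdir The participant directory.
#' @return A `driver_session`-shaped list (without the generating config).
#' @export
read_session_bundle <- function(pdir) {
  pid <- basename(pdir)
  trips <- sort(as.integer(sub("^trip(\\d+)_ecg\\.tsv$", "\\1",
                               list.files(pdir, pattern = "^trip\\d+_ecg\\.tsv$"))))
  ecg <- dplyr::bind_rows(lapply(trips, function(k) {
    dplyr::mutate(read_tsv_det(file.path(pdir, sprintf("trip%d_ecg.tsv", k))),
                  trip = k, .before = 1)
  }))
  speed <- dplyr::bind_rows(lapply(trips, function(k) {
    dplyr::mutate(read_tsv_det(file.path(pdir, sprintf("trip%d_speed.tsv", k))),
                  trip = k, .before = 1)
  }))
  ratings <- dplyr::mutate(read_tsv_det(file.path(pdir, "ratings.tsv")),
                           pid = pid, .before = 1)
  truth_path <- file.path(pdir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path) else NULL
  structure(
    list(pid = pid, ecg = ecg, speed = speed,
         markers = read_tsv_det(file.path(pdir, "markers.tsv")),
         ratings = ratings, truth = truth, config = NULL),
    class = "driver_session"
  )
}
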