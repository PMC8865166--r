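# cardiac preprocessing: filter, detector, beat correction, HR, resampling

test_that("band-pass filter attenuates DC and passes mid-band per its design response", {
  fs <- 500
  td <- seq(0, 60, by = 1 / fs)
  dc <- tibble::tibble(time_s = td, mv = rep(2, length(td)))
  outdc <- bandpass_filter(dc, fs = fs)
  mid <- outdc$mv[td > 20 & td < 40] # well clear of the filtfilt transients
  expect_lt(max(abs(mid)), 2 * 1e-6)
  t <- seq(0, 10, by = 1 / fs)

  # oracle: the squared magnitude response of the designed Butterworth
  bf <- signal::butter(4, c(2, 40) / (fs / 2), type = "pass")
  gain_at <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    h <- sum(bf$b * z^(0:(length(bf$b) - 1))) /
      sum(bf$a * z^(0:(length(bf$a) - 1)))
    Mod(h)^2 # filtfilt applies the filter forward and backward
  }
  for (f in c(10, 0.2)) {
    sine <- tibble::tibble(time_s = t, mv = sin(2 * pi * f * t))
    out <- bandpass_filter(sine, fs = fs)
    amp <- max(abs(out$mv[t > 4 & t < 6]))
    expect_equal(amp, gain_at(f), tolerance = 0.02)
  }
  # and the spec-level bands: ~unity at 10 Hz, strong rejection at 0.2 Hz
  s10 <- bandpass_filter(tibble::tibble(time_s = t, mv = sin(2 * pi * 10 * t)), fs = fs)
  expect_true(max(abs(s10$mv[t > 4 & t < 6])) >= 0.95 &&
                max(abs(s10$mv[t > 4 & t < 6])) <= 1.0)
  s02 <- bandpass_filter(tibble::tibble(time_s = t, mv = sin(2 * pi * 0.2 * t)), fs = fs)
  expect_lt(max(abs(s02$mv[t > 4 & t < 6])), 0.1)

  expect_error(bandpass_filter(dc[1:5000, ], high = 260, fs = fs), "Nyquist")
})

test_that("detector recovers clean beats to within 10 ms", {
  cfg <- session_config(baseline_hr = 60, hrv_sd = 0, rsa_amplitude = 0)
  beats <- sample_rr_train(cfg, NULL, duration = 59, seed = 1) + 0.5
  ecg <- synthesize_ecg(beats, 500, noise_sd = 0, duration = 60)
  det <- detect_r_peaks(bandpass_filter(ecg, fs = 500), fs = 500)
  expect_true(length(det) %in% c(60, 61))
  offsets <- vapply(beats, function(b) min(abs(det - b)), numeric(1))
  expect_lt(max(offsets), 0.010)
})

test_that("flat signal yields an empty detection with a warning", {
  flat <- tibble::tibble(time_s = seq(0, 5, by = 1 / 500), mv = 0)
  expect_warning(det <- detect_r_peaks(flat, fs = 500), "flat")
  expect_length(det, 0)
})

test_that("detector keeps >= 99% sensitivity and precision under 10% noise", {
  sens <- ppv <- numeric(0)
  for (s in 1:3) {
    cfg <- session_config(baseline_hr = 72, hrv_sd = 3)
    beats <- sample_rr_train(cfg, NULL, duration = 119, seed = s) + 0.5
    ecg <- synthesize_ecg(beats, 500, noise_sd = 0.10, duration = 120, seed = s)
    det <- detect_r_peaks(bandpass_filter(ecg, fs = 500), fs = 500)
    m <- match_beats(det, beats, tol = 0.05)
    sens <- c(sens, m$sensitivity)
    ppv <- c(ppv, m$ppv)
  }
  expect_gte(mean(sens), 0.99)
  expect_gte(mean(ppv), 0.99)
})

test_that("noise robustness: beat count shifts by at most 1% at 10% noise", {
  cfg <- session_config(baseline_hr = 70, hrv_sd = 2)
  beats <- sample_rr_train(cfg, NULL, duration = 299, seed = 4) + 0.5
  clean <- synthesize_ecg(beats, 500, noise_sd = 0, duration = 300)
  noisy <- synthesize_ecg(beats, 500, noise_sd = 0.10, duration = 300, seed = 5)
  n_clean <- length(detect_r_peaks(bandpass_filter(clean, fs = 500), fs = 500))
  n_noisy <- length(detect_r_peaks(bandpass_filter(noisy, fs = 500), fs = 500))
  expect_lte(abs(n_noisy - n_clean) / n_clean, 0.01)
})

test_that("beat correction fills missed beats and drops false triggers", {
  clean <- seq(0, 60, by = 0.8)
  cb <- correct_beats(clean)
  expect_true(all(cb$flag == "kept"))
  expect_false(attr(cb, "bad_ecg"))
  expect_equal(attr(cb, "n_edits"), 0)

  # delete the beat nearest t = 30 s: exactly one insertion close to it
  deleted <- clean[-which.min(abs(clean - 30))]
  cb2 <- correct_beats(deleted)
  ins <- cb2$r_time_s[cb2$flag == "inserted"]
  expect_length(ins, 1)
  expect_lt(abs(ins - clean[which.min(abs(clean - 30))]), 0.1)

  # a spurious double 40 ms after a true beat is removed (weaker apex)
  spur <- sort(c(clean, clean[20] + 0.04))
  amps <- ifelse(spur %in% clean, 1, 0.4)
  cb3 <- correct_beats(spur, amplitudes = amps)
  expect_equal(attr(cb3, "n_removed"), 1)
  expect_equal(cb3$r_time_s, clean, tolerance = 1e-12)

  # 30% spurious doubles condemn the record
  set.seed(1)
  idx <- sample(seq_along(clean)[-length(clean)], round(0.3 * length(clean)))
  bad <- sort(c(clean, clean[idx] + 0.05))
  cb4 <- correct_beats(bad)
  expect_true(attr(cb4, "bad_ecg"))
})

test_that("heart-rate conversion and the rate-interval identity hold", {
  hr <- instantaneous_hr(c(0, 1, 1.5, 2.25))
  expect_equal(hr$hr_bpm, c(60, 120, 80))
  expect_equal(hr$time_s, c(1, 1.5, 2.25))

  # HR * RRI = 60 for any corrected beat series
  cb <- correct_beats(cumsum(c(0, runif(50, 0.6, 1.1))))
  prod <- cb$hr_bpm[-1] * cb$rri_s[-1]
  expect_true(all(abs(prod - 60) < 1e-9))
})

test_that("spline resampling reproduces constants and quadratics, refuses extrapolation", {
  const <- tibble::tibble(time_s = c(0, 1, 2, 3, 4, 5), hr_bpm = 70)
  out <- resample_hr(const, 0, 5)
  expect_equal(out$hr_bpm, rep(70, 11))
  expect_equal(diff(out$time_s), rep(0.5, 10))

  # natural splines are exact for polynomials up to degree 1 everywhere and
  # reproduce a quadratic in the interior away from the natural ends
  quad <- function(t) 60 + 2 * t - 0.3 * t^2
  knots <- tibble::tibble(time_s = seq(0, 20, by = 0.4), hr_bpm = quad(seq(0, 20, by = 0.4)))
  out2 <- resample_hr(knots, 5, 15)
  expect_equal(out2$hr_bpm, quad(out2$time_s), tolerance = 1e-6)

  expect_error(resample_hr(const, 0, 6), "extrapolation")
  expect_error(resample_hr(const[1:3, ], 0, 1), "4")
})

test_that("full preprocessing chain recovers manifest heart rate on clean sessions", {
  cfg <- scaled_session_config(hrv_sd = 2, ecg_noise_sd = 0.03)
  s <- generate_session(cfg, seed = 21)
  prep <- preprocess_session(s)
  expect_false(prep$bad_ecg)
  truth_beats <- s$truth$beat_times$trip2
  truth_hr <- instantaneous_hr(truth_beats)
  got <- prep$trips$trip2$hr
  # compare on the common interior support via interpolation
  common <- truth_hr$time_s > 2 & truth_hr$time_s < cfg$trip_duration_s - 2
  est <- approx(got$time_s, got$hr_bpm, truth_hr$time_s[common])$y
  rmse <- sqrt(mean((est - truth_hr$hr_bpm[common])^2))
  expect_lt(rmse, 1)
})
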