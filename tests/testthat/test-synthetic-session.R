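# simulator: beat trains, ECG rendering, sessions, cohorts

test_that("constant-rate beat train inverts the rate exactly", {
  cfg <- session_config(baseline_hr = 60, hrv_sd = 0, rsa_amplitude = 0)
  beats <- sample_rr_train(cfg, NULL, duration = 10, seed = 1)
  expect_length(beats, 11)
  expect_equal(beats, 0:10, tolerance = 1e-9)

  # a constant +60 bpm offset halves the interval
  beats2 <- sample_rr_train(cfg, function(t) 60, duration = 10, seed = 1)
  expect_equal(unique(round(diff(beats2), 12)), 0.5)
})

test_that("mean recovered heart rate matches the configured baseline under noise", {
  cfg <- session_config(baseline_hr = 70, hrv_sd = 3, rsa_amplitude = 0)
  beats <- sample_rr_train(cfg, NULL, duration = 300, seed = 42)
  hr <- instantaneous_hr(beats)
  expect_lt(abs(mean(hr$hr_bpm) - 70), 1)
})

test_that("beat-train round trip reproduces baseline plus template at beat times", {
  tpl <- ecr_template(-5, 1, 6, 3)
  cfg <- session_config(baseline_hr = 70, hrv_sd = 0, rsa_amplitude = 0)
  onset <- 15
  beats <- sample_rr_train(cfg, function(t) eval_ecr(tpl, t - onset),
                           duration = 25, seed = 1)
  hr <- instantaneous_hr(beats)
  truth <- 70 + eval_ecr(tpl, hr$time_s - onset)
  expect_lt(max(abs(hr$hr_bpm - truth)), 0.5)
})

test_that("ECR template is zero outside its support and at onset", {
  tpl <- ecr_template(-5, 1, 6, 3, lobe_width = 0.5)
  expect_equal(eval_ecr(tpl, c(-1, 0)), c(0, 0))
  expect_equal(eval_ecr(tpl, 1), -5)
  expect_equal(eval_ecr(tpl, 3), 6)
  expect_equal(eval_ecr(tpl, 3 + 3 * 0.5 + 0.01), 0)
  # continuity across the support edge
  expect_lt(abs(eval_ecr(tpl, 4 - 1e-6)), 1e-8)
  expect_error(ecr_template(-5, 3, 6, 1), "precede")
  expect_error(ecr_template(5, 1, 6, 3))
})

test_that("synthetic ECG places R apices on the grid and handles edge cases", {
  beats <- c(1, 2, 3)
  ecg <- synthesize_ecg(beats, 500, noise_sd = 0)
  for (bt in beats) {
    win <- which(abs(ecg$time_s - bt) <= 0.15)
    apex <- ecg$time_s[win][which.max(ecg$mv[win])]
    expect_lte(abs(apex - bt), 1 / 500 + 1e-12)
  }
  # R dominates the other waves by >= 3x away from the apex
  far <- abs(ecg$time_s - 2) > 0.05 & abs(ecg$time_s - 1) > 0.05 &
    abs(ecg$time_s - 3) > 0.05
  expect_gte(max(ecg$mv) / max(abs(ecg$mv[far])), 3)

  flat <- synthesize_ecg(numeric(0), 500)
  expect_true(all(flat$mv == 0))
  expect_error(synthesize_ecg(c(1, 1.2), 500), "overlap")
})

test_that("sessions are deterministic and record injected templates in the manifest", {
  cfg <- scaled_session_config(hrv_sd = 1)
  s1 <- generate_session(cfg, seed = 11, pid = "pX")
  s2 <- generate_session(cfg, seed = 11, pid = "pX")
  expect_identical(s1$ecg, s2$ecg)
  expect_identical(s1$speed, s2$speed)
  expect_identical(s1$markers, s2$markers)
  expect_identical(s1$ratings, s2$ratings)

  # byte-identical on disk too
  d1 <- tempfile(); d2 <- tempfile()
  write_session_bundle(s1, d1)
  write_session_bundle(s2, d2)
  for (f in list.files(file.path(d1, "pX"))) {
    expect_identical(readBin(file.path(d1, "pX", f), "raw", 1e7),
                     readBin(file.path(d2, "pX", f), "raw", 1e7))
  }

  # manifest bookkeeping: the P postcue template parameters survive verbatim
  tpl_list <- s1$truth$injected_templates[[2]]
  p_postcue <- Filter(function(a) a$condition == "P" && a$window == "postcue",
                      tpl_list)[[1]]
  expect_equal(p_postcue$decel_amplitude, -5)
  expect_equal(p_postcue$accel_amplitude, 6)
  expect_equal(p_postcue$decel_peak_time, 1)
  expect_equal(p_postcue$accel_peak_time, 3)
})

test_that("trip 1 carries no U/P templates but an attenuated PF first exposure", {
  cfg <- scaled_session_config()
  s <- generate_session(cfg, seed = 3, render_ecg = FALSE)
  t1 <- s$truth$injected_templates[[1]]
  conds <- vapply(t1, `[[`, character(1), "condition")
  expect_true(all(conds == "PF"))
  expect_true(all(vapply(t1, `[[`, numeric(1), "scale") == 0.6))
  t2 <- s$truth$injected_templates[[2]]
  expect_true(all(vapply(t2, `[[`, numeric(1), "scale") == 1))
})

test_that("markers too close to the recording end are rejected", {
  cfg <- scaled_session_config()
  cfg$trip_duration_s <- 70 # PF event onset at 73.5 would exceed it
  expect_error(generate_session(cfg, seed = 1, render_ecg = FALSE), "8 s")
})

test_that("null-template trips differ from each other only by noise", {
  cfg <- scaled_session_config(hrv_sd = 2)
  cfg$ecr_by_condition <- list(U = list(postcue = NULL, postevent = NULL),
                               P = list(postcue = NULL, postevent = NULL),
                               PF = list(postcue = NULL, postevent = NULL))
  eps <- lapply(1:40, function(i) {
    s <- generate_session(cfg, seed = 100 + i, render_ecg = FALSE)
    ep <- epoch_session(s, prep = NULL, channels = "hr")
    ep[ep$condition == "P" & ep$window == "postcue", ]
  })
  diffs <- vapply(eps, function(e) {
    mean(e$change[e$condition_type == "experimental"]) -
      mean(e$change[e$condition_type == "control"])
  }, numeric(1))
  # simulated null: mean experimental-control difference compatible with 0
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("cohort exclusion bookkeeping and stress-group counts are exact", {
  coh <- generate_cohort(34, config = scaled_session_config(),
                         exclusions = list(motion_sickness = 5, bad_ecg = 2),
                         stress_counts = c(high = 11, low = 16 + 7),
                         render_ecg = FALSE, seed = 9)
  expect_equal(nrow(coh$manifest), 34)
  expect_equal(sum(coh$manifest$exclusion_flag != "none"), 7)
  expect_equal(sum(coh$manifest$exclusion_flag == "motion_sickness"), 5)
  expect_equal(sum(coh$manifest$exclusion_flag == "bad_ecg"), 2)
  expect_equal(sum(coh$manifest$stress_group == "high"), 11)

  one <- generate_cohort(1, config = scaled_session_config(),
                         render_ecg = FALSE, seed = 2)
  expect_equal(nrow(one$manifest), 1)
  expect_true(all(one$manifest$exclusion_flag == "none"))

  expect_error(generate_cohort(3, exclusions = list(motion_sickness = 2, bad_ecg = 2),
                               render_ecg = FALSE, seed = 1),
               "exceed")
})

test_that("participant substreams are invariant to cohort size", {
  cfg <- scaled_session_config()
  c3 <- generate_cohort(3, config = cfg, render_ecg = FALSE, seed = 5)
  c5 <- generate_cohort(5, config = cfg, render_ecg = FALSE, seed = 5)
  expect_identical(c3$sessions[["p02"]]$truth$beat_times,
                   c5$sessions[["p02"]]$truth$beat_times)
})

test_that("injected template is recoverable from the cohort grand mean", {
  tpl <- ecr_template(-5, 1, 6, 3)
  # oracle: the expected beat-sampled, spline-discretized curve, from a
  # noise-free cohort (beat phases still vary with participant baselines)
  noisy <- simulate_change_cohort(250, template = tpl, seed = 55)
  clean <- simulate_change_cohort(400, template = tpl, hrv_sd = 0,
                                  rsa_amplitude = 0, seed = 99)
  gm <- colMeans(noisy$experimental)
  oracle <- colMeans(clean$experimental)
  se <- sqrt(apply(noisy$experimental, 2, var) / 250 +
               apply(clean$experimental, 2, var) / 400)
  # the stochastic machinery adds no bias beyond the sampling discretization
  expect_true(all(abs(gm - oracle)[-1] <= 3 * se[-1]))
  # and the recovered curve tracks the injected biphasic shape
  expect_gt(cor(gm, eval_ecr(tpl, noisy$rel_times)), 0.95)
  trough <- which.min(gm); peak <- which.max(gm)
  expect_equal(noisy$rel_times[trough], 1.0)
  expect_equal(noisy$rel_times[peak], 3.0)
})
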