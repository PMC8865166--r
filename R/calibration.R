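# Monte-Carlo calibration helpers: cohorts of baseline-referenced change
# matrices generated at the beat-train level (simulator -> instantaneous
# heart rate -> spline grid -> epoch), skipping waveform synthesis and
# peak detection. Used for type-I-error, power and template-recovery
# studies, where thousands of cohorts are needed.

#' Simulate a cohort of heart-rate change matrices
#'
#' For each participant, draws a baseline heart rate, simulates a beat
#' train with (experimental) and without (control) an injected biphasic
#' template time-locked to a marker, converts to instantaneous heart rate,
#' spline-resamples onto the 0.5 s grid around the marker and extracts the
#' baseline-referenced change epoch. With `template = NULL` both members
#' are null and the pair probes the type-I error of downstream tests.
#'
#' @param n Number of participants.
#' @param template An [ecr_template()] injected in the experimental member,
#'   or `NULL` for a null cohort.
#' @param end_rel Window end relative to the marker, seconds (4.5 gives the
#'   10-level U/P grid, 7.5 the 16-level PF grid).
#' @param baseline_hr,hrv_sd,rsa_amplitude Cohort-level simulator settings
#'   (per-participant baselines are jittered with SD `hr_jitter_sd`).
#' @param hr_jitter_sd Between-participant baseline jitter, bpm.
#' @param seed Integer seed.
#' @return List with matrices `experimental` and `control` (n x
#'   (2 + end_rel / 0.5) post-baseline columns named `t0`, `t0.5`, ...)
#'   and `rel_times`.
#' @export
simulate_change_cohort <- function(n, template = NULL, end_rel = 4.5,
                                   baseline_hr = 75, hrv_sd = 2.5,
                                   rsa_amplitude = 2, hr_jitter_sd = 7,
                                   seed = 1L) {
  onset <- 15
  duration <- onset + end_rel + 3
  rel <- seq(0, end_rel, by = 0.5)
  k <- length(rel)
  delta <- if (is.null(template)) NULL else function(t) {
    r <- t - onset
    if (r > 0) eval_ecr(template, r) else 0
  }
  draws <- with_seed(substream_seed(seed, 0L, salt = 20L),
                     list(jit = rnorm(n, 0, hr_jitter_sd),
                          phase = runif(n, 0, 2 * pi)))
  base_cfg <- session_config(baseline_hr = baseline_hr, hrv_sd = hrv_sd,
                             rsa_amplitude = rsa_amplitude)
  one <- function(i, arm) {
    cfg <- base_cfg # validated once; per-participant fields patched in place
    cfg$baseline_hr <- clamp(baseline_hr + draws$jit[i], 45, 120)
    cfg$rsa_phase <- draws$phase[i]
    beats <- sample_rr_train(cfg,
                             ecr_delta = if (arm == "experimental") delta else NULL,
                             duration = duration,
                             seed = substream_seed(seed, i,
                                                   salt = if (arm == "experimental") 21L else 22L))
    change_epoch_from_beats(beats, onset, end_rel)[-1]
  }
  m_exp <- t(vapply(seq_len(n), one, numeric(k), arm = "experimental"))
  m_ctrl <- t(vapply(seq_len(n), one, numeric(k), arm = "control"))
  colnames(m_exp) <- colnames(m_ctrl) <- paste0("t", rel)
  rownames(m_exp) <- rownames(m_ctrl) <- sprintf("p%03d", seq_len(n))
  list(experimental = m_exp, control = m_ctrl, rel_times = rel)
}

# lean equivalent of instantaneous_hr -> resample_hr -> extract_epoch for
# the Monte-Carlo loops; a unit test pins it to the tibble-based path
change_epoch_from_beats <- function(beats, onset, end_rel) {
  hr <- 60 / diff(beats)
  f <- splinefun(beats[-1], hr, method = "natural")
  vals <- f(seq(onset - 0.5, onset + end_rel, by = 0.5))
  vals - vals[1]
}

#' Type-I error of the GG-corrected interaction test on null cohorts
#'
#' Repeatedly simulates null cohorts (no injected template in either arm),
#' runs the 2 x k repeated-measures ANOVA and records how often the
#' Greenhouse-Geisser-corrected interaction p value falls below alpha.
#' Under a calibrated test the rate should sit near alpha.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param n Participants per cohort.
#' @param end_rel Window end, seconds (4.5 gives 10 time levels).
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return A list: `rate`, `rejections`, `n_cohorts`.
#' @export
type1_error_study <- function(n_cohorts = 1000, n = 27, end_rel = 4.5,
                              alpha = 0.05, seed = 1L) {
  rej <- vapply(seq_len(n_cohorts), function(b) {
    cohort <- simulate_change_cohort(n, template = NULL, end_rel = end_rel,
                                     seed = substream_seed(seed, b, salt = 30L))
    fit <- rm_anova_2x_k(cohort$experimental, cohort$control, alpha = alpha)
    fit$table$p_gg[fit$table$effect == "interaction"] < alpha
  }, logical(1))
  list(rate = mean(rej), rejections = sum(rej), n_cohorts = n_cohorts)
}

#' Power of the quadratic trend contrast under the default template
#'
#' Simulates cohorts with the biphasic template injected in the
#' experimental arm and records how often the quadratic contrast on the
#' experimental matrix reaches significance.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param n Participants per cohort.
#' @param template Injected [ecr_template()].
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return A list: `power`, plus the per-cohort quadratic p values.
#' @export
quadratic_power_study <- function(n_cohorts = 50, n = 27,
                                  template = ecr_template(-5, 1, 6, 3),
                                  alpha = 0.05, seed = 1L) {
  pvals <- vapply(seq_len(n_cohorts), function(b) {
    cohort <- simulate_change_cohort(n, template = template,
                                     seed = substream_seed(seed, b, salt = 40L))
    ct <- polynomial_contrast(cohort$experimental)
    ct$table$p_value[ct$table$order == "quadratic"]
  }, numeric(1))
  list(power = mean(pvals < alpha), p_values = pvals)
}

#' Template recovery in the grand-mean change curve
#'
#' Simulates one large cohort with an injected template and compares the
#' grand-mean postcue change curve against the template evaluated on the
#' grid, reporting the Monte-Carlo standard error at each point.
#'
#' @param n Participants.
#' @param template Injected [ecr_template()].
#' @param seed Integer seed.
#' @return Tibble: rel_time_s, truth (template on the grid), mean_change,
#'   mc_se.
#' @export
template_recovery_study <- function(n = 200,
                                    template = ecr_template(-5, 1, 6, 3),
                                    seed = 1L) {
  cohort <- simulate_change_cohort(n, template = template, seed = seed)
  rel <- cohort$rel_times
  tibble(
    rel_time_s = rel,
    truth = eval_ecr(template, rel),
    mean_change = colMeans(cohort$experimental),
    mc_se = apply(cohort$experimental, 2, sd) / sqrt(n)
  )
}
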