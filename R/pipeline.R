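# Orchestration: simulate -> preprocess -> epoch -> analyze -> report,
# configurable, logged and seedable.

#' Pipeline configuration
#'
#' Bundles every analysis constant with its study default: 2-40 Hz filter
#' band, 0.5 s resampling grid, per-condition window ends (4.5 s for U and
#' P, 7.5 s for PF), the 2.5 perceived-stress split on the 1-5 scale, and
#' alpha = .05. The `simulate` block configures the synthetic cohort
#' (34 enrolled, 5 motion-sickness and 2 bad-ECG exclusions by default,
#' leaving 27 analysed participants).
#'
#' @param seed Global seed for the run.
#' @param out_dir Output directory for tables, figures and the run log.
#' @param input_dir Optional directory of session bundles to analyse
#'   instead of simulating.
#' @param n_participants Enrolled cohort size when simulating.
#' @param exclusions Named list of `motion_sickness` and `bad_ecg` counts.
#' @param session Base [session_config()] for the simulator.
#' @param filter_low,filter_high ECG band edges, Hz.
#' @param grid_step Resampling step, seconds.
#' @param window_ends Named vector of per-condition window ends, seconds.
#' @param split_threshold Perceived-stress split point.
#' @param alpha Significance level.
#' @param channels Channels to analyse, subset of `c("hr", "speed")`.
#' @param plots Emit mean-change figures?
#' @param render_ecg Synthesize raw ECG (and run detection) or work from
#'   the simulator's ground-truth beat times directly.
#' @param verbose Log progress messages?
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("drivecr_run_"),
                            input_dir = NULL,
                            n_participants = 34,
                            exclusions = list(motion_sickness = 5, bad_ecg = 2),
                            session = session_config(),
                            filter_low = 2, filter_high = 40,
                            grid_step = 0.5,
                            window_ends = c(U = 4.5, P = 4.5, PF = 7.5),
                            split_threshold = 2.5,
                            alpha = 0.05,
                            channels = c("hr", "speed"),
                            plots = FALSE,
                            render_ecg = TRUE,
                            verbose = TRUE) {
  stopifnot_scalar_num(grid_step, "grid_step", lo = 1e-6)
  stopifnot_scalar_num(alpha, "alpha", 0, 1)
  stopifnot_scalar_num(split_threshold, "split_threshold", 1, 5)
  stopifnot(all(channels %in% c("hr", "speed")), length(channels) >= 1)
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, input_dir = input_dir,
         n_participants = n_participants, exclusions = exclusions,
         session = session, filter_low = filter_low,
         filter_high = filter_high, grid_step = grid_step,
         window_ends = window_ends, split_threshold = split_threshold,
         alpha = alpha, channels = channels, plots = plots,
         render_ecg = render_ecg, verbose = verbose),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; missing keys keep
#' their defaults. The `session` block is passed to [session_config()].
#'
#' @param path Path to a YAML config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sess_args <- raw$session %||% list()
  raw$session <- NULL
  if (!is.null(raw$window_ends)) raw$window_ends <- unlist(raw$window_ends)
  if (!is.null(raw$channels)) raw$channels <- unlist(raw$channels)
  do.call(pipeline_config,
          c(raw, list(session = do.call(session_config, sess_args))))
}

#' Apply the participant-exclusion filter
#'
#' Participants flagged in the cohort manifest (motion sickness: did not
#' complete; bad ECG: unsatisfactory recording) and participants whose
#' automated beat correction condemned a trip are removed before any
#' matrix is built. Counts reconcile: included = enrolled - excluded.
#'
#' @param manifest Cohort manifest tibble (`pid`, `exclusion_flag`, ...).
#' @param detected_bad_ecg Character vector of pids condemned during
#'   preprocessing.
#' @return A list: `included` pids, `excluded` tibble (pid, reason),
#'   `n_enrolled`, `n_included`.
#' @export
apply_exclusions <- function(manifest, detected_bad_ecg = character(0)) {
  flagged <- manifest[manifest$exclusion_flag != "none",
                      c("pid", "exclusion_flag")]
  names(flagged) <- c("pid", "reason")
  det <- setdiff(detected_bad_ecg, flagged$pid)
  excluded <- dplyr::bind_rows(
    as_tibble(flagged),
    tibble(pid = det, reason = rep("bad_ecg_detected", length(det)))
  )
  included <- setdiff(manifest$pid, excluded$pid)
  list(included = included, excluded = excluded,
       n_enrolled = nrow(manifest), n_included = length(included))
}

#' Analyse an epoch table
#'
#' The inferential stage, callable on its own so a saved `epochs.tsv` can
#' be re-analysed: builds the participant x time matrices, runs the
#' 2 x k repeated-measures ANOVA and Bonferroni post hocs for every
#' condition/window/channel, polynomial trend contrasts for the cued
#' (predictable) conditions in the postcue heart-rate window (P
#' experimental; PF experimental and control, since PF's control drive also
#' contains the cue), and paired AUC comparisons within each
#' perceived-stress group for U and P.
#'
#' @param epochs Long epoch tibble (from [epoch_session()] or read back
#'   from `epochs.tsv`).
#' @param ratings Ratings tibble (`pid`, `condition`, `rating`).
#' @param config A [pipeline_config()].
#' @return A list of tibbles: `matrices`, `anova`, `posthoc`, `contrasts`,
#'   `paired_auc`, `auc`, `stress_groups`.
#' @export
analyze_epochs <- function(epochs, ratings, config = pipeline_config()) {
  mats <- build_epoch_matrices(epochs)

  anova_tab <- purrr::pmap_dfr(
    mats[, c("condition", "window", "channel")],
    function(condition, window, channel) {
      row <- mats[mats$condition == condition & mats$window == window &
                    mats$channel == channel, ]
      fit <- rm_anova_2x_k(row$experimental[[1]], row$control[[1]],
                           alpha = config$alpha)
      dplyr::mutate(tidy(fit), condition = condition, window = window,
                    channel = channel, n = fit$n, .before = 1)
    }
  )

  posthoc_tab <- purrr::pmap_dfr(
    mats[, c("condition", "window", "channel")],
    function(condition, window, channel) {
      row <- mats[mats$condition == condition & mats$window == window &
                    mats$channel == channel, ]
      ph <- bonferroni_posthoc(row$experimental[[1]], row$control[[1]],
                               alpha = config$alpha)
      dplyr::mutate(ph, condition = condition, window = window,
                    channel = channel, .before = 1)
    }
  )

  contrast_spec <- tibble(
    condition = c("P", "PF", "PF"),
    condition_type = c("experimental", "experimental", "control")
  )
  contrasts_tab <- purrr::pmap_dfr(contrast_spec, function(condition, condition_type) {
    row <- mats[mats$condition == condition & mats$window == "postcue" &
                  mats$channel == "hr", ]
    if (!nrow(row)) return(tibble())
    m <- row[[condition_type]][[1]]
    ct <- polynomial_contrast(m)
    dplyr::mutate(tidy(ct), condition = condition,
                  condition_type = condition_type, .before = 1)
  })

  aucs <- auc_table(epochs[!is.na(epochs$change), ])
  groups <- median_split(ratings[ratings$pid %in% unique(epochs$pid), ],
                         threshold = config$split_threshold)

  grid <- tidyr::expand_grid(
    condition = c("U", "P"),
    window = unique(aucs$window),
    channel = unique(aucs$channel),
    group = c("high", "low")
  )
  paired_tab <- purrr::pmap_dfr(grid, function(condition, window, channel, group) {
    g_pids <- groups$pid[groups$condition == condition & groups$group == group]
    sub <- aucs[aucs$condition == condition & aucs$window == window &
                  aucs$channel == channel & aucs$pid %in% g_pids, ]
    ex <- sub[sub$condition_type == "experimental", c("pid", "auc")]
    ct <- sub[sub$condition_type == "control", c("pid", "auc")]
    common <- intersect(ex$pid, ct$pid)
    if (length(common) < 2) {
      return(tibble(condition = condition, window = window,
                    channel = channel, group = group,
                    n = length(common)))
    }
    res <- paired_auc_test(ex[ex$pid %in% common, ], ct[ct$pid %in% common, ])
    dplyr::mutate(tidy(res), condition = condition, window = window,
                  channel = channel, group = group, .before = 1)
  })

  list(matrices = mats, anova = anova_tab, posthoc = posthoc_tab,
       contrasts = contrasts_tab, paired_auc = paired_tab,
       auc = aucs, stress_groups = groups)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, excludes flagged participants,
#' preprocesses the ECG, builds baseline-referenced change epochs, runs the
#' inferential stage and writes every output table (and optionally figures)
#' under `config$out_dir`. Deterministic: identical config and seed give
#' byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report`: stage record counts, exclusions
#'   with reasons, output paths, the config echo, seed and package version;
#'   the analysis results are attached as `$results` and the epoch table as
#'   `$epochs`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  verbose <- isTRUE(config$verbose)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- simulate or load -----------------------------------------------
  if (!is.null(config$input_dir)) {
    log_msg("loading session bundles from %s", config$input_dir, verbose = verbose)
    pdirs <- list.dirs(config$input_dir, recursive = FALSE)
    sessions <- lapply(pdirs, read_session_bundle)
    names(sessions) <- vapply(sessions, `[[`, character(1), "pid")
    manifest <- read_tsv_det(file.path(config$input_dir, "cohort_manifest.tsv"))
    cohort <- structure(list(sessions = sessions, manifest = manifest,
                             seed = config$seed), class = "driver_cohort")
  } else {
    log_msg("simulating cohort of %d (seed %d)", config$n_participants,
            config$seed, verbose = verbose)
    cohort <- generate_cohort(config$n_participants, config = config$session,
                              exclusions = config$exclusions,
                              seed = config$seed,
                              render_ecg = config$render_ecg)
  }
  n_enrolled <- nrow(cohort$manifest)

  # --- exclusions + preprocessing -------------------------------------
  manifest_ok <- cohort$manifest$pid[cohort$manifest$exclusion_flag == "none"]
  preps <- list()
  detected_bad <- character(0)
  if (config$render_ecg || !is.null(config$input_dir)) {
    for (pid in manifest_ok) {
      s <- cohort$sessions[[pid]]
      if (is.null(s$ecg)) next
      prep <- preprocess_session(s, low = config$filter_low,
                                 high = config$filter_high)
      if (prep$bad_ecg) {
        detected_bad <- c(detected_bad, pid)
        log_msg("participant %s condemned by beat correction", pid,
                level = "WARN", verbose = verbose)
      } else {
        preps[[pid]] <- prep
      }
    }
  }
  excl <- apply_exclusions(cohort$manifest, detected_bad)
  log_msg("%d enrolled, %d excluded, %d analysed", excl$n_enrolled,
          nrow(excl$excluded), excl$n_included, verbose = verbose)

  # --- epoching --------------------------------------------------------
  epochs <- dplyr::bind_rows(lapply(excl$included, function(pid) {
    epoch_session(cohort$sessions[[pid]], prep = preps[[pid]],
                  channels = config$channels,
                  window_ends = config$window_ends)
  }))
  ratings <- dplyr::bind_rows(lapply(excl$included, function(pid) {
    cohort$sessions[[pid]]$ratings
  }))

  # --- analysis --------------------------------------------------------
  results <- analyze_epochs(epochs, ratings, config)

  # --- outputs ---------------------------------------------------------
  paths <- c(
    epochs = write_tsv_det(epochs, file.path(config$out_dir, "epochs.tsv")),
    auc = write_tsv_det(results$auc, file.path(config$out_dir, "auc.tsv")),
    anova = write_tsv_det(results$anova,
                          file.path(config$out_dir, "anova_results.tsv")),
    contrasts = write_tsv_det(results$contrasts,
                              file.path(config$out_dir, "contrasts.tsv")),
    posthoc = write_tsv_det(results$posthoc,
                            file.path(config$out_dir, "posthoc.tsv")),
    paired_auc = write_tsv_det(results$paired_auc,
                               file.path(config$out_dir, "paired_auc.tsv"))
  )
  if (isTRUE(config$plots)) {
    for (cond in c("U", "P", "PF")) {
      for (win in c("postcue", "postevent")) {
        if (!"hr" %in% config$channels) next
        p <- plot_mean_change(epochs, cond, win, "hr")
        f <- file.path(config$out_dir, sprintf("mean_hr_change_%s_%s.png", cond, win))
        ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 150)
        paths <- c(paths, setNames(f, sprintf("fig_%s_%s", cond, win)))
      }
    }
  }

  report <- structure(
    list(n_enrolled = n_enrolled, n_included = excl$n_included,
         excluded = excl$excluded,
         n_epochs = nrow(epochs),
         counts = c(enrolled = n_enrolled,
                    excluded = nrow(excl$excluded),
                    included = excl$n_included),
         paths = paths, config = config, seed = config$seed,
         version = as.character(packageVersion("drivecr")),
         results = results, epochs = epochs, ratings = ratings),
    class = "run_report"
  )
  writeLines(yaml::as.yaml(list(
    seed = config$seed, version = report$version,
    enrolled = n_enrolled, included = excl$n_included,
    excluded = as.list(table(excl$excluded$reason)),
    outputs = as.list(paths)
  )), file.path(config$out_dir, "run_report.yaml"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> drivecr %s, seed %d\n", x$version, x$seed))
  cat(sprintf("  participants: %d enrolled, %d excluded, %d analysed\n",
              x$n_enrolled, nrow(x$excluded), x$n_included))
  cat(sprintf("  epochs: %d rows; outputs in %s\n", x$n_epochs,
              dirname(x$paths[["epochs"]])))
  invisible(x)
}

#' Human-readable summary tables
#'
#' Renders the AUC comparison shaped like the study's perceived-stress
#' table (per condition, channel, window and stress group: group size,
#' AUC mean and SD for the experimental and control drives, p and Cohen's
#' d) and the trend table (3 rows for P experimental, 6 for PF
#' experimental + control), plus a compact ANOVA summary. Stress groups
#' with no members are omitted.
#'
#' @param results The `$results` element of a [run_pipeline()] report (or
#'   the output of [analyze_epochs()]).
#' @return A list of tibbles: `auc_by_stress`, `trends`, `anova`.
#' @export
report_tables <- function(results) {
  for (nm in c("paired_auc", "contrasts", "anova")) {
    if (is.null(results[[nm]])) abort(sprintf("missing upstream table `%s`", nm))
  }
  auc_by_stress <- results$paired_auc |>
    dplyr::filter(!is.na(.data$n) & .data$n > 0) |>
    dplyr::transmute(
      condition = .data$condition, channel = .data$channel,
      window = .data$window, group = .data$group, n = .data$n,
      auc_experimental = sprintf("%.2f (%.2f)", .data$mean_exp, .data$sd_exp),
      auc_control = sprintf("%.2f (%.2f)", .data$mean_ctrl, .data$sd_ctrl),
      p_value = .data$p_value, cohens_d = .data$cohens_d
    )
  trends <- results$contrasts |>
    dplyr::transmute(condition = .data$condition,
                     condition_type = .data$condition_type,
                     trend = .data$order, t = .data$statistic,
                     df = .data$df, p_value = .data$p_value)
  anova <- results$anova |>
    dplyr::transmute(condition = .data$condition, window = .data$window,
                     channel = .data$channel, effect = .data$effect,
                     F = .data$statistic, gg_epsilon = .data$gg_epsilon,
                     p = .data$p_reported,
                     partial_eta_sq = .data$partial_eta_sq)
  list(auc_by_stress = auc_by_stress, trends = trends, anova = anova)
}
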