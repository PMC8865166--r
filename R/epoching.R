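# Baseline-referenced change epochs on the 0.5 s grid, AUC summaries and
# the perceived-stress median split.

#' Analysis-window end for a predictability condition
#'
#' The analysed grid runs from -0.5 s to 4.5 s for the U and P conditions
#' (10 post-baseline time points) and to 7.5 s for PF (16 points), for both
#' the postcue and postevent windows.
#'
#' @param condition `"U"`, `"P"` or `"PF"`.
#' @return Window end in seconds relative to onset.
#' @export
window_end <- function(condition) {
  ends <- c(U = 4.5, P = 4.5, PF = 7.5)
  if (!all(condition %in% names(ends))) abort("condition must be one of U, P, PF")
  unname(ends[condition])
}

#' Extract one baseline-referenced change epoch
#'
#' Samples a uniform series at onset-relative times -0.5, 0.0, ..., `end_rel`
#' (0.5 s steps), takes the value at -0.5 s as the baseline, and returns
#' change = value - baseline, so the change at -0.5 s is exactly zero.
#' Off-grid requests are linearly interpolated (the heart-rate series used
#' by the pipeline is spline-resampled onto an onset-aligned grid upstream,
#' so its samples are exact; the 10 Hz speed trace is dense relative to the
#' 0.5 s grid, so linear interpolation suffices). If the series does not
#' cover the whole window the epoch is returned marked missing.
#'
#' @param series Data frame with `time_s` and one value column (`hr_bpm`,
#'   `kmh` or `value`).
#' @param onset Marker onset in seconds (absolute time of the series).
#' @param end_rel Window end relative to onset, seconds.
#' @param channel `"hr"` or `"speed"` (metadata only).
#' @return A tibble `rel_time_s`, `value`, `change` with attributes
#'   `baseline`, `channel` and `missing`.
#' @export
extract_epoch <- function(series, onset, end_rel, channel = "hr") {
  stopifnot("time_s" %in% names(series))
  vcol <- setdiff(names(series), c("time_s", "trip", "pid"))[1]
  rel <- seq(-0.5, end_rel, by = 0.5)
  abs_t <- onset + rel
  missing <- min(series$time_s) - 1e-9 > min(abs_t) ||
    max(series$time_s) + 1e-9 < max(abs_t)
  if (missing) {
    out <- tibble(rel_time_s = rel, value = NA_real_, change = NA_real_)
    attr(out, "baseline") <- NA_real_
  } else {
    vals <- approx(series$time_s, series[[vcol]], xout = abs_t)$y
    baseline <- vals[1]
    out <- tibble(rel_time_s = rel, value = vals, change = vals - baseline)
    attr(out, "baseline") <- baseline
  }
  attr(out, "channel") <- channel
  attr(out, "missing") <- missing
  class(out) <- c("drivecr_epoch", class(out))
  out
}

#' Signed area under a change epoch
#'
#' Trapezoidal integral of the change values over relative times 0.0 to the
#' window end (the forced-zero baseline point at -0.5 s is excluded so it
#' does not dilute the summary), step 0.5 s. Units: bpm*s or (km/h)*s.
#'
#' @param epoch An epoch from [extract_epoch()], or any data frame with
#'   `rel_time_s` and `change`.
#' @return The signed AUC (scalar); `NA` for a missing epoch.
#' @export
epoch_auc <- function(epoch) {
  keep <- epoch$rel_time_s >= 0 - 1e-9
  x <- epoch$rel_time_s[keep]
  y <- epoch$change[keep]
  if (anyNA(y)) return(NA_real_)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Epoch every marker of one session
#'
#' Builds heart-rate and speed change epochs for each condition x window x
#' trip of a session. Trip 1 supplies the control epochs (matched route
#' positions; for PF the first exposure), Trip 2 the experimental epochs.
#' Heart rate is spline-resampled onto a grid aligned to each marker before
#' differencing; speed is linearly interpolated from the 10 Hz trace.
#'
#' @param session A `driver_session`.
#' @param prep Output of [preprocess_session()] for the same session. When
#'   `NULL`, heart rate is taken from the ground-truth beat times in the
#'   session manifest (simulation-only shortcut used by calibration
#'   studies).
#' @param channels Character subset of `c("hr", "speed")`.
#' @param window_ends Named vector of per-condition window ends, seconds.
#' @return A long tibble: pid, condition, condition_type, window, channel,
#'   rel_time_s, value, change (missing epochs yield `NA` rows).
#' @export
epoch_session <- function(session, prep = NULL,
                          channels = c("hr", "speed"),
                          window_ends = c(U = 4.5, P = 4.5, PF = 7.5)) {
  markers <- session$markers
  rows <- list()
  for (k in sort(unique(markers$trip))) {
    ctype <- if (k == 1) "control" else "experimental"
    hr_pairs <- NULL
    if ("hr" %in% channels) {
      hr_pairs <- if (!is.null(prep)) {
        prep$trips[[paste0("trip", k)]]$hr
      } else {
        bt <- as.numeric(unlist(session$truth$beat_times[[paste0("trip", k)]]))
        instantaneous_hr(bt)
      }
    }
    speed_k <- if ("speed" %in% channels) {
      dplyr::filter(session$speed, .data$trip == k)
    } else NULL
    mk <- dplyr::filter(markers, .data$trip == k)
    for (j in seq_len(nrow(mk))) {
      cond <- mk$condition[j]
      win <- if (mk$marker_type[j] == "cue_onset") "postcue" else "postevent"
      onset <- mk$onset_s[j]
      endr <- unname(window_ends[[cond]])
      for (ch in channels) {
        ep <- if (ch == "hr") {
          if (is.null(hr_pairs) || nrow(hr_pairs) < 4 ||
              onset - 0.5 < min(hr_pairs$time_s) ||
              onset + endr > max(hr_pairs$time_s)) {
            NULL
          } else {
            grid <- resample_hr(hr_pairs, onset - 0.5, onset + endr)
            extract_epoch(grid, onset, endr, channel = "hr")
          }
        } else {
          extract_epoch(speed_k[, c("time_s", "kmh")], onset, endr,
                        channel = "speed")
        }
        if (is.null(ep)) {
          ep <- tibble(rel_time_s = seq(-0.5, endr, 0.5),
                       value = NA_real_, change = NA_real_)
        }
        rows[[length(rows) + 1L]] <- dplyr::mutate(
          as_tibble(ep),
          pid = session$pid, condition = cond, condition_type = ctype,
          window = win, channel = ch, .before = 1
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Assemble participant x time change matrices
#'
#' Pivots a long epoch table into one matrix per (condition, window,
#' channel, condition_type): rows are participants, columns the
#' post-baseline time points (10 for U and P, 16 for PF). Handling is
#' complete-case at the matrix level: a participant missing any cell of
#' either the experimental or the control member of a pair is dropped from
#' both, and the drop is recorded.
#'
#' @param epochs Long tibble from [epoch_session()] (rows from many
#'   participants).
#' @return A tibble with one row per (condition, window, channel): `n`,
#'   list-columns `experimental` and `control` (matrices with participant
#'   rownames and `t<rel>` colnames), and `dropped` (list of pids).
#' @export
build_epoch_matrices <- function(epochs) {
  post <- dplyr::filter(epochs, .data$rel_time_s >= 0 - 1e-9)
  combos <- dplyr::distinct(post, .data$condition, .data$window, .data$channel)
  purrr::pmap_dfr(combos, function(condition, window, channel) {
    sub <- post[post$condition == condition & post$window == window &
                  post$channel == channel, ]
    mats <- lapply(c("experimental", "control"), function(ct) {
      wide <- tidyr::pivot_wider(
        sub[sub$condition_type == ct, c("pid", "rel_time_s", "change")],
        names_from = "rel_time_s", values_from = "change",
        names_prefix = "t", names_sort = TRUE
      )
      m <- as.matrix(wide[, -1, drop = FALSE])
      rownames(m) <- wide$pid
      m
    })
    names(mats) <- c("experimental", "control")
    all_pids <- union(rownames(mats$experimental), rownames(mats$control))
    ok <- vapply(all_pids, function(p) {
      p %in% rownames(mats$experimental) && p %in% rownames(mats$control) &&
        !anyNA(mats$experimental[p, ]) && !anyNA(mats$control[p, ])
    }, logical(1))
    keep <- all_pids[ok]
    dropped <- all_pids[!ok]
    if (length(dropped)) {
      log_msg("dropping %d participant(s) from %s/%s/%s (incomplete epochs): %s",
              length(dropped), condition, window, channel,
              paste(dropped, collapse = ", "), level = "WARN")
    }
    tibble(condition = condition, window = window, channel = channel,
           n = length(keep),
           experimental = list(mats$experimental[keep, , drop = FALSE]),
           control = list(mats$control[keep, , drop = FALSE]),
           dropped = list(dropped))
  })
}

#' AUC table for every epoch of a cohort
#'
#' @param epochs Long tibble from [epoch_session()].
#' @return Tibble: pid, condition, condition_type, window, channel, auc.
#' @export
auc_table <- function(epochs) {
  epochs |>
    dplyr::group_by(.data$pid, .data$condition, .data$condition_type,
                    .data$window, .data$channel) |>
    dplyr::summarise(auc = epoch_auc(dplyr::pick("rel_time_s", "change")),
                     .groups = "drop")
}

#' Perceived-stress median split
#'
#' Assigns each participant, per condition, to the high-perceived-stress
#' group if their 1-5 Likert rating of the hazardous event (relative to the
#' safe control drive) exceeds `threshold` (2.5, the scale midpoint split),
#' and to the low group otherwise. Computed per condition; the PF condition
#' has no rating (no safe counterpart existed to rate against).
#'
#' @param ratings Tibble with `pid`, `condition`, `rating` (integers 1-5).
#' @param threshold Split point on the rating scale.
#' @return The input with a `group` column (`"high"`/`"low"`).
#' @export
median_split <- function(ratings, threshold = 2.5) {
  stopifnot(all(c("pid", "condition", "rating") %in% names(ratings)))
  bad <- !(ratings$rating %in% 1:5)
  if (any(bad)) {
    abort(sprintf("rating outside 1-5 for participant(s): %s",
                  paste(unique(ratings$pid[bad]), collapse = ", ")))
  }
  dplyr::mutate(as_tibble(ratings),
                group = ifelse(.data$rating > threshold, "high", "low"))
}
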