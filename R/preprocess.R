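# ECG -> uniformly resampled instantaneous heart rate.
# Band-pass filter, automatic R-peak detection, rule-based beat correction,
# RR -> bpm conversion, natural-cubic-spline resampling on a 0.5 s grid.

#' Zero-phase band-pass filter for ECG
#'
#' Forward-backward (zero-phase) 4th-order Butterworth band-pass, 2-40 Hz
#' by default. Zero-phase filtering preserves R-peak timing, which is what
#' the event-locked analysis depends on.
#'
#' @param ecg Data frame with columns `time_s` and `mv` on a uniform grid.
#' @param low,high Band edges in Hz.
#' @param order Butterworth order (applied twice by filtfilt).
#' @param fs Sampling rate in Hz; inferred from `time_s` when `NULL`.
#' @return A tibble on the same grid with filtered `mv`.
#' @export
bandpass_filter <- function(ecg, low = 2, high = 40, order = 4, fs = NULL) {
  stopifnot(all(c("time_s", "mv") %in% names(ecg)))
  if (is.null(fs)) fs <- infer_fs(ecg$time_s)
  if (!(low > 0 && low < high)) abort("need 0 < low < high")
  if (high >= fs / 2) {
    abort(sprintf("high edge %g Hz is at or above the Nyquist frequency of fs = %g Hz", high, fs))
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- tibble(time_s = ecg$time_s,
                mv = as.numeric(signal::filtfilt(bf, ecg$mv)))
  attr(out, "fs") <- fs
  out
}

moving_average <- function(x, width) {
  as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
}

#' Automatic R-peak detection
#'
#' Pan-Tompkins-style chain on an already band-passed ECG: centred
#' five-point derivative, squaring, 150 ms moving-window integration,
#' adaptive signal/noise thresholding over recent integrated peaks, a
#' 250 ms refractory period (capping detectable rate at 240 bpm), and apex
#' refinement to the local signal maximum within +/-50 ms.
#'
#' @param ecg Band-passed ECG data frame (`time_s`, `mv`).
#' @param fs Sampling rate, Hz; inferred when `NULL`.
#' @param threshold_frac Fraction positioning the adaptive threshold between
#'   the running noise and signal peak levels.
#' @return Numeric vector of candidate R times in seconds (empty, with a
#'   warning, for a flat signal).
#' @export
detect_r_peaks <- function(ecg, fs = NULL, threshold_frac = 0.25) {
  stopifnot(all(c("time_s", "mv") %in% names(ecg)))
  if (is.null(fs)) fs <- attr(ecg, "fs") %||% infer_fs(ecg$time_s)
  x <- ecg$mv
  n <- length(x)
  if (n < 2 * fs) abort("need at least 2 s of signal")
  if (sd(x) < 1e-10) {
    warn("flat ECG signal: no beats detected")
    return(numeric(0))
  }
  # centred derivative (no group delay), then squaring and integration
  d <- c(0, 0, (2 * (x[4:(n - 1)] - x[2:(n - 3)]) + (x[5:n] - x[1:(n - 4)])) / 8, 0, 0)
  sq <- d^2
  w <- max(3L, round(0.150 * fs))
  if (w %% 2L == 0L) w <- w + 1L
  mwi <- moving_average(sq, w)
  mwi[is.na(mwi)] <- 0

  # local maxima of the integrated signal
  pk <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(pk)) {
    warn("no integrated-signal maxima: no beats detected")
    return(numeric(0))
  }
  refr <- round(0.250 * fs)
  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- 0.6 * max(init)
  npki <- 0.5 * mean(init)
  thr <- npki + threshold_frac * (spki - npki)
  accepted <- integer(0)
  last <- -Inf
  last_height <- 0
  for (i in pk) {
    h <- mwi[i]
    if (h > thr) {
      if (i - last >= refr) {
        accepted <- c(accepted, i)
        last <- i
        last_height <- h
        spki <- 0.125 * h + 0.875 * spki
      } else if (h > last_height) {
        accepted[length(accepted)] <- i
        last <- i
        last_height <- h
        spki <- 0.125 * h + 0.875 * spki
      }
    } else {
      npki <- 0.125 * h + 0.875 * npki
    }
    thr <- npki + threshold_frac * (spki - npki)
  }
  if (!length(accepted)) {
    warn("no peaks exceeded the adaptive threshold")
    return(numeric(0))
  }
  # apex refinement: local maximum of the band-passed signal within +/-50 ms
  half <- round(0.050 * fs)
  apex <- vapply(accepted, function(i) {
    lo <- max(1L, as.integer(i - half)); hi <- min(n, as.integer(i + half))
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  apex <- sort(unique(apex))
  # enforce refractory after refinement
  if (length(apex) > 1) {
    keep <- logical(length(apex))
    keep[1] <- TRUE
    last <- apex[1]
    for (j in 2:length(apex)) {
      if (apex[j] - last >= refr) {
        keep[j] <- TRUE
        last <- apex[j]
      } else if (x[apex[j]] > x[last]) {
        keep[which(apex == last)] <- FALSE
        keep[j] <- TRUE
        last <- apex[j]
      }
    }
    apex <- apex[keep]
  }
  ecg$time_s[apex]
}

#' Rule-based correction of a detected beat train
#'
#' Automates the visual artifact check: an interval longer than
#' `long_factor` times the local median (window of 9 intervals) is treated
#' as one or more missed beats and filled by evenly spaced insertion; an
#' interval shorter than `short_factor` times the local median is treated
#' as a false trigger and the weaker apex is removed (the later beat when
#' no amplitudes are supplied). R-R intervals and instantaneous heart rate
#' are recomputed after editing, and a per-beat flag records every edit.
#' If more than `max_edit_frac` of the original intervals needed editing
#' the record is condemned as `bad_ecg` (attribute on the result), the
#' automated analogue of rejecting an unsatisfactory recording.
#'
#' @param r_times Candidate R times in seconds (at least 3).
#' @param amplitudes Optional apex amplitudes aligned with `r_times`, used
#'   to pick which of two implausibly close beats to drop.
#' @param long_factor,short_factor Multiples of the local median interval
#'   defining a missed beat and a false trigger.
#' @param window Width (odd) of the running-median interval window.
#' @param max_edit_frac Edit budget above which the record is flagged.
#' @return A `beat_series` tibble: `r_time_s`, `rri_s`, `hr_bpm`, `flag`
#'   (`kept` or `inserted`; `rri_s`/`hr_bpm` are `NA` for the first beat).
#'   Attributes: `bad_ecg`, `n_edits`, `edit_frac`, `n_removed`.
#' @export
correct_beats <- function(r_times, amplitudes = NULL,
                          long_factor = 1.8, short_factor = 0.4,
                          window = 9, max_edit_frac = 0.2) {
  if (length(r_times) < 3) abort("need at least 3 candidate beats")
  if (is.unsorted(r_times, strictly = TRUE)) abort("candidate beat times must be strictly increasing")
  if (!is.null(amplitudes) && length(amplitudes) != length(r_times)) {
    abort("amplitudes must align with r_times")
  }
  times <- r_times
  amps <- amplitudes %||% rep(1, length(r_times))
  flags <- rep("kept", length(times))
  n0_intervals <- length(times) - 1L
  n_edits <- 0L
  n_removed <- 0L

  local_median <- function(rri) {
    if (length(rri) >= window) runmed(rri, window, endrule = "median")
    else rep(median(rri), length(rri))
  }

  for (iter in 1:20) {
    rri <- diff(times)
    if (!length(rri)) break
    med <- local_median(rri)
    edited <- FALSE

    short <- which(rri < short_factor * med)
    if (length(short)) {
      # process non-adjacent short intervals in one sweep (adjacent runs are
      # re-examined on the next iteration once the first removal lands)
      keep_idx <- short[c(TRUE, diff(short) > 1)]
      drop <- vapply(keep_idx, function(i) {
        if (amps[i + 1] <= amps[i]) i + 1L else i
      }, integer(1))
      drop <- unique(drop)
      times <- times[-drop]
      amps <- amps[-drop]
      flags <- flags[-drop]
      n_edits <- n_edits + length(drop)
      n_removed <- n_removed + length(drop)
      edited <- TRUE
    } else {
      long <- which(rri > long_factor * med)
      if (length(long)) {
        ins_times <- numeric(0)
        for (i in long) {
          m <- max(2L, round(rri[i] / med[i]))
          ins_times <- c(ins_times, times[i] + rri[i] * seq_len(m - 1L) / m)
        }
        ord <- order(c(times, ins_times))
        all_t <- c(times, ins_times)[ord]
        all_a <- c(amps, rep(0, length(ins_times)))[ord]
        all_f <- c(flags, rep("inserted", length(ins_times)))[ord]
        times <- all_t; amps <- all_a; flags <- all_f
        n_edits <- n_edits + length(ins_times) # one edit per inserted beat
        edited <- TRUE
      }
    }
    if (!edited) break
  }

  rri <- c(NA_real_, diff(times))
  out <- tibble(r_time_s = times, rri_s = rri, hr_bpm = 60 / rri, flag = flags)
  edit_frac <- if (n0_intervals > 0) n_edits / n0_intervals else 0
  attr(out, "bad_ecg") <- edit_frac > max_edit_frac
  attr(out, "n_edits") <- n_edits
  attr(out, "n_removed") <- n_removed
  attr(out, "edit_frac") <- edit_frac
  class(out) <- c("beat_series", class(out))
  out
}

#' Instantaneous heart rate from a beat series
#'
#' Converts each R-R interval to beats per minute (`60 / RRI` with the
#' interval in seconds) and assigns the value to the time of the second
#' beat of the interval — the moment the interval becomes known.
#'
#' @param beats A `beat_series` from [correct_beats()], or a numeric vector
#'   of beat times.
#' @return A tibble with `time_s` and `hr_bpm` (one row per interval).
#' @export
instantaneous_hr <- function(beats) {
  times <- if (is.data.frame(beats)) beats$r_time_s else as.numeric(beats)
  if (length(times) < 2) abort("need at least 2 beats")
  rri <- diff(times)
  tibble(time_s = times[-1], hr_bpm = 60 / rri)
}

#' Resample instantaneous heart rate onto a uniform grid
#'
#' Fits a natural cubic spline through the (beat time, bpm) knots and
#' evaluates it every `step` seconds. No extrapolation: the requested grid
#' must lie within the span of the knots.
#'
#' @param hr_pairs Tibble from [instantaneous_hr()] (`time_s`, `hr_bpm`).
#' @param grid_start,grid_end Grid limits in seconds.
#' @param step Grid spacing in seconds (0.5 s in this analysis).
#' @return A tibble `time_s`, `hr_bpm` on the uniform grid.
#' @export
resample_hr <- function(hr_pairs, grid_start, grid_end, step = 0.5) {
  stopifnot(all(c("time_s", "hr_bpm") %in% names(hr_pairs)))
  if (nrow(hr_pairs) < 4) abort("need at least 4 heart-rate knots for a cubic spline")
  if (grid_start < min(hr_pairs$time_s) - 1e-9 ||
      grid_end > max(hr_pairs$time_s) + 1e-9) {
    abort("requested grid extends beyond the heart-rate knots (no extrapolation)")
  }
  f <- splinefun(hr_pairs$time_s, hr_pairs$hr_bpm, method = "natural")
  grid <- seq(grid_start, grid_end, by = step)
  tibble(time_s = grid, hr_bpm = f(grid))
}

#' Full cardiac preprocessing for one session
#'
#' Runs filter -> detect -> correct -> instantaneous HR for each trip of a
#' session and reports whether any trip was condemned as `bad_ecg`.
#'
#' @param session A `driver_session`.
#' @param low,high Filter band, Hz.
#' @return A list with per-trip `beats` (beat_series) and `hr` (tibbles),
#'   plus `bad_ecg` (logical).
#' @export
preprocess_session <- function(session, low = 2, high = 40) {
  trips <- sort(unique(session$ecg$trip))
  out <- lapply(trips, function(k) {
    ecg <- dplyr::filter(session$ecg, .data$trip == k)
    fs <- infer_fs(ecg$time_s)
    filt <- bandpass_filter(ecg, low = low, high = high, fs = fs)
    cand <- detect_r_peaks(filt, fs = fs)
    if (length(cand) < 3) {
      return(list(beats = NULL, hr = NULL, bad = TRUE))
    }
    amp <- approx(filt$time_s, filt$mv, cand)$y
    beats <- correct_beats(cand, amplitudes = amp)
    list(beats = beats, hr = instantaneous_hr(beats),
         bad = isTRUE(attr(beats, "bad_ecg")))
  })
  names(out) <- paste0("trip", trips)
  list(trips = out, bad_ecg = any(vapply(out, `[[`, logical(1), "bad")))
}
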