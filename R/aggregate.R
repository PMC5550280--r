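## Baseline normalization onto the common 3200-point time base and
## per-experiment averaging with the >=3-valid-trials rule.

#' Construct a baseline-normalized series
#'
#' @param kind `"freq_pct"`, `"abs_phase_deg"` or `"firing_pct"`.
#' @param values Values on the common time base.
#' @param time_axis_s Time axis (s).
#' @param baseline_window Control window `[a, b)` used for the baseline.
#' @param experiment_id,trial_id Identifiers.
#' @return A `normalized_series`.
#' @export
normalized_series <- function(kind, values, time_axis_s, baseline_window,
                              experiment_id = NA_character_,
                              trial_id = NA_character_) {
  structure(list(kind = kind, values = values, time_axis_s = time_axis_s,
                 baseline_window = baseline_window,
                 experiment_id = experiment_id, trial_id = trial_id),
            class = "normalized_series")
}

window_idx <- function(t, window) t >= window[1] & t < window[2]

#' Absolute phase change relative to the pre-light baseline
#'
#' Computes the circular mean of the inter-root phase over the control
#' window, takes the pointwise wrapped difference from that baseline on
#' the circle, and keeps its absolute value (degrees, range `[0, 180]`).
#'
#' @param phase A `phase_series` (see [pair_phase()]).
#' @param control_window Baseline window `[a, b)` in seconds on the
#'   trimmed time base; must be at least 5 s and lie before the light
#'   (default `c(10, 55)`, the edge-clipped pre-light span).
#' @return A `normalized_series` with `kind = "abs_phase_deg"`.
#' @export
normalize_phase <- function(phase, control_window = c(10, 55)) {
  stopifnot(inherits(phase, "phase_series"))
  if (diff(control_window) < 5) {
    stop("control window shorter than 5 s")
  }
  idx <- window_idx(phase$time_axis_s, control_window)
  rad <- phase$phase_deg[idx] * pi / 180
  base <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  out <- abs(wrap_deg(phase$phase_deg - base))
  normalized_series("abs_phase_deg", out, phase$time_axis_s, control_window)
}

#' Percent frequency change relative to the pre-light baseline
#'
#' `100 * (f(t) / mean(f[control]) - 1)`, so the control period averages
#' zero.
#'
#' @param rhythm A `rhythm_series` or `phase_series` carrying a
#'   joint-ridge `freq_Hz`.
#' @inheritParams normalize_phase
#' @return A `normalized_series` with `kind = "freq_pct"`.
#' @export
normalize_frequency <- function(rhythm, control_window = c(10, 55)) {
  f <- rhythm$freq_Hz
  idx <- window_idx(rhythm$time_axis_s, control_window)
  fbar <- mean(f[idx])
  if (!is.finite(fbar) || fbar == 0) {
    stop("control-window mean frequency is zero; ",
         "the trial should have been discarded")
  }
  normalized_series("freq_pct", 100 * (f / fbar - 1), rhythm$time_axis_s,
                    control_window,
                    experiment_id = rhythm$experiment_id %||% NA_character_,
                    trial_id = rhythm$trial_id %||% NA_character_)
}

#' Percent change in motoneuron firing from the integrated neurogram
#'
#' Resamples the integrated neurogram to 19 Hz (anti-aliasing is inherent
#' — the trace is band-limited to 5 Hz by its filter chain), resizes it
#' linearly onto the wavelet time base (`n_time` points over the
#' record), and normalizes to the control window:
#' `100 * (y(t) / mean(y[control]) - 1)`. Negative values indicate
#' decreased firing, positive increased.
#'
#' @param integrated A `filtered_trace` with `kind = "integrated"`
#'   covering the trimmed 170-s record.
#' @param control_window Baseline window `[a, b)` s (default `c(10, 55)`).
#' @param resample_Hz Intermediate resampling rate (default 19).
#' @param n_time Output length (default 3200).
#' @param duration_s Record length (default 170 s).
#' @return A `normalized_series` with `kind = "firing_pct"`.
#' @export
normalize_firing <- function(integrated, control_window = c(10, 55),
                             resample_Hz = 19, n_time = 3200,
                             duration_s = 170) {
  stopifnot(inherits(integrated, "filtered_trace"))
  if (integrated$kind != "integrated") {
    stop("normalize_firing expects an integrated trace")
  }
  n <- length(integrated$samples)
  dur <- n / integrated$fs
  if (dur < duration_s - 1 / integrated$fs) {
    stop("integrated trace is ", round(dur, 2), " s; ", duration_s,
         " s required")
  }
  t <- (seq_len(n) - 1) / integrated$fs
  t19 <- seq(0, duration_s, by = 1 / resample_Hz)
  y19 <- stats::approx(t, integrated$samples, t19, rule = 2)$y
  tgrid <- (seq_len(n_time) - 1) * duration_s / n_time
  y <- stats::approx(t19, y19, tgrid, rule = 2)$y
  idx <- window_idx(tgrid, control_window)
  ybar <- mean(y[idx])
  if (!is.finite(ybar) || ybar == 0) {
    stop("control-window mean of the integrated neurogram is zero")
  }
  normalized_series("firing_pct", 100 * (y / ybar - 1), tgrid, control_window)
}

#' Average normalized series across the valid trials of one experiment
#'
#' Pointwise mean over valid trials only. Experiments with fewer than
#' `min_valid` valid trials are excluded: the function emits a log
#' message and returns `NULL`.
#'
#' @param series_list List of `normalized_series`, all of the same kind.
#' @param valid Logical vector of per-trial validity flags (from
#'   [check_validity()]); default all valid.
#' @param min_valid Minimum number of valid trials (default 3).
#' @param experiment_id Identifier used in the log message.
#' @return An `experiment_average` (fields `kind`, `values`,
#'   `time_axis_s`, `n_valid_trials`, `experiment_id`), or `NULL` when
#'   the experiment is excluded.
#' @export
average_experiment <- function(series_list, valid = NULL, min_valid = 3,
                               experiment_id = NA_character_) {
  stopifnot(length(series_list) >= 1)
  kinds <- unique(vapply(series_list, `[[`, character(1), "kind"))
  if (length(kinds) != 1) {
    stop("cannot average mixed series kinds: ", paste(kinds, collapse = ", "))
  }
  if (is.null(valid)) valid <- rep(TRUE, length(series_list))
  stopifnot(length(valid) == length(series_list))
  n_valid <- sum(valid)
  if (n_valid < min_valid) {
    message("experiment ", experiment_id, " excluded: ", n_valid,
            " valid trial(s) < required ", min_valid)
    return(NULL)
  }
  vals <- vapply(series_list[valid], `[[`,
                 numeric(length(series_list[[1]]$values)), "values")
  structure(list(kind = kinds, values = rowMeans(vals),
                 time_axis_s = series_list[[1]]$time_axis_s,
                 n_valid_trials = n_valid, experiment_id = experiment_id),
            class = "experiment_average")
}

#' Standard 10-s window summaries of a normalized series
#'
#' Means (or signed extrema, for pulse-train protocols) over the four
#' standard windows: the 10 s before the light ("control"), the first
#' 10 s of the light ("start_light"), the last 10 s of the light
#' ("end_light") and the first 10 s after the light ("after_light").
#' Windows are half-open `[a, b)` and taken flush against the light
#' transitions on the trimmed time base.
#'
#' @param series A `normalized_series` or `experiment_average`.
#' @param light_window Light epoch `[on, off)` (default `c(55, 115)` s).
#' @param width_s Window width (default 10 s).
#' @param stat `"mean"`, or `"max"` for the maximum-change variant
#'   (value of largest magnitude within each window).
#' @return Named numeric vector
#'   `c(control, start_light, end_light, after_light)`.
#' @export
window_summary <- function(series, light_window = c(55, 115), width_s = 10,
                           stat = c("mean", "max")) {
  stat <- match.arg(stat)
  t <- series$time_axis_s
  windows <- list(
    control = c(light_window[1] - width_s, light_window[1]),
    start_light = c(light_window[1], light_window[1] + width_s),
    end_light = c(light_window[2] - width_s, light_window[2]),
    after_light = c(light_window[2], light_window[2] + width_s))
  span <- c(t[1], t[length(t)] + (t[2] - t[1]))
  vapply(windows, function(w) {
    if (w[1] < span[1] || w[2] > span[2]) {
      stop("window [", w[1], ", ", w[2], ") lies outside the series span")
    }
    v <- series$values[window_idx(t, w)]
    if (stat == "mean") mean(v) else v[which.max(abs(v))]
  }, numeric(1))
}
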