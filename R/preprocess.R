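## Filtering chains and artifact correction for ventral-root neurograms.
## All IIR stages are 4th-order Butterworth run forward-backward
## (zero-phase); edges are protected by odd-reflection padding.

#' Zero-phase Butterworth filtering with reflective padding
#'
#' Applies a 4th-order Butterworth filter forward and backward
#' (zero-phase) after odd-reflection padding of `pad_s` seconds at each
#' end, so that startup transients do not leak into the record.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param cutoff_Hz Cutoff (scalar for low/high).
#' @param type `"low"` or `"high"`.
#' @param order Filter order (default 4).
#' @param pad_s Reflection pad length in seconds (default 2 s, capped at
#'   the signal length).
#' @return Filtered vector, same length as `x`.
#' @export
butter_zerophase <- function(x, fs, cutoff_Hz, type = c("low", "high"),
                             order = 4, pad_s = 2) {
  type <- match.arg(type)
  w <- cutoff_Hz / (fs / 2)
  if (w <= 0 || w >= 1) {
    stop("cutoff ", cutoff_Hz, " Hz is not inside (0, Nyquist) at fs = ",
         fs, " Hz")
  }
  bf <- signal::butter(order, w, type)
  n <- length(x)
  np <- min(n - 1L, max(1L, round(pad_s * fs)))
  # odd reflection: continuous in value and slope at the joints
  pre <- 2 * x[1] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  xp <- c(pre, x, post)
  y <- rev(signal::filter(bf, rev(signal::filter(bf, xp))))
  y[(np + 1L):(np + n)]
}

#' Integrated neurogram (rectified firing envelope)
#'
#' Produces the integrated neurogram from one raw channel by the cascade:
#' low-pass 200 Hz, high-pass 10 Hz, full-wave rectification, low-pass
#' 5 Hz. All stages are zero-phase (4th-order Butterworth forward-
#' backward). Small negative undershoots of the final smoothing stage are
#' clipped to zero so the output is an envelope.
#'
#' @param x Numeric vector of raw samples (volts).
#' @param fs Sampling rate; must exceed 400 Hz for the 200-Hz stage.
#' @param cutoffs Named list overriding the chain cutoffs
#'   (`lp1`, `hp`, `lp2`, in Hz).
#' @return A `filtered_trace` (fields `samples`, `fs`, `kind =
#'   "integrated"`, `provenance`).
#' @export
integrate_neurogram <- function(x, fs,
                                cutoffs = list(lp1 = 200, hp = 10, lp2 = 5)) {
  if (fs <= 2 * cutoffs$lp1) {
    stop("fs = ", fs, " Hz too low for the ", cutoffs$lp1, "-Hz low-pass stage")
  }
  y <- butter_zerophase(x, fs, cutoffs$lp1, "low")
  y <- butter_zerophase(y, fs, cutoffs$hp, "high")
  y <- abs(y)
  y <- butter_zerophase(y, fs, cutoffs$lp2, "low")
  filtered_trace(pmax(y, 0), fs, "integrated",
                 provenance = list(chain = "lp200>hp10>rect>lp5",
                                   cutoffs = cutoffs))
}

#' Slow locomotor drive potential
#'
#' Extracts the slow potential from one raw channel: low-pass 200 Hz
#' followed by a 0.01–5 Hz band-pass, all zero-phase. The 5-Hz low-pass
#' runs at the native rate; the 0.01-Hz high-pass edge is applied by
#' estimating the sub-0.01-Hz baseline on a ~19-Hz decimated copy
#' (alias-free, since the trace is already limited to 5 Hz) with 100 s of
#' reflective padding, then interpolating it back and subtracting. A
#' direct 4th-order recursion at 0.01 Hz is numerically unstable at
#' kilohertz rates, which this realization avoids; the result is
#' zero-mean over long windows.
#'
#' @inheritParams integrate_neurogram
#' @param band Band-pass corners in Hz (default `c(0.01, 5)`).
#' @param baseline_pad_s Reflective pad for the low-frequency edge (s).
#' @return A `filtered_trace` with `kind = "slow"`.
#' @export
extract_slow_potential <- function(x, fs, band = c(0.01, 5),
                                   baseline_pad_s = 100) {
  if (fs <= 400) stop("fs = ", fs, " Hz too low for the 200-Hz low-pass stage")
  y <- butter_zerophase(x, fs, 200, "low")
  y <- butter_zerophase(y, fs, band[2], "low")
  # low-frequency edge on a decimated copy
  fs_lo <- 19
  n <- length(y)
  t <- (seq_len(n) - 1) / fs
  t_lo <- seq(0, t[n], by = 1 / fs_lo)
  y_lo <- stats::approx(t, y, t_lo, rule = 2)$y
  base_lo <- butter_zerophase(y_lo, fs_lo, band[1], "low",
                              pad_s = baseline_pad_s)
  base <- stats::approx(t_lo, base_lo, t, rule = 2)$y
  filtered_trace(y - base, fs, "slow",
                 provenance = list(chain = "lp200>bp0.01-5", band = band))
}

#' Construct a filtered trace
#'
#' Container for one channel's filtered signal: `kind = "integrated"`
#' (non-negative firing envelope) or `kind = "slow"` (slow locomotor
#' drive potential, zero-mean over long windows).
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param kind `"integrated"` or `"slow"`.
#' @param provenance Free-form list describing the source chain.
#' @return A `filtered_trace`.
#' @export
filtered_trace <- function(samples, fs, kind = c("integrated", "slow"),
                           provenance = list()) {
  kind <- match.arg(kind)
  structure(list(samples = samples, fs = fs, kind = kind,
                 provenance = provenance),
            class = "filtered_trace")
}

#' @export
print.filtered_trace <- function(x, ...) {
  cat(sprintf("<filtered_trace %s: %.1f s @ %g Hz>\n",
              x$kind, length(x$samples) / x$fs, x$fs))
  invisible(x)
}

#' Remove light on/off step artifacts
#'
#' Continuous illumination injects DC steps into the root signal at the
#' light transitions. For each transition, the baseline on each side is
#' estimated from the medians of the thirds of a `window_s` window,
#' extrapolated quadratically to the transition instant — medians reject
#' spikes, and the quadratic extrapolation cancels the local slope and
#' curvature of the locomotor rhythm. The step (post minus pre baseline) is
#' subtracted from everything after the transition, making the DC level
#' continuous while leaving spike content untouched.
#'
#' @param x Numeric vector of raw samples.
#' @param fs Sampling rate (Hz).
#' @param light A [light_epoch()] (continuous mode).
#' @param window_s Baseline window on each side of a transition (default
#'   0.2 s).
#' @return Corrected vector.
#' @export
correct_step_artifact <- function(x, fs, light, window_s = 0.2) {
  stopifnot(inherits(light, "light_epoch"))
  n <- length(x)
  w <- round(window_s * fs)
  edge_value <- function(i1, i2, at) {
    # quadratic extrapolation to sample position `at` through the medians
    # of the three thirds of [i1, i2] (Lagrange form); medians reject
    # spikes, the quadratic absorbs the rhythm's local slope + curvature
    b <- round(seq(i1, i2 + 1L, length.out = 4L))
    tm <- numeric(3); mm <- numeric(3)
    for (k in 1:3) {
      ix <- b[k]:(b[k + 1L] - 1L)
      tm[k] <- mean(ix)
      mm[k] <- stats::median(x[ix])
    }
    sum(vapply(1:3, function(k) {
      others <- setdiff(1:3, k)
      mm[k] * prod((at - tm[others]) / (tm[k] - tm[others]))
    }, numeric(1)))
  }
  for (tt in c(light$onset_s, light$offset_s)) {
    i <- round(tt * fs) + 1L
    if (i - w < 1L || i + w - 1L > n) {
      stop("light transition at ", tt, " s lies outside the record")
    }
    pre <- edge_value(i - w, i - 1L, i - 0.5)
    post <- edge_value(i, i + w - 1L, i - 0.5)
    x[i:n] <- x[i:n] - (post - pre)
  }
  x
}

#' Subtract averaged pulse artifacts
#'
#' Each pulse of a stimulation train leaves a small stereotyped artifact.
#' The artifact template is the mean waveform over all pulses in a fixed
#' window starting at each pulse onset (capped at the inter-pulse
#' interval so windows never overlap at 100 Hz); the template is then
#' subtracted at every pulse time. With fewer than 10 pulses the trace is
#' returned unchanged with a warning.
#'
#' @param x Numeric vector of raw samples.
#' @param fs Sampling rate (Hz).
#' @param pulse_times Pulse onset times, seconds (may be empty).
#' @param window_s Template window length (default 5 ms, capped at the
#'   minimum inter-pulse interval).
#' @return Corrected vector.
#' @export
subtract_pulse_artifacts <- function(x, fs, pulse_times, window_s = 0.005) {
  if (length(pulse_times) == 0) return(x)
  if (length(pulse_times) < 10) {
    warning("fewer than 10 pulses; artifact template not estimated",
            call. = FALSE)
    return(x)
  }
  ipi <- min(diff(sort(pulse_times)))
  w <- max(2L, floor(min(window_s, ipi) * fs))
  starts <- round(pulse_times * fs) + 1L
  starts <- starts[starts >= 1L & starts + w - 1L <= length(x)]
  seg <- vapply(starts, function(i) x[i:(i + w - 1L)], numeric(w))
  template <- rowMeans(seg)
  for (i in starts) x[i:(i + w - 1L)] <- x[i:(i + w - 1L)] - template
  x
}

#' Align and trim a trial to the common 170-s window
#'
#' Drops 5 s at each end of a 180-s trial so every trial is aligned to
#' the light onset: the trimmed record is 170 s with the light at
#' `[55, 115)` s. Metadata (light epoch) is updated.
#'
#' @param tr A [trial()] of at least 180 s with light at `[60, 120)` s.
#' @param trim_s Seconds removed at each end (default 5).
#' @return Trimmed [trial()].
#' @export
align_trim <- function(tr, trim_s = 5) {
  stopifnot(inherits(tr, "trial"))
  dur <- trial_duration_s(tr)
  if (dur < 180) {
    stop("trial is ", round(dur, 3),
         " s; at least 180 s are required before trimming")
  }
  start_s <- tr$light$onset_s - (60 - trim_s)
  end_s <- start_s + 180 - 2 * trim_s
  if (start_s < 0 || end_s > dur) {
    stop("cannot align: light onset at ", tr$light$onset_s,
         " s leaves no room for the trimmed window")
  }
  keep <- (round(start_s * tr$fs) + 1L):round(end_s * tr$fs)
  tr$samples <- tr$samples[, keep, drop = FALSE]
  tr$light <- light_epoch(tr$light$onset_s - start_s,
                          tr$light$offset_s - start_s,
                          tr$light$mode, tr$light$pulse_rate_Hz,
                          tr$light$pulse_width_ms)
  tr
}
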