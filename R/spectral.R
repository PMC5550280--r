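## Complex-Morlet wavelet spectrograms, instantaneous-frequency ridges and
## cross-channel phase series for the 0.1-2 Hz locomotor band.

#' Default frequency grid for the locomotor band
#'
#' 64 logarithmically spaced frequencies over 0.1-2 Hz.
#' @param n Number of frequencies.
#' @param range_Hz Two-element band.
#' @return Increasing numeric vector of frequencies (Hz).
#' @export
default_freq_grid <- function(n = 64, range_Hz = c(0.1, 2)) {
  exp(seq(log(range_Hz[1]), log(range_Hz[2]), length.out = n))
}

#' Complex Morlet wavelet spectrogram on the 3200-point time base
#'
#' Computes the continuous wavelet transform (complex Morlet, centre
#' frequency parameter `omega0 = 6`) of a slow-potential trace on a fixed
#' frequency grid, with exactly `n_time` points along the time dimension
#' spanning the 170-s record. The trace — band-limited to 5 Hz by its own
#' filter chain — is interpolated onto the uniform `n_time` base
#' (alias-free by construction) and the transform is evaluated there by
#' FFT convolution with zero padding. The cone of influence (e-folding
#' time of the wavelet envelope, `sqrt(2) * scale`) is recorded per
#' frequency.
#'
#' @param trace A `filtered_trace` (normally `kind = "slow"`), or a
#'   numeric vector with `fs` supplied.
#' @param freq_grid Strictly increasing frequencies (Hz);
#'   default [default_freq_grid()].
#' @param fs Sampling rate when `trace` is a bare vector.
#' @param n_time Number of time points (default 3200).
#' @param duration_s Expected record length (default 170 s); shorter
#'   traces are an error.
#' @param omega0 Morlet centre-frequency parameter (default 6).
#' @return A `wavelet_spectrogram`: complex `coefficients`
#'   (frequencies x n_time), `freq_grid_Hz`, `time_axis_s`,
#'   `coi_s` (per-frequency e-folding time), `omega0`.
#' @export
cwt_spectrogram <- function(trace, freq_grid = default_freq_grid(),
                            fs = NULL, n_time = 3200, duration_s = 170,
                            omega0 = 6) {
  if (inherits(trace, "filtered_trace")) {
    x <- trace$samples
    fs <- trace$fs
  } else {
    x <- as.numeric(trace)
    if (is.null(fs)) stop("fs must be supplied for a bare numeric trace")
  }
  if (any(diff(freq_grid) <= 0)) stop("freq_grid must be strictly increasing")
  dur <- length(x) / fs
  if (dur < duration_s - 1 / fs) {
    stop("trace is ", round(dur, 3), " s; a ", duration_s,
         "-s record is required")
  }
  dt <- duration_s / n_time
  tgrid <- (seq_len(n_time) - 1) * dt
  xr <- stats::approx((seq_along(x) - 1) / fs, x, tgrid, rule = 2)$y
  xr <- xr - mean(xr)

  npad <- 2^ceiling(log2(2 * n_time))
  xhat <- stats::fft(c(xr, rep(0, npad - n_time)))
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)
  # Fourier factor relating scale to equivalent Fourier period
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- 1 / (freq_grid * fourier_factor)
  coef <- matrix(0i, nrow = length(freq_grid), ncol = n_time)
  norm0 <- pi^(-1 / 4)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi_hat <- numeric(npad)
    pos <- omega > 0
    psi_hat[pos] <- sqrt(2 * pi * s / dt) * norm0 *
      exp(-(s * omega[pos] - omega0)^2 / 2)
    w <- stats::fft(xhat * psi_hat, inverse = TRUE) / npad
    coef[j, ] <- w[seq_len(n_time)]
  }
  structure(list(coefficients = coef, freq_grid_Hz = freq_grid,
                 time_axis_s = tgrid, coi_s = sqrt(2) * scales,
                 omega0 = omega0, duration_s = duration_s),
            class = "wavelet_spectrogram")
}

in_band_rows <- function(spec, band_Hz) {
  rows <- which(spec$freq_grid_Hz >= band_Hz[1] &
                  spec$freq_grid_Hz <= band_Hz[2])
  if (length(rows) == 0) stop("empty frequency band [", band_Hz[1], ", ",
                              band_Hz[2], "] Hz")
  rows
}

ridge_pick <- function(P, freqs, threshold_frac) {
  nf <- nrow(P)
  imax <- max.col(t(P), ties.method = "first")
  pmax <- P[cbind(imax, seq_len(ncol(P)))]
  # low-power rule: relative to the trial's median ridge power, so that
  # epochs whose rhythm collapses read as frequency 0
  threshold <- threshold_frac * stats::median(pmax)
  lf <- log(freqs)
  f <- freqs[imax]
  # parabolic refinement of log-power across log-frequency
  interior <- which(imax > 1L & imax < nf & pmax > 0)
  if (length(interior)) {
    i <- imax[interior]
    l1 <- log(pmax(P[cbind(i - 1L, interior)], 1e-300))
    l2 <- log(pmax(P[cbind(i, interior)], 1e-300))
    l3 <- log(pmax(P[cbind(i + 1L, interior)], 1e-300))
    denom <- l1 - 2 * l2 + l3
    delta <- ifelse(denom < 0, 0.5 * (l1 - l3) / denom, 0)
    delta <- pmin(pmax(delta, -0.5), 0.5)
    step <- (lf[length(lf)] - lf[1]) / (length(lf) - 1)
    f[interior] <- exp(lf[i] + delta * step)
  }
  f[pmax <= threshold] <- 0
  list(freq = f, power = pmax)
}

#' Instantaneous rhythm frequency from the wavelet ridge
#'
#' At each time point, takes the frequency of maximal wavelet power
#' within `band_Hz`, refined by parabolic interpolation of log-power over
#' log-frequency between the neighbouring grid rows. Where the ridge
#' power falls below `threshold_frac` of the trial's median in-band power
#' the frequency is set to 0 — this feeds the trial-discard rule (see
#' [check_validity()]).
#'
#' @param spec A [cwt_spectrogram()].
#' @param band_Hz Search band (must intersect the grid).
#' @param threshold_frac Low-power threshold as a fraction of the
#'   trial's median ridge (in-band maximum) power (default 0.05).
#' @param trial_id,experiment_id Carried identifiers.
#' @return A `rhythm_series`: `freq_Hz`, `power`, `time_axis_s`,
#'   `valid` (NA until [check_validity()] is applied), ids.
#' @export
ridge_frequency <- function(spec, band_Hz = c(0.1, 2), threshold_frac = 0.05,
                            trial_id = NA_character_,
                            experiment_id = NA_character_) {
  stopifnot(inherits(spec, "wavelet_spectrogram"))
  rows <- in_band_rows(spec, band_Hz)
  P <- Mod(spec$coefficients[rows, , drop = FALSE])^2
  r <- ridge_pick(P, spec$freq_grid_Hz[rows], threshold_frac)
  structure(list(freq_Hz = r$freq, power = r$power,
                 time_axis_s = spec$time_axis_s, valid = NA,
                 trial_id = trial_id, experiment_id = experiment_id),
            class = "rhythm_series")
}

#' Inter-root phase from the cross-wavelet spectrum
#'
#' Forms the cross-wavelet spectrum `A * Conj(B)` of two spectrograms on
#' the same grid and reads the phase along the joint ridge (maximum
#' cross-power within `band_Hz`; ties broken toward the lowest
#' frequency), in degrees wrapped to (-180, 180]. Positive phase means
#' channel A leads channel B. The joint-ridge frequency is also returned
#' and can serve as the trial's rhythm frequency series.
#'
#' @param specA,specB [cwt_spectrogram()]s with identical grids and time
#'   axes.
#' @param band_Hz Search band.
#' @param pair Character vector of the two channel labels.
#' @param pair_class `"bilateral_flexor"` or
#'   `"ipsilateral_flexor_extensor"`.
#' @param threshold_frac Low-power threshold (as in [ridge_frequency()])
#'   applied to cross-power; below it the joint-ridge frequency is 0.
#' @return A `phase_series`: `phase_deg`, `freq_Hz` (joint ridge),
#'   `power`, `pair`, `pair_class`, `time_axis_s`.
#' @export
pair_phase <- function(specA, specB, band_Hz = c(0.1, 2),
                       pair = c("A", "B"),
                       pair_class = c("bilateral_flexor",
                                      "ipsilateral_flexor_extensor"),
                       threshold_frac = 0.05) {
  pair_class <- match.arg(pair_class)
  stopifnot(inherits(specA, "wavelet_spectrogram"),
            inherits(specB, "wavelet_spectrogram"))
  if (!isTRUE(all.equal(specA$freq_grid_Hz, specB$freq_grid_Hz)) ||
      !isTRUE(all.equal(specA$time_axis_s, specB$time_axis_s))) {
    stop("spectrogram grids/time axes do not match")
  }
  rows <- in_band_rows(specA, band_Hz)
  cross <- specA$coefficients[rows, , drop = FALSE] *
    Conj(specB$coefficients[rows, , drop = FALSE])
  P <- Mod(cross)
  r <- ridge_pick(P, specA$freq_grid_Hz[rows], threshold_frac)
  imax <- max.col(t(P), ties.method = "first")
  ph <- Arg(cross[cbind(imax, seq_len(ncol(cross)))]) * 180 / pi
  structure(list(phase_deg = wrap_deg(ph), freq_Hz = r$freq, power = r$power,
                 pair = pair, pair_class = pair_class,
                 time_axis_s = specA$time_axis_s),
            class = "phase_series")
}

#' Wrap angles in degrees to (-180, 180]
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_deg <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

#' Mark wavelet edge artifacts invalid
#'
#' Wavelet transforms smear across edges, so the first and last
#' `clip_s` seconds of every derived series are excluded from plotting
#' and statistics. The values are kept (light-epoch indexing is
#' preserved); an `analyzed` logical mask marks the usable span.
#' Idempotent.
#'
#' @param series Any series with a `time_axis_s` field
#'   (`rhythm_series`, `phase_series`, `normalized_series`).
#' @param clip_s Seconds clipped at each end (default 10).
#' @return The series with an `analyzed` mask (and `clip_s` recorded).
#' @export
clip_edges <- function(series, clip_s = 10) {
  t <- series$time_axis_s
  span <- t[length(t)] + (t[2] - t[1])
  series$analyzed <- t >= clip_s & t < span - clip_s
  series$clip_s <- clip_s
  series
}

#' Trial-discard rule: frequency dropout before or during the light
#'
#' A trial is invalid when its ridge frequency drops to zero (signal
#' power too low) at any analyzed point before the light or during the
#' light; dropouts after the light do not invalidate a trial. Applied to
#' the edge-clipped span.
#'
#' @param rhythm A `rhythm_series` (or `phase_series` carrying a
#'   joint-ridge `freq_Hz`).
#' @param light_window Light epoch `[on, off)` on the trimmed time base
#'   (default `c(55, 115)`).
#' @param clip_s Edge clip (default 10 s); the checked span is
#'   `[clip_s, off)`.
#' @return `TRUE` if the trial is valid, else `FALSE`.
#' @export
check_validity <- function(rhythm, light_window = c(55, 115), clip_s = 10) {
  t <- rhythm$time_axis_s
  checked <- t >= clip_s & t < light_window[2]
  !any(rhythm$freq_Hz[checked] == 0)
}
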