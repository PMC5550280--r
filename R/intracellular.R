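## Intracellular motoneuron sweep analyses: epoch spike counts, input
## resistance from the I-V slope, and collision-protocol electrical
## coupling amplitude.

#' Intracellular sweep container
#'
#' @param voltage Membrane potential samples (mV).
#' @param fs Sampling rate (Hz).
#' @param current Injected current (pA): a vector matching `voltage` or
#'   a single command value.
#' @param stim_times Stimulus times (s), each within the record.
#' @param holding_mV Holding potential (mV).
#' @return A `sweep` object.
#' @export
icell_sweep <- function(voltage, fs, current = NULL,
                        stim_times = numeric(0), holding_mV = NA_real_) {
  stopifnot(is.numeric(voltage), all(is.finite(voltage)), fs > 0)
  dur <- length(voltage) / fs
  if (length(stim_times) && any(stim_times < 0 | stim_times >= dur)) {
    stop("stim_times must lie within the record")
  }
  structure(list(voltage = voltage, fs = fs, current = current,
                 stim_times = stim_times, holding_mV = holding_mV),
            class = "icell_sweep")
}

#' Count spikes per epoch by threshold crossing
#'
#' Upward crossings of the threshold with a refractory period. The
#' default threshold is -20 mV absolute; with `relative = TRUE` the
#' threshold is interpreted as mV above the trace median, making the
#' count invariant to DC offset.
#'
#' @param sweep An [icell_sweep()] (or bare numeric vector with `fs`).
#' @param epochs Named list of `[a, b)` windows in seconds.
#' @param threshold_mV Detection threshold (mV; absolute by default).
#' @param refractory_s Minimum inter-spike interval (default 2 ms).
#' @param relative Interpret `threshold_mV` relative to the trace
#'   median.
#' @param fs Sampling rate when `sweep` is a bare vector.
#' @return Named integer vector of counts per epoch.
#' @export
count_spikes <- function(sweep, epochs, threshold_mV = -20,
                         refractory_s = 0.002, relative = FALSE, fs = NULL) {
  if (inherits(sweep, "icell_sweep")) {
    v <- sweep$voltage; fs <- sweep$fs
  } else {
    v <- as.numeric(sweep)
    if (is.null(fs)) stop("fs must be supplied for a bare vector")
  }
  thr <- if (relative) stats::median(v) + threshold_mV else threshold_mV
  up <- which(v[-1] >= thr & v[-length(v)] < thr) + 1L
  if (length(up) > 1) {
    # enforce refractory sequentially
    last <- up[1]; sel <- logical(length(up)); sel[1] <- TRUE
    for (i in seq_along(up)[-1]) {
      if (up[i] - last >= refractory_s * fs) { sel[i] <- TRUE; last <- up[i] }
    }
    up <- up[sel]
  }
  spike_t <- (up - 1) / fs
  vapply(epochs, function(w) {
    if (w[1] < 0 || w[2] > length(v) / fs) {
      stop("epoch [", w[1], ", ", w[2], ") lies outside the sweep")
    }
    sum(spike_t >= w[1] & spike_t < w[2])
  }, numeric(1))
}

#' Input resistance from the I-V slope
#'
#' Least-squares slope of steady-state voltage (mV) on injected current
#' (pA) over points in the linear range, expressed in megaohms.
#'
#' @param iv_points Data frame with columns `injected_current_pA` and
#'   `steady_voltage_mV` (>= 3 rows; 200-ms pulses by convention).
#' @return Input resistance (MOhm).
#' @export
input_resistance <- function(iv_points) {
  need <- c("injected_current_pA", "steady_voltage_mV")
  if (!all(need %in% names(iv_points))) {
    stop("iv_points needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(iv_points) < 3) {
    stop("at least 3 I-V points in the linear range are required")
  }
  fit <- stats::lm(steady_voltage_mV ~ injected_current_pA, data = iv_points)
  unname(stats::coef(fit)[2]) * 1000  # mV/pA = GOhm -> MOhm
}

#' Electrical-coupling amplitude by the collision protocol
#'
#' Subtracts the averaged orthodromic action potential from the averaged
#' collided antidromic response; the residual short-latency
#' depolarization is the electrotonic coupling potential from
#' antidromically activated, gap-junction-coupled motoneurons. Both
#' inputs should be averages of at least 20 aligned sweeps taken at 2x
#' antidromic threshold. Traces are baseline-aligned on the 10 ms before
#' the stimulus; the amplitude is the peak of the difference in a
#' post-stimulus window.
#'
#' @param collided,orthodromic Averaged sweeps ([icell_sweep()] or bare
#'   vectors), equal length and rate.
#' @param stim_time_s Stimulus time (taken from the sweep metadata when
#'   available).
#' @param window_s Post-stimulus search window (default 1-10 ms).
#' @param fs Sampling rate for bare vectors.
#' @param n_sweeps Number of sweeps each average is built from (a
#'   warning is issued below 20).
#' @return List: `amplitude_mV` (peak of the difference), `latency_s`,
#'   `difference` (full trace).
#' @export
coupling_amplitude <- function(collided, orthodromic, stim_time_s = NULL,
                               window_s = c(0.001, 0.010), fs = NULL,
                               n_sweeps = 20) {
  get <- function(x) {
    if (inherits(x, "icell_sweep"))

      list(v = x$voltage, fs = x$fs,
           stim = if (length(x$stim_times)) x$stim_times[1] else NULL)
    else list(v = as.numeric(x), fs = fs, stim = NULL)
  }
  a <- get(collided); b <- get(orthodromic)
  if (is.null(a$fs) || is.null(b$fs)) stop("fs must be available")
  if (length(a$v) != length(b$v) || a$fs != b$fs) {
    stop("collided and orthodromic averages must share length and rate")
  }
  if (n_sweeps < 20) {
    warning("averages built from fewer than 20 sweeps", call. = FALSE)
  }
  stim <- stim_time_s %||% a$stim %||% b$stim
  if (is.null(stim)) stop("stimulus time unknown: supply stim_time_s")
  fsr <- a$fs
  i_stim <- round(stim * fsr) + 1L
  base_n <- max(1L, round(0.010 * fsr))
  base_ix <- max(1L, i_stim - base_n):(i_stim - 1L)
  va <- a$v - mean(a$v[base_ix])
  vb <- b$v - mean(b$v[base_ix])
  d <- va - vb
  ix <- (i_stim + round(window_s[1] * fsr)):(i_stim + round(window_s[2] * fsr))
  ix <- ix[ix >= 1 & ix <= length(d)]
  ipk <- ix[which.max(d[ix])]
  list(amplitude_mV = d[ipk], latency_s = (ipk - i_stim) / fsr,
       difference = d)
}

#' Voltage-independence check for coupling potentials
#'
#' Gap-junction-mediated short-latency depolarizations keep their
#' amplitude across holding potentials; chemically mediated ones do not.
#' Flags a set of amplitudes as voltage-independent when the spread is
#' below `tol_frac` of the mean magnitude.
#'
#' @param amplitudes_mV Coupling amplitudes at >= 2 holding potentials.
#' @param tol_frac Allowed relative spread (default 0.10).
#' @return `TRUE` when voltage-independent.
#' @export
voltage_independent <- function(amplitudes_mV, tol_frac = 0.10) {
  stopifnot(length(amplitudes_mV) >= 2)
  m <- mean(abs(amplitudes_mV))
  if (m == 0) return(TRUE)
  (max(amplitudes_mV) - min(amplitudes_mV)) / m < tol_frac
}

#' Import intracellular sweeps from CSV
#'
#' Expects columns `time_s`, `voltage_mV` and optionally `current_pA`;
#' sweep-level metadata (`fs` inferred from time column).
#'
#' @param path CSV file.
#' @param stim_times,holding_mV Metadata passed through.
#' @return An [icell_sweep()].
#' @export
read_sweep_csv <- function(path, stim_times = numeric(0),
                           holding_mV = NA_real_) {
  dt <- data.table::fread(path)
  if (!all(c("time_s", "voltage_mV") %in% names(dt))) {
    stop("sweep CSV needs columns time_s, voltage_mV")
  }
  fs <- 1 / stats::median(diff(dt$time_s))
  icell_sweep(dt$voltage_mV, fs,
              current = if ("current_pA" %in% names(dt)) dt$current_pA,
              stim_times = stim_times, holding_mV = holding_mV)
}
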