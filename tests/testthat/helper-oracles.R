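# Shared fixtures and independent oracles.
# Unit-test scenarios synthesize at 500 Hz to keep the suite fast; the
# filter chains only require fs > 400 Hz.

small_scenario <- function(...) {
  args <- list(n_experiments = 2, trials_per_experiment = 3,
               fs = 500, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_scenario, args)
}

clean_scenario <- function(...) {
  # deterministic rhythm: no jitter, no noise, drive potential only
  args <- list(effect_jitter_sdlog = 0, trial_freq_sd_Hz = 0,
               base_freq_sd_Hz = 0, noise_sd = 0, spike_amp_V = 0,
               drive_amp_V = 2e-5)
  over <- list(...)
  args[names(over)] <- over
  do.call(small_scenario, args)
}

# FFT peak frequency of a trace (independent of the wavelet path)
fft_peak_Hz <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(stats::fft(x))[1:(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1) * fs / n
  freqs[which.max(sp)]
}

# Hilbert-transform instantaneous phase difference (degrees, A minus B)
hilbert_phase_deg <- function(xa, xb) {
  analytic <- function(x) {
    n <- length(x)
    h <- numeric(n)
    if (n %% 2 == 0) {
      h[c(1, n / 2 + 1)] <- 1
      h[2:(n / 2)] <- 2
    } else {
      h[1] <- 1
      h[2:((n + 1) / 2)] <- 2
    }
    stats::fft(stats::fft(x - mean(x)) * h, inverse = TRUE) / n
  }
  Arg(analytic(xa) * Conj(analytic(xb))) * 180 / pi
}

# Exhaustive enumeration of the 3-vs-3 shift-method bootstrap null.
# Degenerate resamples (both groups constant, unequal means) have an
# infinite statistic and always count as exceedances.
exhaustive_boot_p <- function(a, b, t_obs) {
  welch3 <- function(x, y) {
    d <- sqrt(stats::var(x) / 3 + stats::var(y) / 3)
    num <- mean(x) - mean(y)
    if (d == 0) { if (num == 0) 0 else Inf } else num / d
  }
  pooled <- mean(c(a, b))
  a0 <- a - mean(a) + pooled
  b0 <- b - mean(b) + pooled
  idx <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  count <- 0L; total <- 0L
  for (i in seq_len(nrow(idx))) {
    for (j in seq_len(nrow(idx))) {
      ts <- welch3(a0[idx[i, ]], b0[idx[j, ]])
      if (abs(ts) >= abs(t_obs)) count <- count + 1L
      total <- total + 1L
    }
  }
  count / total
}
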