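## Ground-truth synthetic fictive-locomotion generator.
##
## Emulates the statistical structure the analysis assumes: slow
## alternating bursting on four lumbar roots (~0.45 Hz), 180-degree
## bilateral-flexor and ipsilateral flexor-extensor alternation, a
## light epoch [60,120) s with firing suppression (stronger in extensor
## roots), a transient frequency drop recovering within the light,
## post-light rebound of both frequency and firing, transient phase
## perturbations, inter-trial and inter-animal variability, and optional
## light-step / pulse-train artifacts.

#' Scenario parameters for the synthetic generator
#'
#' Bundles all generative parameters with a seed. Defaults describe a
#' cohort with the effect scales typical of optogenetic motoneuron
#' silencing during drug-induced locomotor-like activity: per-experiment
#' base frequency ~ Normal(0.45, 0.06) Hz; peak frequency drop 8% of
#' baseline recovering within the light (tau 30 s); post-light frequency
#' rebound (peak 13%, tau 10 s); firing suppression 63% (flexor) / 78%
#' (extensor) with slow in-light recovery (tau 130 s) and post-light
#' firing rebound (peak 40%, tau 10 s); transient phase shifts of 24 deg
#' (bilateral flexor pair) / 55 deg (ipsilateral flexor-extensor pair)
#' decaying with tau 30 s. Effect sizes are jittered per experiment by a
#' mean-one lognormal (sdlog 0.15). A wild-type-like cohort is obtained
#' by zeroing the effect fields (see [wildtype_scenario()]).
#'
#' @param n_experiments Number of animals/preparations.
#' @param trials_per_experiment Trials per experiment (default 4).
#' @param base_freq_Hz,base_freq_sd_Hz Per-experiment base rhythm
#'   frequency distribution (Hz).
#' @param trial_freq_sd_Hz Trial-to-trial base-frequency jitter (Hz).
#' @param phase_lags_deg Named per-channel burst phase lags (degrees);
#'   names define the channel layout (`rL2`, `lL2`, `lL5`, `rL5` by
#'   default: bilateral flexors and ipsilateral flexor-extensor pairs in
#'   antiphase).
#' @param light_freq_drop_frac Peak fractional frequency drop at light
#'   onset.
#' @param light_recovery_tau_s Within-light frequency recovery time
#'   constant (s; `Inf` = sustained drop).
#' @param rebound_freq_frac,rebound_tau_s Post-light frequency rebound
#'   (peak fraction, decay tau).
#' @param firing_suppression_frac Named fractions (`flexor`, `extensor`)
#'   by which burst firing is suppressed during the light.
#' @param firing_recovery_tau_s In-light recovery tau of the firing
#'   suppression (s).
#' @param rebound_firing_frac Post-light firing rebound peak fraction.
#' @param phase_shift_light_deg Named peak phase perturbations during
#'   the light (`bilateral`, `ipsilateral`, degrees).
#' @param phase_shift_tau_s In-light decay tau of the phase perturbation.
#' @param effect_jitter_sdlog Sdlog of the mean-one lognormal
#'   per-experiment jitter on all effect sizes.
#' @param duty_cycle Burst duty cycle (fraction of the cycle bursting).
#' @param carrier `"spike_train"` (inhomogeneous Poisson spikes
#'   convolved with a biphasic unit waveform), `"filtered_noise"`
#'   (band-limited noise amplitude-modulated by the envelope), or
#'   `"rate"` (the deterministic rate function itself, for calibration
#'   tests).
#' @param spike_rate_peak_Hz Peak pooled multiunit spike rate at a burst
#'   crest.
#' @param spike_amp_V Spike waveform amplitude (V).
#' @param kernel_ms Biphasic unit-waveform duration (ms).
#' @param drive_amp_V Amplitude of the slow locomotor drive potential
#'   superimposed on each channel (V) — the sub-5-Hz population
#'   depolarization the slow-potential chain extracts; biphasic spikes
#'   carry no power there.
#' @param drive_mod_frac Fraction of the firing suppression/rebound
#'   applied to the drive-potential amplitude (the synaptic drive is
#'   attenuated less than spiking when motoneurons are hyperpolarized).
#' @param noise_sd Additive Gaussian noise SD (V).
#' @param artifact_step_V DC step injected while the light is on
#'   (continuous mode; 0 = none).
#' @param artifact_pulse_V Per-pulse artifact amplitude (pulse-train
#'   mode; 0 = none).
#' @param light A [light_epoch()] (default continuous `[60, 120)`).
#' @param fs Synthesis sampling rate (Hz). Default 1000: all analysed
#'   structure lies below the 200-Hz filter stage.
#' @param duration_s Trial length (default 180 s).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A validated `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(
    n_experiments = 4,
    trials_per_experiment = 4,
    base_freq_Hz = 0.45, base_freq_sd_Hz = 0.06,
    trial_freq_sd_Hz = 0.015,
    phase_lags_deg = c(rL2 = 0, lL2 = 180, lL5 = 0, rL5 = 180),
    light_freq_drop_frac = 0.08,
    light_recovery_tau_s = 30,
    rebound_freq_frac = 0.13, rebound_tau_s = 10,
    firing_suppression_frac = c(flexor = 0.63, extensor = 0.78),
    firing_recovery_tau_s = 130,
    rebound_firing_frac = 0.40,
    phase_shift_light_deg = c(bilateral = 24, ipsilateral = 55),
    phase_shift_tau_s = 30,
    effect_jitter_sdlog = 0.15,
    duty_cycle = 0.5,
    carrier = c("spike_train", "filtered_noise", "rate"),
    spike_rate_peak_Hz = 20,
    spike_amp_V = 1e-3,
    kernel_ms = 3,
    drive_amp_V = 2e-5,
    drive_mod_frac = 0.5,
    noise_sd = 5e-7,
    artifact_step_V = 0,
    artifact_pulse_V = 0,
    light = light_epoch(60, 120),
    fs = 1000, duration_s = 180,
    seed = 1L) {
  carrier <- match.arg(carrier)
  sc <- as.list(environment())
  fracs <- c(light_freq_drop_frac, rebound_freq_frac,
             firing_suppression_frac, rebound_firing_frac, duty_cycle)
  if (any(!is.finite(fracs)) || any(fracs < 0 | fracs > 1)) {
    stop("all fractional effect parameters must be finite and in [0, 1]")
  }
  if (!is.finite(base_freq_Hz) || base_freq_Hz <= 0.1 || base_freq_Hz >= 2) {
    stop("base_freq_Hz must lie in (0.1, 2)")
  }
  if (!all(c("flexor", "extensor") %in% names(firing_suppression_frac))) {
    stop("firing_suppression_frac needs named 'flexor' and 'extensor' entries")
  }
  if (anyNA(phase_lags_deg) || is.null(names(phase_lags_deg))) {
    stop("phase_lags_deg must be a named numeric vector of channel lags")
  }
  stopifnot(n_experiments >= 1, trials_per_experiment >= 1,
            fs > 400, duration_s >= 180, noise_sd >= 0,
            is.finite(seed))
  structure(sc, class = "synthetic_scenario")
}

#' Wild-type-like null scenario
#'
#' The same rhythm model with every light-locked effect set to zero —
#' cohorts generated from it differ from an effect cohort only through
#' the light response, and two of them differ in nothing (the null for
#' type-I-error calibration).
#'
#' @param ... Overrides passed to [synthetic_scenario()].
#' @return A `synthetic_scenario`.
#' @export
wildtype_scenario <- function(...) {
  args <- list(
    light_freq_drop_frac = 0, rebound_freq_frac = 0,
    firing_suppression_frac = c(flexor = 0, extensor = 0),
    rebound_firing_frac = 0,
    phase_shift_light_deg = c(bilateral = 0, ipsilateral = 0))
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_scenario, args)
}

derive_seed <- function(seed, a, b) {
  (as.integer(seed) %% 1000003L) * 2011L + a * 1009L + b * 7L
}

scenario_channels <- function(sc) {
  lapply(names(sc$phase_lags_deg), function(lab) {
    side <- if (startsWith(lab, "l")) "left" else "right"
    segment <- toupper(sub("^[lr]", "", lab))
    channel_meta(lab, segment, side)
  })
}

exp_effects <- function(sc, experiment_index) {
  set.seed(derive_seed(sc$seed, experiment_index, 0L))
  jit <- function(x) {
    s <- sc$effect_jitter_sdlog
    x * exp(stats::rnorm(length(x), -s^2 / 2, s))
  }
  list(
    f0 = min(max(stats::rnorm(1, sc$base_freq_Hz, sc$base_freq_sd_Hz), 0.15),
             1.9),
    drop = min(jit(sc$light_freq_drop_frac), 1),
    reb = jit(sc$rebound_freq_frac),
    supp = pmin(jit(sc$firing_suppression_frac), 1),
    reb_fir = jit(sc$rebound_firing_frac),
    pshift = jit(sc$phase_shift_light_deg))
}

# temporal weight of light-locked transient effects: fast rise at onset,
# exponential decay with tau inside the light, fast decay after offset
effect_weight <- function(t, on, off, tau, rise_tau = 1.5) {
  w <- numeric(length(t))
  inl <- t >= on & t < off
  w[inl] <- (1 - exp(-(t[inl] - on) / rise_tau)) * exp(-(t[inl] - on) / tau)
  w_off <- (1 - exp(-(off - on) / rise_tau)) * exp(-(off - on) / tau)
  post <- t >= off
  w[post] <- w_off * exp(-(t[post] - off) / rise_tau)
  w
}

#' Generate one synthetic trial with its ground truth
#'
#' Builds a 180-s multichannel trial: the instantaneous phase is
#' integrated from the true frequency trajectory `f(t)`; each channel's
#' burst envelope is a raised cosine of its lagged phase; the carrier is
#' an inhomogeneous Poisson spike train convolved with a biphasic unit
#' waveform (or band-limited noise) amplitude-modulated by the envelope;
#' during the light the envelope is scaled by the suppression factor
#' (with exponential partial recovery) and `f(t)` drops (recovering with
#' its own tau); after the light both rebound transiently; Gaussian
#' noise and optional light-step / pulse artifacts are added.
#'
#' @param sc A [synthetic_scenario()].
#' @param experiment_index,trial_index 1-based indices; together with the
#'   scenario seed they determine the experiment-level random effects and
#'   the trial realization.
#' @param group_id Cohort label stored on the trial.
#' @return `list(trial = <trial>, truth = <ground_truth>)`; the ground
#'   truth shares the trial's native time base and carries the true
#'   frequency trajectory, per-channel firing rate (and firing
#'   modulation), and true pairwise phase-difference trajectories.
#' @export
generate_trial <- function(sc, experiment_index = 1L, trial_index = 1L,
                           group_id = "A") {
  stopifnot(inherits(sc, "synthetic_scenario"))
  eff <- exp_effects(sc, experiment_index)
  set.seed(derive_seed(sc$seed, experiment_index, trial_index))
  fs <- sc$fs
  n <- round(sc$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  on <- sc$light$onset_s; off <- sc$light$offset_s

  f0 <- eff$f0 + stats::rnorm(1, 0, sc$trial_freq_sd_Hz)
  fac <- rep(1, n)
  inl <- t >= on & t < off
  fac[inl] <- 1 - eff$drop * exp(-(t[inl] - on) / sc$light_recovery_tau_s)
  post <- t >= off
  fac[post] <- 1 + eff$reb * exp(-(t[post] - off) / sc$rebound_tau_s)
  freq <- f0 * fac
  phi <- cumsum(freq) / fs  # cycles

  labs <- names(sc$phase_lags_deg)
  chans <- scenario_channels(sc)
  dominance <- vapply(chans, `[[`, character(1), "dominance")
  side <- vapply(chans, `[[`, character(1), "side")

  # per-channel transient phase offsets realizing the pair-level shifts
  w_phase <- effect_weight(t, on, off, sc$phase_shift_tau_s)
  bil <- eff$pshift[["bilateral"]]; ips <- eff$pshift[["ipsilateral"]]
  peak_off <- ifelse(dominance == "flexor",
                     ifelse(side == "left", bil, 0),
                     ifelse(side == "left", bil - ips, -ips))

  # firing modulation per channel
  w_sup <- rep(0, n)
  w_sup[inl] <- exp(-(t[inl] - on) / sc$firing_recovery_tau_s)
  w_reb <- rep(0, n)
  w_reb[post] <- exp(-(t[post] - off) / sc$rebound_tau_s)

  d <- sc$duty_cycle
  samples <- matrix(0, length(labs), n)
  rates <- matrix(0, length(labs), n)
  kern_n <- max(2L, round(sc$kernel_ms / 1000 * fs))
  kernel <- sc$spike_amp_V * sin(2 * pi * (seq_len(kern_n) - 0.5) / kern_n)
  for (ci in seq_along(labs)) {
    ph <- phi + (sc$phase_lags_deg[ci] + peak_off[ci] * w_phase) / 360
    u <- ph %% 1
    env <- ifelse(u < d, 0.5 * (1 - cos(2 * pi * u / d)), 0)
    modf <- 1 - eff$supp[[dominance[ci]]] * w_sup + eff$reb_fir * w_reb
    dm <- sc$drive_mod_frac
    mod_drive <- 1 - dm * eff$supp[[dominance[ci]]] * w_sup +
      dm * eff$reb_fir * w_reb
    rate <- sc$spike_rate_peak_Hz * env * modf
    rates[ci, ] <- rate
    x <- switch(sc$carrier,
      rate = rate * sc$spike_amp_V,
      spike_train = {
        spikes <- as.numeric(stats::runif(n) < rate / fs)
        as.numeric(stats::filter(spikes, kernel, method = "convolution",
                                 sides = 1))
      },
      filtered_noise = {
        nz <- butter_zerophase(stats::rnorm(n), fs, min(200, fs / 2 - 1),
                               "low")
        nz <- butter_zerophase(nz, fs, 10, "high")
        sc$spike_amp_V * (rate / sc$spike_rate_peak_Hz) *
          nz / stats::sd(nz)
      })
    x[is.na(x)] <- 0
    if (sc$drive_amp_V != 0) x <- x + sc$drive_amp_V * env * mod_drive
    if (sc$noise_sd > 0) x <- x + stats::rnorm(n, 0, sc$noise_sd)
    samples[ci, ] <- x
  }

  if (sc$light$mode == "continuous" && sc$artifact_step_V != 0) {
    samples[, inl] <- samples[, inl] + sc$artifact_step_V
  }
  pulse_times <- numeric(0)
  if (sc$light$mode == "pulse_train" && sc$artifact_pulse_V != 0) {
    pulse_times <- seq(on, off - 1 / sc$light$pulse_rate_Hz,
                       by = 1 / sc$light$pulse_rate_Hz)
    art_n <- max(2L, round(sc$light$pulse_width_ms / 1000 * fs))
    art <- sc$artifact_pulse_V * sin(2 * pi * (seq_len(art_n) - 0.5) / art_n)
    for (pt in pulse_times) {
      i <- round(pt * fs) + 1L
      j <- min(i + art_n - 1L, n)
      samples[, i:j] <- sweep(samples[, i:j, drop = FALSE], 2,
                              art[seq_len(j - i + 1L)], `+`)
    }
  }

  tr <- trial(samples, fs, chans, sc$light,
              trial_id = paste0("t", trial_index),
              experiment_id = paste0("e", experiment_index),
              group_id = group_id, check_fs = FALSE)
  pairs <- find_pairs(chans)
  pair_truth <- lapply(pairs, function(ix) {
    wrap_deg((sc$phase_lags_deg[[ix[1]]] + peak_off[ix[1]] * w_phase) -
               (sc$phase_lags_deg[[ix[2]]] + peak_off[ix[2]] * w_phase))
  })
  # instantaneous frequency of the measured pair signal: the CPG frequency
  # plus the mean rate of change of the two channels' transient phase
  # offsets (a moving phase lag IS a transient frequency excursion)
  pair_freq <- lapply(pairs, function(ix) {
    off_cyc <- (peak_off[ix[1]] + peak_off[ix[2]]) / 2 * w_phase / 360
    freq + c(0, diff(off_cyc)) * fs
  })
  truth <- structure(
    list(time_s = t, freq_Hz = freq, pair_freq_Hz = pair_freq,
         rate_Hz = rates,
         firing_mod = list(
           flexor = 1 - eff$supp[["flexor"]] * w_sup + eff$reb_fir * w_reb,
           extensor = 1 - eff$supp[["extensor"]] * w_sup + eff$reb_fir * w_reb),
         pair_phase_deg = pair_truth,
         channel_labels = labs, f0 = f0, effects = eff),
    class = "ground_truth")
  list(trial = tr, truth = truth)
}

#' Generate two labelled cohorts of experiments
#'
#' Builds every trial of both cohorts (use [run_pipeline()] for large
#' cohorts — it streams generation and processing trial by trial instead
#' of materializing all raw signals). Warns when the two scenarios share
#' a seed, since the cohorts would then reuse random streams.
#'
#' @param scenarioA,scenarioB [synthetic_scenario()]s.
#' @param group_ids Labels for the two cohorts.
#' @return `list(groupA, groupB, truth)`: lists of [experiment()]s plus a
#'   ground-truth bundle (per group, per experiment, per trial).
#' @export
generate_groups <- function(scenarioA, scenarioB,
                            group_ids = c("A", "B")) {
  if (identical(scenarioA$seed, scenarioB$seed)) {
    warning("scenarioA and scenarioB share a seed; cohorts will reuse ",
            "random streams", call. = FALSE)
  }
  one_group <- function(sc, gid) {
    exps <- vector("list", sc$n_experiments)
    truths <- vector("list", sc$n_experiments)
    for (e in seq_len(sc$n_experiments)) {
      gen <- lapply(seq_len(sc$trials_per_experiment), function(k) {
        generate_trial(sc, e, k, group_id = gid)
      })
      exps[[e]] <- experiment(lapply(gen, `[[`, "trial"))
      truths[[e]] <- lapply(gen, `[[`, "truth")
    }
    list(experiments = exps, truth = truths)
  }
  a <- one_group(scenarioA, group_ids[1])
  b <- one_group(scenarioB, group_ids[2])
  list(groupA = a$experiments, groupB = b$experiments,
       truth = list(groupA = a$truth, groupB = b$truth))
}

#' Ground-truth window summaries on the trimmed time base
#'
#' Maps a trial's ground truth onto the trimmed (170-s) record and
#' computes the same normalized window summaries the pipeline estimates:
#' percent frequency change, percent firing change per dominance class,
#' and absolute phase change per pair class, each over the standard
#' windows.
#'
#' @param truth A `ground_truth` from [generate_trial()].
#' @param trim_s Alignment trim (default 5 s).
#' @param control_window,light_window,width_s As in the pipeline
#'   (trimmed time base).
#' @return Nested list: `freq_pct`, `firing_pct$flexor/extensor`,
#'   `abs_phase_deg$<pair class>`, each a named window vector.
#' @export
truth_window_summaries <- function(truth, trim_s = 5,
                                   control_window = c(10, 55),
                                   light_window = c(55, 115),
                                   width_s = 10) {
  tt <- truth$time_s - trim_s
  windows <- list(
    control = c(light_window[1] - width_s, light_window[1]),
    start_light = c(light_window[1], light_window[1] + width_s),
    end_light = c(light_window[2] - width_s, light_window[2]),
    after_light = c(light_window[2], light_window[2] + width_s))
  wmean <- function(v, w) mean(v[tt >= w[1] & tt < w[2]])
  ctrl <- function(v) mean(v[tt >= control_window[1] & tt < control_window[2]])

  # the frequency the pipeline reads out is the bilateral pair's
  # instantaneous frequency (CPG frequency plus transient phase-lag drift)
  ftr <- truth$pair_freq_Hz$bilateral_flexor %||% truth$freq_Hz
  fbar <- ctrl(ftr)
  freq_pct <- vapply(windows, function(w) {
    100 * (wmean(ftr, w) / fbar - 1)
  }, numeric(1))

  firing_pct <- lapply(c(flexor = "flexor", extensor = "extensor"),
                       function(cl) {
    m <- truth$firing_mod[[cl]]
    mbar <- ctrl(m)
    vapply(windows, function(w) 100 * (wmean(m, w) / mbar - 1), numeric(1))
  })

  abs_phase_deg <- lapply(truth$pair_phase_deg, function(ph) {
    rad <- ph[tt >= control_window[1] & tt < control_window[2]] * pi / 180
    base <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
    dev <- abs(wrap_deg(ph - base))
    vapply(windows, function(w) wmean(dev, w), numeric(1))
  })

  list(freq_pct = freq_pct, firing_pct = firing_pct,
       abs_phase_deg = abs_phase_deg)
}

#' Series-level synthetic rhythm cohort
#'
#' Generates per-trial instantaneous-frequency series directly from the
#' generative frequency model (base frequency, light-locked drop and
#' rebound, multiplicative measurement noise with short-range
#' autocorrelation) on the standard 3200-point/170-s time base, skipping
#' raw-signal synthesis. Intended for statistical calibration
#' (type-I-error and power studies of the bootstrap), where hundreds of
#' cohorts are needed.
#'
#' @param sc A [synthetic_scenario()] (series-level fields only are
#'   used).
#' @param noise_frac Multiplicative measurement-noise SD as a fraction
#'   of the local frequency (default 0.02).
#' @param noise_tau_s Autocorrelation time of the measurement noise (s).
#' @param n_time,duration_s Time base (defaults 3200 points / 170 s).
#' @param trim_s Alignment trim already applied (light at
#'   `[60 - trim_s, 120 - trim_s)`).
#' @return List over experiments; each element a list of
#'   `rhythm_series` (one per trial).
#' @export
synth_rhythm_series <- function(sc, noise_frac = 0.02, noise_tau_s = 2,
                                n_time = 3200, duration_s = 170,
                                trim_s = 5) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  dt <- duration_s / n_time
  t <- (seq_len(n_time) - 1) * dt
  on <- sc$light$onset_s - trim_s; off <- sc$light$offset_s - trim_s
  rho <- exp(-dt / noise_tau_s)
  lapply(seq_len(sc$n_experiments), function(e) {
    eff <- exp_effects(sc, e)
    lapply(seq_len(sc$trials_per_experiment), function(k) {
      set.seed(derive_seed(sc$seed, e, k) + 500000L)
      f0 <- eff$f0 + stats::rnorm(1, 0, sc$trial_freq_sd_Hz)
      fac <- rep(1, n_time)
      inl <- t >= on & t < off
      fac[inl] <- 1 - eff$drop * exp(-(t[inl] - on) / sc$light_recovery_tau_s)
      post <- t >= off
      fac[post] <- 1 + eff$reb * exp(-(t[post] - off) / sc$rebound_tau_s)
      eps <- stats::filter(stats::rnorm(n_time, 0,
                                        noise_frac * sqrt(1 - rho^2)),
                           rho, method = "recursive")
      freq <- f0 * fac * (1 + as.numeric(eps))
      structure(list(freq_Hz = freq, power = rep(1, n_time),
                     time_axis_s = t, valid = TRUE,
                     trial_id = paste0("t", k),
                     experiment_id = paste0("e", e)),
                class = "rhythm_series")
    })
  })
}
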